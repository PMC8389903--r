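#!/usr/bin/env Rscript
# Generate the synthetic study systems that stand in for production MD:
# an ideal-gas electrolyte mixture (null model), a Metropolis MC
# Lennard-Jones fluid (correlated structure), Brownian ion tracks with
# planted diffusivities, and a dipole/ion-current process with planted
# susceptibility components. Short excerpts are written in the package's
# interchange formats together with a JSON sidecar of planted truths; the
# full data sets are regenerated deterministically from the recorded seeds
# by the downstream stages, so only excerpts are kept on disk.

suppressPackageStartupMessages(library(kbff))

out_root <- "results/synthetic"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

head_traj <- function(traj, n = 10L) {
  n <- min(n, dim(traj$coords)[1])
  trajectory(traj$coords[seq_len(n), , , drop = FALSE], traj$species,
             traj$box_length, traj$dt, charges = traj$charges)
}

message("ideal-gas mixture (12 ion pairs + 60 solvent, L = 3.2 nm) ...")
ig <- ideal_gas(c("P" = 12, "M" = 12, "W" = 60), n_frames = 300,
                box_length = 3.2, seed = seed)
write_trajectory(head_traj(ig), file.path(out_root, "ideal_gas_head.xyz"))

message("Metropolis MC Lennard-Jones fluid (32 particles, L = 2.2 nm) ...")
ff <- list(A = species_params("A", 0.34, 0.8))
mc <- mc_fluid(c(A = 32), ff, box_length = 2.2, temperature = 300,
               n_sweeps = 300, equil_sweeps = 150, sample_every = 5,
               max_disp = 0.12, seed = seed + 1L)
write_trajectory(head_traj(mc), file.path(out_root, "mc_fluid_head.gro"))
message("  acceptance rate: ", signif(attr(mc, "acceptance"), 3))

message("Brownian electrolyte (planted D+ = 1.5e-3, D- = 1e-3 nm^2/ps) ...")
bw <- brownian(c(P = 64, M = 64), c(P = 1.5e-3, M = 1e-3), n_steps = 2500,
               box_length = 5, dt = 1, seed = seed + 2L)
write_trajectory(head_traj(bw), file.path(out_root, "brownian_head.xyz"))

message("dipole / ion-current process (planted chi = 60 / 4 / 8) ...")
dp <- dipole_process(chi_ww = 60, chi_wi = 4, chi_ii = 8, volume = 274.6,
                     temperature = 300, n_steps = 40000, dt = 0.1,
                     seed = seed + 3L)
head_series <- function(s, n = 500L) {
  scalar_series(s$values[seq_len(min(n, nrow(s$values))), , drop = FALSE],
                s$dt)
}
write_scalar_series(head_series(dp$M), file.path(out_root,
                                                 "box_dipole_head.csv"))
write_scalar_series(head_series(dp$J), file.path(out_root,
                                                 "ion_current_head.csv"))

planted <- list(
  note = paste("files are 10-frame / 500-step excerpts;",
               "regenerate full data from the seeds below"),
  ideal_gas = list(seed = seed, n_frames = 300,
                   truth = "g(r) = 1, G_inf = 0, a_cc = 1"),
  mc_fluid = list(seed = seed + 1L, sigma = 0.34, epsilon = 0.8,
                  temperature = 300,
                  acceptance = attr(mc, "acceptance")),
  brownian = list(seed = seed + 2L, n_steps = 2500,
                  D = list(P = 1.5e-3, M = 1e-3)),
  dipole_process = list(seed = seed + 3L, n_steps = 40000, chi_ww = 60,
                        chi_wi = 4, chi_ii = 8, volume = 274.6,
                        temperature = 300)
)
jsonlite::write_json(planted, file.path(out_root, "planted_truths.json"),
                     auto_unbox = TRUE, pretty = TRUE)
write_run_manifest(out_root, "synth",
                   config = list(excerpt_frames = 10, excerpt_steps = 500),
                   seed = seed)
message("wrote ", out_root, " (format excerpts + planted_truths.json)")
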