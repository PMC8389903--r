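test_that("generators are bit-reproducible under a fixed seed", {
  a <- ideal_gas(20, 5, 3, seed = 41)
  b <- ideal_gas(20, 5, 3, seed = 41)
  expect_identical(a$coords, b$coords)
  c1 <- brownian(c(A = 5), c(A = 1e-3), 50, 3, seed = 41)
  c2 <- brownian(c(A = 5), c(A = 1e-3), 50, 3, seed = 41)
  expect_identical(c1$coords, c2$coords)
  expect_false(identical(a$coords, ideal_gas(20, 5, 3, seed = 42)$coords))
})

test_that("ideal-gas RDF is flat at 1 within 3 standard errors", {
  traj <- ideal_gas(c(A = 40), 300, box_length = 3, seed = 43)
  rdf <- radial_distribution(traj, c("A", "A"), bin_width = 0.1)
  # analytic null SE: bin counts are Poisson with the ideal-gas expectation
  expected <- 300 * (40 * 39 / 2) *
    4 * pi / 3 * (rdf$r_hi^3 - rdf$r_lo^3) / 3^3
  se_g <- 1 / sqrt(expected)
  keep <- rdf$r_mid > 0.3   # skip low-count innermost bins
  expect_true(all(abs(rdf$g[keep] - 1) <= 3 * se_g[keep]))
})

test_that("ideal-gas KB integrals vanish within the blocking CI", {
  traj <- ideal_gas(c(A = 40), 300, box_length = 3, seed = 44)
  kb <- kb_chain(traj, c("A", "A"), bin_width = 0.05)
  blocks <- vapply(1:5, function(b) {
    frames <- ((b - 1) * 60 + 1):(b * 60)
    kb_chain(traj, c("A", "A"), bin_width = 0.05, frames = frames)$G_infinity
  }, numeric(1))
  se <- sd(blocks) / sqrt(5)
  expect_lt(abs(kb$G_infinity), 3 * se + 1e-3)
})

test_that("ideal gas rejects degenerate boxes", {
  expect_error(ideal_gas(10, 5, 0), "box_length")
  expect_error(ideal_gas(1, 5, 2), "2 particles")
})

test_that("MC fluid shows excluded volume below sigma", {
  ff <- lj_test_ff()
  traj <- mc_fluid(c(A = 32), ff, box_length = 2.2, temperature = 300,
                   n_sweeps = 200, equil_sweeps = 100, sample_every = 5,
                   max_disp = 0.12, seed = 45)
  rdf <- radial_distribution(traj, c("A", "A"), bin_width = 0.02)
  expect_equal(max(rdf$g[rdf$r_mid < 0.25]), 0)
  expect_gt(max(rdf$g), 1)   # first solvation shell
  expect_true(attr(traj, "acceptance") > 0.05 &&
                attr(traj, "acceptance") < 0.95)
})

test_that("two-particle MC matches the direct Boltzmann quadrature", {
  ff <- list(A = species_params("A", 0.34, 1.2))
  L <- 1.6
  traj <- mc_fluid(c(A = 2), ff, box_length = L, temperature = 300,
                   n_sweeps = 6000, equil_sweeps = 500, sample_every = 2,
                   max_disp = 0.5, seed = 46)
  bw <- 0.05
  rdf <- radial_distribution(traj, c("A", "A"), bin_width = bw)
  # oracle: p(r) proportional to r^2 exp(-beta u(r)) for r < L/2
  pair <- combine_lorentz_berthelot(ff$A, ff$A, cutoff = min(0.9, L / 2))
  beta <- 1 / thermal_energy(300)
  dense_r <- seq(1e-3, L / 2, length.out = 4000)
  dens <- dense_r^2 * exp(-beta * lj_potential_shifted(dense_r, pair))
  bin_of <- pmin(floor(dense_r / bw) + 1L, nrow(rdf))
  p_oracle <- tapply(dens, bin_of, sum)
  p_oracle <- p_oracle / sum(p_oracle)
  p_sim <- rdf$counts / sum(rdf$counts)
  # multinomial SE on the simulated histogram (frames are correlated: allow 5x)
  n_obs <- sum(rdf$counts)
  se <- sqrt(p_oracle * (1 - p_oracle) / n_obs)
  expect_true(all(abs(p_sim - p_oracle) < 5 * se + 0.01))
})

test_that("MC energy histogram reweights consistently across temperatures", {
  ff <- list(A = species_params("A", 0.34, 1.0))
  run <- function(temp, seed) {
    tr <- mc_fluid(c(A = 16), ff, box_length = 1.8, temperature = temp,
                   n_sweeps = 600, equil_sweeps = 200, sample_every = 2,
                   max_disp = 0.15, seed = seed)
    attr(tr, "energy_trace")
  }
  e1 <- run(300, 47)
  e2 <- run(330, 48)
  beta1 <- 1 / thermal_energy(300); beta2 <- 1 / thermal_energy(330)
  w <- exp(-(beta2 - beta1) * (e1 - mean(e1)))
  reweighted_mean <- sum(w * e1) / sum(w)
  se <- sqrt(block_average_error(e1, 5)^2 + block_average_error(e2, 5)^2)
  expect_lt(abs(reweighted_mean - mean(e2)), 6 * se + 0.05 * abs(mean(e2)))
})

test_that("Brownian generator plants recoverable diffusion constants", {
  traj <- brownian(c(A = 256), c(A = 1e-3), n_steps = 3000, box_length = 5,
                   dt = 1, seed = 49)
  msd <- mean_squared_displacement(unwrap(traj), "A", max_lag = 600,
                                   lag_stride = 10)
  fit <- fit_self_diffusion(msd, window = c(30, 600))
  expect_lt(abs(fit$D_sim - 1e-3) / 1e-3, 0.05)
})

test_that("zero-diffusion species are immobile", {
  traj <- brownian(c(A = 5), c(A = 0), n_steps = 50, box_length = 2, seed = 50)
  msd <- mean_squared_displacement(unwrap(traj), "A")
  expect_equal(msd$msd, rep(0, nrow(msd)))
})

test_that("a planted 2:1 diffusivity ratio between species is recovered", {
  traj <- brownian(c(P = 48, M = 48), c(P = 2e-3, M = 1e-3), n_steps = 2500,
                   box_length = 5, dt = 1, seed = 51)
  un <- unwrap(traj)
  Dp <- fit_self_diffusion(mean_squared_displacement(un, "P", lag_stride = 15))
  Dm <- fit_self_diffusion(mean_squared_displacement(un, "M", lag_stride = 15))
  ratio_se <- 2 * sqrt((Dp$D_stderr / Dp$D_sim)^2 + (Dm$D_stderr / Dm$D_sim)^2)
  expect_lt(abs(Dp$D_sim / Dm$D_sim - 2), 2 + 20 * ratio_se)
  expect_lt(abs(Dp$D_sim / Dm$D_sim - 2), 0.25)
})

test_that("Brownian generator validates dt and D", {
  expect_error(brownian(c(A = 3), c(A = 1e-3), 10, 2, dt = 0), "dt")
  expect_error(brownian(c(A = 3), c(A = -1), 10, 2), ">= 0")
  expect_error(brownian(c(A = 3), c(B = 1), 10, 2), "every species")
})

test_that("dipole process with independent M and J has zero cross term", {
  dp <- dipole_process(chi_ww = 40, chi_wi = 0, chi_ii = 6, volume = 200,
                       temperature = 300, n_steps = 30000, seed = 52)
  sus <- susceptibility_components(dp$M, dp$J, 200, 300)
  # CI from 5-block averaging of the instantaneous cross product
  expect_lt(abs(sus$chi_wi), 0.15 * sqrt(40 * 6))
})

test_that("dipole process with silent ions gives exactly zero ion terms", {
  dp <- dipole_process(chi_ww = 40, chi_wi = 0, chi_ii = 0, volume = 200,
                       temperature = 300, n_steps = 5000, seed = 53)
  expect_equal(max(abs(dp$J$values)), 0)
  sus <- susceptibility_components(dp$M, dp$J, 200, 300)
  expect_identical(sus$chi_ii, 0)
  expect_identical(sus$chi_wi, 0)
})

test_that("dipole process validates correlation times and planted values", {
  expect_error(dipole_process(1, 0, 1, 100, 300, tau_w = 0), "correlation")
  expect_error(dipole_process(1, 5, 1, 100, 300), "Cauchy")
})

test_that("mock backend has zero objective exactly at the planted optimum", {
  be <- mock_backend()
  m <- seq(0.5, 4.5, by = 0.5)
  ref <- lapply(setNames(nm = be$salts), function(s) be$reference_curve(s, m))
  spec <- objective_spec(ref, m)
  sim <- lapply(setNames(nm = be$salts), function(s) {
    ions <- be$salt_ions[[s]]
    be$activity_curve(s, be$planted[[ions[1]]], be$planted[[ions[2]]], m)
  })
  expect_equal(objective_k(sim, spec), 0)
})

test_that("mock backend free-energy isolines pass through the planted point", {
  be <- mock_backend()
  planted_na <- be$planted$`Na+`
  F_at_planted <- be$pair_free_energy("NaCl", planted_na, be$planted$`Cl-`)
  iso <- free_energy_isoline(be, "NaCl", be$planted$`Cl-`, F_at_planted,
                             eps_grid = c(0.25, planted_na[["epsilon"]], 0.8))
  hit <- iso[abs(iso$epsilon - planted_na[["epsilon"]]) < 1e-9, ]
  expect_equal(hit$sigma, planted_na[["sigma"]], tolerance = 1e-3)
})

test_that("mock backend rejects parameters outside its domain", {
  be <- mock_backend()
  expect_error(be$pair_free_energy("NaCl", c(sigma = 0.05, epsilon = 0.5),
                                   be$planted$`Cl-`), "domain")
})
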