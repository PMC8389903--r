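#' Ideal-gas configurations (uncorrelated uniform positions)
#'
#' Null model for pair-structure estimators: every frame is an independent
#' draw of uniform particle positions, so g(r) = 1 in expectation for all
#' species pairs and every Kirkwood-Buff integral vanishes.
#'
#' @param n_particles Total particle count (>= 2) or a named vector of counts
#'   per species, e.g. `c("Na+" = 10, "Cl-" = 10, W = 100)`.
#' @param n_frames Number of frames.
#' @param box_length Cubic box edge in nm, > 0.
#' @param dt Frame spacing in ps. Default 1.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A [trajectory()] with attribute `"planted"` recording the spec.
#' @export
ideal_gas <- function(n_particles, n_frames, box_length, dt = 1, seed = 1L) {
  if (box_length <= 0) stop("box_length must be > 0")
  if (is.null(names(n_particles))) {
    stopifnot(length(n_particles) == 1L)
    if (n_particles < 2) stop("need at least 2 particles")
    species <- rep("A", n_particles)
  } else {
    species <- rep(names(n_particles), times = n_particles)
  }
  np <- length(species)
  if (np < 2) stop("need at least 2 particles")
  set.seed(seed)
  coords <- array(stats::runif(n_frames * np * 3, 0, box_length),
                  dim = c(n_frames, np, 3))
  traj <- trajectory(coords, species, box_length, dt)
  attr(traj, "planted") <- list(kind = "ideal-gas", seed = seed)
  traj
}

#' Metropolis Monte Carlo sampling of a Lennard-Jones(-Coulomb) fluid
#'
#' Samples equilibrium configurations of a truncated-and-shifted
#' Lennard-Jones fluid (optionally with minimum-image Coulomb interactions)
#' by single-particle Metropolis moves. This replaces molecular dynamics for
#' pair-structure work: the Kirkwood-Buff estimators only require equilibrium
#' configurations, not dynamics. Intended for small systems (N <= 200).
#'
#' @param composition Named integer vector of particle counts per species.
#' @param forcefield Named list of [species_params()] covering all species.
#' @param box_length Cubic box edge in nm.
#' @param temperature Temperature in K.
#' @param n_sweeps Production sweeps (one sweep = N single-particle moves).
#' @param equil_sweeps Discarded equilibration sweeps.
#' @param sample_every Store a frame every this many sweeps.
#' @param max_disp Maximum displacement per move in nm.
#' @param coulomb Include minimum-image Coulomb interactions (toy, no Ewald).
#' @param cutoff Lennard-Jones cutoff in nm (capped at L/2).
#' @param seed Integer seed.
#' @return A [trajectory()] with attributes `"planted"` (spec), `"acceptance"`
#'   (acceptance rate) and `"energy_trace"` (per-sweep total energy).
#' @export
mc_fluid <- function(composition, forcefield, box_length, temperature,
                     n_sweeps = 500L, equil_sweeps = 200L, sample_every = 5L,
                     max_disp = 0.05, coulomb = FALSE, cutoff = 0.9,
                     seed = 1L) {
  species <- rep(names(composition), times = composition)
  np <- length(species)
  stopifnot(np >= 2, box_length > 0, temperature > 0)
  if (np > 200) stop("mc_fluid is a desk-scale sampler; use N <= 200")
  missing_sp <- setdiff(unique(species), names(forcefield))
  if (length(missing_sp)) stop("species missing from force field: ",
                               paste(missing_sp, collapse = ", "))
  cutoff <- min(cutoff, box_length / 2)
  beta <- 1 / thermal_energy(temperature)
  sig <- vapply(species, function(s) forcefield[[s]]$sigma, numeric(1))
  eps <- vapply(species, function(s) forcefield[[s]]$epsilon, numeric(1))
  chg <- vapply(species, function(s) forcefield[[s]]$charge, numeric(1))

  # Lorentz-Berthelot arrays against every other particle (computed per move)
  set.seed(seed)
  # start from a cubic lattice to avoid overlaps
  n_side <- ceiling(np^(1 / 3))
  lat <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                               z = seq_len(n_side)))[seq_len(np), ]
  pos <- (lat - 0.5) * (box_length / n_side)
  pos <- pos[sample.int(np), , drop = FALSE]  # randomize species placement

  pair_energy_one <- function(i, xi) {
    d <- sweep(pos, 2, xi, "-")
    d <- minimum_image(d, box_length)
    r2 <- rowSums(d * d)
    r2[i] <- Inf
    inside <- which(r2 < cutoff^2)
    if (!length(inside)) return(0)
    r <- sqrt(r2[inside])
    sij <- (sig[i] + sig[inside]) / 2
    eij <- sqrt(eps[i] * eps[inside])
    sr6 <- (sij / r)^6
    sc6 <- (sij / cutoff)^6
    u <- sum(4 * eij * ((sr6^2 - sr6) - (sc6^2 - sc6)))
    if (coulomb) {
      # toy minimum-image Coulomb over all pairs (no cutoff, no Ewald)
      rall <- sqrt(r2)
      u <- u + kbff_constants$f_coulomb * chg[i] * sum(chg[-i] / rall[-i])
    }
    u
  }

  total_energy <- function() {
    e <- 0
    for (i in seq_len(np - 1)) {
      d <- sweep(pos[(i + 1):np, , drop = FALSE], 2, pos[i, ], "-")
      d <- minimum_image(d, box_length)
      r2 <- rowSums(d * d)
      inside <- which(r2 < cutoff^2)
      if (length(inside)) {
        r <- sqrt(r2[inside])
        jj <- ((i + 1):np)[inside]
        sij <- (sig[i] + sig[jj]) / 2
        eij <- sqrt(eps[i] * eps[jj])
        sr6 <- (sij / r)^6
        sc6 <- (sij / cutoff)^6
        e <- e + sum(4 * eij * ((sr6^2 - sr6) - (sc6^2 - sc6)))
      }
      if (coulomb) {
        r <- sqrt(r2)
        e <- e + kbff_constants$f_coulomb * chg[i] * sum(chg[(i + 1):np] / r)
      }
    }
    e
  }

  n_acc <- 0L; n_try <- 0L
  frames <- list(); energy_trace <- numeric(0)
  total_sweeps <- equil_sweeps + n_sweeps
  for (sweep_i in seq_len(total_sweeps)) {
    for (mv in seq_len(np)) {
      i <- sample.int(np, 1L)
      old <- pos[i, ]
      e_old <- pair_energy_one(i, old)
      new <- (old + stats::runif(3, -max_disp, max_disp)) %% box_length
      e_new <- pair_energy_one(i, new)
      n_try <- n_try + 1L
      if (e_new <= e_old || stats::runif(1) < exp(-beta * (e_new - e_old))) {
        pos[i, ] <- new
        n_acc <- n_acc + 1L
      }
    }
    if (sweep_i > equil_sweeps) {
      prod_i <- sweep_i - equil_sweeps
      energy_trace <- c(energy_trace, total_energy())
      if (prod_i %% sample_every == 0L) frames[[length(frames) + 1L]] <- pos
    }
  }
  acc <- n_acc / n_try
  if (acc < 0.05 || acc > 0.95) {
    warning("Metropolis acceptance rate ", signif(acc, 3),
            " outside (0.05, 0.95); tune max_disp")
  }
  # non-ergodicity screen: drift of the first vs last energy block mean
  # against their within-block (sub-blocked) standard errors
  if (length(energy_trace) >= 250) {
    bm <- block_means(energy_trace, 5L)
    bl <- length(energy_trace) %/% 5L
    se_first <- block_average_error(energy_trace[seq_len(bl)], 5L)
    se_last <- block_average_error(energy_trace[((4L * bl) + 1L):(5L * bl)], 5L)
    se <- sqrt(se_first^2 + se_last^2)
    if (se > 0 && abs(bm[5] - bm[1]) > 6 * se) {
      stop("energy trace non-stationary (first/last block means differ by > 6 SE);",
           " increase equil_sweeps")
    }
  }
  coords <- array(0, dim = c(length(frames), np, 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]
  traj <- trajectory(coords, species, box_length, dt = sample_every,
                     charges = chg)
  attr(traj, "planted") <- list(kind = "mc-fluid", seed = seed,
                                temperature = temperature, cutoff = cutoff)
  attr(traj, "acceptance") <- acc
  attr(traj, "energy_trace") <- energy_trace
  traj
}

#' Brownian (overdamped) trajectories with planted diffusion constants
#'
#' Independent Gaussian displacements with variance 2 D dt per Cartesian
#' component per step, per species. Coordinates are stored wrapped into the
#' box; [unwrap()] recovers the continuous tracks exactly as long as single
#' steps stay below L/2.
#'
#' @param composition Named integer vector of particle counts per species.
#' @param D Named vector of diffusion constants per species in nm^2/ps (>= 0).
#' @param n_steps Number of stored frames.
#' @param box_length Cubic box edge in nm.
#' @param dt Time step between stored frames in ps, > 0.
#' @param seed Integer seed.
#' @return A wrapped [trajectory()] with attribute `"planted"` carrying the
#'   per-species D.
#' @export
brownian <- function(composition, D, n_steps, box_length, dt = 1, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  species <- rep(names(composition), times = composition)
  np <- length(species)
  stopifnot(np >= 1, n_steps >= 2, box_length > 0)
  if (!all(unique(species) %in% names(D))) {
    stop("D must name every species in the composition")
  }
  Dp <- D[species]
  if (any(Dp < 0)) stop("diffusion constants must be >= 0")
  set.seed(seed)
  sd_step <- sqrt(2 * Dp * dt)   # per component, per particle
  coords <- array(0, dim = c(n_steps, np, 3))
  coords[1, , ] <- matrix(stats::runif(np * 3, 0, box_length), ncol = 3)
  steps <- array(0, dim = c(n_steps - 1, np, 3))
  for (c3 in 1:3) {
    steps[, , c3] <- sweep(matrix(stats::rnorm((n_steps - 1) * np),
                                  ncol = np), 2, sd_step, "*")
  }
  for (k in 2:n_steps) coords[k, , ] <- coords[k - 1, , ] + steps[k - 1, , ]
  coords <- coords %% box_length
  traj <- trajectory(coords, species, box_length, dt)
  attr(traj, "planted") <- list(kind = "brownian", seed = seed, D = D)
  traj
}

# exact stationary Ornstein-Uhlenbeck path with unit variance per component
.ou_path <- function(n, dt, tau, ncomp = 3L) {
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(1 - phi^2)
  x <- matrix(0, nrow = n, ncol = ncomp)
  x[1, ] <- stats::rnorm(ncomp)
  eta <- matrix(stats::rnorm((n - 1) * ncomp), ncol = ncomp)
  for (k in 2:n) x[k, ] <- phi * x[k - 1, ] + innov_sd * eta[k - 1, ]
  x
}

#' Box-dipole and ion-current processes with planted susceptibilities
#'
#' Generates stationary Gaussian (Ornstein-Uhlenbeck) vector processes for
#' the water box dipole M(t) and the integrated ion dipole M_I(t), emitting
#' the ion current J(t) as the exact discrete time derivative of M_I. The
#' planted zero-frequency susceptibility contributions (water, cross, ion)
#' are fixed by the planted variances and the cross correlation:
#' chi_ww = <dM^2>/(3 eps0 V kBT), chi_wi = 2 <dM.dM_I>/(3 eps0 V kBT),
#' chi_ii = <dM_I^2>/(3 eps0 V kBT).
#'
#' @param chi_ww,chi_ii Planted water-dipole and ion contributions (>= 0).
#' @param chi_wi Planted cross contribution; requires
#'   `chi_wi^2 <= 4 chi_ww chi_ii`.
#' @param volume Box volume in nm^3.
#' @param temperature Temperature in K.
#' @param n_steps Number of frames.
#' @param dt Frame spacing in ps.
#' @param tau_w,tau_i Correlation times (ps) of the water and ion processes, > 0.
#' @param seed Integer seed.
#' @return A list with elements `M` and `J` ([scalar_series()] vectors of
#'   length `n_steps - 1`, aligned), and `planted` (the planted components).
#' @export
dipole_process <- function(chi_ww, chi_wi, chi_ii, volume, temperature,
                           n_steps = 20000L, dt = 0.1, tau_w = 1, tau_i = 1,
                           seed = 1L) {
  if (tau_w <= 0 || tau_i <= 0) stop("correlation times must be > 0")
  stopifnot(chi_ww >= 0, chi_ii >= 0, volume > 0, temperature > 0, n_steps >= 10)
  if (chi_wi^2 > 4 * chi_ww * chi_ii + 1e-12) {
    stop("chi_wi^2 must not exceed 4 * chi_ww * chi_ii (Cauchy-Schwarz)")
  }
  # scale: chi = 4 pi f <dM^2> / (3 V kBT) with <dM^2> = 3 * var per component
  kT <- thermal_energy(temperature)
  scale2 <- function(chi) chi * volume * kT / (4 * pi * kbff_constants$f_coulomb)
  a <- sqrt(scale2(chi_ww))            # per-component sd of M_w
  b <- sqrt(scale2(chi_ii))            # per-component sd of M_I
  rho <- if (a > 0 && b > 0) chi_wi * volume * kT /
    (4 * pi * kbff_constants$f_coulomb) / (2 * a * b) else 0
  set.seed(seed)
  X <- .ou_path(n_steps, dt, tau_w)
  Y <- .ou_path(n_steps, dt, tau_i)
  Mw <- a * X
  MI <- b * (rho * X + sqrt(max(0, 1 - rho^2)) * Y)
  J <- (MI[-1, , drop = FALSE] - MI[-n_steps, , drop = FALSE]) / dt
  M <- Mw[-n_steps, , drop = FALSE]
  list(M = scalar_series(M, dt),
       J = scalar_series(J, dt),
       planted = list(chi_ww = chi_ww, chi_wi = chi_wi, chi_ii = chi_ii,
                      volume = volume, temperature = temperature, seed = seed))
}

#' Analytic observable backend with a planted optimum
#'
#' Stand-in for the expensive simulation layer during optimizer work: a
#' smooth analytic map from ion Lennard-Jones parameters to salt pair
#' solvation free energies and activity-derivative curves, constructed so
#' that (a) each ion's planted (sigma*, eps*) lies on the isoline of its
#' salts' target pair free energies, and (b) the activity objective has its
#' global minimum exactly at the planted parameter set.
#'
#' The pair free energy responds linearly to both ions,
#' \deqn{F_{pair} = F^*_{salt} + A (\sigma_c - \sigma_c^*) + B (\epsilon_c - \epsilon_c^*)
#'                          + A (\sigma_a - \sigma_a^*) + B (\epsilon_a - \epsilon_a^*),}
#' and the activity curve responds linearly with ion- and
#' direction-specific molality profiles,
#' \deqn{a_{cc}(m) = a^{ref}_{salt}(m) + C\left[\frac{\Delta\sigma_c}{s_\sigma}
#'   + \frac{\Delta\epsilon_c}{s_\epsilon}\frac{m}{5}
#'   + \frac{\Delta\sigma_a}{s_\sigma}\sqrt{m/5}
#'   + \frac{\Delta\epsilon_a}{s_\epsilon}\left(\frac{m}{5}\right)^2\right],}
#' so the activity objective is a positive-definite quadratic form in the
#' parameter deviations (the four profiles are linearly independent) with its
#' global minimum, value zero, exactly at the planted set. Optional iid
#' Gaussian observation noise is added to a_cc.
#'
#' @param planted Named list of planted `c(sigma, epsilon)` per ion; defaults
#'   to the optimized table ([ion_table()]).
#' @param targets Named vector of target pair free energies per salt
#'   (kJ/mol); defaults to round illustrative values.
#' @param A,B Linear free-energy sensitivities (kJ/mol per nm, per kJ/mol).
#' @param C Curvature of the activity penalty. Default 2.
#' @param s_sigma,s_epsilon Penalty scales (nm, kJ/mol).
#' @param noise_sd Gaussian observation noise on a_cc. Default 0.
#' @param seed Seed for the observation noise stream.
#' @return An object of class `observable_backend`: a list with functions
#'   `pair_free_energy(cation, anion)` and
#'   `activity_curve(salt, params, molalities)`, plus the planted truth.
#' @export
mock_backend <- function(planted = NULL, targets = NULL,
                         A = -300, B = 40, C = 2,
                         s_sigma = 0.05, s_epsilon = 0.3,
                         noise_sd = 0, seed = 1L) {
  if (is.null(planted)) {
    tab <- ion_table()
    planted <- lapply(tab, function(p) c(sigma = p$sigma, epsilon = p$epsilon))
  }
  if (is.null(targets)) {
    targets <- c("NaCl" = -720, "KCl" = -650, "NaBr" = -690, "KBr" = -620)
  }
  salt_ions <- list("NaCl" = c("Na+", "Cl-"), "KCl" = c("K+", "Cl-"),
                    "NaBr" = c("Na+", "Br-"), "KBr" = c("K+", "Br-"))
  domain <- list(sigma = c(0.1, 0.7), epsilon = c(0.01, 3))
  check_domain <- function(p) {
    if (p[["sigma"]] < domain$sigma[1] || p[["sigma"]] > domain$sigma[2] ||
        p[["epsilon"]] < domain$epsilon[1] || p[["epsilon"]] > domain$epsilon[2]) {
      stop("parameters outside backend domain: sigma in [",
           domain$sigma[1], ", ", domain$sigma[2], "], epsilon in [",
           domain$epsilon[1], ", ", domain$epsilon[2], "]")
    }
  }
  ion_dev <- function(name, p) {
    check_domain(p)
    st <- planted[[name]]
    c(ds = p[["sigma"]] - st[["sigma"]], de = p[["epsilon"]] - st[["epsilon"]])
  }
  # reference a_cc curves: Debye-Hueckel-like decay plus salt-specific slope
  slope <- c("NaCl" = 0.10, "KCl" = 0.04, "NaBr" = 0.12, "KBr" = 0.06)
  a_ref <- function(salt, m) {
    1 - 0.45 * sqrt(m) / (1 + 1.2 * sqrt(m)) + slope[[salt]] * m / 5
  }
  rng_state <- seed
  backend <- list(
    salts = names(salt_ions),
    salt_ions = salt_ions,
    planted = planted,
    targets = targets,
    reference_curve = function(salt, molalities) {
      data.frame(molality = molalities, a_cc = a_ref(salt, molalities))
    },
    pair_free_energy = function(salt, cation_params, anion_params) {
      ions <- salt_ions[[salt]]
      dc <- ion_dev(ions[1], cation_params)
      da <- ion_dev(ions[2], anion_params)
      targets[[salt]] + A * (dc[["ds"]] + da[["ds"]]) +
        B * (dc[["de"]] + da[["de"]])
    },
    activity_curve = function(salt, cation_params, anion_params, molalities) {
      ions <- salt_ions[[salt]]
      dc <- ion_dev(ions[1], cation_params)
      da <- ion_dev(ions[2], anion_params)
      x <- molalities / 5
      pen <- C * (dc[["ds"]] / s_sigma +
                  dc[["de"]] / s_epsilon * x +
                  da[["ds"]] / s_sigma * sqrt(x) +
                  da[["de"]] / s_epsilon * x^2)
      vals <- a_ref(salt, molalities) + pen
      if (noise_sd > 0) {
        set.seed(rng_state)
        rng_state <<- rng_state + 1L
        vals <- vals + stats::rnorm(length(vals), 0, noise_sd)
      }
      data.frame(molality = molalities, a_cc = vals)
    }
  )
  class(backend) <- "observable_backend"
  backend
}
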