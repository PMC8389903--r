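make_spec <- function(backend, m = seq(0.5, 4.5, by = 0.5)) {
  ref <- lapply(setNames(nm = backend$salts),
                function(s) backend$reference_curve(s, m))
  objective_spec(ref, m)
}

test_that("objective algebra: uniform offsets give delta^2 exactly", {
  m <- seq(0.5, 4.5, by = 0.5)
  ref <- list(NaCl = data.frame(molality = m, a_cc = 0.9),
              KCl = data.frame(molality = m, a_cc = 0.95))
  spec1 <- objective_spec(ref["NaCl"], m, "NaCl")
  delta <- 0.07
  sim <- list(NaCl = data.frame(molality = m, a_cc = 0.9 + delta))
  expect_equal(objective_k(sim, spec1), delta^2)
  # identical curves give zero
  expect_equal(objective_k(list(NaCl = ref$NaCl), spec1), 0)
  # two salts with offsets d1, d2: (d1^2 + d2^2)/2
  d1 <- 0.05; d2 <- -0.11
  spec2 <- objective_spec(ref, m)
  sim2 <- list(NaCl = data.frame(molality = m, a_cc = 0.9 + d1),
               KCl = data.frame(molality = m, a_cc = 0.95 + d2))
  expect_equal(objective_k(sim2, spec2), (d1^2 + d2^2) / 2)
  expect_error(objective_k(sim2["NaCl"], spec2), "missing")
})

test_that("objective is invariant under permutation of salts and molalities", {
  set.seed(111)
  m <- seq(0.25, 4.75, by = 0.25)
  ref <- list(A = data.frame(molality = m, a_cc = runif(length(m))),
              B = data.frame(molality = m, a_cc = runif(length(m))))
  sim <- list(B = data.frame(molality = m, a_cc = runif(length(m))),
              A = data.frame(molality = m, a_cc = runif(length(m))))
  k1 <- objective_k(sim, objective_spec(ref, m, c("A", "B")))
  k2 <- objective_k(sim, objective_spec(ref, m, c("B", "A")))
  expect_equal(k1, k2)
  # reversing the molality order of a simulated curve changes nothing
  sim_rev <- sim
  sim_rev$A <- sim_rev$A[nrow(sim_rev$A):1, ]
  sim_rev$A <- data.frame(molality = sim_rev$A$molality,
                          a_cc = sim_rev$A$a_cc)
  expect_equal(objective_k(sim_rev, objective_spec(ref, m, c("A", "B"))),
               k1, tolerance = 1e-12)
})

test_that("objective spec enforces the open molality range (0, 5)", {
  ref <- list(A = data.frame(molality = 1:4, a_cc = 1))
  expect_error(objective_spec(ref, c(0, 1)), "strictly inside")
  expect_error(objective_spec(ref, c(1, 5)), "strictly inside")
})

test_that("isoline candidates satisfy the free-energy target", {
  be <- mock_backend()
  target <- be$targets[["KCl"]]
  iso <- free_energy_isoline(be, "KCl", be$planted$`Cl-`, target,
                             eps_grid = seq(0.3, 1.5, by = 0.2))
  expect_gt(nrow(iso), 0)
  for (r in seq_len(nrow(iso))) {
    F_r <- be$pair_free_energy("KCl",
                               c(sigma = iso$sigma[r],
                                 epsilon = iso$epsilon[r]),
                               be$planted$`Cl-`)
    expect_lt(abs(F_r - target), 0.5)   # |dF/dsigma| * 0.001 nm tolerance
  }
})

test_that("unattainable free-energy targets yield an empty-isoline error", {
  be <- mock_backend()
  expect_error(
    suppressMessages(free_energy_isoline(be, "KCl", be$planted$`Cl-`,
                                         -1e5, eps_grid = c(0.4, 0.8))),
    "empty isoline")
})

test_that("noiseless optimization recovers the planted parameters on-grid", {
  be <- mock_backend()
  spec <- make_spec(be)
  grid <- expand.grid(sigma = seq(0.40, 0.46, by = 0.01),
                      epsilon = seq(0.32, 0.52, by = 0.05))
  res <- optimize_salt_family(grid, be, spec,
                              cation_eps_grid = seq(0.2, 1.4, by = 0.05))
  expect_equal(res$best$sigma, 0.43)
  expect_equal(res$best$epsilon, 0.42)
  expect_lt(res$best$k, 1e-4)
  ffp <- res$forcefield
  expect_equal(ffp$`Na+`$sigma, 0.231, tolerance = 2e-3)
  expect_equal(ffp$`Na+`$epsilon, 0.45, tolerance = 0.05)
  expect_equal(ffp$`K+`$sigma, 0.283, tolerance = 2e-3)
  expect_equal(ffp$`Br-`$sigma, 0.443, tolerance = 0.01)
  expect_equal(ffp$`Br-`$epsilon, 0.75, tolerance = 0.05)
  # interpolated minimum stays inside the sampled rectangle
  expect_true(res$interpolated_minimum$sigma >= min(grid$sigma) &&
                res$interpolated_minimum$sigma <= max(grid$sigma))
  expect_true(res$interpolated_minimum$epsilon >= min(grid$epsilon) &&
                res$interpolated_minimum$epsilon <= max(grid$epsilon))
})

test_that("interpolation refines an off-grid optimum", {
  be <- mock_backend(planted = list(
    "K+" = c(sigma = 0.283, epsilon = 0.90),
    "Na+" = c(sigma = 0.231, epsilon = 0.45),
    "Cl-" = c(sigma = 0.435, epsilon = 0.445),  # between grid nodes
    "Br-" = c(sigma = 0.443, epsilon = 0.75)))
  spec <- make_spec(be)
  grid <- expand.grid(sigma = seq(0.40, 0.47, by = 0.01),
                      epsilon = seq(0.32, 0.57, by = 0.05))
  res <- optimize_salt_family(grid, be, spec,
                              cation_eps_grid = seq(0.2, 1.4, by = 0.05))
  truth <- c(0.435, 0.445)
  d_best <- sqrt(sum((c(res$best$sigma, res$best$epsilon) - truth)^2))
  d_interp <- sqrt(sum((c(res$interpolated_minimum$sigma,
                          res$interpolated_minimum$epsilon) - truth)^2))
  expect_lt(d_interp, d_best)
})

test_that("a single-point chloride grid is returned with a warning", {
  be <- mock_backend()
  spec <- make_spec(be)
  grid <- data.frame(sigma = 0.43, epsilon = 0.42)
  expect_warning(res <- optimize_salt_family(grid, be, spec,
                                             cation_eps_grid = seq(0.3, 1.3,
                                                                   by = 0.1)),
                 "single-point")
  expect_equal(res$best$sigma, 0.43)
  expect_null(res$interpolated_minimum)
})

test_that("observation noise sets the objective floor at the true optimum", {
  m <- seq(0.5, 4.5, by = 0.5)
  s_noise <- 0.05
  ks <- vapply(1:40, function(s) {
    be <- mock_backend(noise_sd = s_noise, seed = 7000 + s * 13)
    spec <- make_spec(be, m)
    sim <- lapply(setNames(nm = be$salts), function(salt) {
      ions <- be$salt_ions[[salt]]
      be$activity_curve(salt, be$planted[[ions[1]]], be$planted[[ions[2]]], m)
    })
    objective_k(sim, spec)
  }, numeric(1))
  # E[k] = s^2; the mean over 40 seeds x 4 salts x 9 molalities is tight
  expect_lt(abs(mean(ks) - s_noise^2), 0.2 * s_noise^2)
})

test_that("interpolated minimum of a quadratic landscape matches analytics", {
  sg <- seq(-1, 1, by = 0.25); eg <- seq(-1, 1, by = 0.25)
  grid <- expand.grid(sigma = sg, epsilon = eg)
  truth <- c(0.13, -0.31)
  grid$k <- (grid$sigma - truth[1])^2 + 0.5 * (grid$epsilon - truth[2])^2
  interp <- kbff:::.bicubic_min(grid)
  expect_lt(abs(interp$sigma - truth[1]), 0.25 / 2)
  expect_lt(abs(interp$epsilon - truth[2]), 0.25 / 2)
})
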