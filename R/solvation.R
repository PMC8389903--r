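#' Thermodynamic-integration record
#'
#' Holds the lambda grid of ensemble averages <dH/dlambda> for one coupling
#' stage (Lennard-Jones growth or charging).
#'
#' @param lambda Coupling values in [0, 1], sorted, unique.
#' @param dHdl_mean Mean of dH/dlambda at each state, kJ/mol.
#' @param dHdl_err Standard error at each state, kJ/mol (>= 0). Default 0.
#' @param stage "lj-growth" or "charging".
#' @return An object of class `ti_record`.
#' @export
ti_record <- function(lambda, dHdl_mean, dHdl_err = NULL,
                      stage = c("lj-growth", "charging")) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(lambda), is.numeric(dHdl_mean),
            length(lambda) == length(dHdl_mean))
  if (is.null(dHdl_err)) dHdl_err <- rep(0, length(lambda))
  if (length(dHdl_err) != length(lambda)) stop("dHdl_err length mismatch")
  if (any(lambda < 0 | lambda > 1)) stop("lambda values must lie in [0, 1]")
  if (is.unsorted(lambda, strictly = TRUE)) {
    stop("lambda values must be sorted and unique")
  }
  if (any(dHdl_err < 0)) stop("errors must be non-negative")
  structure(list(lambda = lambda, dHdl_mean = dHdl_mean,
                 dHdl_err = dHdl_err, stage = stage),
            class = "ti_record")
}

#' Read a TI record from CSV
#'
#' Columns: `lambda, dHdl_mean, dHdl_err, stage` (header required).
#'
#' @param path CSV path.
#' @return A list of [ti_record()], one per stage present in the file.
#' @export
read_ti_record <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lambda", "dHdl_mean", "dHdl_err", "stage")
  if (!all(need %in% names(df))) {
    stop("TI CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$stage), function(s) {
    s <- s[order(s$lambda), ]
    ti_record(s$lambda, s$dHdl_mean, s$dHdl_err, stage = s$stage[1])
  })
}

#' Integrate a TI record over lambda
#'
#' Quadrature of the mean <dH/dlambda> curve from the smallest to the largest
#' lambda on the grid. The trapezoid scheme is exact for integrands linear in
#' lambda; the cubic-spline scheme integrates a natural interpolating spline.
#' The error is propagated from the per-lambda standard errors assuming
#' independence across lambda states.
#'
#' @param record A [ti_record()].
#' @param scheme "trapezoid" (default) or "cubic-spline".
#' @return List with `value` (kJ/mol) and `stderr` (kJ/mol).
#' @export
ti_integrate <- function(record, scheme = c("trapezoid", "cubic-spline")) {
  stopifnot(inherits(record, "ti_record"))
  scheme <- match.arg(scheme)
  lam <- record$lambda; y <- record$dHdl_mean; err <- record$dHdl_err
  if (length(lam) < 2) stop("need at least 2 lambda points")
  if (scheme == "trapezoid") {
    dl <- diff(lam)
    w <- c(dl / 2, 0) + c(0, dl / 2)   # trapezoid weights per node
    value <- sum(w * y)
    stderr <- sqrt(sum((w * err)^2))
  } else {
    sf <- stats::splinefun(lam, y, method = "natural")
    value <- stats::integrate(sf, min(lam), max(lam),
                              rel.tol = 1e-10)$value
    # conservative: propagate with trapezoid weights
    dl <- diff(lam)
    w <- c(dl / 2, 0) + c(0, dl / 2)
    stderr <- sqrt(sum((w * err)^2))
  }
  list(value = value, stderr = stderr)
}

#' Finite-size correction for a charged solute under periodic boundaries
#'
#' Analytic correction removing the spurious interaction of an ion with its
#' periodic images and with the homogeneous neutralizing background in a
#' cubic box of edge L filled with a dielectric medium:
#' \deqn{F_{corr} = \frac{f q^2}{\varepsilon}\left[-\frac{\xi}{2L}
#'    + \frac{2\pi r^2}{3 L^3}\right]}
#' with f = 1/(4 pi eps0), the cubic-lattice constant xi = -2.837297 from
#' [wigner_constant()], and the ion Lennard-Jones radius r = 2^(1/6) sigma.
#' The correction is quadratic in q (identical for +e and -e) and vanishes as
#' L grows.
#'
#' @param q Ion charge in e.
#' @param dielectric Dielectric constant of the solvent model, >= 1.
#' @param L Cubic box edge in nm.
#' @param sigma_ion Ion Lennard-Jones sigma in nm.
#' @param xi Lattice constant; default the converged Ewald value.
#' @return Correction in kJ/mol (positive for the usual sign of xi).
#' @export
finite_size_correction <- function(q, dielectric, L, sigma_ion,
                                   xi = wigner_constant()) {
  stopifnot(is.numeric(q), is.numeric(L), is.numeric(sigma_ion))
  if (L <= 0) stop("L must be > 0")
  if (dielectric < 1) stop("dielectric must be >= 1")
  r_ion <- 2^(1 / 6) * sigma_ion
  kbff_constants$f_coulomb * q^2 / dielectric *
    (-xi / (2 * L) + 2 * pi * r_ion^2 / (3 * L^3))
}

#' Standard-state (pressure) correction for solvation free energies
#'
#' Free energy of compressing an ideal gas from the standard pressure p0 to
#' the ideal-solution pressure p1 = kB T n of the target concentration:
#' F_p = kB T ln(p1/p0). At 300 K, 1 mol/L and 1 atm this equals 3.2 kB T.
#'
#' @param temperature Temperature in K.
#' @param target_concentration Solution concentration in mol/L, > 0.
#' @param p0 Standard pressure in atm. Default 1.
#' @return Correction in kJ/mol.
#' @export
pressure_correction <- function(temperature, target_concentration, p0 = 1) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (target_concentration <= 0) stop("concentration must be > 0")
  kT <- thermal_energy(temperature)
  n <- molar_to_number_density(target_concentration)   # 1/nm^3
  p1 <- kT * n                                         # kJ/(mol nm^3)
  kT * log(p1 / atm_to_kjmolnm3(p0))
}

#' Assemble a corrected solvation free energy
#'
#' F_total = F_sim + F_corr + F_p. Salt pair free energies are sums of the
#' cation and anion single-ion totals; only pair values are compared with
#' experiment (no extra-thermodynamic single-ion split).
#'
#' @param F_sim Simulated (raw TI) free energy, kJ/mol.
#' @param F_corr Periodic-boundary correction, kJ/mol (see
#'   [finite_size_correction()]).
#' @param F_p Standard-state correction, kJ/mol (see [pressure_correction()]).
#' @param box_length,dielectric,sigma_ion Optional metadata recorded with the
#'   result.
#' @return An object of class `solvation_result` with field `F_total` and the
#'   components.
#' @export
solvation_free_energy <- function(F_sim, F_corr, F_p, box_length = NA,
                                  dielectric = NA, sigma_ion = NA) {
  stopifnot(is.numeric(F_sim), is.numeric(F_corr), is.numeric(F_p))
  structure(list(F_sim = F_sim, F_corr = F_corr, F_p = F_p,
                 F_total = F_sim + F_corr + F_p,
                 box_length = box_length, dielectric = dielectric,
                 sigma_ion = sigma_ion),
            class = "solvation_result")
}

#' Toy charging problem with a closed-form free energy
#'
#' Validation harness for the TI bookkeeping: a particle in a harmonic well
#' (stiffness kspring) charged against a fixed linear external potential
#' phi(x) = E x, H(lambda) = kspring x^2/2 + lambda q E x. The exact free
#' energy difference is \eqn{\Delta F = -(qE)^2 / (2 k_{spring})}, and
#' <dH/dlambda> at fixed lambda is -lambda (qE)^2 / kspring, linear in
#' lambda. Samples each lambda state exactly from its Gaussian ensemble.
#'
#' @param kspring Spring constant, kJ/(mol nm^2).
#' @param qE Coupling strength q*E, kJ/(mol nm).
#' @param temperature Temperature in K.
#' @param n_lambda Number of lambda states. Default 10.
#' @param n_samples Samples per state.
#' @param seed Integer seed.
#' @return List with `record` (a [ti_record()]), `estimate` (ti_integrate
#'   trapezoid result) and `exact` (closed form).
#' @export
toy_charging_ti <- function(kspring = 100, qE = 20, temperature = 300,
                            n_lambda = 10L, n_samples = 1000L, seed = 1L) {
  stopifnot(kspring > 0, n_lambda >= 2, n_samples >= 2)
  kT <- thermal_energy(temperature)
  set.seed(seed)
  lam <- seq(0, 1, length.out = n_lambda)
  means <- numeric(n_lambda); errs <- numeric(n_lambda)
  for (i in seq_along(lam)) {
    # x ~ N(-lam*qE/kspring, kT/kspring) exactly
    x <- stats::rnorm(n_samples, mean = -lam[i] * qE / kspring,
                      sd = sqrt(kT / kspring))
    dhdl <- qE * x
    means[i] <- mean(dhdl)
    errs[i] <- stats::sd(dhdl) / sqrt(n_samples)
  }
  rec <- ti_record(lam, means, errs, stage = "charging")
  list(record = rec,
       estimate = ti_integrate(rec, "trapezoid"),
       exact = -qE^2 / (2 * kspring))
}
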