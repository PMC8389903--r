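#' Mean-squared displacement of one species
#'
#' MSD averaged over all time origins and all particles of the species. The
#' input must be unwrapped (continuous) coordinates; wrapped input is
#' detected through inter-frame jumps larger than L/2 and rejected with a
#' pointer to [unwrap()].
#'
#' @param traj An unwrapped [trajectory()].
#' @param species Species label.
#' @param max_lag Largest lag in ps; default half the trajectory length.
#' @param lag_stride Evaluate every `lag_stride`-th lag (>= 1). Default 1.
#' @return An object of class `msd_curve`: data frame with `lag` (ps) and
#'   `msd` (nm^2), attribute `n_particles`. Lag 0 (msd = 0) is included.
#' @export
mean_squared_displacement <- function(traj, species, max_lag = NULL,
                                      lag_stride = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- which(traj$species == species)
  if (!length(idx)) stop("no particles of species ", species)
  x <- traj$coords[, idx, , drop = FALSE]
  nf <- dim(x)[1]
  L <- traj$box_length
  jumps <- abs(x[-1, , , drop = FALSE] - x[-nf, , , drop = FALSE])
  if (max(jumps) > L / 2) {
    stop("inter-frame jumps exceed L/2: coordinates look wrapped; ",
         "apply unwrap() before computing the MSD")
  }
  if (is.null(max_lag)) max_lag <- floor(nf / 2) * traj$dt
  k_max <- min(nf - 1L, floor(max_lag / traj$dt))
  if (k_max < 1) stop("max_lag shorter than one frame spacing")
  lags_k <- unique(c(0L, seq.int(lag_stride, k_max, by = lag_stride)))
  msd <- vapply(lags_k, function(k) {
    if (k == 0L) return(0)
    d <- x[(1 + k):nf, , , drop = FALSE] - x[1:(nf - k), , , drop = FALSE]
    sum(d^2) / ((nf - k) * length(idx))
  }, numeric(1))
  structure(data.frame(lag = lags_k * traj$dt, msd = msd),
            class = c("msd_curve", "data.frame"),
            n_particles = length(idx), species = species)
}

#' Fit the self-diffusion constant from an MSD curve
#'
#' Least-squares line msd = 6 D tau + c over a lag window; the offset c
#' absorbs short-time deviations from diffusive behaviour. The default
#' window spans 10% to 50% of the largest available lag ("long-time"
#' region). A coefficient of determination below `r2_warn` triggers a
#' poor-linearity warning (e.g. ballistic input).
#'
#' @param msd An [mean_squared_displacement()] curve.
#' @param window Lag window in ps as `c(lo, hi)`; default the 10-50% rule.
#' @param r2_warn R^2 threshold for the linearity diagnostic. Default 0.9.
#' @return An object of class `diffusion_result`: list with `D_sim`
#'   (nm^2/ps), `c_offset` (nm^2), `fit_window`, `r_squared`, `D_stderr`.
#' @export
fit_self_diffusion <- function(msd, window = NULL, r2_warn = 0.9) {
  stopifnot(inherits(msd, "msd_curve"))
  lag_max <- max(msd$lag)
  if (is.null(window)) window <- c(0.1, 0.5) * lag_max
  sel <- msd$lag >= window[1] & msd$lag <= window[2] & msd$lag > 0
  if (sum(sel) < 3) stop("fewer than 3 lags inside the fit window")
  ols <- kbff_ols_line(msd$lag[sel], msd$msd[sel])
  r2 <- ols$r_squared
  if (is.finite(r2) && r2 < r2_warn) {
    warning("MSD fit R^2 = ", signif(r2, 3),
            " below ", r2_warn, ": curve is not linear in the window ",
            "(non-diffusive input?)")
  }
  structure(list(D_sim = ols$slope / 6, c_offset = ols$intercept,
                 fit_window = window, r_squared = r2,
                 D_stderr = ols$slope_se / 6,
                 species = attr(msd, "species")),
            class = "diffusion_result")
}

#' Finite-size correction of a self-diffusion constant
#'
#' Yeh-Hummer hydrodynamic correction for a cubic periodic box:
#' \deqn{D_{self} = D_{sim} - \frac{\xi\, k_B T}{6 \pi \eta L}}
#' with the (negative) cubic-lattice constant xi from [wigner_constant()],
#' so the correction is positive and scales as T/(eta L). The solvent
#' viscosity is a required input per water model; there is no silent default.
#'
#' @param D_sim Simulated diffusion constant in nm^2/ps.
#' @param temperature Temperature in K.
#' @param eta Solvent shear viscosity in mPa s (= 1e-3 Pa s).
#' @param L Cubic box edge in nm.
#' @param xi Lattice constant; default the converged Ewald value.
#' @return List with `D_self` (nm^2/ps), `D_sim`, `correction`, `eta`, `L`.
#' @export
finite_size_diffusion_correction <- function(D_sim, temperature, eta, L,
                                             xi = wigner_constant()) {
  if (missing(eta) || is.null(eta) || !is.finite(eta)) {
    stop("eta (water-model viscosity, mPa s) is required; no default")
  }
  if (eta <= 0) stop("eta must be > 0")
  if (L <= 0) stop("L must be > 0")
  # SI evaluation, converted to nm^2/ps (1 m^2/s = 1e6 nm^2/ps)
  corr_SI <- -xi * kbff_constants$kB_SI * temperature /
    (6 * pi * eta * 1e-3 * L * 1e-9)
  corr <- corr_SI * 1e6
  list(D_self = D_sim + corr, D_sim = D_sim, correction = corr,
       eta = eta, L = L, temperature = temperature)
}

#' Einstein-Smoluchowski ionic conductivity
#'
#' kappa = n e^2 (D+ + D-) / (kB T) for a monovalent salt, with n the ion
#' pair number density. Inputs are in simulation units; the result is
#' converted to S/m.
#'
#' @param n Salt number density in 1/nm^3.
#' @param D_plus,D_minus Cation/anion self-diffusion constants in nm^2/ps.
#' @param temperature Temperature in K.
#' @return Conductivity in S/m.
#' @export
conductivity <- function(n, D_plus, D_minus, temperature) {
  stopifnot(n >= 0, D_plus >= 0, D_minus >= 0, temperature > 0)
  n_SI <- n * 1e27                      # 1/m^3
  D_SI <- (D_plus + D_minus) * 1e-6     # m^2/s
  n_SI * kbff_constants$e_charge^2 * D_SI /
    (kbff_constants$kB_SI * temperature)
}
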