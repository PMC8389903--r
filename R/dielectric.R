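#' Static dielectric susceptibility components of a salt solution
#'
#' Decomposes the zero-frequency electric susceptibility into three additive
#' contributions from the water box dipole M(t) and the ion current J(t):
#' water-dipole, water-dipole/ion-current cross, and ion-current terms. The
#' omega -> 0 limit is taken analytically from equilibrium fluctuation
#' formulas of M and the integrated ion dipole M_I(t) = int J dt (recovered
#' by cumulative summation, insensitive to the unknown integration constant):
#' \deqn{\chi_{ww} = \frac{\langle \delta M^2\rangle}{3\varepsilon_0 V k_B T},\quad
#'   \chi_{wi} = \frac{2\langle \delta M\cdot\delta M_I\rangle}{3\varepsilon_0 V k_B T},\quad
#'   \chi_{ii} = \frac{\langle \delta M_I^2\rangle}{3\varepsilon_0 V k_B T}}
#' and eps = 1 + chi_ww + chi_wi + chi_ii. The components are additive by
#' construction: the same formula applied to the total moment M + M_I gives
#' the identical epsilon.
#'
#' A stationarity diagnostic compares five block means of |M|^2 against
#' their block standard error and warns on drifts beyond 5 SE.
#'
#' @param M Water box-dipole series, [scalar_series()] with 3 components,
#'   e nm.
#' @param J Ion-current series, [scalar_series()] with 3 components,
#'   e nm/ps, aligned and equal in length to `M`.
#' @param volume Box volume in nm^3.
#' @param temperature Temperature in K.
#' @return An object of class `susceptibility_result`: list with `chi_ww`,
#'   `chi_wi`, `chi_ii`, `epsilon_total`, `volume`, `temperature`.
#' @export
susceptibility_components <- function(M, J, volume, temperature) {
  stopifnot(inherits(M, "scalar_series"), inherits(J, "scalar_series"),
            volume > 0, temperature > 0)
  if (nrow(M$values) != nrow(J$values)) {
    stop("M and J series lengths differ (", nrow(M$values), " vs ",
         nrow(J$values), ")")
  }
  if (abs(M$dt - J$dt) > 1e-12) stop("M and J must share the frame spacing")
  if (ncol(M$values) != 3L || ncol(J$values) != 3L) {
    stop("M and J must be 3-component vector series")
  }
  Mv <- M$values
  # integrated ion dipole; the constant of integration drops out of the
  # centered fluctuation formulas
  MI <- apply(J$values * J$dt, 2, function(col) cumsum(c(0, col[-length(col)])))

  # stationarity screen on |M|^2: drift of the first vs last block mean
  # against their within-block (sub-blocked) standard errors
  m2 <- rowSums(Mv^2)
  if (length(m2) >= 250) {
    bm <- block_means(m2, 5L)
    bl <- length(m2) %/% 5L
    se_first <- block_average_error(m2[seq_len(bl)], 5L)
    se_last <- block_average_error(m2[((4L * bl) + 1L):(5L * bl)], 5L)
    se <- sqrt(se_first^2 + se_last^2)
    if (se > 0 && abs(bm[5] - bm[1]) > 5 * se) {
      warning("block means of |M|^2 drift by more than 5 SE: ",
              "series may be non-stationary; trim transients")
    }
  }

  kT <- thermal_energy(temperature)
  norm <- 4 * pi * kbff_constants$f_coulomb / (3 * volume * kT)
  dM <- sweep(Mv, 2, colMeans(Mv))
  dI <- sweep(MI, 2, colMeans(MI))
  chi_ww <- norm * mean(rowSums(dM^2)) * nrow(dM) / (nrow(dM) - 1)
  chi_ii <- norm * mean(rowSums(dI^2)) * nrow(dI) / (nrow(dI) - 1)
  chi_wi <- 2 * norm * sum(dM * dI) / (nrow(dM) - 1)
  structure(list(chi_ww = chi_ww, chi_wi = chi_wi, chi_ii = chi_ii,
                 epsilon_total = 1 + chi_ww + chi_wi + chi_ii,
                 volume = volume, temperature = temperature),
            class = "susceptibility_result")
}

#' Dielectric decrement relative to the pure solvent
#'
#' Delta eps = eps_solution - eps_pure. The conventional pure-water value
#' for the SPC/E model is 72.0.
#'
#' @param epsilon_solution Dielectric constant of the salt solution, >= 1.
#' @param epsilon_pure Dielectric constant of the pure solvent, >= 1.
#' @return The (usually negative) decrement.
#' @export
dielectric_decrement <- function(epsilon_solution, epsilon_pure = 72.0) {
  stopifnot(is.numeric(epsilon_solution), is.numeric(epsilon_pure))
  if (any(epsilon_solution < 1) || any(epsilon_pure < 1)) {
    stop("dielectric constants must be >= 1")
  }
  epsilon_solution - epsilon_pure
}
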