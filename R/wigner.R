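#' Specification of the Ewald lattice sum
#'
#' Controls the Ewald evaluation of the cubic-lattice self-interaction
#' constant (Wigner constant). All quantities are in reduced units of the box
#' length L = 1, so `alpha` is dimensionless (multiply by 1/L to obtain 1/nm).
#'
#' @param alpha Ewald splitting parameter in units of 1/L. Default 6.
#' @param n_real Real-space cutoff: images with |n_i| <= n_real are summed.
#' @param n_recip Reciprocal-space cutoff: integer shells |m_i| <= n_recip.
#' @param tol Convergence tolerance on the constant. Default 1e-6.
#' @return An object of class `lattice_sum_spec`.
#' @export
lattice_sum_spec <- function(alpha = 6, n_real = 3L, n_recip = 8L, tol = 1e-6) {
  stopifnot(alpha > 0, n_real >= 1L, n_recip >= 1L, tol > 0)
  structure(list(alpha = alpha, n_real = as.integer(n_real),
                 n_recip = as.integer(n_recip), tol = tol),
            class = "lattice_sum_spec")
}

# sum of erfc(alpha |n|)/|n| over nonzero integer vectors with |n_i| <= n_max
.wigner_real_sum <- function(alpha, n_max) {
  g <- seq.int(-n_max, n_max)
  grid <- expand.grid(x = g, y = g, z = g)
  r <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  r <- r[r > 0]
  # erfc via pnorm: erfc(x) = 2*pnorm(-sqrt(2)*x)
  sum(2 * stats::pnorm(-sqrt(2) * alpha * r) / r)
}

# sum of exp(-pi^2 m^2/alpha^2)/(pi m^2) over nonzero integer vectors
.wigner_recip_sum <- function(alpha, m_max) {
  g <- seq.int(-m_max, m_max)
  grid <- expand.grid(x = g, y = g, z = g)
  m2 <- grid$x^2 + grid$y^2 + grid$z^2
  m2 <- m2[m2 > 0]
  sum(exp(-pi^2 * m2 / alpha^2) / (pi * m2))
}

#' Wigner constant of the cubic lattice by Ewald summation
#'
#' Self-interaction constant xi of a unit point charge in a cubic periodic
#' lattice with a uniform neutralizing background: the energy of the charge
#' with all its images and the background is xi * q^2 / (8 pi eps0 L). The
#' Ewald split is
#' \deqn{\xi = \sum_{n \ne 0} \mathrm{erfc}(\alpha|n|)/|n|
#'   + \sum_{m \ne 0} e^{-\pi^2 m^2/\alpha^2}/(\pi m^2)
#'   - 2\alpha/\sqrt{\pi} - \pi/\alpha^2}
#' in units of the box length. The value is independent of the splitting
#' parameter alpha; convergence of both sums is verified by comparing against
#' enlarged cutoffs, and failure to converge names the unconverged term.
#'
#' @param spec A [lattice_sum_spec()].
#' @return The dimensionless constant, approximately -2.837297.
#' @examples
#' wigner_constant()
#' @export
wigner_constant <- function(spec = lattice_sum_spec()) {
  stopifnot(inherits(spec, "lattice_sum_spec"))
  a <- spec$alpha
  real_sum <- .wigner_real_sum(a, spec$n_real)
  recip_sum <- .wigner_recip_sum(a, spec$n_recip)

  # convergence check: enlarging either cutoff must not move the result
  real_tail <- .wigner_real_sum(a, spec$n_real + 2L) - real_sum
  if (abs(real_tail) > spec$tol) {
    stop("real-space lattice sum not converged at n_real = ", spec$n_real,
         " (tail ", signif(real_tail, 3), " > tol ", spec$tol,
         "); increase n_real or alpha")
  }
  recip_tail <- .wigner_recip_sum(a, spec$n_recip + 2L) - recip_sum
  if (abs(recip_tail) > spec$tol) {
    stop("reciprocal-space sum not converged at n_recip = ", spec$n_recip,
         " (tail ", signif(recip_tail, 3), " > tol ", spec$tol,
         "); increase n_recip or decrease alpha")
  }

  real_sum + recip_sum - 2 * a / sqrt(pi) - pi / a^2
}
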