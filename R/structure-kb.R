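#' Radial distribution function between two species
#'
#' Standard minimum-image histogram estimator on uniform half-open bins
#' `[lo, hi)`, normalized by the ideal-gas pair count per spherical shell.
#' For identical species, self pairs are excluded and each unordered pair is
#' counted once. Pairs at exactly `r_max` are excluded.
#'
#' @param traj A [trajectory()] with wrapped coordinates.
#' @param pair Character vector of two species labels (alpha, beta).
#' @param bin_width Bin width in nm. Default 0.002.
#' @param r_max Histogram range in nm; must not exceed L/2.
#' @param frames Optional integer subset of frames to use (for block averaging).
#' @return An object of class `rdf_table`: data frame with columns `r_lo`,
#'   `r_hi`, `r_mid`, `counts`, `g`, plus attributes `pair`, `n_frames`,
#'   `box_length`, `n_alpha`, `n_beta`.
#' @export
radial_distribution <- function(traj, pair, bin_width = 0.002, r_max = NULL,
                                frames = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(pair) == 2L)
  L <- traj$box_length
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-12) {
    stop("r_max (", r_max, ") must not exceed L/2 = ", L / 2,
         " (minimum-image validity)")
  }
  ia <- which(traj$species == pair[1])
  ib <- which(traj$species == pair[2])
  if (!length(ia)) stop("no particles of species ", pair[1])
  if (!length(ib)) stop("no particles of species ", pair[2])
  if (is.null(frames)) frames <- seq_len(dim(traj$coords)[1])
  same <- identical(pair[1], pair[2])
  # whole bins only: the range is truncated to floor(r_max / bin_width) bins
  nb <- floor(r_max / bin_width + 1e-9)
  if (nb < 1) stop("r_max must cover at least one bin")
  edges <- (0:nb) * bin_width
  r_max <- edges[nb + 1L]
  counts <- numeric(nb)
  for (k in frames) {
    A <- matrix(traj$coords[k, ia, ], ncol = 3)
    B <- matrix(traj$coords[k, ib, ], ncol = 3)
    dx <- minimum_image(outer(A[, 1], B[, 1], "-"), L)
    dy <- minimum_image(outer(A[, 2], B[, 2], "-"), L)
    dz <- minimum_image(outer(A[, 3], B[, 3], "-"), L)
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (same) r <- r[upper.tri(r)]
    r <- r[r < r_max]
    if (length(r)) {
      idx <- pmin(floor(r / bin_width) + 1L, nb)
      counts <- counts + tabulate(idx, nbins = nb)
    }
  }
  n_pairs <- if (same) length(ia) * (length(ia) - 1) / 2 else
    length(ia) * length(ib)
  shell_vol <- 4 * pi / 3 * (edges[-1]^3 - edges[-length(edges)]^3)
  expected <- length(frames) * n_pairs * shell_vol / L^3
  g <- ifelse(expected > 0, counts / expected, 0)
  out <- data.frame(r_lo = edges[-length(edges)], r_hi = edges[-1],
                    r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                    counts = counts, g = g)
  structure(out, class = c("rdf_table", "data.frame"),
            pair = pair, n_frames = length(frames), box_length = L,
            n_alpha = length(ia), n_beta = length(ib))
}

#' Finite-volume Kirkwood-Buff integral
#'
#' Integrates h(r) = g(r) - 1 against the geometric weight of a spherical
#' subvolume of radius R,
#' \deqn{G^R = \int_0^{2R} 4\pi r^2 h(r)\, w(x)\, dr, \quad
#'   w(x) = 1 - \tfrac{3}{2}x + \tfrac{1}{2}x^3, \; x = r/(2R).}
#' The binned g is treated as piecewise constant and the polynomial weight is
#' integrated exactly within each bin, so the quadrature is exact for any
#' step-shaped correlation aligned with bin edges.
#'
#' @param rdf An [radial_distribution()] table.
#' @param R Subvolume radius in nm; requires 2R within the resolved range.
#' @return The finite-volume integral G^R in nm^3.
#' @export
kb_integral_finite <- function(rdf, R) {
  stopifnot(inherits(rdf, "rdf_table"), is.numeric(R), length(R) == 1L, R > 0)
  r_max <- rdf$r_hi[nrow(rdf)]
  if (2 * R > r_max + 1e-12) {
    stop("2R = ", 2 * R, " exceeds the resolved RDF range r_max = ", r_max)
  }
  lo <- rdf$r_lo; hi <- pmin(rdf$r_hi, 2 * R)
  keep <- lo < 2 * R
  lo <- lo[keep]; hi <- hi[keep]
  h <- rdf$g[keep] - 1
  # exact integral of 4 pi r^2 (1 - 3r/(4R) + r^3/(16 R^3)) over [lo, hi]
  seg <- 4 * pi * ((hi^3 - lo^3) / 3 - 3 * (hi^4 - lo^4) / (16 * R) +
                     (hi^6 - lo^6) / (96 * R^3))
  sum(h * seg)
}

#' Extrapolate finite-volume KB integrals to the thermodynamic limit
#'
#' Ordinary least squares of G^R against 1/R over a fit window; the intercept
#' at 1/R = 0 is the infinite-volume integral G^inf.
#'
#' @param R_values Subvolume radii in nm.
#' @param G_R Finite-volume integrals in nm^3 (same length).
#' @param fit_window Range of 1/R (1/nm) to include, as `c(lo, hi)`. Default:
#'   all points.
#' @return An object of class `kb_result`: list with `G_infinity`, `slope`,
#'   `stderr` (intercept SE), `slope_stderr`, `fit_window`, `R_values`, `G_R`,
#'   `r_squared`.
#' @export
kb_extrapolate <- function(R_values, G_R, fit_window = NULL) {
  stopifnot(is.numeric(R_values), is.numeric(G_R),
            length(R_values) == length(G_R), all(R_values > 0))
  invR <- 1 / R_values
  if (is.null(fit_window)) fit_window <- range(invR)
  sel <- invR >= fit_window[1] - 1e-12 & invR <= fit_window[2] + 1e-12
  if (sum(sel) < 3) stop("need at least 3 points inside the fit window")
  x <- invR[sel]; y <- G_R[sel]
  if (stats::sd(x) == 0) stop("zero variance in 1/R inside the fit window")
  ols <- kbff_ols_line(x, y)
  structure(list(G_infinity = ols$intercept, slope = ols$slope,
                 stderr = ols$intercept_se, slope_stderr = ols$slope_se,
                 fit_window = fit_window,
                 R_values = R_values[sel], G_R = G_R[sel],
                 r_squared = ols$r_squared),
            class = "kb_result")
}

# ordinary least squares of y on x with closed-form standard errors;
# degenerate (perfect-fit) cases return zero SEs without warnings
kbff_ols_line <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  tss <- sum((y - yb)^2)
  s2 <- if (n > 2) rss / (n - 2) else 0
  list(intercept = intercept, slope = slope,
       intercept_se = sqrt(s2 * (1 / n + xb^2 / sxx)),
       slope_se = sqrt(s2 / sxx),
       r_squared = if (tss > 0) 1 - rss / tss else 1)
}

#' Full RDF -> finite-volume KB -> extrapolation chain for one species pair
#'
#' @param traj A [trajectory()].
#' @param pair Two species labels.
#' @param bin_width RDF bin width in nm.
#' @param R_values Subvolume radii for the finite-volume integrals; default a
#'   grid over [L/8, L/4].
#' @param frames Optional frame subset.
#' @return A [kb_extrapolate()] result.
#' @export
kb_chain <- function(traj, pair, bin_width = 0.01, R_values = NULL,
                     frames = NULL) {
  L <- traj$box_length
  if (is.null(R_values)) R_values <- seq(L / 8, L / 4, length.out = 12)
  rdf <- radial_distribution(traj, pair, bin_width = bin_width,
                             r_max = L / 2, frames = frames)
  G_R <- vapply(R_values, function(R) kb_integral_finite(rdf, R), numeric(1))
  kb_extrapolate(R_values, G_R)
}

#' Ion number density from Kirkwood-Buff integrals
#'
#' For a charge-neutral monovalent salt the ion density obeys
#' n = 1 / (G_+-^inf - G_++^inf); used as an internal consistency check
#' between composition and structure.
#'
#' @param G_plus_minus Cation-anion KB integral, nm^3.
#' @param G_plus_plus Cation-cation KB integral, nm^3.
#' @return Number density in 1/nm^3.
#' @export
density_from_kb <- function(G_plus_minus, G_plus_plus) {
  stopifnot(is.numeric(G_plus_minus), is.numeric(G_plus_plus))
  d <- G_plus_minus - G_plus_plus
  if (any(d == 0)) stop("G_+- equals G_++: density undefined")
  1 / d
}
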