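#' Kirkwood-Buff integral set for one electrolyte state point
#'
#' Infinite-volume KB integrals between cation (+), anion (-) and solvent (s)
#' together with the salt and solvent number densities. For a symmetric
#' treatment of a monovalent salt, G_++ and G_-- are represented by a single
#' cation-cation value.
#'
#' @param G_pp,G_pm,G_ps,G_ss,G_ms KB integrals in nm^3 (cation-cation,
#'   cation-anion, cation-solvent, solvent-solvent, anion-solvent).
#' @param n_salt Salt (ion-pair) number density in 1/nm^3.
#' @param n_solvent Solvent number density in 1/nm^3.
#' @return An object of class `kb_set`.
#' @export
kb_set <- function(G_pp, G_pm, G_ps, G_ss = 0, G_ms = G_ps, n_salt,
                   n_solvent = NA_real_) {
  vals <- c(G_pp, G_pm, G_ps, G_ss, G_ms, n_salt)
  if (!all(is.finite(vals))) stop("all KB integrals and n_salt must be finite")
  if (n_salt <= 0) stop("n_salt must be > 0")
  structure(list(G_pp = G_pp, G_pm = G_pm, G_ps = G_ps, G_ss = G_ss,
                 G_ms = G_ms, n_salt = n_salt, n_solvent = n_solvent),
            class = "kb_set")
}

#' Activity derivative of a monovalent salt from Kirkwood-Buff integrals
#'
#' Logarithmic derivative of the mean ion activity with respect to the ion
#' number density at constant temperature and pressure. For a symmetric 1:1
#' electrolyte treated with indistinguishable ions,
#' \deqn{a_{cc} = \frac{1}{1 + n\,(G_{++} + G_{+-} - G_{+s} - G_{-s})}}
#' with n the salt density. All KB integrals zero gives the ideal-solution
#' limit a_cc = 1. The solvent-solvent integral does not enter the
#' constant-pressure derivative (it is carried for density checks only).
#'
#' @param kb A [kb_set()].
#' @return The dimensionless activity derivative.
#' @export
activity_derivative <- function(kb) {
  stopifnot(inherits(kb, "kb_set"))
  denom <- 1 + kb$n_salt * (kb$G_pp + kb$G_pm - kb$G_ps - kb$G_ms)
  if (abs(denom) < 1e-12) {
    stop("singular denominator: 1 + n(G_pp + G_pm - G_ps - G_ms) = 0 ",
         "(osmotic instability in the supplied integrals)")
  }
  1 / denom
}

#' Activity-derivative curve from a set of trajectories
#'
#' Chains the structural estimators per molality:
#' [radial_distribution()] -> [kb_integral_finite()] -> [kb_extrapolate()]
#' -> [activity_derivative()]. The per-point error is a five-block estimate:
#' the chain is re-run on five contiguous frame blocks and the standard error
#' of the block values is reported.
#'
#' @param trajectories List of [trajectory()] objects, one per molality.
#' @param molalities Numeric vector of molalities (mol/kg), same length.
#' @param cation,anion,solvent Species labels in the trajectories.
#' @param bin_width RDF bin width in nm. Default 0.01 (desk-scale boxes).
#' @param R_values Subvolume radii for the KB integrals; default per
#'   [kb_chain()].
#' @param n_blocks Blocks for the error estimate. Default 5.
#' @return An object of class `activity_curve`: data frame with columns
#'   `molality`, `a_cc`, `error`.
#' @export
activity_curve <- function(trajectories, molalities, cation, anion,
                           solvent = NULL, bin_width = 0.01, R_values = NULL,
                           n_blocks = 5L) {
  stopifnot(length(trajectories) == length(molalities))
  if (is.unsorted(molalities, strictly = TRUE)) {
    stop("molalities must be strictly increasing")
  }
  one_acc <- function(traj, frames = NULL) {
    V <- traj$box_length^3
    n_salt <- sum(traj$species == cation) / V
    G_pp <- kb_chain(traj, c(cation, cation), bin_width, R_values,
                     frames)$G_infinity
    G_pm <- kb_chain(traj, c(cation, anion), bin_width, R_values,
                     frames)$G_infinity
    if (!is.null(solvent)) {
      G_ps <- kb_chain(traj, c(cation, solvent), bin_width, R_values,
                       frames)$G_infinity
      G_ms <- kb_chain(traj, c(anion, solvent), bin_width, R_values,
                       frames)$G_infinity
    } else {
      G_ps <- 0; G_ms <- 0
    }
    activity_derivative(kb_set(G_pp, G_pm, G_ps, 0, G_ms, n_salt))
  }
  a_cc <- numeric(length(molalities)); err <- numeric(length(molalities))
  for (i in seq_along(trajectories)) {
    traj <- trajectories[[i]]
    nf <- dim(traj$coords)[1]
    a_cc[i] <- tryCatch(one_acc(traj), error = function(e) {
      stop("molality ", molalities[i], " mol/kg: ", conditionMessage(e))
    })
    block_len <- nf %/% n_blocks
    if (block_len >= 2) {
      blocks <- vapply(seq_len(n_blocks), function(b) {
        frames <- ((b - 1) * block_len + 1):(b * block_len)
        one_acc(traj, frames)
      }, numeric(1))
      err[i] <- stats::sd(blocks) / sqrt(n_blocks)
    } else {
      err[i] <- NA_real_
    }
  }
  structure(data.frame(molality = molalities, a_cc = a_cc, error = err),
            class = c("activity_curve", "data.frame"))
}

#' Load an experimental reference activity-derivative curve
#'
#' CSV with columns `molality_molkg, a_cc` (optional `error`). The package
#' ships only synthetic reference files; real experimental tables are
#' user-supplied. Molalities outside the optimization range (0, 5] mol/kg
#' trigger a warning.
#'
#' @param path CSV path.
#' @return An object of class `activity_curve` (data frame `molality`,
#'   `a_cc`, `error`).
#' @export
load_reference_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("molality_molkg", "a_cc") %in% names(df))) {
    stop("reference CSV must have columns molality_molkg, a_cc")
  }
  m <- df$molality_molkg
  if (anyDuplicated(m)) stop("duplicated molality in reference curve")
  if (is.unsorted(m)) stop("molalities must be increasing")
  if (any(m <= 0)) stop("molalities must be > 0")
  if (any(m > 5)) {
    warning("reference molalities above 5 mol/kg lie outside the ",
            "optimization range (0, 5]")
  }
  err <- if ("error" %in% names(df)) df$error else rep(NA_real_, nrow(df))
  structure(data.frame(molality = m, a_cc = df$a_cc, error = err),
            class = c("activity_curve", "data.frame"))
}
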