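#' Per-species force-field parameters
#'
#' @param name Species label, e.g. "Na+".
#' @param sigma Lennard-Jones sigma in nm, > 0.
#' @param epsilon Lennard-Jones epsilon in kJ/mol, >= 0.
#' @param charge Charge in units of e.
#' @param mass Mass in u (optional, NA allowed).
#' @return An object of class `species_params`.
#' @export
species_params <- function(name, sigma, epsilon, charge = 0, mass = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(charge), length(charge) == 1L)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0 (nm)")
  if (!is.finite(epsilon) || epsilon < 0) stop("epsilon must be >= 0 (kJ/mol)")
  structure(list(name = name, sigma = sigma, epsilon = epsilon,
                 charge = charge, mass = mass),
            class = "species_params")
}

#' Read a force-field table from CSV
#'
#' Expected columns: `species, sigma_nm, epsilon_kjmol, charge_e, mass_u`
#' (header required). The bundled file `table1_ions.csv` carries the optimized
#' alkali-halide ion parameters (K+, Na+, Cl-, Br-).
#'
#' @param path Path to the CSV file.
#' @return A named list of [species_params()], one per row.
#' @export
read_forcefield <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "sigma_nm", "epsilon_kjmol", "charge_e", "mass_u")
  if (!all(need %in% names(df))) {
    stop("force-field table must have columns: ", paste(need, collapse = ", "))
  }
  ff <- lapply(seq_len(nrow(df)), function(i) {
    species_params(df$species[i], df$sigma_nm[i], df$epsilon_kjmol[i],
                   df$charge_e[i], df$mass_u[i])
  })
  names(ff) <- df$species
  ff
}

#' The optimized alkali-halide ion parameter set
#'
#' Loads the bundled table of optimized Lennard-Jones parameters and charges
#' for K+, Na+, Cl-, Br- (sigma in nm, epsilon in kJ/mol, charge in e).
#'
#' @return A named list of [species_params()].
#' @examples
#' ion_table()$`Na+`
#' @export
ion_table <- function() {
  read_forcefield(system.file("extdata", "table1_ions.csv", package = "kbff",
                              mustWork = TRUE))
}

#' Lorentz-Berthelot combination of two species
#'
#' Arithmetic mean of sigma, geometric mean of epsilon. The resulting pair
#' carries the Lennard-Jones cutoff and the shift that makes the truncated
#' potential vanish exactly at the cutoff (no long-range dispersion
#' correction is applied).
#'
#' @param i,j [species_params()] objects.
#' @param cutoff Lennard-Jones cutoff in nm. Default 0.9.
#' @return An object of class `pair_params` with fields `sigma`, `epsilon`,
#'   `cutoff`, `shift`, `qq` (charge product, e^2).
#' @export
combine_lorentz_berthelot <- function(i, j, cutoff = 0.9) {
  stopifnot(inherits(i, "species_params"), inherits(j, "species_params"),
            cutoff > 0)
  if (i$epsilon < 0 || j$epsilon < 0) stop("epsilon must be non-negative")
  sigma <- (i$sigma + j$sigma) / 2
  epsilon <- sqrt(i$epsilon * j$epsilon)
  shift <- .lj_plain(cutoff, sigma, epsilon)
  structure(list(sigma = sigma, epsilon = epsilon, cutoff = cutoff,
                 shift = shift, qq = i$charge * j$charge,
                 names = c(i$name, j$name)),
            class = "pair_params")
}

# unshifted Lennard-Jones
.lj_plain <- function(r, sigma, epsilon) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' Truncated-and-shifted Lennard-Jones potential
#'
#' 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] - shift for r <= cutoff, 0 beyond;
#' the shift equals the unshifted value at the cutoff, so the potential is
#' continuous (and exactly zero) at the cutoff.
#'
#' @param r Distance(s) in nm, > 0.
#' @param pair A [combine_lorentz_berthelot()] pair.
#' @return Potential energy in kJ/mol (vectorized over `r`).
#' @export
lj_potential_shifted <- function(r, pair) {
  stopifnot(inherits(pair, "pair_params"), is.numeric(r))
  if (any(r <= 0)) stop("r must be > 0")
  out <- .lj_plain(r, pair$sigma, pair$epsilon) - pair$shift
  out[r > pair$cutoff] <- 0
  out
}

#' Soft-core Lennard-Jones potential for alchemical coupling
#'
#' Lambda-regularized variant of the shifted Lennard-Jones interaction used
#' for thermodynamic-integration endpoints: with soft-core radius alpha (nm)
#' and power p,
#' \deqn{V(r, \lambda) = \lambda\, V_{LJ}^{shifted}(r_{sc}), \quad
#'   r_{sc} = (\alpha^6 (1-\lambda)^p + r^6)^{1/6}.}
#' At lambda = 1 this is the plain shifted potential (the cutoff shift is
#' retained throughout the coupling path); at lambda = 0 the interaction is
#' fully decoupled (identically zero); for 0 < lambda < 1 the potential is
#' finite at r = 0.
#'
#' @param r Distance(s) in nm, >= 0.
#' @param lam Coupling parameter in [0, 1].
#' @param pair A [combine_lorentz_berthelot()] pair.
#' @param alpha Soft-core radius in nm. Default 0.5.
#' @param p Soft-core power. Default 1.
#' @return Potential energy in kJ/mol (vectorized over `r`).
#' @export
softcore_potential <- function(r, lam, pair, alpha = 0.5, p = 1) {
  stopifnot(inherits(pair, "pair_params"), is.numeric(r), is.numeric(lam),
            length(lam) == 1L)
  if (lam < 0 || lam > 1) stop("lam must be within [0, 1]")
  if (any(r < 0)) stop("r must be >= 0")
  if (lam == 0) return(rep(0, length(r)))
  r_sc <- (alpha^6 * (1 - lam)^p + r^6)^(1 / 6)
  lam * lj_potential_shifted(pmax(r_sc, .Machine$double.eps), pair)
}
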