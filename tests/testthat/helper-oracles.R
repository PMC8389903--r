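# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package estimators.

# naive O(N^2)-per-frame RDF histogram with the same binning convention
oracle_rdf_counts <- function(traj, pair, bin_width, r_max) {
  L <- traj$box_length
  ia <- which(traj$species == pair[1])
  ib <- which(traj$species == pair[2])
  same <- identical(pair[1], pair[2])
  nb <- floor(r_max / bin_width + 1e-9)
  r_max <- nb * bin_width
  counts <- numeric(nb)
  for (k in seq_len(dim(traj$coords)[1])) {
    for (i in ia) {
      for (j in ib) {
        if (same && j <= i) next
        d <- traj$coords[k, i, ] - traj$coords[k, j, ]
        d <- d - L * round(d / L)
        r <- sqrt(sum(d^2))
        if (r < r_max) {
          b <- min(floor(r / bin_width) + 1L, nb)
          counts[b] <- counts[b] + 1
        }
      }
    }
  }
  counts
}

# naive all-origins, all-particles MSD
oracle_msd <- function(traj, species, lags_k) {
  idx <- which(traj$species == species)
  x <- traj$coords[, idx, , drop = FALSE]
  nf <- dim(x)[1]
  vapply(lags_k, function(k) {
    if (k == 0L) return(0)
    acc <- 0; cnt <- 0
    for (t0 in 1:(nf - k)) {
      for (p in seq_along(idx)) {
        acc <- acc + sum((x[t0 + k, p, ] - x[t0, p, ])^2)
        cnt <- cnt + 1
      }
    }
    acc / cnt
  }, numeric(1))
}

# direct lattice sum for the Wigner constant: point images on a cubic grid
# with |n_i| <= N, minus the uniform background integrated over the same
# cube of side (2N+1) (charge-neutral cell-by-cell grouping). Uses the
# closed form for the potential integral of a unit cube at its center,
# 3*log(2+sqrt(3)) - pi/2. Cell-wise summation converges to the
# tinfoil/Ewald value shifted by the cell second moment, 2*pi/3 * M2 with
# M2 = -1/4 for a point charge plus cubic background, i.e. direct sum =
# Ewald value + pi/6; the shift is removed below.
oracle_wigner_direct <- function(N) {
  g <- seq.int(-N, N)
  grid <- expand.grid(x = g, y = g, z = g)
  r <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  r <- r[r > 0]
  cube_I1 <- 3 * log(2 + sqrt(3)) - pi / 2
  sum(1 / r) - (2 * N + 1)^2 * cube_I1
}

oracle_wigner <- function(N1 = 6, N2 = 10) {
  x1 <- oracle_wigner_direct(N1)
  x2 <- oracle_wigner_direct(N2)
  # eliminate the leading 1/N^2 truncation error, remove the shape term
  (x2 / N2^2 - x1 / N1^2) / (1 / N2^2 - 1 / N1^2) - pi / 6
}

# random small trajectory fixture
random_trajectory <- function(n_frames, species, box_length, dt = 1,
                              seed = 1L) {
  set.seed(seed)
  np <- length(species)
  coords <- array(stats::runif(n_frames * np * 3, 0, box_length),
                  dim = c(n_frames, np, 3))
  trajectory(coords, species, box_length, dt)
}

lj_test_ff <- function() {
  list(A = species_params("A", 0.34, 0.8),
       B = species_params("B", 0.30, 0.5))
}
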