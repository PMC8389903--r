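test_that("write/read roundtrips are identity for xyz, gro and csv", {
  traj <- random_trajectory(3, c("Na", "Cl", rep("W", 8)), 2.5, dt = 0.5,
                            seed = 31)
  for (fmt in c("xyz", "csv")) {
    tmp <- tempfile(fileext = paste0(".", fmt))
    write_trajectory(traj, tmp)
    back <- read_trajectory(tmp, dt = if (fmt == "csv") 0.5 else NULL,
                            box_length = traj$box_length)
    expect_equal(back$coords, traj$coords, tolerance = 1e-9)
    expect_equal(back$species, traj$species)
    expect_equal(back$box_length, traj$box_length)
    expect_equal(back$dt, traj$dt)
  }
  # gro stores 3 decimals: roundtrip to that precision
  tmp <- tempfile(fileext = ".gro")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(dim(back$coords), dim(traj$coords))
})

test_that("frame with a missing particle is rejected naming the frame", {
  lines <- c("2", "box=2 t=0", "A 0.1 0.1 0.1", "A 0.5 0.5 0.5",
             "2", "box=2 t=1", "A 0.2 0.2 0.2")
  tmp <- tempfile(fileext = ".xyz")
  writeLines(lines, tmp)
  expect_error(read_trajectory(tmp), "frame 2")
})

test_that("csv trajectories with inconsistent particle counts are rejected", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("frame,particle,species,x,y,z",
               "1,1,A,0,0,0", "1,2,A,1,1,1", "2,1,A,0,0,0"), tmp)
  expect_error(read_trajectory(tmp, box_length = 2), "particle count")
})

test_that("species labels are resolved against a force field on read", {
  traj <- random_trajectory(2, c("A", "B", "B"), 2, seed = 32)
  tmp <- tempfile(fileext = ".xyz")
  write_trajectory(traj, tmp)
  ff <- lj_test_ff()
  ff$A$charge <- 1; ff$B$charge <- -1
  back <- read_trajectory(tmp, forcefield = ff)
  expect_equal(back$charges, c(1, -1, -1))
  expect_error(read_trajectory(tmp, forcefield = ff["A"]), "unknown species")
})

test_that("minimum-image distance comes out right for a hand-built pair", {
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 1, ] <- c(0.1, 0.5, 0.5)
  coords[1, 2, ] <- c(1.6, 0.5, 0.5)   # 1.5 apart, box 2: image distance 0.5
  traj <- trajectory(coords, c("A", "A"), 2, 1)
  tmp <- tempfile(fileext = ".xyz")
  write_trajectory(traj, tmp)
  back <- read_trajectory(tmp)
  d <- minimum_image(back$coords[1, 1, ] - back$coords[1, 2, ], 2)
  expect_equal(sqrt(sum(d^2)), 0.5)
})

test_that("minimum-image distances are invariant under global translation", {
  traj <- random_trajectory(1, rep("A", 10), 3, seed = 33)
  shift <- c(1.234, -0.77, 2.5)
  pd <- function(coords) {
    d <- outer(coords[, 1], coords[, 1], "-")
    dy <- outer(coords[, 2], coords[, 2], "-")
    dz <- outer(coords[, 3], coords[, 3], "-")
    sqrt(minimum_image(d, 3)^2 + minimum_image(dy, 3)^2 +
           minimum_image(dz, 3)^2)
  }
  a <- pd(matrix(traj$coords[1, , ], ncol = 3))
  b <- pd(sweep(matrix(traj$coords[1, , ], ncol = 3), 2, shift, "+") %% 3)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("unwrapping a boundary-crossing drift yields a linear track", {
  L <- 2
  nf <- 30
  x <- (0.1 * L * (0:(nf - 1)) + 0.95 * L) %% L
  coords <- array(0, dim = c(nf, 1, 3))
  coords[, 1, 1] <- x
  traj <- trajectory(coords, "A", L, 1)
  un <- unwrap(traj)
  expect_equal(diff(un$coords[, 1, 1]), rep(0.1 * L, nf - 1))
  # idempotence on already-continuous input
  again <- unwrap(un)
  expect_equal(again$coords, un$coords)
})

test_that("wrap(unwrap(x)) reproduces wrapped random walks exactly", {
  set.seed(34)
  for (rep_i in 1:5) {
    L <- runif(1, 1, 4)
    nf <- 60
    steps <- matrix(rnorm(3 * (nf - 1), sd = 0.05 * L), ncol = 3)
    path <- apply(rbind(runif(3, 0, L), steps), 2, cumsum)
    coords <- array(0, dim = c(nf, 1, 3))
    coords[, 1, ] <- path %% L
    traj <- trajectory(coords, "A", L, 1)
    rewrapped <- wrap(unwrap(traj))
    expect_equal(rewrapped$coords, traj$coords, tolerance = 1e-12)
  }
})

test_that("ambiguous unwrapping (jumps near L/2) is refused", {
  coords <- array(0, dim = c(2, 1, 3))
  coords[2, 1, 1] <- 0.49 * 2   # jump of 0.49 L
  traj <- trajectory(coords, "A", 2, 1)
  expect_error(unwrap(traj), "ambiguous")
})

test_that("triclinic gro boxes are rejected loudly", {
  lines <- c("t= 0", "    1",
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "A", "A", 1, .5, .5, .5),
             "   2.00000   2.00000   2.00000   0.00000   0.00000   0.50000")
  tmp <- tempfile(fileext = ".gro")
  writeLines(lines, tmp)
  expect_error(read_trajectory(tmp), "triclinic")
})

test_that("scalar series roundtrip via CSV preserves values and spacing", {
  s <- scalar_series(matrix(rnorm(30), ncol = 3), dt = 0.25, time0 = 1)
  tmp <- tempfile(fileext = ".csv")
  write_scalar_series(s, tmp)
  back <- read_scalar_series(tmp)
  expect_equal(back$values, s$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$dt, 0.25)
  v <- scalar_series(rnorm(10), dt = 1)
  tmp2 <- tempfile(fileext = ".csv")
  write_scalar_series(v, tmp2)
  expect_equal(read_scalar_series(tmp2)$values[, 1], v$values[, 1],
               tolerance = 1e-12)
})

test_that("trajectory constructor validates its invariants", {
  coords <- array(0, dim = c(2, 3, 3))
  expect_error(trajectory(coords, c("A", "A"), 2, 1), "species")
  expect_error(trajectory(coords, c("A", "A", "A"), -1, 1), "box_length")
  expect_error(trajectory(coords, c("A", "A", "A"), 2, 0), "dt")
  coords[1, 1, 1] <- NaN
  expect_error(trajectory(coords, c("A", "A", "A"), 2, 1), "finite")
})
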