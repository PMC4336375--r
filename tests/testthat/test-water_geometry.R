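test_that("body-frame quaternion reproduces known rotations", {
  # reference orientation -> identity
  q0 <- body_frame_quaternion(ref_water_atoms())
  expect_equal(q0, c(1, 0, 0, 0), tolerance = 1e-12)

  # half-turn about laboratory z -> (0,0,0,1) up to hemisphere
  qz <- body_frame_quaternion(rotate_water(ref_water_atoms(),
                                           rot_axis_angle(c(0, 0, 1), pi)))
  expect_equal(abs(qz), c(0, 0, 0, 1), tolerance = 1e-9)

  # round trip against the rotation-matrix <-> quaternion oracle
  set.seed(42)
  for (i in 1:25) {
    M <- random_rotation()
    q <- body_frame_quaternion(rotate_water(ref_water_atoms(), M))
    expect_lt(orient_distance(q, quat_from_matrix(M)), 1e-9)
    # and the matrix reconstruction closes the loop
    expect_equal(quat_to_matrix(q), M, tolerance = 1e-9)
  }
})

test_that("degenerate and malformed water geometries are rejected", {
  expect_error(water_atoms(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)), "angle")
  o <- c(0, 0, 0)
  expect_error(
    body_frame_quaternion(
      structure(list(oxygen = o, hydrogen1 = c(1, 0, 0),
                     hydrogen2 = c(-1, 0, 0)), class = "water_atoms")),
    "collinear")
  expect_error(water_atoms(o, c(0.5, 0, 0.5), c(-1.2, 0, 1.2)), "20%")
})

test_that("distance metrics match their closed-form examples", {
  p1 <- water_pose(c(0, 0, 0), c(1, 0, 0, 0))
  p2 <- water_pose(c(3, 4, 0), c(1, 0, 0, 0))
  expect_identical(trans_distance(p1, p1), 0)
  expect_equal(trans_distance(p1, p2), 5)

  expect_identical(orient_distance(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(orient_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), pi)
  expect_equal(orient_distance(c(1, 0, 0, 0), c(sqrt(2)/2, sqrt(2)/2, 0, 0)),
               pi / 2)
  expect_error(orient_distance(c(1, 0.1, 0, 0), c(1, 0, 0, 0)), "unit")

  # Pythagorean composition: d_trans = 0.3, d_orient = 0.4
  qa <- c(cos(0.2), sin(0.2), 0, 0)
  a <- water_pose(c(0, 0, 0), c(1, 0, 0, 0))
  b <- water_pose(c(0.3, 0, 0), qa)
  expect_equal(total_distance(a, b), 0.5, tolerance = 1e-12)

  # d_total = 0.3 on site 1 and 0.4 on site 2
  qb <- c(cos(0.15), 0, sin(0.15), 0)
  pA <- list(water_pose(c(0, 0, 0), c(1, 0, 0, 0)),
             water_pose(c(5, 0, 0), c(1, 0, 0, 0)))
  pB <- list(water_pose(c(0, 0, 0), qb),
             water_pose(c(5, 0.4, 0), c(1, 0, 0, 0)))
  expect_equal(pair_distance(pA, pA), 0)
  expect_equal(pair_distance(pA, pB), 0.5, tolerance = 1e-12)

  # random poses against direct formula evaluation
  set.seed(7)
  for (i in 1:20) {
    x <- water_pose(rnorm(3), uniform_quaternion(1)[1, ])
    y <- water_pose(rnorm(3), uniform_quaternion(1)[1, ])
    dt <- sqrt(sum((x$position - y$position)^2))
    do <- 2 * acos(min(1, abs(sum(x$orientation * y$orientation))))
    expect_equal(trans_distance(x, y), dt, tolerance = 1e-12)
    expect_equal(total_distance(x, y), sqrt(dt^2 + do^2), tolerance = 1e-12)
  }
})

test_that("metrics are symmetric and satisfy the triangle inequality", {
  set.seed(11)
  n <- 10000
  pos <- array(rnorm(3 * 3 * n), c(n, 3, 3))
  qs <- lapply(1:3, function(i) uniform_quaternion(n))
  for (m in 1:3) {
    i <- m; j <- m %% 3 + 1; k <- (m + 1) %% 3 + 1
    dt_ij <- sqrt(rowSums((pos[, , i] - pos[, , j])^2))
    dt_ik <- sqrt(rowSums((pos[, , i] - pos[, , k])^2))
    dt_kj <- sqrt(rowSums((pos[, , k] - pos[, , j])^2))
    ao <- function(a, b) 2 * acos(pmin(1, abs(rowSums(qs[[a]] * qs[[b]]))))
    tot <- function(dt, do) sqrt(dt^2 + do^2)
    d_ij <- tot(dt_ij, ao(i, j)); d_ik <- tot(dt_ik, ao(i, k))
    d_kj <- tot(dt_kj, ao(k, j))
    expect_true(all(d_ij <= d_ik + d_kj + 1e-12))
    expect_true(all(ao(i, j) <= ao(i, k) + ao(k, j) + 1e-12))
  }
  # scalar interface agrees with the vectorized check and is symmetric
  for (r in sample(n, 25)) {
    a <- water_pose(pos[r, , 1], qs[[1]][r, ])
    b <- water_pose(pos[r, , 2], qs[[2]][r, ])
    expect_identical(total_distance(a, b), total_distance(b, a))
  }
})

test_that("double cover and degenerate reductions hold", {
  set.seed(3)
  for (i in 1:20) {
    q <- uniform_quaternion(1)[1, ]
    # double cover: negating either argument changes nothing, bit for bit
    p <- rnorm(3); p2 <- rnorm(3)
    q2 <- uniform_quaternion(1)[1, ]
    expect_identical(orient_distance(q, q2), orient_distance(q, -q2))
    expect_identical(orient_distance(q, q2), orient_distance(-q, q2))
    # self-antipode distance is zero up to the rounding of |q.q| toward 1
    expect_lt(orient_distance(q, -q), 1e-7)
    # equal orientations: total reduces to trans
    expect_equal(total_distance(water_pose(p, q), water_pose(p2, q)),
                 sqrt(sum((p - p2)^2)), tolerance = 1e-12)
    # equal positions: total reduces to orient
    expect_equal(total_distance(water_pose(p, q), water_pose(p, q2)),
                 orient_distance(q, q2), tolerance = 1e-12)
    # pair metric reduces to total when one member matches
    pa <- list(water_pose(p, q), water_pose(p2, q2))
    pb <- list(water_pose(p, q), water_pose(p2 + 1, q2))
    expect_equal(pair_distance(pa, pb),
                 total_distance(pa[[2]], pb[[2]]), tolerance = 1e-12)
  }
})

test_that("pose containers validate their invariants", {
  expect_error(water_pose(c(0, 0, 0), c(1, 1e-4, 0, 0)), "unit quaternion")
  expect_error(water_pose(c(0, 0, 0), c(1, 0, 0, 0), -1), "frame_index")
  q <- uniform_quaternion(5, seed = 1)
  expect_error(pose_series(matrix(0, 5, 3), q * 1.01), "unit quaternions")
  ps <- pose_series(matrix(rnorm(15), 5, 3), q)
  expect_equal(n_poses(ps), 5)
})
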