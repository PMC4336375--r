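test_that("pair energy matches closed-form limits", {
  a <- nonbonded_sites("A", matrix(c(0, 0, 0), 1), charge = 0, sigma = 3,
                       epsilon = 0.2)
  # LJ is exactly zero at r = sigma
  b <- nonbonded_sites("B", matrix(c(3, 0, 0), 1), charge = 0, sigma = 3,
                       epsilon = 0.2)
  expect_equal(pair_energy(a, b), 0, tolerance = 1e-14)
  # vanishing at huge separation
  far <- nonbonded_sites("B", matrix(c(1e6, 0, 0), 1), charge = 0.5,
                         sigma = 3, epsilon = 0.2)
  expect_lt(abs(pair_energy(a, far)), 1e-12)
  # singularity between interacting coincident sites
  qa <- nonbonded_sites("A", matrix(c(0, 0, 0), 1), charge = 0.5, sigma = 3,
                        epsilon = 0.2)
  atop <- nonbonded_sites("B", matrix(c(0, 0, 0), 1), charge = 0.1,
                          sigma = 0, epsilon = 0)
  expect_error(pair_energy(qa, atop), "singularity")
  # coincident but inert sites contribute nothing
  inert <- nonbonded_sites("B", matrix(c(0, 0, 0), 1), charge = 0,
                           sigma = 0, epsilon = 0)
  expect_identical(pair_energy(a, inert), 0)
})

test_that("pair energy equals an independently coded double loop", {
  set.seed(21)
  for (rep in 1:8) {
    a <- random_molecule(sample(2:4, 1), c(0, 0, 0))
    b <- random_molecule(sample(2:4, 1), c(runif(1, 4, 12), 0, 0))
    expect_equal(pair_energy(a, b), brute_pair_energy(a, b),
                 tolerance = 1e-10)
    expect_identical(pair_energy(a, b), pair_energy(b, a))
    expect_equal(pair_energy(a, b, scheme = "switched"),
                 brute_pair_energy(a, b, switched = TRUE), tolerance = 1e-10)
    box <- c(15, 17, 19)
    expect_equal(pair_energy(a, b, box = box),
                 brute_pair_energy(a, b, box = box), tolerance = 1e-10)
  }
})

test_that("hydrogen-bonded water dimer energy matches the oracle", {
  m <- tip4p2005()
  expect_lt(abs(2 * m$q_H + m$q_M), 1e-12)
  # donor rotated so one O-H points at the acceptor oxygen 2.8 A above
  half <- m$theta_HOH / 2 * pi / 180
  qd <- c(cos(-half / 2), 0, sin(-half / 2), 0)
  w1 <- water_nonbonded_sites(c(0, 0, 0), qd)
  w2 <- water_nonbonded_sites(c(0, 0, 2.8), c(1, 0, 0, 0))
  e <- pair_energy(w1, w2)
  expect_equal(e, brute_pair_energy(w1, w2), tolerance = 1e-10)
  expect_lt(e, 0)  # attractive in a hydrogen-bonding geometry
})

test_that("LJ switching is C1-continuous at both bounds", {
  a <- nonbonded_sites("A", matrix(c(0, 0, 0), 1), charge = 0, sigma = 3.2,
                       epsilon = 0.2)
  at <- function(r) pair_energy(a, nonbonded_sites("B", matrix(c(r, 0, 0), 1),
                                                   charge = 0, sigma = 3.2,
                                                   epsilon = 0.2),
                                scheme = "switched")
  for (r0 in c(9, 11)) {
    expect_lt(abs(at(r0 + 1e-7) - at(r0 - 1e-7)), 1e-8)
    h <- 1e-4
    d_left <- (at(r0 - h) - at(r0 - 3 * h)) / (2 * h)
    d_right <- (at(r0 + 3 * h) - at(r0 + h)) / (2 * h)
    expect_lt(abs(d_left - d_right), 1e-4)
  }
  expect_identical(at(11.5), 0)
})

test_that("solute-water energy averages frame energies", {
  st <- sample_site(synthetic_spec("gaussian_well", n_frames = 30, seed = 5))
  inert <- nonbonded_sites(c("C1", "C2", "C3"),
                           matrix(rnorm(9, sd = 3), 3), charge = 0,
                           sigma = 0, epsilon = 0)
  expect_equal(solute_water_energy(st, inert), 0)

  sol <- random_molecule(3, c(4, 0, 0))
  # single frame equals the frame energy
  one <- series_subset(st$poses, 0)
  w <- water_nonbonded_sites(one$position[1, ], one$quaternion[1, ])
  expect_equal(solute_water_energy(one, sol), pair_energy(w, sol),
               tolerance = 1e-12)
  # mean over frames equals the frame-by-frame oracle
  ps <- st$poses
  per_frame <- sapply(seq_len(nrow(ps$position)), function(i)
    brute_pair_energy(water_nonbonded_sites(ps$position[i, ],
                                            ps$quaternion[i, ]), sol))
  expect_equal(solute_water_energy(st, sol), mean(per_frame),
               tolerance = 1e-10)
  expect_error(solute_water_energy(series_subset(ps, integer(0)), sol),
               "insufficient")
})

test_that("water-water energies conserve the half-share bookkeeping", {
  set.seed(31)
  n <- 12
  mk <- function(center) pose_series(
    sweep(matrix(rnorm(3 * n, sd = 0.25), n, 3), 2, center, "+"),
    uniform_quaternion(n))
  w <- list(mk(c(0, 0, 0)), mk(c(2.8, 0, 0)), mk(c(0, 2.9, 0)))

  expect_identical(water_water_energy(w[[1]], list()), 0)

  e_site <- sapply(1:3, function(i) water_water_energy(w[[i]], w[-i]))
  # total unique-pair energy, frame by frame, independently coded
  tot <- mean(sapply(seq_len(n), function(f) {
    s <- 0
    for (i in 1:2) for (j in (i + 1):3) {
      wi <- water_nonbonded_sites(w[[i]]$position[f, ], w[[i]]$quaternion[f, ])
      wj <- water_nonbonded_sites(w[[j]]$position[f, ], w[[j]]$quaternion[f, ])
      s <- s + brute_pair_energy(wi, wj)
    }
    s
  }))
  expect_equal(sum(e_site), tot, tolerance = 1e-9)

  # two identical-trajectory waters split the pair energy evenly
  e12 <- water_water_energy(w[[1]], w[[2]])
  e21 <- water_water_energy(w[[2]], w[[1]])
  expect_equal(e12, e21, tolerance = 1e-12)
  expect_equal(e12 + e21, mean(sapply(seq_len(n), function(f) {
    wi <- water_nonbonded_sites(w[[1]]$position[f, ], w[[1]]$quaternion[f, ])
    wj <- water_nonbonded_sites(w[[2]]$position[f, ], w[[2]]$quaternion[f, ])
    brute_pair_energy(wi, wj)
  })), tolerance = 1e-10)
})

test_that("pose reconstruction and the energy ledger arithmetic are exact", {
  # pose -> atoms -> pose closes
  set.seed(17)
  for (i in 1:10) {
    q <- uniform_quaternion(1)[1, ]
    p <- rnorm(3)
    at <- pose_to_atoms(p, q)
    expect_lt(orient_distance(body_frame_quaternion(at), q), 1e-7)
    m <- tip4p2005()
    expect_equal(sqrt(sum((at$hydrogen1 - at$oxygen)^2)), m$r_OH,
                 tolerance = 1e-12)
  }
  expect_equal(delta_E_ifst(0, -11.5748, 1), 0)
  expect_lt(abs(delta_E_ifst(-30.27, 0, 1) - (-18.70)), 0.01)
  set.seed(2)
  for (i in 1:5) {
    v <- rnorm(4)
    expect_identical(delta_E_ifst(v[1], v[2], 2, v[4]),
                     v[1] + v[2] - 2 * v[4])
  }
})
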