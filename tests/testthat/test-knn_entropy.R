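test_that("absolute-entropy formula components are exact", {
  expect_identical(harmonic_number(0), 0)
  expect_equal(harmonic_number(1:4), c(1, 1.5, 1.5 + 1/3, 1.5 + 1/3 + 0.25))
  # increments are 1/j
  j <- 1:10
  expect_equal(harmonic_number(j) - harmonic_number(j - 1), 1 / j)

  # n = 2, k = 1, distances forcing the log argument to one: H = gamma
  d <- (6 / (2 * pi^3))^(1/6)
  expect_equal(knn_abs_entropy(c(d, d), p = 6), EULER_GAMMA, tolerance = 1e-12)

  expect_error(knn_abs_entropy(c(0, 1), p = 6), "duplicate")
})

test_that("compiled neighbour search agrees with a brute-force oracle", {
  set.seed(5)
  n <- 120
  pos <- matrix(rnorm(3 * n, sd = 0.4), n, 3)
  quat <- uniform_quaternion(n)
  for (k in c(1, 2, 4)) {
    d_pkg <- hydrosite:::.rigid_knn(pos, quat, k)
    expect_equal(d_pkg, brute_rigid_nn(pos, quat, k), tolerance = 1e-12)
  }
})

test_that("solute-water entropy recovers the Gaussian closed form", {
  errs <- sapply(1:8, function(s) {
    st <- sample_site(synthetic_spec("gaussian_well", n_frames = 4000,
                                     seed = s))
    solute_water_entropy(st)$value - analytic_reference(st)$S_sw
  })
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
  # sanity on the sign: a 0.5 A well is localized relative to bulk
  st <- sample_site(synthetic_spec("gaussian_well", n_frames = 4000, seed = 1))
  expect_lt(solute_water_entropy(st)$value, -1)
  expect_equal(analytic_reference(st)$S_sw, gauss_S_sw(0.5), tolerance = 1e-12)
})

test_that("estimates agree with closed forms for k = 1, 2, 4", {
  for (k in c(1, 2, 4)) {
    errs <- sapply(1:8, function(s) {
      st <- sample_site(synthetic_spec("harmonic_boltzmann", n_frames = 2000,
                                       seed = s))
      solute_water_entropy(st, k = k)$value - analytic_reference(st)$S_sw
    })
    expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
  }
})

test_that("estimator is invariant under relabeling and rigid motions", {
  st <- sample_site(synthetic_spec("gaussian_well", n_frames = 500, seed = 9))
  ps <- st$poses
  base <- solute_water_entropy(ps)$value

  # permutation invariance: relabeled samples give the identical estimate
  set.seed(1); perm <- sample.int(nrow(ps$position))
  shuffled <- pose_series(ps$position[perm, ], ps$quaternion[perm, ],
                          ps$frame[perm])
  expect_identical(solute_water_entropy(shuffled)$value, base)

  # global rotation + translation of the laboratory frame
  set.seed(2)
  M <- random_rotation(); qR <- quat_from_matrix(M); t <- rnorm(3, sd = 10)
  pos2 <- t(M %*% t(ps$position)) + rep(t, each = nrow(ps$position))
  quat2 <- t(apply(ps$quaternion, 1, function(q) quat_multiply(qR, q)))
  quat2 <- quat2 / sqrt(rowSums(quat2^2))
  moved <- pose_series(pos2, quat2, ps$frame)
  expect_equal(solute_water_entropy(moved)$value, base, tolerance = 1e-9)
})

test_that("uniform-support estimates converge with the known boundary bias", {
  # hard-edged supports carry a positive nearest-neighbour boundary bias
  # that decays as a power law; assert the decay and the sign rather than
  # tight equality
  med_err <- sapply(c(250, 1000, 4000), function(n) {
    errs <- sapply(1:6, function(s) {
      st <- sample_site(synthetic_spec("uniform_box", n_frames = n, seed = s))
      solute_water_entropy(st)$value - analytic_reference(st)$S_sw
    })
    median(errs)
  })
  expect_true(all(med_err > 0))
  expect_true(all(diff(med_err) < 0))
  # analytic reference for the 1 A box is R ln(rho)
  st <- sample_site(synthetic_spec("uniform_box", n_frames = 100, seed = 1))
  expect_equal(analytic_reference(st)$S_sw, 1.9872 * log(0.03324),
               tolerance = 1e-12)
})

test_that("duplicate poses raise unless jitter is requested", {
  pos <- matrix(0, 4, 3)
  quat <- matrix(rep(c(1, 0, 0, 0), each = 4), 4, 4)
  ps <- pose_series(pos, quat)
  expect_error(solute_water_entropy(ps), "duplicate")
  set.seed(1)
  est <- solute_water_entropy(ps, jitter = TRUE)
  expect_true(is.finite(est$value))
  expect_error(solute_water_entropy(pose_series(matrix(0, 1, 3),
                                                matrix(c(1, 0, 0, 0), 1, 4))),
               "insufficient")
})

test_that("pair entropy approaches marginal additivity and diverges for coupled sites", {
  # independent sites: the joint estimate approaches the sum of the
  # marginals, but only asymptotically -- the 12D estimate carries a
  # finite-n bias the two 6D estimates do not share. Assert the gap shrinks.
  gap_at <- function(n) mean(sapply(1:4, function(s) {
    pr <- sample_correlated_pair(synthetic_spec("correlated_pair",
                                                n_frames = n, seed = s,
                                                r = 0))
    pair_entropy(pr)$value - solute_water_entropy(pr$a)$value -
      solute_water_entropy(pr$b)$value
  }))
  gaps <- abs(sapply(c(500, 2000, 8000), gap_at))
  expect_true(all(diff(gaps) < 0))

  # a perfectly coupled pair lives on a lower-dimensional set: the joint
  # estimate decreases without bound as n grows
  est_coupled <- sapply(c(250, 1000), function(n) {
    st <- sample_site(synthetic_spec("gaussian_well", n_frames = n, seed = 3))
    b <- pose_series(st$poses$position + 2.8, st$poses$quaternion,
                     st$poses$frame)
    pair_entropy(pair_series(c("s1", "s2"), st$poses, b))$value
  })
  expect_lt(est_coupled[2], est_coupled[1])
})
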