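test_that("entropy and free-energy ledger arithmetic is exact", {
  bulk <- bulk_reference(S_bulk = "consistent")
  expect_equal(delta_S_ifst(bulk$S_bulk, 0, 1, bulk), 0)
  expect_identical(delta_G_ifst(0, 0), 0)
  expect_equal(delta_G_ifst(-13.50, 2.16), -11.34)

  # strongly bound benchmark site, assembled from its printed components
  S_sw <- -7.29 * 1000 / 300
  tc <- thermo_components(E_sw = -30.27, E_ww = 0, S_sw = S_sw, S_ww = 0,
                          bulk = bulk)
  expect_lt(abs(tc$minus_T_dS_ifst - 2.67), 0.01)
  expect_lt(abs(tc$dG_ifst - (-16.03)), 0.01)
  expect_lt(abs(tc$dE_ifst - (-18.70)), 0.01)

  # internal identities hold to 1e-9 for random inputs
  set.seed(6)
  for (i in 1:10) {
    v <- rnorm(4, sd = 5)
    tc <- thermo_components(v[1], v[2], v[3], v[4], bulk = bulk)
    expect_equal(tc$dG_ifst, tc$dE_ifst + tc$minus_T_dS_ifst,
                 tolerance = 1e-9)
    expect_equal(tc$minus_T_dS_ifst,
                 -300 * (v[3] + v[4] - bulk$S_bulk) / 1000, tolerance = 1e-9)
  }
})

test_that("bulk reference conventions are mutually consistent", {
  printed <- bulk_reference()
  expect_equal(printed$S_bulk, -15.5097)
  cons <- bulk_reference(S_bulk = "consistent")
  # T S_bulk equals E_bulk - dG_insertion by construction
  expect_equal(cons$S_bulk * cons$temperature / 1000,
               cons$E_bulk - cons$dG_insertion)
  expect_lt(abs(cons$S_bulk * cons$temperature / 1000 - (-4.62)), 0.01)
  # the two conventions differ by under 0.1 cal/mol/K
  expect_lt(abs(printed$S_bulk - cons$S_bulk), 0.1)
})

test_that("nonlocal correction follows the thermal-expansion form", {
  expect_equal(nonlocal_correction(0), -GAS_CONSTANT_CAL)
  b1 <- bulk_reference(alpha = 1 / 300)           # alpha T = 1
  expect_equal(nonlocal_correction(5, b1), 5)
  b2 <- bulk_reference(alpha = 1 / 600)           # alpha = 1/(2T)
  expect_equal(nonlocal_correction(0, b2), -GAS_CONSTANT_CAL / 2)
})

test_that("comparison statistics reproduce the benchmark agreement", {
  expect_error(comparison_stats(1:3, 1:2), "mismatch")
  idid <- comparison_stats(c(-1, -5, -9), c(-1, -5, -9))
  expect_equal(idid$r_squared, 1)
  expect_identical(idid$mud, 0)
  expect_identical(idid$mean_signed, 0)

  three <- comparison_stats(c(1, 2, 3), c(0, 3, 3))
  expect_equal(three$mud, 2 / 3)
  expect_identical(three$mean_signed, 0)

  b <- hydration_benchmark()
  expect_equal(nrow(b), 19)
  st <- comparison_stats(b$dG_reference, b$dG_ifst)
  expect_equal(round(st$r_squared, 3), 0.995)
  expect_equal(round(st$mud, 2), 0.45)
  expect_equal(round(st$mean_signed, 2), -0.31)
})

test_that("per-site summaries reproduce the benchmark footer", {
  tab <- hydration_site_table()
  expect_equal(nrow(tab), 23)
  sm <- summarize_sites(tab[c("mTdS_ifst", "dG_ifst", "dE_ifst")])
  expect_equal(sm["mean", "mTdS_ifst"], 1.82)
  expect_equal(sm["minimum", "mTdS_ifst"], 0.46)
  expect_equal(sm["maximum", "mTdS_ifst"], 2.67)
  expect_equal(sm["minimum", "dG_ifst"], -16.03)
  expect_equal(sm["maximum", "dG_ifst"], -2.55)
  expect_equal(sm["minimum", "dE_ifst"], -18.70)

  one <- summarize_sites(data.frame(x = 1.234))
  expect_true(all(one$x == 1.23))

  # every doubly assembled row closes its own ledger at rounding precision
  expect_true(all(abs(tab$dE_ifst + tab$mTdS_ifst - tab$dG_ifst) < 0.015))
})

test_that("the end-to-end report closes its ledger and recovers a harmonic well", {
  # two co-occupied synthetic sites, no solute
  n <- 400
  pr <- sample_correlated_pair(synthetic_spec("correlated_pair",
                                              n_frames = n, seed = 3, r = 0.3))
  frames <- lapply(seq_len(n), function(i) list(
    frame_index = i - 1L,
    mol_id = c("w1", "w2"),
    position = rbind(pr$a$position[i, ], pr$b$position[i, ]),
    quaternion = rbind(pr$a$quaternion[i, ], pr$b$quaternion[i, ])))
  traj <- water_trajectory(frames)
  sites <- list(hydration_site("s1", c(0, 0, 0), radius = 2.5),
                hydration_site("s2", c(2.8, 0, 0), radius = 2.5))
  rep <- ifst_site_report(traj, sites, n_permutations = 2, seed = 5)
  expect_equal(nrow(rep$per_site), 2)
  expect_equal(nrow(rep$pairs), 1)
  expect_equal(rep$per_site$dG_ifst,
               rep$per_site$dE_ifst + rep$per_site$minus_T_dS_ifst,
               tolerance = 1e-9)
  # both members carry half the pair's -(I_ww) as S_ww
  expect_equal(rep$per_site$minus_T_S_ww[1], rep$per_site$minus_T_S_ww[2])

  # blocked variant: disjoint blocks, mean/sd columns present
  repb <- ifst_site_report(traj, sites, n_blocks = 2, block_size = 200,
                           n_permutations = 2, seed = 5)
  expect_true(all(c("dG_ifst_mean", "dG_ifst_sd") %in% names(repb$per_site)))

  # a harmonic-well site recovers the closed-form -T dS_IFST
  bulk <- bulk_reference(S_bulk = "consistent")
  errs <- sapply(1:5, function(s) {
    st <- sample_site(synthetic_spec("harmonic_boltzmann", n_frames = 4000,
                                     seed = s))
    est <- solute_water_entropy(st, rho = bulk$rho)
    mTdS <- -300 * delta_S_ifst(est$value, 0, 1, bulk) / 1000
    s2 <- 1.9872e-3 * 300 / 0.5
    S_cf <- 1.9872 * (1.5 * log(2 * pi * exp(1) * s2) + log(bulk$rho))
    mTdS_cf <- -300 * (S_cf - bulk$S_bulk) / 1000
    mTdS - mTdS_cf
  })
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(5))
})
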