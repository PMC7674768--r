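test_that("sphere dose matches a decay-by-decay hand computation", {
  chain <- build_default_chain()
  tau <- 0.37; mass <- 53; rbe <- 5; af <- 0.01
  res <- sphere_dose_coefficient(tau, sphere_organ("parotid", mass, af),
                                 chain, rbe_alpha = rbe)
  # spreadsheet-style oracle: loop nuclide by nuclide with explicit constants
  mev_to_j <- 1.602176634e-13
  unweighted <- weighted <- 0
  for (i in seq_len(nrow(chain))) {
    decays <- tau * 3600 * 1e6 * chain$yield[i]
    e_local <- chain$e_alpha_mev[i] + chain$e_beta_mev[i] +
      chain$e_gamma_mev[i] * af
    e_w <- rbe * chain$e_alpha_mev[i] + chain$e_beta_mev[i] +
      chain$e_gamma_mev[i] * af
    unweighted <- unweighted + decays * e_local * mev_to_j / (mass / 1000)
    weighted <- weighted + decays * e_w * mev_to_j / (mass / 1000)
  }
  expect_equal(res$total_unweighted, unweighted, tolerance = 1e-12)
  expect_equal(res$total_weighted, weighted, tolerance = 1e-12)
})

test_that("RBE of one collapses weighted and unweighted totals", {
  res <- sphere_dose_coefficient(0.5, sphere_organ("sg", 17), rbe_alpha = 1)
  expect_equal(res$total_weighted, res$total_unweighted, tolerance = 1e-14)
})

test_that("alpha dominates the weighted dose for any sphere", {
  for (mass in c(13, 53, 89)) {
    res <- sphere_dose_coefficient(0.4, sphere_organ("o", mass), rbe_alpha = 5)
    expect_gte(emission_shares(res)[["alpha"]], 0.982)
  }
})

test_that("excluding Po-213 removes about 30% of the unweighted dose", {
  organ <- sphere_organ("parotid", 53)
  full <- sphere_dose_coefficient(0.4, organ)
  no_po <- sphere_dose_coefficient(0.4, organ, exclude = "Po-213")
  reduction <- 1 - no_po$total_unweighted / full$total_unweighted
  expect_equal(reduction, 0.30, tolerance = 0.02 / 0.30)
  expect_error(sphere_dose_coefficient(0.4, organ, exclude = "Xx-999"),
               "unknown nuclide")
})

test_that("dose is linear in residence time, additive, and inverse in mass", {
  organ <- sphere_organ("parotid", 53)
  r1 <- sphere_dose_coefficient(0.4, organ)
  r2 <- sphere_dose_coefficient(0.8, organ)
  expect_equal(r2$total_weighted, 2 * r1$total_weighted, tolerance = 1e-14)
  expect_equal(r1$total_unweighted, sum(r1$per_nuclide$dose_total_gy),
               tolerance = 1e-14)
  # exclusion is exact subtraction
  no_pb <- sphere_dose_coefficient(0.4, organ, exclude = "Pb-209")
  pb_row <- r1$per_nuclide$dose_total_gy[r1$per_nuclide$nuclide == "Pb-209"]
  expect_equal(no_pb$total_unweighted, r1$total_unweighted - pb_row,
               tolerance = 1e-14)
  heavy <- sphere_dose_coefficient(0.4, sphere_organ("parotid", 106))
  expect_equal(heavy$total_weighted, r1$total_weighted / 2, tolerance = 1e-14)
})

test_that("emission shares sum to one and obey the photon policy", {
  res0 <- sphere_dose_coefficient(0.4, sphere_organ("o", 53))
  expect_equal(sum(emission_shares(res0)), 1, tolerance = 1e-12)
  expect_identical(emission_shares(res0)[["gamma"]], 0)
  res_af <- sphere_dose_coefficient(0.4, sphere_organ("o", 53, 0.05))
  expect_gt(emission_shares(res_af)[["gamma"]], 0)
  # large RBE drives the alpha share towards one
  res_big <- sphere_dose_coefficient(0.4, sphere_organ("o", 53),
                                     rbe_alpha = 1e6)
  expect_gt(emission_shares(res_big)[["alpha"]], 0.999999)
})

test_that("units work out: 1 h residence of a 1 MeV-per-decay source in 1 kg", {
  # tau = 1 h -> 3.6e9 decays/MBq; 1 MeV = 1.602176634e-13 J; mass 1 kg
  # expected dose = 3.6e9 * 1.602176634e-13 = 5.767835882e-4 Gy/MBq
  chain <- build_default_chain()
  chain$e_alpha_mev <- ifelse(chain$nuclide == "Ac-225", 1, 0)
  chain$e_beta_mev <- 0
  chain$e_gamma_mev <- 0
  res <- sphere_dose_coefficient(1, sphere_organ("unit", 1000), chain,
                                 rbe_alpha = 1)
  expect_equal(res$total_unweighted, 3.6e9 * 1.602176634e-13,
               tolerance = 1e-12)
})

test_that("weighted-to-alpha conversion inverts the chain's energy split", {
  chain <- build_default_chain()
  res <- sphere_dose_coefficient(0.4, sphere_organ("o", 53), chain,
                                 rbe_alpha = 5)
  alpha_unweighted <- sum(res$per_nuclide$dose_alpha_gy)
  expect_equal(alpha_dose_from_weighted(res$total_weighted, chain, 5),
               alpha_unweighted, tolerance = 1e-12)
})
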