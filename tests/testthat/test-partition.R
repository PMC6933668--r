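test_that("partition denominator matches hand-evaluated cases", {
  ads <- adsorption_params(K_dR = 0.05, kappa_RF = 10, kappa_RX = 10,
                           kappa_RL = 50, kappa_Rs = 50)
  # 1 + 10*(0.2/0.1) + 10*(0.05/0.1) + (0.9/0.1)*(0.05 + 50*0 + 50*0.1)
  expect_equal(partition_denominator(0.1, 0.2, 0.05, 0, 0.1, 0.9, ads),
               71.45, tolerance = 1e-12)

  # equal split when the only sink balances the free-pool scale
  only_GR <- adsorption_params(K_dR = 0.05, kappa_RF = 0, kappa_RX = 0,
                               kappa_RL = 0, kappa_Rs = 0)
  expect_equal(partition_denominator(0.05 * 0.9, 0, 0, 0, 0, 0.9, only_GR),
               2)

  # with all competing terms off, D = 1 + eps_l * K_dR / c_GR
  expect_equal(partition_denominator(0.2, 0, 0, 0.3, 0.4, 0.8, only_GR),
               1 + 0.8 * 0.05 / 0.2)

  expect_error(partition_denominator(-0.1, 0, 0, 0, 0, 0.9, ads),
               "non-negative")
})

test_that("closed-form partition matches hand-worked pools and is linear", {
  ads <- adsorption_params(K_dR = 0.05, kappa_RF = 10, kappa_RX = 10,
                           kappa_RL = 50, kappa_Rs = 50)
  cat <- species_catalog()
  dens <- density_spec()
  # state engineered to reproduce the worked denominator of 71.45 exactly:
  # slurry-molar c_GR = 0.1, c_GF = 0.2, c_X = 0.05 and liquid c_ss = 0.1
  # at eps_l = 0.9, c_ET = 1e-4
  f_is <- 0.1
  s <- slurry_state(
    f_GR = 0.1 * cat$MW_G / 1000, f_GF = 0.2 * cat$MW_G / 1000,
    f_X = 0.05 * cat$MW_X / 1000,
    f_O = f_is - (0.3 * cat$MW_G + 0.05 * cat$MW_X) / 1000,
    f_g = 0.1 * 0.9 * cat$MW_g / 1000, f_ET = 1e-4 * cat$MW_E / 1000
  )
  expect_equal(insoluble_fraction(s), 0.1, tolerance = 1e-12)
  p <- partition_enzyme(s, ads, cat, dens)
  expect_equal(p$c_EGR, 1e-4 / 71.45, tolerance = 1e-10)
  expect_equal(p$c_EGF, 10 * 2 * 1e-4 / 71.45, tolerance = 1e-10)
  expect_equal(p$c_EX, 10 * 0.5 * 1e-4 / 71.45, tolerance = 1e-10)

  # no enzyme -> all pools zero
  s0 <- s
  s0[["f_ET"]] <- 0
  p0 <- partition_enzyme(s0, ads, cat, dens)
  expect_true(all(as.numeric(p0[1, 1:6]) == 0))

  # linearity in total enzyme
  s2 <- s
  s2[["f_ET"]] <- 2 * s[["f_ET"]]
  p2 <- partition_enzyme(s2, ads, cat, dens)
  expect_equal(as.numeric(p2[1, 1:6]), 2 * as.numeric(p[1, 1:6]),
               tolerance = 1e-12)
})

test_that("partition closes to total enzyme on randomized states", {
  set.seed(21)
  cat <- species_catalog()
  dens <- density_spec(use_constant_density = FALSE)
  for (i in 1:1000) {
    s <- random_state()
    ads <- random_adsorption()
    p <- partition_enzyme(s, ads, cat, dens)
    c_ET <- s[["f_ET"]] * slurry_density(s, dens) / cat$MW_E
    expect_equal(sum(as.numeric(p[1, 1:6])), c_ET, tolerance = 1e-10)
  }
})

test_that("closed form agrees with the independent equilibrium root-solve", {
  set.seed(22)
  cat <- species_catalog()
  dens <- density_spec(use_constant_density = FALSE)
  for (i in 1:50) {
    s <- random_state()
    ads <- random_adsorption()
    p <- as.numeric(partition_enzyme(s, ads, cat, dens)[1, 1:6])
    q <- as.numeric(oracle_partition(s, ads, cat, dens))
    expect_rel_equal(p[p > 0], q[p > 0], 1e-8)
  }
})

test_that("sugar inhibition and accessibility shift the partition as expected", {
  ads <- adsorption_params()
  cat <- species_catalog()
  base <- toy_state()
  sugars <- seq(0, 0.08, by = 0.02)
  pools <- lapply(sugars, function(fg) {
    s <- base
    s[["f_g"]] <- fg
    partition_enzyme(s, ads, cat)
  })
  c_EGR <- vapply(pools, function(p) p$c_EGR, numeric(1))
  c_EGF <- vapply(pools, function(p) p$c_EGF, numeric(1))
  expect_true(all(diff(c_EGR) < 0))
  expect_true(all(diff(c_EGF) < 0))

  # increasing kappa_RF raises the facile-to-recalcitrant adsorbed ratio
  ratios <- vapply(c(2, 5, 10, 20), function(k) {
    p <- partition_enzyme(base, adsorption_params(kappa_RF = k), cat)
    p$c_EGF / p$c_EGR
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("partition is continuous as recalcitrant glucan is depleted", {
  ads <- adsorption_params()
  cat <- species_catalog()
  s <- toy_state()
  f_grid <- c(1e-4, 1e-6, 1e-8, 1e-10, 0)
  pools <- lapply(f_grid, function(f) {
    s[["f_GR"]] <- f
    partition_enzyme(s, ads, cat)
  })
  c_EGR <- vapply(pools, function(p) p$c_EGR, numeric(1))
  expect_true(all(diff(c_EGR) < 0))
  expect_identical(c_EGR[length(c_EGR)], 0)
  # remaining pools stay finite and close to their limit
  expect_equal(pools[[4]]$c_EGF, pools[[5]]$c_EGF, tolerance = 1e-4)
})

test_that("accessibility is the reciprocal of kappa_RF", {
  expect_equal(accessibility(adsorption_params(kappa_RF = 1)), 1)
  expect_equal(accessibility(adsorption_params(kappa_RF = 2)), 0.5)
  expect_equal(accessibility(adsorption_params(kappa_RF = 9.34)), 1 / 9.34)
  expect_warning(a <- accessibility(adsorption_params(kappa_RF = 0.5)),
                 "invalid")
  expect_equal(a, 2)
})
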