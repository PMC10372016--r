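test_that("generator honors size, seed and support invariants", {
  expect_equal(nrow(synthesize_samples(n = 0, seed = 1)), 0)

  a <- synthesize_samples(n = 40, seed = 5)
  b <- synthesize_samples(n = 40, seed = 5)
  expect_identical(a, b)
  c <- synthesize_samples(n = 40, seed = 6)
  expect_false(identical(a, c))

  ions <- c("k", "na", "ca", "mg", "cl", "so4", "hco3", "co3", "no3")
  expect_true(all(as.matrix(a[ions]) >= 0))
  expect_true(all(a$ph >= 5.11 & a$ph <= 9.37))
  expect_true(all(a$depth_m >= 3.5 & a$depth_m <= 340))
})

test_that("point-mass marginals give identical samples with fixed balance", {
  marg <- tibble::tribble(
    ~analyte, ~family, ~mean, ~sd, ~lower, ~upper,
    "na", "point", 46, 0, NA, NA,
    "cl", "point", 70.9, 0, NA, NA
  )
  cfg <- synthetic_config(n = 10, seed = 9, marginals = marg,
                          correlations = hainan_correlations()[0, ],
                          cbe_repair = FALSE)
  d <- synthesize_samples(config = cfg)
  expect_equal(nrow(dplyr::distinct(dplyr::select(d, "na", "cl"))), 1)
  cbe <- charge_balance(d)$cbe
  expect_equal(cbe, rep(cbe[1], 10))
})

test_that("infeasible truncated-normal targets error naming the analyte", {
  marg <- tibble::tribble(
    ~analyte, ~family, ~mean, ~sd, ~lower, ~upper,
    "ph", "truncnorm", 7, 3, 6, 8
  )
  cfg <- synthetic_config(n = 5, seed = 1, marginals = marg,
                          correlations = hainan_correlations()[0, ],
                          cbe_repair = FALSE)
  expect_error(synthesize_samples(config = cfg), "ph")
})

test_that("truncated-normal moment matching recovers the pH targets", {
  # the parent sd must exceed the target because truncation shrinks spread
  cfg <- synthetic_config(n = 20000, seed = 13, cbe_repair = FALSE)
  d <- synthesize_samples(config = cfg)
  expect_equal(mean(d$ph), 7.47, tolerance = 0.01)
  expect_equal(sd(d$ph), 1.03, tolerance = 0.02)
  expect_true(all(d$ph >= 5.11 & d$ph <= 9.37))
})

test_that("charge-balance repair is minimal, boundary-respecting and flagged", {
  balanced <- sample_from_meq(na = 2, cl = 2)
  expect_equal(cbe_repair(balanced)$na, balanced$na)
  expect_false(cbe_repair(balanced)$cbe_repaired)

  # cations 5, anions 4 meq/L, balancing on Cl alone -> exact balance
  lop <- sample_from_meq(na = 3, ca = 2, cl = 2, hco3 = 2)
  rep0 <- cbe_repair(lop, tolerance = 0, ions = "cl")
  expect_equal(charge_balance(rep0)$cbe, 0, tolerance = 1e-6)
  expect_equal(rep0$na, lop$na)     # other ions untouched
  expect_equal(rep0$hco3, lop$hco3)
  expect_equal(oracle_meq(rep0$cl, "cl"), 3, tolerance = 1e-9)

  # within tolerance -> untouched
  mild <- sample_from_meq(na = 2.6, cl = 2.4)  # CBE = 4%
  rep5 <- cbe_repair(mild, tolerance = 5)
  expect_equal(rep5$na, mild$na)
  expect_equal(rep5$cl, mild$cl)

  # proportional method lands every sample inside the QC band
  set.seed(161)
  d <- random_samples(200)
  repp <- cbe_repair(d, method = "proportional")
  expect_true(all(charge_balance(repp)$cbe_ok))

  # unrepairable sample (no candidate can go negative enough) is flagged
  hopeless <- sample_from_meq(hco3 = 5, so4 = 3)   # no cations at all
  flagged <- cbe_repair(hopeless, ions = "cl")
  expect_true(flagged$cbe_flagged)
  expect_equal(flagged$hco3, hopeless$hco3)
})

test_that("validation recovers point-mass configs exactly and rejects empty data", {
  marg <- tibble::tribble(
    ~analyte, ~family, ~mean, ~sd, ~lower, ~upper,
    "na", "point", 46, 0, NA, NA,
    "cl", "point", 70.9, 0, NA, NA
  )
  cfg <- synthetic_config(n = 8, seed = 3, marginals = marg,
                          correlations = hainan_correlations()[0, ],
                          cbe_repair = FALSE)
  d <- synthesize_samples(config = cfg)
  v <- validate_synthetic(d, cfg)
  expect_true(all(v$marginals$mean_ok))
  expect_true(all(v$marginals$sd_ok))
  expect_error(validate_synthetic(d[0, ], cfg), "empty")
})

test_that("nitrate exceedance of a synthetic cohort tracks the lognormal tail", {
  cfg <- synthetic_config(n = 5000, seed = 29, cbe_repair = FALSE)
  d <- synthesize_samples(config = cfg)
  got <- nitrate_exceedance(d, 20)$pct_exceed / 100
  # closed-form tail of the moment-matched lognormal NO3 marginal
  s2 <- log(1 + (51.52 / 38.92)^2)
  mu <- log(38.92) - s2 / 2
  expected <- stats::plnorm(20, mu, sqrt(s2), lower.tail = FALSE)
  expect_equal(got, expected, tolerance = 0.05)
})
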