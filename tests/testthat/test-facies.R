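test_that("Piper fractions hit the vertex and symmetry cases", {
  pure <- sample_from_meq(ca = 2, hco3 = 2)
  pc <- piper_coordinates(pure)
  expect_equal(c(pc$cat_ca, pc$cat_mg, pc$cat_nak), c(100, 0, 0))
  expect_equal(c(pc$an_hco3, pc$an_so4, pc$an_cl), c(100, 0, 0))

  equal3 <- sample_from_meq(ca = 1, mg = 1, na = 1, hco3 = 3)
  pc <- piper_coordinates(equal3)
  expect_equal(c(pc$cat_ca, pc$cat_mg, pc$cat_nak), rep(100 / 3, 3),
               tolerance = 1e-9)

  camg <- sample_from_meq(ca = 1.7, mg = 1.7, cl = 3.4)
  pc <- piper_coordinates(camg)
  expect_equal(c(pc$cat_ca, pc$cat_mg, pc$cat_nak), c(50, 50, 0), tolerance = 1e-9)

  expect_error(piper_coordinates(sample_from_meq()), "zero")
})

test_that("Piper fraction triples always sum to 100", {
  set.seed(51)
  d <- random_samples(200)
  pc <- piper_coordinates(d)
  expect_equal(pc$cat_ca + pc$cat_mg + pc$cat_nak, rep(100, 200), tolerance = 1e-9)
  expect_equal(pc$an_hco3 + pc$an_so4 + pc$an_cl, rep(100, 200), tolerance = 1e-9)
  expect_true(all(pc[c("cat_ca", "cat_mg", "cat_nak",
                       "an_hco3", "an_so4", "an_cl")] >= 0))
})

test_that("Shchukarev typing applies the 25% threshold with ordered labels", {
  d <- sample_from_meq(hco3 = 5, cl = 3, so4 = 2, na = 7, ca = 2, mg = 1)
  expect_equal(shchukarev_classify(d)$facies, "HCO3–Cl–Na")

  d2 <- sample_from_meq(hco3 = 4, ca = 4)
  expect_equal(shchukarev_classify(d2)$facies, "HCO3–Ca")

  d3 <- sample_from_meq(hco3 = 4, cl = 3.5, so4 = 2.5,
                        na = 4, ca = 3.5, mg = 1.5, k = 1)
  expect_equal(shchukarev_classify(d3)$facies,
               "HCO3–Cl–SO4–Na–Ca")

  # invariant to uniform scaling of all concentrations
  set.seed(61)
  d4 <- random_samples(50)
  ions <- c("k", "na", "ca", "mg", "cl", "so4", "hco3", "co3", "no3")
  d5 <- dplyr::mutate(d4, dplyr::across(dplyr::all_of(ions), ~ .x * 7.3))
  expect_equal(shchukarev_classify(d4)$facies, shchukarev_classify(d5)$facies)
})

test_that("Gibbs classification assigns the documented regions", {
  rock <- sample_from_meq(na = 0.3, ca = 0.7, hco3 = 1)
  rock$tds <- 300
  expect_equal(as.character(gibbs_classify(rock)$gibbs_region), "rock_dominance")

  precip <- sample_from_meq(na = 0.9, ca = 0.1, hco3 = 1)
  precip$tds <- 30
  expect_equal(as.character(gibbs_classify(precip)$gibbs_region),
               "precipitation_dominance")

  sea <- sample_from_meq(na = 49, ca = 1, cl = 50)
  sea$tds <- 50000
  expect_equal(as.character(gibbs_classify(sea)$gibbs_region),
               "evaporation_dominance")

  set.seed(71)
  d <- random_samples(100)
  rd <- ratio_diagnostics(d)
  expect_true(all(rd$gibbs_cation >= 0 & rd$gibbs_cation <= 1, na.rm = TRUE))
  expect_true(all(rd$gibbs_anion >= 0 & rd$gibbs_anion <= 1, na.rm = TRUE))
})

test_that("ratio diagnostics compute boundary and undefined cases", {
  d <- sample_from_meq(ca = 1, mg = 1, hco3 = 2, na = 2, cl = 2)
  rd <- ratio_diagnostics(d)
  expect_equal(rd$carb_index, 1, tolerance = 1e-9)
  expect_equal(rd$exch_x, 0, tolerance = 1e-9)  # Na on the 1:1 Cl line

  online <- sample_from_meq(na = 3, k = 1, cl = 2, mg = 1, ca = 1,
                            so4 = 2, hco3 = 2)
  rd2 <- ratio_diagnostics(online)
  expect_equal(rd2$exch_x, 2, tolerance = 1e-9)
  expect_equal(rd2$exch_y, -2, tolerance = 1e-9)

  nothing <- sample_from_meq(ca = 1)
  rd3 <- ratio_diagnostics(nothing)
  expect_true(is.na(rd3$mg_na))       # Na denominator zero
  expect_true(is.na(rd3$carb_index))  # HCO3 denominator zero
})

test_that("chloro-alkaline indices and exchange direction follow their definitions", {
  none <- sample_from_meq(na = 1, k = 1, cl = 2, hco3 = 1)
  r <- cai_indices(none)
  expect_equal(r$cai_1, 0)
  expect_equal(r$cai_2, 0)
  expect_equal(as.character(r$direction), "none")

  rev <- sample_from_meq(cl = 2, na = 1, so4 = 2, hco3 = 1, no3 = 1)
  r <- cai_indices(rev)
  expect_equal(r$cai_1, 0.5, tolerance = 1e-9)
  expect_equal(r$cai_2, 0.25, tolerance = 1e-9)
  expect_equal(as.character(r$direction), "reverse_exchange")

  fwd <- sample_from_meq(cl = 1, na = 2, k = 1, so4 = 1, hco3 = 1)
  r <- cai_indices(fwd)
  expect_equal(r$cai_1, -2, tolerance = 1e-9)
  expect_equal(r$cai_2, -1, tolerance = 1e-9)
  expect_equal(as.character(r$direction), "forward_exchange")

  # CAI-I and CAI-II share sign whenever the common numerator is nonzero
  set.seed(81)
  d <- random_samples(300)
  r <- cai_indices(d)
  nz <- !is.na(r$cai_1) & !is.na(r$cai_2) & abs(r$cai_1) > 1e-12
  expect_true(all(sign(r$cai_1[nz]) == sign(r$cai_2[nz])))
})

test_that("cation-exchange OLS recovers exact and degenerate slopes", {
  # points exactly on y = -x: x = Na meq, y = -HCO3 meq with HCO3 = Na
  na_meq <- seq(0.5, 3, length.out = 10)
  d <- purrr::map_dfr(na_meq, ~ sample_from_meq(na = .x, hco3 = .x))
  fit <- suppressWarnings(cation_exchange_fit(d))  # exact fit trips lm's summary
  expect_equal(fit$slope, -1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)

  flat <- purrr::map_dfr(na_meq, ~ sample_from_meq(na = .x))
  expect_equal(cation_exchange_fit(flat)$slope, 0, tolerance = 1e-9)

  same <- purrr::map_dfr(rep(1, 5), ~ sample_from_meq(na = .x, hco3 = 2))
  expect_error(cation_exchange_fit(same), "zero variance")
})

test_that("Pearson screen matches a brute-force two-pass oracle and cor.test", {
  set.seed(91)
  d <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  d$b <- d$a * 0.6 + d$b
  cs <- correlation_screen(d, c("a", "b", "c"))

  # brute-force two-pass covariance oracle
  for (v1 in c("a", "b", "c")) {
    for (v2 in c("a", "b", "c")) {
      x <- d[[v1]]; y <- d[[v2]]
      cov_xy <- sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1)
      r_oracle <- cov_xy / sqrt(sum((x - mean(x))^2) / (length(x) - 1)) /
        sqrt(sum((y - mean(y))^2) / (length(y) - 1))
      expect_equal(cs$r[v1, v2], r_oracle, tolerance = 1e-12)
    }
  }
  ct <- stats::cor.test(d$a, d$b)
  expect_equal(cs$p["a", "b"], ct$p.value, tolerance = 1e-9)

  exact <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  expect_equal(correlation_screen(exact, c("x", "y"))$r["x", "y"], 1)

  set.seed(92)
  big <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  expect_lt(abs(correlation_screen(big, c("x", "y"))$r["x", "y"]), 0.1)

  flat <- tibble::tibble(x = rep(1, 10), y = rnorm(10))
  expect_true(is.na(correlation_screen(flat, c("x", "y"))$r["x", "y"]))
})

test_that("nitrate exceedance screening uses a strict threshold", {
  expect_equal(nitrate_exceedance(tibble::tibble(no3 = rep(0, 5)))$pct_exceed, 0)
  expect_equal(nitrate_exceedance(tibble::tibble(no3 = c(25, 1, 2, 3)))$pct_exceed, 25)
  expect_equal(nitrate_exceedance(tibble::tibble(no3 = c(20, 20)))$n_exceed, 0)
})
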