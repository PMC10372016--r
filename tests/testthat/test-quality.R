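test_that("relative weights normalise and validate", {
  w <- tibble::tibble(parameter = letters[1:4], weight = rep(2, 4),
                      standard = rep(1, 4))
  expect_equal(relative_weights(w)$rel_weight, rep(0.25, 4))
  expect_equal(relative_weights(w[1, ])$rel_weight, 1)
  w2 <- tibble::tibble(parameter = c("a", "b", "c"), weight = c(5, 3, 2),
                       standard = 1)
  expect_equal(relative_weights(w2)$rel_weight, c(0.5, 0.3, 0.2))
  expect_error(relative_weights(dplyr::mutate(w, weight = c(1, 0, 1, 1))),
               "positive")
})

test_that("WQI identity, zero and effective-weight cases", {
  # concentrations exactly at the standards -> WQI 100 for any weights
  std <- wqi_weights()
  at_standard <- tibble::as_tibble(as.list(stats::setNames(std$standard,
                                                           std$parameter)))
  for (seed in 1:5) {
    set.seed(seed)
    w <- dplyr::mutate(std, weight = runif(dplyr::n(), 0.5, 9))
    res <- water_quality_index(at_standard, w)
    expect_equal(res$scores$wqi, 100, tolerance = 1e-9)
  }

  # neutral pH and zero concentrations -> WQI 0, class excellent
  zero <- dplyr::mutate(at_standard, dplyr::across(-"ph", ~0), ph = 7)
  res0 <- water_quality_index(zero, std)
  expect_equal(res0$scores$wqi, 0)
  expect_equal(as.character(res0$scores$wqi_class), "excellent")

  # two-parameter worked case: W = (0.5, 0.5), C/S = (0.5, 1.5)
  w2 <- tibble::tibble(parameter = c("na", "cl"), weight = c(1, 1),
                       standard = c(100, 100))
  d2 <- tibble::tibble(na = 50, cl = 150)
  res2 <- water_quality_index(d2, w2)
  expect_equal(res2$scores$wqi, 100, tolerance = 1e-9)
  expect_equal(sort(res2$effective_weights$ew), c(25, 75), tolerance = 1e-9)
})

test_that("WQI is linear in concentrations and scale-invariant in (C, S)", {
  set.seed(101)
  d <- random_samples(20)
  w <- dplyr::filter(wqi_weights(), parameter != "ph")
  base <- water_quality_index(d, w)$scores$wqi
  ions <- intersect(w$parameter, names(d))
  d2 <- dplyr::mutate(d, dplyr::across(dplyr::all_of(ions), ~ .x * 3))
  # th is derived from ca and mg, so it scales with them too
  expect_equal(water_quality_index(d2, w)$scores$wqi, 3 * base, tolerance = 1e-9)

  w_scaled <- dplyr::mutate(w, standard = standard * 3)
  expect_equal(water_quality_index(d2, w_scaled)$scores$wqi, base,
               tolerance = 1e-9)
})

test_that("WQI class bands are total and match the stated bounds", {
  expect_equal(as.character(classify_wqi(c(9.96, 50, 100, 266.1, 300))),
               c("excellent", "good", "poor", "very_poor", "non_drinkable"))
  set.seed(111)
  x <- c(runif(500, 0, 600), 0, 49.999, 299.999)
  expect_false(anyNA(classify_wqi(x)))
})

test_that("irrigation indices match direct unit cases", {
  d <- sample_from_meq(na = 1, ca = 1, mg = 1)
  expect_equal(sar(d), 1, tolerance = 1e-9)
  expect_equal(sar(sample_from_meq(ca = 1, mg = 1)), 0)
  expect_equal(sar(sample_from_meq(na = 2, ca = 2)), 2, tolerance = 1e-9)
  expect_true(is.na(sar(sample_from_meq(na = 1))))

  expect_equal(percent_na(sample_from_meq(na = 1, k = 1, ca = 1, mg = 1)), 50,
               tolerance = 1e-9)
  expect_equal(percent_na(sample_from_meq(na = 2, k = 1)), 100)
  expect_equal(percent_na(sample_from_meq(na = 0.5, k = 0.5, ca = 2, mg = 1)), 25,
               tolerance = 1e-9)

  expect_equal(rsc(sample_from_meq(hco3 = 2, ca = 1, mg = 1)), 0, tolerance = 1e-9)
  expect_equal(rsc(sample_from_meq()), 0)
  expect_equal(rsc(sample_from_meq(hco3 = 3, ca = 0.5, mg = 0.5)), 2,
               tolerance = 1e-9)
})

test_that("SAR and %Na bands use inclusive lower bounds", {
  expect_equal(as.character(classify_sar(c(3.6, 10, 18, 26, 40))),
               c("<10", "10-18", "18-26", ">26", ">26"))
  expect_equal(as.character(classify_percent_na(c(10.28, 20, 59.9, 82.36))),
               c("<20", "20-40", "40-60", ">80"))
})

test_that("Wilcox and USSL classifications place the worked examples", {
  expect_equal(as.character(wilcox_classify(100, 10)), "excellent_to_good")
  expect_warning(cls <- wilcox_classify(5000, 90), "envelope")
  expect_equal(as.character(cls), "unsuitable")
  # boundary point goes to the safer (less suitable) class
  expect_equal(as.character(wilcox_classify(1500, 0)), "good_to_permissible")

  expect_equal(as.character(ussl_classify(200, 1.2)$ussl_class), "S1C1")
  expect_equal(as.character(ussl_classify(444.82, 1.23)$ussl_class), "S1C2")
  expect_equal(as.character(ussl_classify(3000, 30)$ussl_class), "S4C4")
  # sloped boundaries drop with EC: SAR 9 is S1 on fixed bands but S3 at 3000 uS/cm
  expect_equal(as.character(ussl_classify(3000, 9)$s_class), "S1")
  expect_equal(as.character(ussl_classify(3000, 9, sloped = TRUE)$s_class), "S3")
})

test_that("irrigation table falls back to TDS-estimated conductivity", {
  d <- random_samples(10, seed = 121)
  idx <- irrigation_indices(d)
  expect_true(all(idx$ec_estimated))
  expect_equal(idx$ec, d$tds / 0.64)
  d$ec <- 500
  expect_false(any(irrigation_indices(d)$ec_estimated))
})

test_that("SAR/%Na/RSC agree with the independent meq oracle", {
  set.seed(131)
  d <- random_samples(200)
  na <- oracle_meq(d$na, "na"); k <- oracle_meq(d$k, "k")
  ca <- oracle_meq(d$ca, "ca"); mg <- oracle_meq(d$mg, "mg")
  hco3 <- oracle_meq(d$hco3, "hco3"); co3 <- oracle_meq(d$co3, "co3")
  expect_equal(sar(d), na / sqrt((ca + mg) / 2), tolerance = 1e-9)
  expect_equal(percent_na(d), 100 * (na + k) / (na + k + ca + mg),
               tolerance = 1e-9)
  expect_equal(rsc(d), (co3 + hco3) - (ca + mg), tolerance = 1e-9)
})
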