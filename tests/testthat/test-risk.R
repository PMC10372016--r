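test_that("exposure dose and hazard quotient follow the ingestion model", {
  expect_equal(exposure_dose(0, 1, 365, 1, 10, 365), 0)
  expect_equal(exposure_dose(1, 1, 365, 1, 1, 365), 1)   # unit cancellation
  e1 <- exposure_dose(38.92, 0.6, 365, 1, 9, 365)
  expect_equal(exposure_dose(2 * 38.92, 0.6, 365, 1, 9, 365), 2 * e1)
  expect_error(exposure_dose(1, 1, 365, 1, 0, 365), "positive")

  expect_equal(hazard_quotient(1.6, 1.6), 1)
  expect_equal(hazard_quotient(0, 1.6), 0)
  expect_equal(hazard_quotient(3.2, 1.6), 2)
  expect_error(hazard_quotient(1, 0), "positive")
})

test_that("HQ is homogeneous in C, IR, BW and RfD", {
  p <- exposure_params()[2, ]
  hq <- function(c, ir, bw, rfd) {
    hazard_quotient(exposure_dose(c, ir, p$ef, p$ed, bw, p$at), rfd)
  }
  base <- hq(40, p$ir, p$bw, p$rfd)
  expect_equal(hq(80, p$ir, p$bw, p$rfd), 2 * base)
  expect_equal(hq(40, 2 * p$ir, p$bw, p$rfd), 2 * base)
  expect_equal(hq(40, p$ir, 2 * p$bw, p$rfd), base / 2)
  expect_equal(hq(40, p$ir, p$bw, 2 * p$rfd), base / 2)
})

test_that("cohort summaries use strict exceedance and order groups by IR/BW", {
  zeros <- tibble::tibble(sample_id = "a", no3 = 0)
  cr <- cohort_risk(zeros)
  expect_equal(cr$mean_hq, rep(0, 4))
  expect_equal(cr$pct_exceed, rep(0, 4))

  # concentration giving the infant exactly HQ = 1 does not exceed
  p <- exposure_params()
  c_unit <- p$rfd[1] * p$bw[1] / p$ir[1]
  one <- tibble::tibble(no3 = c_unit)
  cr1 <- cohort_risk(one)
  expect_equal(cr1$mean_hq[cr1$group == "infant"], 1, tolerance = 1e-12)
  expect_equal(cr1$pct_exceed[cr1$group == "infant"], 0)

  # group ordering follows IR/BW (EF*ED/AT identical across groups here)
  set.seed(141)
  d <- tibble::tibble(no3 = rlnorm(200, 3, 1))
  cr2 <- cohort_risk(d)
  means <- cr2$mean_hq[match(c("infant", "child", "teenager", "adult"), cr2$group)]
  expect_true(all(diff(means) < 0))
  ratio <- p$ir / p$bw
  expect_equal(means / means[1], ratio / ratio[1], tolerance = 1e-9)

  # nitrate-as-N basis applies the 4.427 conversion
  crN <- cohort_risk(d, nitrate_basis = "as_n")
  expect_equal(crN$mean_hq, cr2$mean_hq * 4.427, tolerance = 1e-9)
})

test_that("degenerate Monte Carlo equals the deterministic path exactly", {
  p <- exposure_params()[1, ]
  det <- hazard_quotient(exposure_dose(50, p$ir, p$ef, p$ed, p$bw, p$at), p$rfd)
  mc <- monte_carlo_hq(p, dist_c = risk_dist("point", value = 50),
                       n = 500, seed = 3)
  expect_identical(unique(mc$hq), det)
  expect_equal(mc$sd, 0)
  expect_equal(mc$p_exceed, as.numeric(det > 1))
})

test_that("Monte Carlo is reproducible and matches the lognormal closed form", {
  p <- exposure_params()[4, ]
  dist_c <- risk_dist("lognormal", mean = 38.92, sd = 51.52)
  a <- monte_carlo_hq(p, dist_c = dist_c, n = 2000, seed = 17)
  b <- monte_carlo_hq(p, dist_c = dist_c, n = 2000, seed = 17)
  expect_identical(a$hq, b$hq)
  expect_true(all(diff(a$percentiles$hq) >= 0))
  expect_gte(a$p_exceed, 0); expect_lte(a$p_exceed, 1)

  # closed form: E[HQ] = E[C] * IR*EF*ED/(BW*AT*RfD) since only C is random
  m <- monte_carlo_hq(p, dist_c = dist_c, n = 10000, seed = 19)
  scale <- p$ir * p$ef * p$ed / (p$bw * p$at * p$rfd)
  expect_lt(abs(m$mean - 38.92 * scale), 3 * m$sd / sqrt(m$n))
})

test_that("Monte Carlo exceedance probability is stable under doubling", {
  p <- exposure_params()[1, ]
  dist_c <- risk_dist("lognormal", mean = 38.92, sd = 51.52)
  p1 <- monte_carlo_hq(p, dist_c = dist_c, n = 5000, seed = 23)$p_exceed
  p2 <- monte_carlo_hq(p, dist_c = dist_c, n = 10000, seed = 23)$p_exceed
  expect_lt(abs(p1 - p2), 3 / sqrt(5000))
})

test_that("distribution specs sample within their supports", {
  set.seed(151)
  tri <- risk_dist("triangular", min = 0.5, mode = 1, max = 1.5)$draw(2000)
  expect_true(all(tri >= 0.5 & tri <= 1.5))
  expect_equal(mean(tri), 1, tolerance = 0.05)

  tn <- risk_dist("truncnorm", mean = 9, sd = 3, lower = 0)$draw(2000)
  expect_true(all(tn >= 0))

  expect_error(risk_dist("triangular", min = 2, mode = 1, max = 3))
})
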