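#' Default exposure parameters for the four age groups
#'
#' Daily water intake IR (L/day), exposure frequency EF (days/year), exposure
#' duration ED (years), body weight BW (kg), averaging time AT (days, here
#' ED x 365 for non-carcinogenic risk) and the nitrate oral reference dose
#' RfD = 1.6 mg/(kg day), drawn from the Chinese exposure-factor handbook
#' values commonly used for nitrate ingestion risk. All values are plain
#' tibble columns and can be overridden by passing an edited copy.
#'
#' @return A tibble with columns `group`, `ir`, `ef`, `ed`, `bw`, `at`, `rfd`.
#' @examples
#' exposure_params()
#' @export
exposure_params <- function() {
  tibble::tibble(
    group = factor(c("infant", "child", "teenager", "adult"),
                   levels = c("infant", "child", "teenager", "adult")),
    ir  = c(0.6, 1.0, 1.4, 1.5),
    ef  = 365,
    ed  = c(1, 10, 8, 30),
    bw  = c(9, 20, 50, 60),
    at  = c(1, 10, 8, 30) * 365,
    rfd = 1.6
  )
}

.check_params <- function(p) {
  needed <- c("group", "ir", "ef", "ed", "bw", "at", "rfd")
  missing <- setdiff(needed, names(p))
  if (length(missing)) stop("Exposure parameters missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  num <- p[setdiff(needed, "group")]
  if (any(unlist(num) <= 0)) stop("All exposure parameters must be positive.",
                                  call. = FALSE)
  invisible(p)
}

#' Exposure dose and hazard quotient
#'
#' Oral exposure dose E = (C x IR x EF x ED) / (BW x AT) in mg/(kg day) and
#' non-carcinogenic hazard quotient HQ = E / RfD; HQ > 1 denotes
#' unacceptable risk.
#'
#' @param c Nitrate concentration(s) in mg/L (non-negative).
#' @param ir,ef,ed,bw,at Exposure parameters (see [exposure_params()]).
#' @param e Exposure dose in mg/(kg day).
#' @param rfd Reference dose in mg/(kg day), > 0.
#' @return Numeric vector.
#' @examples
#' exposure_dose(38.92, ir = 0.6, ef = 365, ed = 1, bw = 9, at = 365)
#' hazard_quotient(2.59, 1.6)
#' @export
exposure_dose <- function(c, ir, ef, ed, bw, at) {
  if (any(c < 0, na.rm = TRUE)) stop("Concentration must be non-negative.", call. = FALSE)
  if (any(bw <= 0) || any(at <= 0)) stop("`bw` and `at` must be positive.", call. = FALSE)
  (c * ir * ef * ed) / (bw * at)
}

#' @rdname exposure_dose
#' @export
hazard_quotient <- function(e, rfd) {
  if (any(rfd <= 0)) stop("`rfd` must be positive.", call. = FALSE)
  e / rfd
}

#' Per-sample, per-group hazard quotients
#'
#' Crosses every sample's nitrate concentration with every age group's
#' exposure parameters and evaluates the deterministic dose and hazard
#' quotient. Set `nitrate_basis = "as_n"` if the input nitrate is reported
#' as nitrate-N; it is then converted to the NO3 ion basis (x 4.427) before
#' use.
#'
#' @param data A data frame with an `no3` column (mg/L).
#' @param params Exposure parameter tibble (default [exposure_params()]).
#' @param nitrate_basis `"as_no3"` (default, concentrations used as
#'   reported) or `"as_n"`.
#' @return A long tibble: `sample_id`, `group`, `c`, `dose`, `hq`, `exceeds`
#'   (strict HQ > 1).
#' @export
hazard_quotients <- function(data, params = exposure_params(),
                             nitrate_basis = c("as_no3", "as_n")) {
  nitrate_basis <- match.arg(nitrate_basis)
  .check_params(params)
  if (is.null(data$no3)) stop("Column `no3` is required.", call. = FALSE)
  conc <- data$no3
  if (nitrate_basis == "as_n") conc <- conc * 4.427
  id <- if ("sample_id" %in% names(data)) data$sample_id else as.character(seq_along(conc))
  tidyr::crossing(tibble::tibble(sample_id = id, c = conc),
                  tibble::as_tibble(params)) |>
    dplyr::mutate(
      dose = exposure_dose(.data$c, .data$ir, .data$ef, .data$ed, .data$bw, .data$at),
      hq = hazard_quotient(.data$dose, .data$rfd),
      exceeds = .data$hq > 1
    ) |>
    dplyr::select("sample_id", "group", "c", "dose", "hq", "exceeds")
}

#' Cohort risk summary by age group
#'
#' Per-group minimum, maximum and mean hazard quotient and the percentage of
#' samples strictly exceeding the acceptable value of 1.
#'
#' @inheritParams hazard_quotients
#' @return A tibble with one row per age group: `group`, `n`, `min_hq`,
#'   `mean_hq`, `max_hq`, `pct_exceed`.
#' @examples
#' d <- synthesize_samples(n = 63, seed = 1)
#' cohort_risk(d)
#' @export
cohort_risk <- function(data, params = exposure_params(),
                        nitrate_basis = c("as_no3", "as_n")) {
  hazard_quotients(data, params, nitrate_basis) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min_hq = min(.data$hq, na.rm = TRUE),
      mean_hq = mean(.data$hq, na.rm = TRUE),
      max_hq = max(.data$hq, na.rm = TRUE),
      pct_exceed = 100 * mean(.data$exceeds, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Distribution specifications for Monte Carlo inputs
#'
#' Families: `point` (degenerate mass at `value`); `lognormal` moment-matched
#' to an arithmetic `mean` and `sd`; `truncnorm` (normal with parent `mean`
#' and `sd` truncated to `[lower, upper]`, default lower 0); `triangular`
#' with `min`, `mode`, `max`.
#'
#' @param family Distribution family.
#' @param ... Family parameters (see Details).
#' @return An object of class `risk_dist` with a `$draw(n)` sampler.
#' @examples
#' risk_dist("lognormal", mean = 38.92, sd = 51.52)
#' @export
risk_dist <- function(family = c("point", "lognormal", "truncnorm", "triangular"),
                      ...) {
  family <- match.arg(family)
  pars <- list(...)
  draw <- switch(
    family,
    point = {
      stopifnot(!is.null(pars$value), pars$value >= 0)
      function(n) rep(pars$value, n)
    },
    lognormal = {
      stopifnot(pars$mean > 0, pars$sd > 0)
      sigma2 <- log(1 + (pars$sd / pars$mean)^2)
      mu <- log(pars$mean) - sigma2 / 2
      function(n) stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
    },
    truncnorm = {
      lower <- pars$lower %||% 0
      upper <- pars$upper %||% Inf
      stopifnot(pars$sd > 0, lower < upper)
      function(n) {
        lo <- stats::pnorm(lower, pars$mean, pars$sd)
        hi <- stats::pnorm(upper, pars$mean, pars$sd)
        if (hi - lo < 1e-12) {
          stop("Truncated-normal mass in [lower, upper] is numerically zero.",
               call. = FALSE)
        }
        stats::qnorm(lo + stats::runif(n) * (hi - lo), pars$mean, pars$sd)
      }
    },
    triangular = {
      stopifnot(pars$min <= pars$mode, pars$mode <= pars$max, pars$min < pars$max)
      function(n) {
        u <- stats::runif(n)
        fc <- (pars$mode - pars$min) / (pars$max - pars$min)
        ifelse(u < fc,
               pars$min + sqrt(u * (pars$max - pars$min) * (pars$mode - pars$min)),
               pars$max - sqrt((1 - u) * (pars$max - pars$min) * (pars$max - pars$mode)))
      }
    }
  )
  structure(list(family = family, pars = pars, draw = draw), class = "risk_dist")
}

# draw n non-negative values, resampling negatives up to `attempts` rounds
.draw_nonneg <- function(dist, n, attempts = 20) {
  x <- dist$draw(n)
  for (i in seq_len(attempts)) {
    bad <- which(x < 0)
    if (!length(bad)) return(x)
    x[bad] <- dist$draw(length(bad))
  }
  if (any(x < 0)) {
    stop("Distribution kept producing negative draws after ", attempts,
         " resampling rounds.", call. = FALSE)
  }
  x
}

#' Monte Carlo hazard-quotient simulation
#'
#' Propagates uncertainty in the nitrate concentration C, body weight BW and
#' ingestion rate IR through the hazard-quotient model by independent random
#' draws (the remaining parameters EF, ED, AT, RfD are taken fixed from
#' `params`). Negative draws are rejected and resampled. With point-mass
#' distributions the simulation reproduces the deterministic HQ exactly.
#'
#' @param params A single age group's exposure parameters (one row of
#'   [exposure_params()]).
#' @param dist_c,dist_bw,dist_ir [risk_dist()] specifications; `dist_bw` and
#'   `dist_ir` default to point masses at the group's deterministic values.
#' @param n Number of iterations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `mc_hq`: `hq` draws, `mean`, `sd`, percentiles
#'   (5/25/50/75/95), `p_exceed` = P(HQ > 1), plus the seed and group label.
#'   `tidy()` returns the percentile tibble, `glance()` the one-row summary,
#'   `autoplot()` the cumulative-probability curve.
#' @examples
#' p <- exposure_params()[1, ]
#' mc <- monte_carlo_hq(p, dist_c = risk_dist("lognormal", mean = 38.92, sd = 51.52),
#'                      n = 1000, seed = 1)
#' glance(mc)
#' @export
monte_carlo_hq <- function(params,
                           dist_c,
                           dist_bw = risk_dist("point", value = params$bw),
                           dist_ir = risk_dist("point", value = params$ir),
                           n = 10000, seed = NULL) {
  stopifnot(nrow(params) == 1, n >= 1)
  .check_params(params)
  if (!inherits(dist_c, "risk_dist")) stop("`dist_c` must be a risk_dist.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  c_draw  <- .draw_nonneg(dist_c, n)
  bw_draw <- .draw_nonneg(dist_bw, n)
  if (any(bw_draw == 0)) bw_draw[bw_draw == 0] <- .draw_nonneg(dist_bw, sum(bw_draw == 0))
  ir_draw <- .draw_nonneg(dist_ir, n)
  hq <- hazard_quotient(
    exposure_dose(c_draw, ir_draw, params$ef, params$ed, bw_draw, params$at),
    params$rfd
  )
  qs <- stats::quantile(hq, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  structure(
    list(group = as.character(params$group), hq = hq, n = n, seed = seed,
         mean = mean(hq), sd = stats::sd(hq),
         percentiles = tibble::tibble(probability = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                      hq = qs),
         p_exceed = mean(hq > 1)),
    class = "mc_hq"
  )
}

#' @export
print.mc_hq <- function(x, ...) {
  cat(sprintf("Monte Carlo hazard quotient - group %s, %d iterations\n",
              x$group, x$n))
  cat(sprintf("  mean %.3f  sd %.3f  median %.3f  P(HQ > 1) %.2f%%\n",
              x$mean, x$sd, x$percentiles$hq[3], 100 * x$p_exceed))
  invisible(x)
}
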