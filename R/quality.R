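#' Default WQI weight/standard table
#'
#' Parameter weights w_i and permissible standards S_i driving the drinking
#' water quality index. Weights follow the usual entropy-of-concern ranking
#' for nitrate-impacted groundwater (nitrate and pH carry the largest
#' weights); standards are the Chinese GB/T 14848-2017 class III limits where
#' the standard regulates the parameter, and common drinking-water guideline
#' values otherwise (Ca 75, Mg 50, K 12, HCO3 300 mg/L). Fully
#' user-overridable: supply any tibble with columns `parameter`, `weight`,
#' `standard`.
#'
#' @return A tibble with columns `parameter`, `weight`, `standard`.
#' @export
wqi_weights <- function() {
  tibble::tibble(
    parameter = c("ph", "tds", "th", "ca", "mg", "na", "k", "cl", "so4", "hco3", "no3"),
    weight    = c(4, 4, 3, 3, 3, 3, 2, 4, 4, 2, 5),
    standard  = c(8.5, 1000, 450, 75, 50, 200, 12, 250, 250, 300, 20)
  )
}

#' Relative weights
#'
#' W_i = w_i / sum(w_i); the relative weights always sum to 1.
#'
#' @param weights A weight table (see [wqi_weights()]).
#' @return The table with a `rel_weight` column appended.
#' @export
relative_weights <- function(weights) {
  if (!nrow(weights)) stop("Weight table is empty.", call. = FALSE)
  if (any(weights$weight <= 0) || any(weights$standard <= 0)) {
    stop("Weights and standards must be positive.", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(weights),
                rel_weight = .data$weight / sum(.data$weight))
}

# concentration-to-standard rating C_i/S_i; pH enters as deviation from
# neutrality scaled by the allowable deviation, so neutral water rates 0
.wqi_rating <- function(value, parameter, standard) {
  if (identical(parameter, "ph")) {
    abs(value - 7) / (standard - 7)
  } else {
    value / standard
  }
}

#' WQI class bands
#'
#' excellent (< 50), good (50-100), poor (100-200), very poor (200-300),
#' non-drinkable (>= 300); lower bounds inclusive.
#'
#' @param wqi Numeric WQI values.
#' @return A factor of class labels.
#' @examples
#' classify_wqi(c(9.96, 50, 266.1))
#' @export
classify_wqi <- function(wqi) {
  cls <- dplyr::case_when(
    wqi < 50  ~ "excellent",
    wqi < 100 ~ "good",
    wqi < 200 ~ "poor",
    wqi < 300 ~ "very_poor",
    TRUE      ~ "non_drinkable"
  )
  cls[is.na(wqi)] <- NA
  factor(cls, levels = c("excellent", "good", "poor", "very_poor", "non_drinkable"))
}

#' Drinking-water quality index
#'
#' Weighted water quality index WQI = sum(W_i * (C_i/S_i) * 100) over the
#' parameters of the weight table, with effective weights
#' EW_i = W_i * (C_i/S_i) / WQI * 100 attributing each parameter's share of
#' the final score. Table parameters missing from `data` are dropped with the
#' remaining weights renormalised (and a warning). pH is rated as
#' |pH - 7| / (S_pH - 7) so that neutral water contributes nothing.
#'
#' @param data A data frame of samples.
#' @param weights Weight/standard table (default [wqi_weights()]).
#' @return An object of class `wqi_result` with elements `scores` (tibble:
#'   `sample_id` if present, `wqi`, `wqi_class`), `effective_weights` (long
#'   tibble: sample row, `parameter`, `ew` in percent, summing to 100 per
#'   sample) and the resolved `weights` table. `tidy()` returns the scores;
#'   `glance()` the cohort summary.
#' @examples
#' d <- synthesize_samples(n = 63, seed = 1)
#' res <- water_quality_index(d)
#' tidy(res)
#' @export
water_quality_index <- function(data, weights = wqi_weights()) {
  weights <- tibble::as_tibble(weights)
  data <- tibble::as_tibble(data)
  if (!"th" %in% names(data) && "th" %in% weights$parameter &&
      all(c("ca", "mg") %in% names(data))) {
    data$th <- total_hardness(data$ca, data$mg)
  }
  present <- weights$parameter %in% names(data)
  if (!any(present)) stop("No WQI parameters present in `data`.", call. = FALSE)
  if (!all(present)) {
    warning("WQI parameters not in data, dropped (weights renormalised): ",
            paste(weights$parameter[!present], collapse = ", "), call. = FALSE)
    weights <- weights[present, ]
  }
  weights <- relative_weights(weights)

  dat <- data
  n <- nrow(dat)
  contrib <- matrix(NA_real_, n, nrow(weights),
                    dimnames = list(NULL, weights$parameter))
  for (j in seq_len(nrow(weights))) {
    p <- weights$parameter[j]
    contrib[, j] <- weights$rel_weight[j] *
      .wqi_rating(dat[[p]], p, weights$standard[j]) * 100
  }
  wqi <- rowSums(contrib)
  ew <- 100 * contrib / ifelse(wqi > 0, wqi, NA_real_)

  row_id <- if ("sample_id" %in% names(dat)) dat$sample_id else as.character(seq_len(n))
  scores <- tibble::tibble(sample_id = row_id, wqi = wqi, wqi_class = classify_wqi(wqi))
  ew_long <- tibble::as_tibble(ew) |>
    dplyr::mutate(sample_id = row_id, .before = 1) |>
    tidyr::pivot_longer(-"sample_id", names_to = "parameter", values_to = "ew")
  structure(list(scores = scores, effective_weights = ew_long, weights = weights),
            class = "wqi_result")
}

#' @export
print.wqi_result <- function(x, ...) {
  cat("Water quality index -", nrow(x$scores), "samples\n")
  cat(sprintf("  WQI range %.2f-%.2f, mean %.2f\n",
              min(x$scores$wqi), max(x$scores$wqi), mean(x$scores$wqi)))
  tab <- table(x$scores$wqi_class)
  cat("  classes:", paste(sprintf("%s %.2f%%", names(tab), 100 * tab / sum(tab)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Sodium adsorption ratio, soluble sodium percentage, residual sodium carbonate
#'
#' Computed on meq/L: SAR = Na / sqrt((Ca + Mg) / 2);
#' \%Na = 100 * (Na + K) / (Na + K + Ca + Mg); RSC = (CO3 + HCO3) - (Ca + Mg).
#' `sar()` is `NA` when Ca + Mg = 0 and `percent_na()` when the cation total
#' is 0; RSC may be negative (calcite/dolomite supersaturated waters).
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @return A numeric vector, one value per sample.
#' @examples
#' d <- tibble::tibble(na = 22.99, k = 0, ca = 20.04, mg = 12.15,
#'                     hco3 = 61, cl = 0, so4 = 0, no3 = 0)
#' sar(d); percent_na(d); rsc(d)
#' @export
sar <- function(data) {
  m <- .meq_matrix(data)
  denom <- .mq(m, "ca") + .mq(m, "mg")
  ifelse(denom > 0, .mq(m, "na") / sqrt(denom / 2), NA_real_)
}

#' @rdname sar
#' @export
percent_na <- function(data) {
  m <- .meq_matrix(data)
  tot <- .mq(m, "na") + .mq(m, "k") + .mq(m, "ca") + .mq(m, "mg")
  ifelse(tot > 0, 100 * (.mq(m, "na") + .mq(m, "k")) / tot, NA_real_)
}

#' @rdname sar
#' @export
rsc <- function(data) {
  m <- .meq_matrix(data)
  (.mq(m, "co3") + .mq(m, "hco3")) - (.mq(m, "ca") + .mq(m, "mg"))
}

#' Irrigation hazard bands
#'
#' `classify_sar()`: "<10", "10-18", "18-26", ">26" (lower bound inclusive);
#' `classify_percent_na()`: "<20", "20-40", "40-60", "60-80", ">80".
#'
#' @param x Numeric SAR or \%Na values.
#' @return An ordered factor of band labels.
#' @export
classify_sar <- function(x) {
  cut(x, breaks = c(-Inf, 10, 18, 26, Inf),
      labels = c("<10", "10-18", "18-26", ">26"),
      right = FALSE, ordered_result = TRUE)
}

#' @rdname classify_sar
#' @export
classify_percent_na <- function(x) {
  cut(x, breaks = c(-Inf, 20, 40, 60, 80, Inf),
      labels = c("<20", "20-40", "40-60", "60-80", ">80"),
      right = FALSE, ordered_result = TRUE)
}

#' Wilcox irrigation suitability
#'
#' Region lookup on the electrical conductivity x soluble-sodium-percentage
#' plane. The five classical regions are approximated by slanted boundary
#' lines of constant u = EC/3000 + \%Na/90 (both hazards contribute, the
#' worse combination moving the sample toward "unsuitable"): u < 0.5
#' excellent-to-good, < 1 good-to-permissible, < 1.5 permissible-to-doubtful,
#' < 2 doubtful-to-unsuitable, else unsuitable. Boundary points take the
#' safer (less suitable) class. Points outside the chart envelope
#' (EC > `ec_max` or \%Na outside 0-100) are "unsuitable" with a warning.
#'
#' @param ec Electrical conductivity in uS/cm.
#' @param pna Soluble sodium percentage (0-100).
#' @param ec_scale,pna_scale,breaks Boundary parameters of the default
#'   region approximation.
#' @param ec_max Chart envelope limit (default 3500 uS/cm).
#' @return A factor of Wilcox classes.
#' @export
wilcox_classify <- function(ec, pna, ec_scale = 3000, pna_scale = 90,
                            breaks = c(0.5, 1, 1.5, 2), ec_max = 3500) {
  stopifnot(all(ec >= 0, na.rm = TRUE))
  if (any(pna < 0 | pna > 100, na.rm = TRUE)) {
    stop("%Na must lie in [0, 100].", call. = FALSE)
  }
  levels <- c("excellent_to_good", "good_to_permissible",
              "permissible_to_doubtful", "doubtful_to_unsuitable", "unsuitable")
  u <- ec / ec_scale + pna / pna_scale
  idx <- findInterval(u, breaks, left.open = FALSE) + 1L
  outside <- !is.na(ec) & ec > ec_max
  if (any(outside)) {
    warning(sum(outside), " sample(s) outside the Wilcox chart envelope; ",
            "classed unsuitable.", call. = FALSE)
    idx[outside] <- 5L
  }
  factor(levels[idx], levels = levels)
}

#' USSL salinity/sodium classification
#'
#' Salinity class from EC: C1 (< 250), C2 (250-750), C3 (750-2250),
#' C4 (>= 2250 uS/cm). Sodium class from SAR: by default the fixed bands
#' S1 (< 10), S2 (10-18), S3 (18-26), S4 (>= 26); with `sloped = TRUE` the
#' classical downward-sloping S-boundaries are used instead (band limits
#' decline linearly in log10(EC) from 10/18/26 at EC = 100 to 2.5/6.5/11 at
#' EC = 5000).
#'
#' @param ec Electrical conductivity in uS/cm.
#' @param sar Sodium adsorption ratio.
#' @param sloped Use EC-sloped sodium-class boundaries (default FALSE).
#' @return A tibble with `c_class`, `s_class` and the combined `ussl_class`
#'   (e.g. "S1C2").
#' @export
ussl_classify <- function(ec, sar, sloped = FALSE) {
  stopifnot(all(ec >= 0, na.rm = TRUE), all(sar >= 0, na.rm = TRUE))
  c_class <- cut(ec, breaks = c(-Inf, 250, 750, 2250, Inf),
                 labels = c("C1", "C2", "C3", "C4"), right = FALSE)
  if (!sloped) {
    s_class <- cut(sar, breaks = c(-Inf, 10, 18, 26, Inf),
                   labels = c("S1", "S2", "S3", "S4"), right = FALSE)
  } else {
    lim <- function(at100, at5000) {
      slope <- (at5000 - at100) / (log10(5000) - 2)
      pmax(at100 + slope * (log10(pmax(ec, 100)) - 2), 0)
    }
    l1 <- lim(10, 2.5); l2 <- lim(18, 6.5); l3 <- lim(26, 11)
    s_class <- factor(dplyr::case_when(
      sar < l1 ~ "S1", sar < l2 ~ "S2", sar < l3 ~ "S3", TRUE ~ "S4"
    ), levels = c("S1", "S2", "S3", "S4"))
    s_class[is.na(sar)] <- NA
  }
  tibble::tibble(c_class = c_class, s_class = s_class,
                 ussl_class = factor(paste0(s_class, c_class)))
}

# EC with the documented TDS-based fallback (EC ~ TDS / 0.64 uS/cm)
.ec_or_estimate <- function(data) {
  ec <- if ("ec" %in% names(data)) data$ec else rep(NA_real_, nrow(data))
  estimated <- is.na(ec)
  if (any(estimated)) {
    if (!"tds" %in% names(data)) {
      stop("Neither `ec` nor `tds` available to derive conductivity.", call. = FALSE)
    }
    ec[estimated] <- data$tds[estimated] / 0.64
  }
  list(ec = ec, estimated = estimated)
}

#' Irrigation suitability indices and classifications
#'
#' One-stop irrigation assessment: SAR, \%Na and RSC with their hazard bands,
#' the Wilcox class and the USSL salinity/sodium class for every sample.
#' When `ec` is missing it is estimated as TDS/0.64 uS/cm and flagged.
#'
#' @param data A data frame of samples.
#' @param sloped_ussl Use sloped USSL sodium boundaries (see
#'   [ussl_classify()]).
#' @return A tibble per sample: `sar`, `percent_na`, `rsc`, `sar_band`,
#'   `na_band`, `ec`, `ec_estimated`, `wilcox_class`, `c_class`, `s_class`,
#'   `ussl_class`.
#' @examples
#' d <- synthesize_samples(n = 63, seed = 1)
#' irrigation_indices(d) |> dplyr::count(ussl_class)
#' @export
irrigation_indices <- function(data, sloped_ussl = FALSE) {
  s <- sar(data)
  p <- percent_na(data)
  r <- rsc(data)
  ecinfo <- .ec_or_estimate(data)
  ussl <- ussl_classify(ecinfo$ec, s, sloped = sloped_ussl)
  out <- tibble::tibble(
    sar = s, percent_na = p, rsc = r,
    sar_band = classify_sar(s), na_band = classify_percent_na(p),
    ec = ecinfo$ec, ec_estimated = ecinfo$estimated,
    wilcox_class = wilcox_classify(ecinfo$ec, p)
  )
  out <- dplyr::bind_cols(out, ussl)
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}
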