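#' Piper trilinear coordinates
#'
#' Computes the cation and anion ternary fractions (percent of the respective
#' meq/L totals) and the projected diamond coordinates of the classical Piper
#' construction. The cation triangle has Ca at the lower-left vertex, Na+K at
#' the lower-right and Mg at the apex; the anion triangle (offset to the
#' right) has HCO3+CO3 lower-left, Cl lower-right and SO4 at the apex. The
#' diamond point is the intersection of the +60 degree line through the
#' cation point and the -60 degree line through the anion point.
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @return A tibble (one row per sample) with percent fractions `cat_ca`,
#'   `cat_mg`, `cat_nak`, `an_hco3`, `an_so4`, `an_cl` (each triple sums to
#'   100), the triangle coordinates `cation_x/y`, `anion_x/y` and the
#'   projected `diamond_x/y`. Samples with zero cation or anion totals error.
#' @examples
#' d <- tibble::tibble(ca = 40, mg = 12, na = 23, k = 4,
#'                     cl = 35, so4 = 48, hco3 = 122, no3 = 6)
#' piper_coordinates(d)
#' @export
piper_coordinates <- function(data) {
  meq <- .meq_matrix(data)
  cat_tot <- rowSums(meq[, .CATIONS, drop = FALSE])
  an_tot  <- rowSums(meq[, c("cl", "so4", "hco3", "co3"), drop = FALSE])
  if (any(cat_tot <= 0) || any(an_tot <= 0)) {
    stop("Piper coordinates undefined: sample(s) with zero cation or anion content.",
         call. = FALSE)
  }
  cat_ca  <- 100 * .mq(meq, "ca") / cat_tot
  cat_mg  <- 100 * .mq(meq, "mg") / cat_tot
  cat_nak <- 100 * (.mq(meq, "na") + .mq(meq, "k")) / cat_tot
  an_hco3 <- 100 * (.mq(meq, "hco3") + .mq(meq, "co3")) / an_tot
  an_so4  <- 100 * .mq(meq, "so4") / an_tot
  an_cl   <- 100 * .mq(meq, "cl") / an_tot

  h <- sqrt(3) / 2
  cation_x <- (cat_nak + 0.5 * cat_mg) / 100
  cation_y <- h * cat_mg / 100
  anion_x  <- 1.1 + (an_cl + 0.5 * an_so4) / 100
  anion_y  <- h * an_so4 / 100
  # intersection of y - yc = sqrt(3)(x - xc) and y - ya = -sqrt(3)(x - xa)
  s3 <- sqrt(3)
  diamond_x <- (s3 * cation_x + s3 * anion_x + anion_y - cation_y) / (2 * s3)
  diamond_y <- cation_y + s3 * (diamond_x - cation_x)

  out <- tibble::tibble(
    cat_ca = cat_ca, cat_mg = cat_mg, cat_nak = cat_nak,
    an_hco3 = an_hco3, an_so4 = an_so4, an_cl = an_cl,
    cation_x = cation_x, cation_y = cation_y,
    anion_x = anion_x, anion_y = anion_y,
    diamond_x = diamond_x, diamond_y = diamond_y
  )
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Shchukarev hydrochemical water type
#'
#' Names each sample's facies by the ions contributing at least a threshold
#' fraction (classically 25\%) of their class's meq total: anions first, then
#' cations, each group in decreasing order of fraction, joined with en-dashes
#' (e.g. "HCO3-Cl-Na-Ca" type waters).
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @param threshold Inclusion threshold as a fraction of the class meq total
#'   (default 0.25).
#' @return A tibble with `sample_id` (if present) and `facies` label.
#' @export
shchukarev_classify <- function(data, threshold = 0.25) {
  meq <- .meq_matrix(data)
  display <- c(k = "K", na = "Na", ca = "Ca", mg = "Mg",
               cl = "Cl", so4 = "SO4", hco3 = "HCO3", co3 = "CO3", no3 = "NO3")
  label_group <- function(frac, ions) {
    keep <- which(frac >= threshold)
    keep <- keep[order(frac[keep], decreasing = TRUE)]
    display[ions[keep]]
  }
  facies <- vapply(seq_len(nrow(meq)), function(i) {
    cat_tot <- sum(meq[i, .CATIONS])
    an_tot  <- sum(meq[i, .ANIONS])
    if (cat_tot <= 0 || an_tot <= 0) return(NA_character_)
    paste(
      c(label_group(meq[i, .ANIONS] / an_tot, .ANIONS),
        label_group(meq[i, .CATIONS] / cat_tot, .CATIONS)),
      collapse = "\u2013"
    )
  }, character(1))
  out <- tibble::tibble(facies = facies)
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Source-attribution ratio diagnostics
#'
#' Per-sample ionic ratios (computed on meq/L unless `basis = "mg"`) used to
#' attribute groundwater chemistry to rock weathering, evaporation,
#' precipitation, cation exchange or anthropogenic input:
#' Gibbs ratios Na/(Na+Ca) and Cl/(Cl+HCO3); endmember ratios Mg/Na, Ca/Na,
#' HCO3/Na; the carbonate index (Ca+Mg)/HCO3 (> 1 carbonate-dominant, < 1
#' silicate/evaporite); the evaporite index (Cl+SO4)/HCO3; the cation
#' exchange coordinates x = Na+K-Cl, y = Mg+Ca-SO4-HCO3 (points along the
#' slope -1 line indicate exchange); and the anthropogenic ratios Cl/Na and
#' NO3/Na. Ratios with zero denominators are returned as `NA`.
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @param basis `"meq"` (default) or `"mg"`.
#' @return A tibble with one row per sample and one column per ratio.
#' @export
ratio_diagnostics <- function(data, basis = c("meq", "mg")) {
  basis <- match.arg(basis)
  if (basis == "meq") {
    m <- .meq_matrix(data)
  } else {
    m <- matrix(0, nrow(data), length(c(.CATIONS, .ANIONS)),
                dimnames = list(NULL, c(.CATIONS, .ANIONS)))
    for (i in colnames(m)) if (i %in% names(data)) {
      v <- data[[i]]; v[is.na(v)] <- 0; m[, i] <- v
    }
  }
  sdiv <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- tibble::tibble(
    gibbs_cation = sdiv(.mq(m, "na"), .mq(m, "na") + .mq(m, "ca")),
    gibbs_anion  = sdiv(.mq(m, "cl"), .mq(m, "cl") + .mq(m, "hco3")),
    mg_na        = sdiv(.mq(m, "mg"), .mq(m, "na")),
    ca_na        = sdiv(.mq(m, "ca"), .mq(m, "na")),
    hco3_na      = sdiv(.mq(m, "hco3"), .mq(m, "na")),
    carb_index   = sdiv(.mq(m, "ca") + .mq(m, "mg"), .mq(m, "hco3")),
    evap_index   = sdiv(.mq(m, "cl") + .mq(m, "so4"), .mq(m, "hco3")),
    exch_x       = .mq(m, "na") + .mq(m, "k") - .mq(m, "cl"),
    exch_y       = .mq(m, "mg") + .mq(m, "ca") - .mq(m, "so4") - .mq(m, "hco3"),
    cl_na        = sdiv(.mq(m, "cl"), .mq(m, "na")),
    no3_na       = sdiv(.mq(m, "no3"), .mq(m, "na"))
  )
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Gibbs mechanism classification
#'
#' Assigns each sample to a Gibbs-diagram region from its TDS and weight
#' ratio: rock (water-rock interaction) dominance, precipitation dominance,
#' evaporation dominance, or outside the model envelope. The default region
#' boundaries are an explicit, configurable approximation of the classical
#' boomerang envelope; the continuous ratios themselves (from
#' [ratio_diagnostics()]) are the primary output of the diagnostic.
#'
#' @param data A data frame of samples with `tds` and ion columns in mg/L.
#' @param which Use the cation ratio Na/(Na+Ca) (default) or the anion ratio
#'   Cl/(Cl+HCO3).
#' @param bounds Named list of region boundaries:
#'   `rock_tds` (TDS range), `rock_ratio_max`, `precip_tds_max`,
#'   `precip_ratio_min`, `evap_tds_min`, `evap_ratio_min`.
#' @return A tibble with the ratio used, `tds` and the `gibbs_region` factor.
#' @export
gibbs_classify <- function(data, which = c("cation", "anion"),
                           bounds = list(rock_tds = c(70, 1000),
                                         rock_ratio_max = 0.7,
                                         precip_tds_max = 70,
                                         precip_ratio_min = 0.5,
                                         evap_tds_min = 1000,
                                         evap_ratio_min = 0.5)) {
  which <- match.arg(which)
  rd <- ratio_diagnostics(data)
  ratio <- if (which == "cation") rd$gibbs_cation else rd$gibbs_anion
  tds <- data$tds
  if (is.null(tds) || any(tds <= 0, na.rm = TRUE)) {
    stop("Gibbs classification requires positive `tds`.", call. = FALSE)
  }
  region <- dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    tds >= bounds$rock_tds[1] & tds <= bounds$rock_tds[2] &
      ratio <= bounds$rock_ratio_max ~ "rock_dominance",
    tds < bounds$precip_tds_max & ratio >= bounds$precip_ratio_min ~
      "precipitation_dominance",
    tds > bounds$evap_tds_min & ratio >= bounds$evap_ratio_min ~
      "evaporation_dominance",
    TRUE ~ "outside"
  )
  out <- tibble::tibble(
    ratio = ratio, tds = tds,
    gibbs_region = factor(region, levels = c("rock_dominance",
                                             "precipitation_dominance",
                                             "evaporation_dominance",
                                             "outside"))
  )
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Chloro-alkaline indices
#'
#' Schoeller's indices of cation exchange between groundwater and aquifer
#' material, on meq/L:
#' CAI-I = (Cl - (Na + K)) / Cl and
#' CAI-II = (Cl - (Na + K)) / (SO4 + HCO3 + CO3 + NO3).
#' Both negative: forward exchange (aquifer Na/K released, water Ca/Mg
#' taken up); both positive: reverse exchange; zero numerator: none.
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @return A tibble with `cai_1`, `cai_2` (NA when the respective denominator
#'   is zero) and the `direction` factor.
#' @export
cai_indices <- function(data) {
  m <- .meq_matrix(data)
  num <- .mq(m, "cl") - (.mq(m, "na") + .mq(m, "k"))
  den2 <- .mq(m, "so4") + .mq(m, "hco3") + .mq(m, "co3") + .mq(m, "no3")
  cai_1 <- ifelse(.mq(m, "cl") > 0, num / .mq(m, "cl"), NA_real_)
  cai_2 <- ifelse(den2 > 0, num / den2, NA_real_)
  direction <- dplyr::case_when(
    is.na(cai_1) | is.na(cai_2) ~ NA_character_,
    cai_1 > 0 & cai_2 > 0 ~ "reverse_exchange",
    cai_1 < 0 & cai_2 < 0 ~ "forward_exchange",
    TRUE ~ "none"
  )
  out <- tibble::tibble(
    cai_1 = cai_1, cai_2 = cai_2,
    direction = factor(direction,
                       levels = c("forward_exchange", "reverse_exchange", "none"))
  )
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

#' Cation-exchange regression
#'
#' Ordinary least-squares fit of (Mg + Ca - SO4 - HCO3) on (Na + K - Cl),
#' both in meq/L. A slope near -1 is the classical signature of alternate
#' cation adsorption (each equivalent of Na+K gained balances an equivalent
#' of Ca+Mg lost).
#'
#' @param data A data frame of samples with ion columns in mg/L.
#' @return An object of class `exchange_fit`: the underlying `lm` plus the
#'   exchange coordinates. Use [tidy()][generics::tidy] / `glance()` or
#'   `$slope`.
#' @export
cation_exchange_fit <- function(data) {
  rd <- ratio_diagnostics(data)
  ok <- stats::complete.cases(rd$exch_x, rd$exch_y)
  if (sum(ok) < 3) stop("Need at least 3 samples with defined exchange coordinates.",
                        call. = FALSE)
  x <- rd$exch_x[ok]; y <- rd$exch_y[ok]
  if (stats::var(x) == 0) stop("Degenerate exchange fit: x has zero variance.",
                               call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(
    list(model = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = summary(fit)$r.squared,
         n = sum(ok),
         data = tibble::tibble(exch_x = x, exch_y = y)),
    class = "exchange_fit"
  )
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Cation-exchange OLS fit (meq/L)\n")
  cat(sprintf("  slope: %.4f  intercept: %.4f  R^2: %.3f  n: %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat("  (slope near -1 indicates alternate cation adsorption)\n")
  invisible(x)
}

#' Pearson correlation screen
#'
#' Pairwise Pearson correlations between hydrochemical variables with
#' two-sided p-values from the t-transform of r on n-2 degrees of freedom,
#' flagged at p < 0.10 (*), p < 0.05 (**) and p < 0.01 (***). Pairs are
#' computed on pairwise-complete observations; zero-variance variables give
#' `NA` correlations.
#'
#' @param data A data frame of samples.
#' @param vars Character vector of numeric columns to correlate (defaults to
#'   the standard analytes present).
#' @return An object of class `cor_screen` holding the correlation matrix
#'   `r`, p-value matrix `p`, star matrix `stars` and per-pair n. `tidy()`
#'   returns the long tibble; `autoplot()` draws the heatmap.
#' @export
correlation_screen <- function(data, vars = NULL) {
  default <- c("ph", "tds", "th", "k", "na", "ca", "mg", "cl", "so4", "hco3", "no3")
  if (is.null(vars)) vars <- intersect(default, names(data))
  stopifnot(length(vars) >= 2)
  x <- as.matrix(data[vars])
  if (!is.numeric(x)) stop("All screened variables must be numeric.", call. = FALSE)
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(x[, i], x[, j])
      n <- sum(ok)
      nmat[i, j] <- n
      if (n < 3) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rij <- stats::cor(xi, xj)
      r[i, j] <- rij
      if (i == j) { p[i, j] <- 0; next }
      tstat <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  }
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  stars[!is.na(p) & p < 0.10] <- "*"
  stars[!is.na(p) & p < 0.05] <- "**"
  stars[!is.na(p) & p < 0.01] <- "***"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, n = nmat, vars = vars),
            class = "cor_screen")
}

#' @export
print.cor_screen <- function(x, digits = 2, ...) {
  cat("Pearson correlation screen (", length(x$vars), " variables)\n", sep = "")
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
              nrow = nrow(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(m, quote = FALSE)
  cat("* p<0.10  ** p<0.05  *** p<0.01\n")
  invisible(x)
}

#' Nitrate exceedance screening
#'
#' Fraction of samples whose nitrate concentration strictly exceeds a
#' drinking-water threshold (default 20 mg/L, the Chinese class III
#' groundwater limit for NO3).
#'
#' @param data A data frame with an `no3` column in mg/L.
#' @param threshold Threshold in mg/L (> 0).
#' @return A one-row tibble: `threshold`, `n`, `n_exceed`, `pct_exceed`
#'   (percent, full precision; reports round to 2 decimals).
#' @export
nitrate_exceedance <- function(data, threshold = 20) {
  stopifnot(threshold > 0)
  no3 <- data$no3
  if (is.null(no3)) stop("Column `no3` is required.", call. = FALSE)
  no3 <- no3[!is.na(no3)]
  n <- length(no3)
  n_exceed <- sum(no3 > threshold)
  tibble::tibble(threshold = threshold, n = n, n_exceed = n_exceed,
                 pct_exceed = if (n > 0) 100 * n_exceed / n else NA_real_)
}
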