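#' Charge-balance error
#'
#' Signed percent imbalance between cation and anion equivalents,
#' CBE = 100 * (sum cations - sum anions) / (sum cations + sum anions),
#' all in meq/L. Cations: K, Na, Ca, Mg; anions: Cl, SO4, HCO3, CO3, NO3.
#' A survey sample is conventionally accepted when |CBE| <= 5\%.
#'
#' @param data A data frame of samples with ion columns in mg/L (missing
#'   optional columns such as `co3` are treated as zero).
#' @param tolerance QC acceptance threshold in percent (default 5).
#' @return The input as a tibble with columns `cation_meq`, `anion_meq`,
#'   `cbe` (percent) and logical `cbe_ok` appended. Samples with zero ionic
#'   content get `NA` CBE (undefined) and `cbe_ok = FALSE`.
#' @examples
#' df <- tibble::tibble(na = 23, cl = 35.5, k = 0, ca = 0, mg = 0,
#'                      so4 = 0, hco3 = 0, no3 = 0)
#' charge_balance(df)$cbe
#' @export
charge_balance <- function(data, tolerance = 5) {
  meq <- .meq_matrix(data)
  cat_tot <- rowSums(meq[, .CATIONS, drop = FALSE])
  an_tot  <- rowSums(meq[, .ANIONS, drop = FALSE])
  denom <- cat_tot + an_tot
  cbe <- ifelse(denom > 0, 100 * (cat_tot - an_tot) / denom, NA_real_)
  dplyr::mutate(tibble::as_tibble(data),
                cation_meq = cat_tot,
                anion_meq  = an_tot,
                cbe        = cbe,
                cbe_ok     = !is.na(cbe) & abs(cbe) <= tolerance)
}

#' Total hardness as CaCO3 equivalent
#'
#' TH (mg/L as CaCO3) = 2.497 * Ca + 4.118 * Mg, the standard CaCO3-equivalent
#' convention (each ion's meq/L times 50.04 mg CaCO3 per meq).
#'
#' @param ca,mg Calcium and magnesium concentrations in mg/L.
#' @return Total hardness in mg/L as CaCO3.
#' @examples
#' total_hardness(40.078, 0)  # ~100.1: 2 meq/L of Ca
#' @export
total_hardness <- function(ca, mg) {
  stopifnot(all(ca >= 0, na.rm = TRUE), all(mg >= 0, na.rm = TRUE))
  2.497 * ca + 4.118 * mg
}

#' Threshold classifiers for TDS, hardness and well depth
#'
#' `classify_tds()`: fresh (< 1000 mg/L) vs brackish (>= 1000 mg/L).
#' `classify_hardness()`: soft (< 150 mg/L as CaCO3) vs hard (>= 150).
#' `classify_depth()`: shallow (0-20 m), middle (20-50 m), deep (> 50 m);
#' interval upper bounds inclusive, so 20 m is shallow and 50 m middle.
#'
#' @param tds,th,depth_m Numeric vectors (mg/L, mg/L as CaCO3, meters).
#' @return A factor with the class labels.
#' @examples
#' classify_tds(c(287.41, 1077.3))
#' classify_depth(c(3.5, 35, 340))
#' @export
classify_tds <- function(tds) {
  if (any(tds < 0, na.rm = TRUE)) stop("TDS must be non-negative.", call. = FALSE)
  factor(ifelse(tds < 1000, "fresh", "brackish"), levels = c("fresh", "brackish"))
}

#' @rdname classify_tds
#' @export
classify_hardness <- function(th) {
  if (any(th < 0, na.rm = TRUE)) stop("Hardness must be non-negative.", call. = FALSE)
  factor(ifelse(th < 150, "soft", "hard"), levels = c("soft", "hard"))
}

#' @rdname classify_tds
#' @export
classify_depth <- function(depth_m) {
  if (any(depth_m < 0, na.rm = TRUE)) stop("Depth must be non-negative.", call. = FALSE)
  cls <- dplyr::case_when(
    depth_m <= 20 ~ "shallow",
    depth_m <= 50 ~ "middle",
    TRUE          ~ "deep"
  )
  cls[is.na(depth_m)] <- NA
  factor(cls, levels = c("shallow", "middle", "deep"))
}

#' Descriptive statistics of hydrochemical analytes
#'
#' Per-analyte arithmetic mean, sample (n-1) standard deviation, coefficient
#' of variation (SD/mean), minimum, median and maximum, the usual summary
#' table of a groundwater survey.
#'
#' @param data A data frame of samples.
#' @param analytes Character vector of column names to summarise. Defaults to
#'   the standard survey analytes present in `data`.
#' @return A tibble with one row per analyte: `analyte`, `n`, `mean`, `sd`,
#'   `cv`, `min`, `median`, `max`. Analytes absent from `data` are skipped
#'   with a warning; `cv` is `NA` when the mean is not positive.
#' @examples
#' d <- synthesize_samples(n = 63, seed = 1)
#' describe_analytes(d)
#' @export
describe_analytes <- function(data, analytes = NULL) {
  default <- c("ph", "tds", "th", "ec", "k", "na", "ca", "mg",
               "cl", "so4", "hco3", "co3", "no3")
  if (is.null(analytes)) analytes <- intersect(default, names(data))
  missing <- setdiff(analytes, names(data))
  if (length(missing)) {
    warning("Analyte(s) not present, skipped: ", paste(missing, collapse = ", "),
            call. = FALSE)
    analytes <- setdiff(analytes, missing)
  }
  if (!length(analytes)) stop("No analytes to summarise.", call. = FALSE)
  purrr::map_dfr(analytes, function(a) {
    x <- data[[a]]
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      warning("Fewer than 2 observations for ", a, "; skipped.", call. = FALSE)
      return(NULL)
    }
    m <- mean(x)
    s <- stats::sd(x)
    tibble::tibble(
      analyte = a, n = length(x), mean = m, sd = s,
      cv = if (m > 0) s / m else NA_real_,
      min = min(x), median = stats::median(x), max = max(x)
    )
  })
}

#' Attach derived chemistry columns to a sample table
#'
#' Convenience step used at the head of the pipeline: computes total hardness
#' (unless a `th` column is already supplied, which then takes precedence),
#' TDS/hardness/depth classes and the charge-balance QC columns.
#'
#' @inheritParams charge_balance
#' @return A tibble with `th`, `tds_class`, `th_class`, `depth_class` (when
#'   `depth_m` present), `cation_meq`, `anion_meq`, `cbe`, `cbe_ok` appended.
#' @export
augment_chemistry <- function(data, tolerance = 5) {
  out <- tibble::as_tibble(data)
  if (!"th" %in% names(out)) {
    out$th <- total_hardness(out$ca, out$mg)
  }
  out$tds_class <- classify_tds(out$tds)
  out$th_class  <- classify_hardness(out$th)
  if ("depth_m" %in% names(out)) out$depth_class <- classify_depth(out$depth_m)
  charge_balance(out, tolerance = tolerance)
}
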