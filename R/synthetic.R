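#' Marginal targets for a Hainan-like groundwater survey
#'
#' Per-analyte distribution family and moment targets reproducing the
#' marginal structure of a tropical-island groundwater campaign: right-skewed
#' lognormal major ions and TDS (coefficients of variation between 0.75 and
#' 1.61), and near-neutral pH as a truncated normal on the observed range.
#' Units are mg/L except pH.
#'
#' @return A tibble with columns `analyte`, `family` (`lognormal`,
#'   `truncnorm` or `point`), `mean`, `sd`, `lower`, `upper`.
#' @export
hainan_marginals <- function() {
  tibble::tribble(
    ~analyte, ~family,     ~mean,   ~sd,    ~lower, ~upper,
    "ph",     "truncnorm", 7.47,    1.03,   5.11,   9.37,
    "tds",    "lognormal", 287.41,  216.13, NA,     NA,
    "ca",     "lognormal", 30.25,   26.41,  NA,     NA,
    "mg",     "lognormal", 11.28,   13.30,  NA,     NA,
    "k",      "lognormal", 13.16,   21.13,  NA,     NA,
    "na",     "lognormal", 30.30,   29.60,  NA,     NA,
    "cl",     "lognormal", 43.88,   55.99,  NA,     NA,
    "so4",    "lognormal", 29.39,   42.12,  NA,     NA,
    "hco3",   "lognormal", 111.29,  98.49,  NA,     NA,
    "no3",    "lognormal", 38.92,   51.52,  NA,     NA
  )
}

#' Pairwise Pearson correlation targets
#'
#' The strong ion-pair correlations characteristic of the emulated system:
#' Na-Cl 0.92 (common marine/evaporite source), Ca-HCO3 0.78 and Mg-HCO3
#' 0.70 (carbonate weathering), NO3-K 0.71 (agricultural input).
#'
#' @return A tibble with columns `var1`, `var2`, `r`.
#' @export
hainan_correlations <- function() {
  tibble::tribble(
    ~var1, ~var2,  ~r,
    "na",  "cl",   0.92,
    "ca",  "hco3", 0.78,
    "mg",  "hco3", 0.70,
    "no3", "k",    0.71
  )
}

#' Synthetic survey configuration
#'
#' @param n Number of samples (default 63, the emulated campaign size).
#' @param seed Integer seed; every draw is reproducible from it.
#' @param marginals Marginal target table (see [hainan_marginals()]).
#' @param correlations Pearson correlation targets (see
#'   [hainan_correlations()]).
#' @param background_r Latent correlation assigned to unspecified pairs of
#'   concentration-like analytes (default 0.45), representing the shared
#'   ionic-strength factor of natural waters; pH is left uncorrelated.
#' @param cbe_repair Rebalance samples whose charge-balance error exceeds
#'   `cbe_tolerance` (default TRUE).
#' @param cbe_method Repair method passed to [cbe_repair()]; the generator
#'   defaults to `"proportional"`, which spreads the correction across both
#'   ion classes and preserves the marginal moments far better than
#'   single-ion balancing.
#' @param cbe_tolerance QC threshold in percent (default 5).
#' @param depth_mix Named proportions over the shallow/middle/deep well
#'   classes.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 63, seed = NULL,
                             marginals = hainan_marginals(),
                             correlations = hainan_correlations(),
                             background_r = 0.45,
                             cbe_repair = TRUE, cbe_method = "proportional",
                             cbe_tolerance = 5,
                             depth_mix = c(shallow = 0.45, middle = 0.35,
                                           deep = 0.20)) {
  stopifnot(n >= 0, abs(sum(depth_mix) - 1) < 1e-9,
            all(c("analyte", "family", "mean", "sd") %in% names(marginals)))
  if (any(marginals$sd < 0)) stop("Marginal target SD must be >= 0.", call. = FALSE)
  bad <- !marginals$family %in% c("lognormal", "truncnorm", "point")
  if (any(bad)) stop("Unknown marginal family for: ",
                     paste(marginals$analyte[bad], collapse = ", "), call. = FALSE)
  structure(list(n = n, seed = seed, marginals = tibble::as_tibble(marginals),
                 correlations = tibble::as_tibble(correlations),
                 background_r = background_r, cbe_repair = cbe_repair,
                 cbe_method = cbe_method, cbe_tolerance = cbe_tolerance,
                 depth_mix = depth_mix),
            class = "synthetic_config")
}

# lognormal parameters moment-matched to an arithmetic mean and sd
.lnorm_pars <- function(mean, sd, analyte = "") {
  if (mean <= 0) stop("Lognormal moment match infeasible for '", analyte,
                      "': mean must be positive.", call. = FALSE)
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# mean and sd of a normal(mu, s) truncated to [lo, hi]
.truncnorm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z < 1e-12) return(c(NA_real_, NA_real_))
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mu + s * (pa - pb) / z
  v <- s^2 * (1 + (a * pa - b * pb) / z - ((pa - pb) / z)^2)
  c(m, sqrt(max(v, 0)))
}

# parent (mu, s) such that the truncated moments hit the targets
.truncnorm_pars <- function(mean, sd, lo, hi, analyte = "") {
  max_sd <- (hi - lo) / sqrt(12)   # uniform limit as the parent flattens
  if (sd >= max_sd) {
    stop("Truncated-normal moment match infeasible for '", analyte,
         "': target SD ", sd, " exceeds the limit ", round(max_sd, 4),
         " attainable on [", lo, ", ", hi, "].", call. = FALSE)
  }
  obj <- function(par) {
    m <- .truncnorm_moments(par[1], exp(par[2]), lo, hi)
    if (anyNA(m)) return(1e6)
    (m[1] - mean)^2 / sd^2 + (m[2] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  got <- .truncnorm_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  if (anyNA(got) || max(abs(got - c(mean, sd)) / sd) > 1e-3) {
    stop("Truncated-normal moment match failed to converge for '", analyte,
         "'.", call. = FALSE)
  }
  list(mu = fit$par[1], s = exp(fit$par[2]), lo = lo, hi = hi)
}

# latent Gaussian correlation giving Pearson r between two lognormal margins
# (exact inversion of r = (exp(rho s1 s2) - 1)/sqrt((e^{s1^2}-1)(e^{s2^2}-1)))
.latent_rho_lnorm <- function(r, s1, s2, pair = "") {
  arg <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (arg <= 0) stop("Correlation target infeasible for pair ", pair, call. = FALSE)
  rho <- log(arg) / (s1 * s2)
  if (abs(rho) > 1) stop("Correlation target infeasible for pair ", pair,
                         " (latent correlation ", round(rho, 3), ").", call. = FALSE)
  rho
}

# latent correlation matrix over the marginal analytes
.latent_correlation <- function(config) {
  marg <- config$marginals
  k <- nrow(marg)
  vars <- marg$analyte
  R <- diag(k); dimnames(R) <- list(vars, vars)

  conc_like <- marg$family == "lognormal"
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (conc_like[i] && conc_like[j]) R[i, j] <- R[j, i] <- config$background_r
    }
  }
  if (nrow(config$correlations)) {
    sig <- vapply(seq_len(k), function(i) {
      if (marg$family[i] == "lognormal")
        .lnorm_pars(marg$mean[i], marg$sd[i], marg$analyte[i])$sigma
      else NA_real_
    }, numeric(1))
    for (q in seq_len(nrow(config$correlations))) {
      v1 <- config$correlations$var1[q]; v2 <- config$correlations$var2[q]
      r  <- config$correlations$r[q]
      i <- match(v1, vars); j <- match(v2, vars)
      if (is.na(i) || is.na(j)) {
        stop("Correlation target names unknown analyte: ", v1, "-", v2, call. = FALSE)
      }
      rho <- if (marg$family[i] == "lognormal" && marg$family[j] == "lognormal") {
        .latent_rho_lnorm(r, sig[i], sig[j], paste(v1, v2, sep = "-"))
      } else r
      R[i, j] <- R[j, i] <- rho
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("Latent correlation matrix not positive definite; applying ",
            "nearest-PSD repair.")
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(vars, vars)
  }
  R
}

#' Generate a synthetic groundwater survey
#'
#' Seeded Gaussian-copula generator: latent standard-normal draws with the
#' configured correlation structure are pushed through each analyte's
#' moment-matched marginal (lognormal ions and TDS, truncated-normal pH).
#' Latent correlations for the target pairs are set by exact inversion of
#' the lognormal attenuation formula so that the realized Pearson r matches
#' the target. Well depths are assigned from the depth class mix (shallow
#' 3.5-20 m, middle 20-50 m uniform; deep 50-340 m log-uniform), EC is
#' derived as TDS/0.64 with 5\% multiplicative noise, CO3 is zero
#' (near-neutral, HCO3-dominated waters), and samples failing charge-balance
#' QC are minimally rebalanced via [cbe_repair()] when configured.
#'
#' @param n,seed Overrides for the config values.
#' @param config A [synthetic_config()].
#' @return A tibble of samples in the standard schema: `sample_id`,
#'   `depth_m`, `ph`, `tds`, `ec`, ion columns in mg/L, plus `cbe_repaired` /
#'   `cbe_flagged` logical QC columns when repair is enabled.
#' @examples
#' d <- synthesize_samples(n = 63, seed = 42)
#' describe_analytes(d)
#' @export
synthesize_samples <- function(n = NULL, seed = NULL, config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) stop("`config` must be a synthetic_config.",
                                                  call. = FALSE)
  if (!is.null(n)) config$n <- n
  if (!is.null(seed)) config$seed <- seed
  n <- config$n
  marg <- config$marginals
  vars <- marg$analyte

  ion_cols <- c("k", "na", "ca", "mg", "cl", "so4", "hco3", "co3", "no3")
  empty <- tibble::as_tibble(
    c(list(sample_id = character(0), depth_m = numeric(0), ph = numeric(0),
           tds = numeric(0), ec = numeric(0)),
      stats::setNames(rep(list(numeric(0)), length(ion_cols)), ion_cols))
  )
  if (n == 0) return(empty)

  if (!is.null(config$seed)) set.seed(config$seed)

  R <- .latent_correlation(config)
  Z <- matrix(stats::rnorm(n * nrow(marg)), nrow = n) %*% chol(R)
  colnames(Z) <- vars

  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (i in seq_along(vars)) {
    fam <- marg$family[i]
    if (fam == "point") {
      X[, i] <- marg$mean[i]
    } else if (fam == "lognormal") {
      p <- .lnorm_pars(marg$mean[i], marg$sd[i], vars[i])
      X[, i] <- exp(p$mu + p$sigma * Z[, i])
    } else {
      p <- .truncnorm_pars(marg$mean[i], marg$sd[i], marg$lower[i], marg$upper[i],
                           vars[i])
      u <- stats::pnorm(Z[, i])
      lo <- stats::pnorm(p$lo, p$mu, p$s); hi <- stats::pnorm(p$hi, p$mu, p$s)
      X[, i] <- stats::qnorm(lo + u * (hi - lo), p$mu, p$s)
    }
  }

  cls <- sample(names(config$depth_mix), n, replace = TRUE, prob = config$depth_mix)
  depth <- numeric(n)
  depth[cls == "shallow"] <- stats::runif(sum(cls == "shallow"), 3.5, 20)
  depth[cls == "middle"]  <- stats::runif(sum(cls == "middle"), 20, 50)
  depth[cls == "deep"]    <- exp(stats::runif(sum(cls == "deep"), log(50), log(340)))

  out <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)), depth_m = depth)
  for (v in vars) out[[v]] <- X[, v]
  for (v in setdiff(ion_cols, vars)) out[[v]] <- 0
  if (!"tds" %in% vars) {
    out$tds <- rowSums(X[, intersect(vars, ion_cols), drop = FALSE]) * 0.9 *
      stats::rlnorm(n, -0.00125, 0.05)
  }
  out$ec <- out$tds / 0.64 * stats::rlnorm(n, -0.00125, 0.05)
  out <- out[, c("sample_id", "depth_m", "ph"[("ph" %in% names(out))], "tds", "ec",
                 ion_cols)]
  if (config$cbe_repair) {
    out <- cbe_repair(out, tolerance = config$cbe_tolerance,
                      method = config$cbe_method)
  }
  out
}

#' Minimal charge-balance repair
#'
#' Brings each sample's charge-balance error to the nearest tolerance
#' boundary (so an already-balanced sample is returned unchanged, and with
#' `tolerance = 0` the sample is balanced exactly). Two methods:
#'
#' * `"ion"`: rescales a single balancing ion per sample — the candidate in
#'   `ions` needing the smallest meq/L change, subject to non-negativity —
#'   leaving every other analyte untouched. Samples that cannot be repaired
#'   within non-negativity are flagged, not dropped.
#' * `"proportional"`: rescales the whole cation vector by f and the whole
#'   anion vector by 1/f, with f chosen so the sample lands on the
#'   tolerance boundary. This is the minimal relative (log-scale) L2
#'   perturbation across all ions and is what the synthetic generator uses,
#'   because it preserves marginal moments far better than concentrating
#'   the correction on one ion.
#'
#' @param data A data frame of samples (ion columns in mg/L).
#' @param tolerance Target |CBE| in percent (default 5).
#' @param method `"ion"` (default, single balancing ion) or
#'   `"proportional"`.
#' @param ions Candidate balancing ions for `method = "ion"` (default Na
#'   and Cl).
#' @return The input tibble with adjusted ion values and logical columns
#'   `cbe_repaired` and `cbe_flagged` appended.
#' @examples
#' d <- tibble::tibble(na = 115, k = 0, ca = 0, mg = 0,
#'                     cl = 141.8, so4 = 0, hco3 = 0, no3 = 0)
#' cbe_repair(d, tolerance = 0, ions = "cl")$cl
#' @export
cbe_repair <- function(data, tolerance = 5, method = c("ion", "proportional"),
                       ions = c("na", "cl")) {
  stopifnot(tolerance >= 0)
  method <- match.arg(method)
  out <- tibble::as_tibble(data)
  meq <- .meq_matrix(out)
  C <- rowSums(meq[, .CATIONS, drop = FALSE])
  A <- rowSums(meq[, .ANIONS, drop = FALSE])
  cbe <- ifelse(C + A > 0, 100 * (C - A) / (C + A), NA_real_)
  repaired <- flagged <- rep(FALSE, nrow(out))
  need <- which(!is.na(cbe) & abs(cbe) > tolerance)
  # aim just inside the boundary so rounding cannot tip |CBE| back over it
  t_ <- sign(cbe) * (tolerance / 100) * (1 - 1e-9)

  if (method == "proportional") {
    if (length(need)) {
      # target cation/anion ratio and the symmetric factor achieving it
      f <- sqrt(((1 + t_[need]) / (1 - t_[need])) / (C[need] / A[need]))
      for (ion in .CATIONS) {
        present <- ion %in% names(out)
        if (present) out[[ion]][need] <- from_meq(meq[need, ion] * f, ion)
      }
      for (ion in .ANIONS) {
        if (ion %in% names(out)) out[[ion]][need] <- from_meq(meq[need, ion] / f, ion)
      }
      repaired[need] <- TRUE
    }
  } else {
    meta <- .ion_lookup(ions)
    for (idx in need) {
      best <- NULL
      for (q in seq_along(ions)) {
        ion <- ions[q]
        is_cat <- meta$charge[q] > 0
        delta <- if (is_cat) {
          A[idx] * (1 + t_[idx]) / (1 - t_[idx]) - C[idx]
        } else {
          C[idx] * (1 - t_[idx]) / (1 + t_[idx]) - A[idx]
        }
        new_meq <- meq[idx, ion] + delta
        if (new_meq < 0) next
        if (is.null(best) || abs(delta) < abs(best$delta)) {
          best <- list(ion = ion, delta = delta, new_meq = new_meq)
        }
      }
      if (is.null(best)) { flagged[idx] <- TRUE; next }
      out[[best$ion]][idx] <- from_meq(best$new_meq, best$ion)
      repaired[idx] <- TRUE
    }
  }
  flagged[is.na(cbe)] <- TRUE
  out$cbe_repaired <- repaired
  out$cbe_flagged <- flagged
  out
}

#' Validate a synthetic dataset against its configuration
#'
#' Recovery report: achieved per-analyte mean/SD/CV against the marginal
#' targets, achieved pairwise Pearson r against the correlation targets, and
#' the fraction of samples passing charge-balance QC, each with a pass flag
#' at the stated tolerances.
#'
#' @param data A generated dataset.
#' @param config The [synthetic_config()] that produced it.
#' @param mean_tol,sd_tol Relative tolerances on achieved mean and SD
#'   (defaults 3\% and 5\%).
#' @param r_tol Absolute tolerance on achieved correlations (default 0.05).
#' @return A list of class `synthetic_validation`: `marginals` and
#'   `correlations` tibbles with `pass` columns, `cbe_fraction_ok`, and the
#'   overall `pass` flag.
#' @export
validate_synthetic <- function(data, config, mean_tol = 0.03, sd_tol = 0.05,
                               r_tol = 0.05) {
  if (!nrow(data)) stop("Cannot validate an empty dataset.", call. = FALSE)
  marg <- config$marginals
  stats <- describe_analytes(data, analytes = marg$analyte)
  marg_rep <- dplyr::left_join(
    dplyr::select(marg, analyte = "analyte", target_mean = "mean", target_sd = "sd"),
    dplyr::select(stats, "analyte", achieved_mean = "mean", achieved_sd = "sd"),
    by = "analyte"
  ) |>
    dplyr::mutate(
      mean_ok = abs(.data$achieved_mean - .data$target_mean) <=
        mean_tol * abs(.data$target_mean),
      sd_ok = dplyr::if_else(.data$target_sd == 0,
                             .data$achieved_sd == 0,
                             abs(.data$achieved_sd - .data$target_sd) <=
                               sd_tol * .data$target_sd),
      pass = .data$mean_ok & .data$sd_ok
    )
  cors <- config$correlations
  cor_rep <- if (nrow(cors)) {
    dplyr::mutate(cors,
                  achieved_r = purrr::map2_dbl(.data$var1, .data$var2, function(a, b) {
                    stats::cor(data[[a]], data[[b]], use = "complete.obs")
                  }),
                  pass = abs(.data$achieved_r - .data$r) <= r_tol)
  } else {
    tibble::tibble(var1 = character(0), var2 = character(0), r = numeric(0),
                   achieved_r = numeric(0), pass = logical(0))
  }
  cbe_frac <- mean(charge_balance(data, config$cbe_tolerance)$cbe_ok)
  structure(
    list(marginals = marg_rep, correlations = cor_rep,
         cbe_fraction_ok = cbe_frac,
         pass = all(marg_rep$pass) && all(cor_rep$pass) && cbe_frac >= 0.99),
    class = "synthetic_validation"
  )
}

#' @export
print.synthetic_validation <- function(x, ...) {
  cat("Synthetic dataset validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  marginals: %d/%d ok; correlations: %d/%d ok; |CBE|<=tol: %.1f%%\n",
              sum(x$marginals$pass), nrow(x$marginals),
              sum(x$correlations$pass), nrow(x$correlations),
              100 * x$cbe_fraction_ok))
  invisible(x)
}
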