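#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects:
#' `tidy(<wqi_result>)` returns the per-sample scores,
#' `glance(<wqi_result>)` the cohort summary with class proportions;
#' `tidy(<cor_screen>)` the long correlation table with significance stars;
#' `tidy(<exchange_fit>)` the coefficient table and `glance(<exchange_fit>)`
#' the fit summary; `tidy(<mc_hq>)` the percentile table and
#' `glance(<mc_hq>)` the one-row Monte Carlo summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy wqi_result
#' @export
tidy.wqi_result <- function(x, ...) x$scores

#' @rdname tidiers
#' @method glance wqi_result
#' @export
glance.wqi_result <- function(x, ...) {
  tab <- table(x$scores$wqi_class)
  props <- stats::setNames(as.numeric(100 * tab / sum(tab)),
                           paste0("pct_", names(tab)))
  dplyr::bind_cols(
    tibble::tibble(n = nrow(x$scores),
                   mean_wqi = mean(x$scores$wqi),
                   min_wqi = min(x$scores$wqi),
                   max_wqi = max(x$scores$wqi)),
    tibble::as_tibble_row(props)
  )
}

#' @rdname tidiers
#' @method tidy cor_screen
#' @export
tidy.cor_screen <- function(x, ...) {
  pairs <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    var1 = x$vars[pairs[, 1]],
    var2 = x$vars[pairs[, 2]],
    r = x$r[pairs],
    p_value = x$p[pairs],
    stars = x$stars[pairs],
    n = as.integer(x$n[pairs])
  )
}

#' @rdname tidiers
#' @method tidy exchange_fit
#' @export
tidy.exchange_fit <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = cf[, 1], std_error = cf[, 2],
                 statistic = cf[, 3], p_value = cf[, 4])
}

#' @rdname tidiers
#' @method glance exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' @rdname tidiers
#' @method tidy mc_hq
#' @export
tidy.mc_hq <- function(x, ...) x$percentiles

#' @rdname tidiers
#' @method glance mc_hq
#' @export
glance.mc_hq <- function(x, ...) {
  tibble::tibble(group = x$group, n = x$n, mean_hq = x$mean, sd_hq = x$sd,
                 q05 = x$percentiles$hq[1], q25 = x$percentiles$hq[2],
                 median_hq = x$percentiles$hq[3], q75 = x$percentiles$hq[4],
                 q95 = x$percentiles$hq[5], p_exceed = x$p_exceed)
}
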