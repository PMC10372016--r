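#' Pipeline configuration
#'
#' One structured configuration object driving [run_pipeline()]: either an
#' `input` CSV path or a `simulate` block, the stages to run, the WQI weight
#' table, exposure parameters, Monte Carlo settings and an optional output
#' directory for CSV reports. [read_pipeline_config()] loads the same
#' structure from a YAML file (unknown keys error; the `simulate`, `mc` and
#' `weights` blocks map onto the corresponding constructors).
#'
#' @param input Path to a sample CSV, or `NULL` to simulate.
#' @param simulate A [synthetic_config()] used when `input` is `NULL`.
#' @param stages Stages to run, a subset of
#'   `c("qc", "stats", "facies", "wqi", "irrigation", "risk")`.
#' @param weights WQI weight table.
#' @param risk_params Exposure parameter tibble.
#' @param mc `NULL` to skip Monte Carlo, or a list with `n` (iterations) and
#'   optional `seed` (defaults to the pipeline seed).
#' @param nitrate_threshold Screening threshold for nitrate (mg/L).
#' @param output_dir Directory to write per-stage CSVs into, or `NULL`.
#' @param seed Seed used for simulation and Monte Carlo.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            simulate = synthetic_config(),
                            stages = c("qc", "stats", "facies", "wqi",
                                       "irrigation", "risk"),
                            weights = wqi_weights(),
                            risk_params = exposure_params(),
                            mc = list(n = 10000),
                            nitrate_threshold = 20,
                            output_dir = NULL,
                            seed = 20230726) {
  known <- c("qc", "stats", "facies", "wqi", "irrigation", "risk")
  if (!length(stages) || !all(stages %in% known)) {
    stop("`stages` must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("Input file does not exist: ", input, call. = FALSE)
  }
  structure(list(input = input, simulate = simulate, stages = stages,
                 weights = weights, risk_params = risk_params, mc = mc,
                 nitrate_threshold = nitrate_threshold,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' @param path YAML configuration file.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$stages)) args$stages <- y$stages
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$nitrate_threshold)) args$nitrate_threshold <- y$nitrate_threshold
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    # YAML 1.1 reads a bare `n:` key as boolean FALSE; accept n_samples too
    names(sim)[names(sim) %in% c("FALSE", "n_samples")] <- "n"
    args$simulate <- do.call(synthetic_config,
                             sim[intersect(names(sim),
                                           names(formals(synthetic_config)))])
  }
  if (!is.null(y$weights)) {
    args$weights <- tibble::as_tibble(as.data.frame(y$weights))
  }
  if (!is.null(y$risk_params)) {
    args$risk_params <- tibble::as_tibble(as.data.frame(y$risk_params))
  }
  if (!is.null(y$mc)) args$mc <- y$mc
  do.call(pipeline_config, args)
}

#' Run the full assessment pipeline
#'
#' Executes the configured stages in order — charge-balance QC, descriptive
#' statistics, facies diagnostics, drinking-water WQI, irrigation indices,
#' and nitrate health risk (deterministic plus Monte Carlo) — on the input
#' or simulated samples, returning every stage's tibble in one report
#' bundle. Each bundle embeds the seed, a configuration hash and the package
#' version, so a rerun from the same config is bit-identical. With
#' `output_dir` set, every stage table is also written as CSV.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `aquachem_report`: `samples` and one element per
#'   executed stage, plus `provenance`.
#' @examples
#' rep <- run_pipeline(pipeline_config(simulate = synthetic_config(n = 63),
#'                                     seed = 1, mc = NULL))
#' rep$risk$cohort
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- if (!is.null(config$input)) {
    read_samples(config$input)
  } else {
    synthesize_samples(seed = config$seed, config = config$simulate)
  }
  if (!nrow(samples)) stop("No samples to process.", call. = FALSE)

  out <- list(samples = samples)
  if ("qc" %in% config$stages) {
    out$qc <- charge_balance(samples) |>
      dplyr::select(dplyr::any_of(c("sample_id", "cation_meq", "anion_meq",
                                    "cbe", "cbe_ok")))
  }
  if ("stats" %in% config$stages) {
    aug <- augment_chemistry(samples)
    out$stats <- describe_analytes(aug)
    out$classes <- list(
      tds = dplyr::count(aug, .data$tds_class),
      th = dplyr::count(aug, .data$th_class),
      depth = if ("depth_class" %in% names(aug)) dplyr::count(aug, .data$depth_class)
    )
    out$nitrate <- nitrate_exceedance(samples, config$nitrate_threshold)
  }
  if ("facies" %in% config$stages) {
    out$facies <- list(
      piper = piper_coordinates(samples),
      types = shchukarev_classify(samples),
      gibbs = gibbs_classify(samples),
      ratios = ratio_diagnostics(samples),
      cai = cai_indices(samples),
      exchange = cation_exchange_fit(samples),
      correlations = correlation_screen(samples)
    )
  }
  if ("wqi" %in% config$stages) {
    out$wqi <- water_quality_index(samples, config$weights)
  }
  if ("irrigation" %in% config$stages) {
    out$irrigation <- irrigation_indices(samples)
  }
  if ("risk" %in% config$stages) {
    risk <- list(
      by_sample = hazard_quotients(samples, config$risk_params),
      cohort = cohort_risk(samples, config$risk_params)
    )
    if (!is.null(config$mc)) {
      mc_seed <- config$mc$seed %||% config$seed
      no3 <- samples$no3[!is.na(samples$no3) & samples$no3 > 0]
      dist_c <- risk_dist("lognormal", mean = mean(no3), sd = stats::sd(no3))
      risk$mc <- purrr::map(seq_len(nrow(config$risk_params)), function(i) {
        p <- config$risk_params[i, ]
        monte_carlo_hq(
          p, dist_c = dist_c,
          dist_bw = risk_dist("truncnorm", mean = p$bw, sd = 0.15 * p$bw, lower = 0),
          dist_ir = risk_dist("triangular", min = 0.5 * p$ir, mode = p$ir,
                              max = 1.5 * p$ir),
          n = config$mc$n %||% 10000,
          seed = mc_seed + i
        )
      })
      names(risk$mc) <- as.character(config$risk_params$group)
    }
    out$risk <- risk
  }

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  out$provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    package_version = as.character(utils::packageVersion("aquachem")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  class(out) <- "aquachem_report"

  if (!is.null(config$output_dir)) .write_report(out, config$output_dir)
  out
}

.write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(x, file.path(dir, paste0(name, ".csv")))
  wr(report$samples, "samples")
  if (!is.null(report$qc)) wr(report$qc, "qc")
  if (!is.null(report$stats)) wr(report$stats, "descriptive_stats")
  if (!is.null(report$nitrate)) wr(report$nitrate, "nitrate_exceedance")
  if (!is.null(report$facies)) {
    wr(report$facies$piper, "piper")
    wr(report$facies$types, "facies_types")
    wr(report$facies$ratios, "ratio_diagnostics")
    wr(report$facies$cai, "cai")
    wr(tidy(report$facies$correlations), "correlations")
  }
  if (!is.null(report$wqi)) {
    wr(report$wqi$scores, "wqi")
    wr(report$wqi$effective_weights, "effective_weights")
  }
  if (!is.null(report$irrigation)) wr(report$irrigation, "irrigation")
  if (!is.null(report$risk)) {
    wr(report$risk$by_sample, "hq_by_sample")
    wr(report$risk$cohort, "hq_cohort")
    if (!is.null(report$risk$mc)) {
      wr(purrr::map_dfr(report$risk$mc, glance), "hq_monte_carlo")
    }
  }
  prov <- report$provenance
  writeLines(c(paste0("seed: ", prov$seed),
               paste0("config_hash: ", prov$config_hash),
               paste0("package_version: ", prov$package_version)),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' @export
print.aquachem_report <- function(x, ...) {
  cat("aquachem assessment report -", nrow(x$samples), "samples\n")
  cat("  seed", x$provenance$seed, " config", substr(x$provenance$config_hash, 1, 8),
      " v", x$provenance$package_version, "\n", sep = "")
  if (!is.null(x$qc)) {
    cat(sprintf("  QC: %.2f%% of samples with |CBE| <= 5%%\n",
                100 * mean(x$qc$cbe_ok)))
  }
  if (!is.null(x$nitrate)) {
    cat(sprintf("  Nitrate > %g mg/L: %.2f%% of samples\n",
                x$nitrate$threshold, x$nitrate$pct_exceed))
  }
  if (!is.null(x$wqi)) {
    tab <- table(x$wqi$scores$wqi_class)
    cat(sprintf("  WQI mean %.2f (%s)\n", mean(x$wqi$scores$wqi),
                paste(sprintf("%s %.2f%%", names(tab), 100 * tab / sum(tab)),
                      collapse = ", ")))
  }
  if (!is.null(x$irrigation)) {
    cat("  USSL:", paste(sprintf("%s %d", names(table(x$irrigation$ussl_class)),
                                 as.integer(table(x$irrigation$ussl_class))),
                         collapse = ", "), "\n")
  }
  if (!is.null(x$risk)) {
    s <- x$risk$cohort
    cat("  HQ means:", paste(sprintf("%s %.2f", s$group, s$mean_hq),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
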