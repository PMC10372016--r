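# Independent meq-level hand calculator used as the oracle for conversion,
# balance and irrigation-index tests. Deliberately written as a standalone
# lookup + arithmetic path, not via the package's converters.
ORACLE_MEQ_FACTOR <- c(
  k = 1 / 39.098, na = 1 / 22.990, ca = 2 / 40.078, mg = 2 / 24.305,
  cl = 1 / 35.453, so4 = 2 / 96.06, hco3 = 1 / 61.016, co3 = 2 / 60.008,
  no3 = 1 / 62.004
)

oracle_meq <- function(mg_l, ion) mg_l * ORACLE_MEQ_FACTOR[[ion]]

# build a one-row sample tibble from meq/L values (0 for unnamed ions)
sample_from_meq <- function(...) {
  meq <- list(...)
  ions <- c("k", "na", "ca", "mg", "cl", "so4", "hco3", "co3", "no3")
  out <- tibble::as_tibble(stats::setNames(as.list(rep(0, length(ions))), ions))
  for (ion in names(meq)) out[[ion]] <- meq[[ion]] / ORACLE_MEQ_FACTOR[[ion]]
  out
}

# random plausible sample table in mg/L
random_samples <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("R%04d", seq_len(n)),
    ph = runif(n, 5, 9.5),
    tds = runif(n, 30, 1100),
    k = rlnorm(n, 1.5, 1), na = rlnorm(n, 3, 0.9), ca = rlnorm(n, 3, 0.9),
    mg = rlnorm(n, 2, 1), cl = rlnorm(n, 3.2, 1.1), so4 = rlnorm(n, 2.5, 1.2),
    hco3 = rlnorm(n, 4.3, 0.9), co3 = 0, no3 = rlnorm(n, 3, 1.2)
  )
}

# printed summary rows of the emulated survey (mean, SD, CV at 2 decimals)
PRINTED_TABLE1 <- tibble::tribble(
  ~analyte, ~mean,  ~sd,    ~cv,
  "tds",    287.41, 216.13, 0.75,
  "ph",     7.47,   1.03,   0.14,
  "th",     121.91, 103.77, 0.85,
  "ca",     30.25,  26.41,  0.87,
  "mg",     11.28,  13.30,  1.18,
  "k",      13.16,  21.13,  1.61,
  "na",     30.30,  29.60,  0.98,
  "cl",     43.88,  55.99,  1.28,
  "so4",    29.39,  42.12,  1.43,
  "no3",    38.92,  51.52,  1.32,
  "sar",    1.23,   0.76,   0.62
)

# two observations with exactly the requested sample mean and sd
two_point <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)
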