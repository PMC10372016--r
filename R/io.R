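#' Read and write sample tables
#'
#' The standard CSV schema: `sample_id`, optional `depth_m`, `ph`, `tds`,
#' optional `ec`, and the ion columns `k`, `na`, `ca`, `mg`, `cl`, `so4`,
#' `hco3`, optional `co3`, `no3`, all mg/L (EC in uS/cm). Rows failing unit
#' sanity checks (negative concentrations, pH outside 0-14) are rejected
#' with a warning naming the offending data line numbers.
#'
#' @param path CSV file path.
#' @return `read_samples()`: a tibble of validated samples.
#' @export
read_samples <- function(path) {
  mandatory <- c("sample_id", "ph", "tds", "k", "na", "ca", "mg",
                 "cl", "so4", "hco3", "no3")
  optional <- c("depth_m", "ec", "co3", "th")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("Input is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(raw)) {
    warning("Input file has a header but no data rows.", call. = FALSE)
    return(tibble::as_tibble(raw))
  }
  numcols <- intersect(c(mandatory[-1], optional), names(raw))
  for (cc in numcols) raw[[cc]] <- as.numeric(raw[[cc]])
  conc_cols <- intersect(c("tds", "ec", "k", "na", "ca", "mg", "cl", "so4",
                           "hco3", "co3", "no3", "th", "depth_m"), names(raw))
  bad <- rep(FALSE, nrow(raw))
  for (cc in conc_cols) bad <- bad | (!is.na(raw[[cc]]) & raw[[cc]] < 0)
  bad <- bad | (!is.na(raw$ph) & (raw$ph < 0 | raw$ph > 14))
  if (any(bad)) {
    warning("Rejected ", sum(bad), " malformed row(s) at data line(s): ",
            paste(which(bad), collapse = ", "),
            " (negative concentration or pH outside [0, 14]).", call. = FALSE)
    raw <- raw[!bad, ]
  }
  tibble::as_tibble(raw)
}

#' @param data A sample table.
#' @rdname read_samples
#' @return `write_samples()`: the path, invisibly.
#' @export
write_samples <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
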