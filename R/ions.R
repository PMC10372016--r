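#' Major-ion metadata
#'
#' Molar masses (IUPAC, g/mol) and signed charges for the major ions handled
#' by the package. These drive every mg/L to meq/L conversion, so they are
#' fixed here rather than accepted as free parameters.
#'
#' @return A tibble with columns `ion` (lower-case symbol used in sample
#'   tables), `molar_mass` (g/mol) and `charge` (signed integer equivalents
#'   per mole).
#' @examples
#' ion_meta()
#' @export
ion_meta <- function() {
  tibble::tibble(
    ion        = c("k", "na", "ca", "mg", "cl", "so4", "hco3", "co3", "no3"),
    molar_mass = c(39.098, 22.990, 40.078, 24.305, 35.453, 96.06, 61.016, 60.008, 62.004),
    charge     = c(1L, 1L, 2L, 2L, -1L, -2L, -1L, -2L, -1L)
  )
}

.ion_lookup <- function(ion) {
  meta <- ion_meta()
  idx <- match(tolower(ion), meta$ion)
  if (anyNA(idx)) {
    stop("Unknown ion symbol(s): ", paste(unique(ion[is.na(idx)]), collapse = ", "),
         ". Known ions: ", paste(meta$ion, collapse = ", "), call. = FALSE)
  }
  meta[idx, ]
}

#' Convert between mg/L and meq/L
#'
#' meq/L = mg/L * |charge| / molar mass. The conversion is exact and
#' invertible; `from_meq()` is the inverse of `to_meq()`.
#'
#' @param x Numeric vector of concentrations (mg/L for `to_meq`, meq/L for
#'   `from_meq`). Must be non-negative.
#' @param ion Ion symbol (scalar or vector recycled against `x`), one of
#'   `ion_meta()$ion` (case-insensitive).
#' @return Numeric vector of converted concentrations.
#' @examples
#' to_meq(40.078, "ca")   # 2 meq/L
#' from_meq(1, "cl")      # 35.453 mg/L
#' @export
to_meq <- function(x, ion) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) {
    stop("Concentrations must be non-negative.", call. = FALSE)
  }
  meta <- .ion_lookup(ion)
  x * abs(meta$charge) / meta$molar_mass
}

#' @rdname to_meq
#' @export
from_meq <- function(x, ion) {
  stopifnot(is.numeric(x))
  meta <- .ion_lookup(ion)
  x * meta$molar_mass / abs(meta$charge)
}

.CATIONS <- c("k", "na", "ca", "mg")
.ANIONS  <- c("cl", "so4", "hco3", "co3", "no3")

# per-sample meq/L matrix for the named ions; missing columns treated as 0
.meq_matrix <- function(data, ions = c(.CATIONS, .ANIONS)) {
  out <- matrix(0, nrow = nrow(data), ncol = length(ions),
                dimnames = list(NULL, ions))
  for (i in ions) {
    if (i %in% names(data)) {
      v <- data[[i]]
      v[is.na(v)] <- 0
      out[, i] <- to_meq(v, i)
    }
  }
  out
}

# unname a meq-matrix column (single-row subsetting keeps dimnames otherwise)
.mq <- function(m, ion) unname(m[, ion])
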