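#' @keywords internal
"_PACKAGE"

# Origin-label vocabulary used across the whole pipeline.  P1/P2 are the two
# homozygous parents (in the motivating cross, LP08 and LP21).
ORIGIN_LABELS <- c("P1", "P2", "HET", "MISSING")
STATE_LABELS <- c("P1", "P2", "HET")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed metabolite tables use
#' ordinary commercial rounding, so totals and folds are reported with halves
#' rounded away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic substream seeds: one root seed, independent substreams per
# (unit, index) so regenerating one line/chromosome does not disturb others.
# Simple 32-bit LCG-style mix, kept below 2^31.
derive_seed <- function(root_seed, ...) {
  keys <- c(...)
  h <- as.double(root_seed) %% 2147483647
  for (k in keys) {
    kv <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.double(k)
    h <- (h * 69069 + kv * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
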