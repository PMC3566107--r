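#' @keywords internal
"_PACKAGE"

#' @importFrom stats median hclust cutree as.dist rbinom rnorm runif rpois
#'   nls coef setNames sd
#' @importFrom utils read.table write.table head tail
NULL

# Validation errors carry their own condition class so that the command-line
# front end can translate them into a distinct exit code.
nm_validation_error <- function(msg, ...) {
  stop(structure(
    class = c("nanomapr_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

nm_pipeline_error <- function(msg, ...) {
  stop(structure(
    class = c("nanomapr_pipeline_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

nm_assert <- function(ok, msg, ...) {
  if (!isTRUE(ok)) nm_validation_error(msg, ...)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Reverse complement of a DNA string
#'
#' Plain character-vector reverse complement over the A/C/G/T/N alphabet,
#' case-insensitive, returned in upper case.
#'
#' @param x a single DNA string.
#' @return the reverse complement as an upper-case string.
#' @export
revcomp <- function(x) {
  nm_assert(is.character(x) && length(x) == 1L, "revcomp() expects one string")
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

# Stable per-task seed derived from a master seed; stays below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1103L + as.integer(k) * 7919L) %% 2147483587L
}

fmt_bp <- function(x) formatC(x, format = "f", digits = 1)
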