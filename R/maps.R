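# Map containers. All in-memory coordinates are 0-based base pairs; file
# writers add 1 at the boundary and readers subtract it (exactly once).

#' Construct a reference (in silico) label map
#'
#' @param map_id map identifier.
#' @param length_bp total map length in bp (>= 0).
#' @param labels named list, one sorted numeric vector of 0-based label
#'   positions per channel; names are channel ids ("1", "2", ...).
#' @param gaps two-column matrix of half-open `[start, end)` intervals marking
#'   runs of N (scaffold gaps); may have zero rows.
#' @return an object of class `reference_map`.
#' @export
reference_map <- function(map_id, length_bp, labels = list(), gaps = empty_gaps()) {
  nm_assert(is.character(map_id) && length(map_id) == 1L, "map_id must be a string")
  nm_assert(is_scalar_number(length_bp) && length_bp >= 0, "length_bp must be >= 0")
  labels <- normalize_labels(labels, length_bp, strict_upper = TRUE)
  gaps <- normalize_gaps(gaps, length_bp)
  structure(list(map_id = map_id, length_bp = as.numeric(length_bp),
                 labels = labels, gaps = gaps),
            class = "reference_map")
}

empty_gaps <- function() matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end")))

normalize_labels <- function(labels, length_bp, strict_upper = FALSE) {
  nm_assert(is.list(labels), "labels must be a named list of position vectors")
  if (length(labels) == 0L) return(labels)
  nm_assert(!is.null(names(labels)) && all(nzchar(names(labels))),
            "labels list must be named by channel id")
  out <- lapply(names(labels), function(ch) {
    p <- as.numeric(labels[[ch]])
    nm_assert(!anyNA(p), "channel %s: NA label position", ch)
    nm_assert(all(diff(p) > 0) || length(p) <= 1L,
              "channel %s: label positions must be strictly increasing", ch)
    hi <- if (strict_upper) max(length_bp - 1e-9, 0) else length_bp
    nm_assert(length(p) == 0L || (min(p) >= 0 && max(p) <= hi),
              "channel %s: label positions outside [0, %s)", ch, format(length_bp))
    p
  })
  names(out) <- names(labels)
  out[order(as.integer(names(out)))]
}

normalize_gaps <- function(gaps, length_bp) {
  if (is.null(gaps) || (is.matrix(gaps) && nrow(gaps) == 0L)) return(empty_gaps())
  gaps <- matrix(as.numeric(gaps), ncol = 2, dimnames = list(NULL, c("start", "end")))
  gaps <- gaps[order(gaps[, 1]), , drop = FALSE]
  nm_assert(all(gaps[, 2] > gaps[, 1]), "gap intervals must have end > start")
  nm_assert(all(gaps[, 1] >= 0) && all(gaps[, 2] <= length_bp),
            "gap intervals must lie within [0, length_bp)")
  if (nrow(gaps) > 1L)
    nm_assert(all(gaps[-1, 1] >= gaps[-nrow(gaps), 2]), "gap intervals must be disjoint")
  gaps
}

#' Construct a single-molecule map
#'
#' One imaged molecule: apparent length plus sorted per-channel label
#' positions, optionally with simulation ground truth attached.
#'
#' @param molecule_id molecule identifier.
#' @param length_bp apparent molecule length in calibrated bp (> 0).
#' @param labels named list of sorted numeric label positions per channel,
#'   all within `[0, length_bp]`.
#' @param truth optional list with ground-truth provenance (source map id,
#'   interval, orientation, per-label provenance).
#' @return an object of class `molecule_map`.
#' @export
molecule_map <- function(molecule_id, length_bp, labels = list(), truth = NULL) {
  nm_assert(is.character(molecule_id) && length(molecule_id) == 1L,
            "molecule_id must be a string")
  nm_assert(is_scalar_number(length_bp) && length_bp > 0, "length_bp must be > 0")
  labels <- normalize_labels(labels, length_bp, strict_upper = FALSE)
  structure(list(molecule_id = molecule_id, length_bp = as.numeric(length_bp),
                 labels = labels, truth = truth),
            class = "molecule_map")
}

#' Construct a consensus map
#'
#' Per-clone or region map: Gaussian-fitted peak positions with uncertainty
#' and molecule support, per channel.
#'
#' @param map_id map identifier.
#' @param length_bp consensus length in bp (> 0).
#' @param peaks named list, one data.frame per channel with columns
#'   `position`, `sd`, `support`; positions strictly increasing.
#' @param n_molecules number of molecules backing the consensus (>= 1).
#' @return an object of class `consensus_map`.
#' @export
consensus_map <- function(map_id, length_bp, peaks = list(), n_molecules = 1L) {
  nm_assert(is.character(map_id) && length(map_id) == 1L, "map_id must be a string")
  nm_assert(is_scalar_number(length_bp) && length_bp > 0, "length_bp must be > 0")
  nm_assert(is_scalar_number(n_molecules) && n_molecules >= 1, "n_molecules must be >= 1")
  if (length(peaks)) {
    nm_assert(!is.null(names(peaks)), "peaks must be named by channel id")
    peaks <- lapply(peaks, function(df) {
      df <- as.data.frame(df)
      nm_assert(all(c("position", "sd", "support") %in% names(df)),
                "peak frames need position/sd/support columns")
      nm_assert(nrow(df) <= 1L || all(diff(df$position) > 0),
                "peak positions must be strictly increasing")
      nm_assert(all(df$sd >= 0) && all(df$support >= 1), "invalid peak sd/support")
      df[c("position", "sd", "support")]
    })
    peaks <- peaks[order(as.integer(names(peaks)))]
  }
  structure(list(map_id = map_id, length_bp = as.numeric(length_bp),
                 peaks = peaks, n_molecules = as.integer(n_molecules)),
            class = "consensus_map")
}

# Uniform accessors so reference and consensus maps can flow through the
# same alignment code: positions per channel, map length, id.
map_positions <- function(map, channel) {
  ch <- as.character(channel)
  if (inherits(map, "consensus_map")) {
    if (is.null(map$peaks[[ch]])) numeric(0) else map$peaks[[ch]]$position
  } else {
    if (is.null(map$labels[[ch]])) numeric(0) else as.numeric(map$labels[[ch]])
  }
}

map_channels <- function(map) {
  nms <- if (inherits(map, "consensus_map")) names(map$peaks) else names(map$labels)
  as.integer(nms)
}

map_id_of <- function(map) map$map_id %||% map$molecule_id

`%||%` <- function(a, b) if (is.null(a)) b else a

n_labels <- function(map) {
  if (inherits(map, "consensus_map"))
    sum(vapply(map$peaks, nrow, integer(1)))
  else
    sum(lengths(map$labels))
}

#' @export
print.reference_map <- function(x, ...) {
  cat(sprintf("<reference_map %s: %s bp, %d labels (%s), %d gap(s)>\n",
              x$map_id, format(x$length_bp, big.mark = ","), n_labels(x),
              paste(sprintf("ch%s:%d", names(x$labels), lengths(x$labels)), collapse = " "),
              nrow(x$gaps)))
  invisible(x)
}

#' @export
print.molecule_map <- function(x, ...) {
  cat(sprintf("<molecule_map %s: %.1f bp, %d labels>\n",
              x$molecule_id, x$length_bp, sum(lengths(x$labels))))
  invisible(x)
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("<consensus_map %s: %.1f bp, %d peaks (%s), %d molecules>\n",
              x$map_id, x$length_bp, n_labels(x),
              paste(sprintf("ch%s:%d", names(x$peaks),
                            vapply(x$peaks, nrow, integer(1))), collapse = " "),
              x$n_molecules))
  invisible(x)
}
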