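# In silico digestion: two-color motif maps computed directly from sequence.

#' Find nicking-endonuclease label sites in a DNA sequence
#'
#' Scans the forward strand for each channel's recognition motif and for the
#' motif's reverse complement (a nicking enzyme recognizes one strand, but
#' sites on either strand produce a visible label on the molecule).
#' Overlapping occurrences are all reported. Runs of 10 or more consecutive
#' N are recorded as scaffold-gap intervals; motifs never match into an N.
#'
#' Label coordinate convention: the 0-based position of the first base of the
#' motif occurrence on the forward strand. The few-bp offset between the
#' recognition site and the actual nick is far below map resolution and is
#' ignored.
#'
#' @param sequence a DNA string over A/C/G/T/N (case-insensitive), or a
#'   `Biostrings::DNAString`.
#' @param channels list of [channel_spec()] objects; defaults to the
#'   Nt.BspQI + Nt.BbvCI two-color set.
#' @param map_id identifier for the resulting map.
#' @param n_gap_min minimum N-run length called as a scaffold gap (bp).
#' @return a [reference_map()] with one label vector per channel.
#' @examples
#' m <- find_nick_sites("GCTCTTCAAAAACCTCAGC")
#' m$labels
#' @export
find_nick_sites <- function(sequence, channels = default_channels(),
                            map_id = "map1", n_gap_min = 10L) {
  channels <- validate_channels(channels)
  if (inherits(sequence, "DNAString") || inherits(sequence, "BString"))
    sequence <- as.character(sequence)
  nm_assert(is.character(sequence) && length(sequence) == 1L,
            "sequence must be a single string")
  seq <- toupper(sequence)
  n <- nchar(seq)
  if (n == 0L) {
    lab <- setNames(rep(list(numeric(0)), length(channels)),
                    as.character(channel_ids(channels)))
    return(reference_map(map_id, 0, lab))
  }
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    nm_validation_error("invalid character '%s' at position %d of %s",
                        substr(seq, bad, bad), as.integer(bad), map_id)

  labels <- lapply(channels, function(ch) {
    hits <- c(fixed_matches(seq, ch$motif), fixed_matches(seq, revcomp(ch$motif)))
    sort(unique(hits))
  })
  names(labels) <- as.character(channel_ids(channels))

  reference_map(map_id, n, labels, gaps = n_run_gaps(seq, n_gap_min))
}

# All 0-based start positions of exact occurrences, including overlapping
# ones (zero-width lookahead so consecutive hits may overlap).
fixed_matches <- function(seq, motif) {
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] < 0L) return(numeric(0))
  as.numeric(hits) - 1
}

# Half-open [start, end) intervals of runs of >= n_min consecutive N.
n_run_gaps <- function(seq, n_min) {
  r <- rle(strsplit(seq, "")[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= n_min
  if (!any(keep)) return(empty_gaps())
  cbind(start = starts[keep], end = ends[keep])
}

#' Label information density of a map
#'
#' Average spacing between labels: map length divided by the total label
#' count across channels, reported in kb per label.
#'
#' @param map a [reference_map()] or [consensus_map()].
#' @return kb of map length per label (positive real).
#' @examples
#' m <- find_nick_sites(strrep("GCTCTTCAAA", 10))
#' label_density(m)
#' @export
label_density <- function(map) {
  total <- n_labels(map)
  if (total < 1L)
    nm_validation_error("label density undefined: map %s has zero labels",
                        map_id_of(map))
  (map$length_bp / total) / 1000
}

#' In silico digestion of a FASTA file
#'
#' Each record becomes an independent reference map named by its FASTA id.
#'
#' @param path path to a (multi-)FASTA file.
#' @inheritParams find_nick_sites
#' @return a named list of [reference_map()] objects.
#' @export
digest_fasta <- function(path, channels = default_channels(), n_gap_min = 10L) {
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(id)
    find_nick_sites(seqs[[id]], channels, map_id = id, n_gap_min = n_gap_min))
  names(out) <- names(seqs)
  out
}
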