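# Assembly validation against a genome map: discrepancy classification,
# scaffold anchoring into gaps, tandem-repeat label-density signatures.

DISCREPANCY_KINDS <- c("EXTRA_SEQUENCE", "MISSING_SEQUENCE", "INTERVAL_MISMATCH",
                       "HIGH_DENSITY_REGION", "UNALIGNED_END")

empty_discrepancies <- function() {
  data.frame(kind = character(0), query_id = character(0),
             ref_start = numeric(0), ref_end = numeric(0),
             query_start = numeric(0), query_end = numeric(0),
             size_bp = numeric(0), evidence = character(0),
             stringsAsFactors = FALSE)
}

discrepancy_row <- function(kind, query_id, ref_int, qry_int, size_bp, evidence = "") {
  stopifnot(kind %in% DISCREPANCY_KINDS)
  data.frame(kind = kind, query_id = query_id,
             ref_start = ref_int[1], ref_end = ref_int[2],
             query_start = qry_int[1], query_end = qry_int[2],
             size_bp = size_bp, evidence = evidence, stringsAsFactors = FALSE)
}

#' Compare an in silico assembly map against a genome map
#'
#' Every scaffold map is aligned to the genome map in fit mode; the matched
#' flank intervals are then walked and classified:
#' \describe{
#'   \item{EXTRA_SEQUENCE}{query labels between matched flanks with no
#'     reference counterpart and query span exceeding the reference span by
#'     more than `tol` (a wrongly inserted contig), or a length-only surplus
#'     whose query interval crosses an annotated scaffold gap / contig
#'     junction.}
#'   \item{MISSING_SEQUENCE}{reference labels between matched flanks absent
#'     from the assembly with a span deficit beyond `tol`, or a genome-map
#'     segment with at least `min_labels` labels not covered by any accepted
#'     scaffold alignment (an assembly gap).}
#'   \item{INTERVAL_MISMATCH}{flanks match, no extra or missing labels, but
#'     the spans disagree by more than `tol` (local misassembly).}
#'   \item{UNALIGNED_END}{a scaffold end with labels that extends beyond its
#'     aligned span by more than `tol`.}
#'   \item{HIGH_DENSITY_REGION}{forwarded from [detect_label_repeats()] via
#'     the `repeats` argument.}
#' }
#' Size estimates are signed differences of flank-to-flank spans (positive =
#' sequence surplus in the assembly). For a label-free gap the size is the
#' genome-map distance between the flanking matched labels.
#'
#' @param assembly_maps a [reference_map()] or list of them (scaffolds).
#' @param genome_map a [consensus_map()] (or reference map) to validate
#'   against.
#' @param params an [alignment_params()].
#' @param tol length-mismatch tolerance in bp; default
#'   `max(1500, 3 * pooled peak sd)` — the map's optical resolution and
#'   sizing accuracy bound.
#' @param min_labels minimum labels for an uncovered genome-map segment to be
#'   called MISSING_SEQUENCE.
#' @param exclusions optional two-column matrix of genome-map intervals
#'   excluded from the completeness denominator (user-supplied annotations,
#'   e.g. regions with known missing clone coverage), never inferred.
#' @param repeats optional discrepancy frame from [detect_label_repeats()].
#' @return list with `discrepancies` (data frame), `completeness` (class
#'   `completeness_report`: aligned_ref_bp, total_ref_bp, fraction,
#'   excluded), and `alignments`.
#' @export
compare_assembly <- function(assembly_maps, genome_map, params = alignment_params(),
                             tol = NULL, min_labels = 3L, exclusions = NULL,
                             repeats = NULL) {
  if (inherits(assembly_maps, "reference_map")) assembly_maps <- list(assembly_maps)
  nm_assert(length(assembly_maps) >= 1L, "no assembly maps given")
  shared <- Reduce(intersect, lapply(c(assembly_maps, list(genome_map)), map_channels))
  nm_assert(length(shared) >= 1L, "assembly and genome map share no channel")
  if (is.null(tol)) tol <- default_tol(genome_map)

  L <- genome_map$length_bp
  disc <- empty_discrepancies()
  aligned_spans <- matrix(numeric(0), ncol = 2)
  alignments <- list()

  for (sm in assembly_maps) {
    aln <- align_maps(sm, genome_map, mode = "fit", params)
    alignments[[map_id_of(sm)]] <- aln
    if (!aln$accepted) next
    aligned_spans <- rbind(aligned_spans, aln$aligned_ref_span)
    disc <- rbind(disc, walk_alignment(aln, sm, genome_map, tol))
  }

  # genome-map segments not covered by any accepted alignment
  disc <- rbind(disc, uncovered_segments(genome_map, aligned_spans, min_labels, tol))
  if (!is.null(repeats) && nrow(repeats)) disc <- rbind(disc, repeats)
  rownames(disc) <- NULL
  disc <- disc[order(disc$ref_start), , drop = FALSE]
  disc <- coalesce_adjacent(disc)

  completeness <- completeness_report(disc, aligned_spans, L, exclusions)
  list(discrepancies = disc, completeness = completeness, alignments = alignments)
}

# A long structural event can be interrupted by a single spurious matched
# pair inside it (the outlier-capped aligner tolerates such a match), which
# splits one event into two rows sharing a boundary; fuse them back.
coalesce_adjacent <- function(disc) {
  if (nrow(disc) < 2L) return(disc)
  k <- 2L
  while (k <= nrow(disc)) {
    a <- disc[k - 1L, ]; b <- disc[k, ]
    fuse <- a$kind == b$kind && a$kind == "MISSING_SEQUENCE" &&
      identical(a$query_id, b$query_id) &&
      isTRUE(b$ref_start - a$ref_end < 5000)
    if (fuse) {
      disc$ref_end[k - 1L] <- b$ref_end
      qr <- range(c(a$query_start, a$query_end, b$query_start, b$query_end))
      # recompute the size over the fused flanks; the small matched island
      # between the parts must not count as recovered sequence
      disc$size_bp[k - 1L] <- if (anyNA(qr)) a$size_bp + b$size_bp
        else (qr[2] - qr[1]) - (b$ref_end - a$ref_start)
      disc$query_start[k - 1L] <- qr[1]
      disc$query_end[k - 1L] <- qr[2]
      disc$evidence[k - 1L] <- paste(a$evidence, b$evidence, sep = "|")
      disc <- disc[-k, , drop = FALSE]
    } else k <- k + 1L
  }
  rownames(disc) <- NULL
  disc
}

default_tol <- function(genome_map) {
  sds <- if (inherits(genome_map, "consensus_map"))
    unlist(lapply(genome_map$peaks, `[[`, "sd")) else numeric(0)
  pooled <- if (length(sds)) sqrt(mean(sds^2)) else 0
  max(1500, 3 * pooled)
}

# classify the intervals between consecutive matched label pairs
walk_alignment <- function(aln, scaffold, genome_map, tol) {
  out <- empty_discrepancies()
  m <- aln$matches
  if (nrow(m) < 2L) return(out)
  qid <- aln$query_id
  Lq <- aln$query_length
  flip <- aln$orientation == "flipped"
  Rm <- merged_labels(genome_map)
  Qm <- merged_labels(scaffold)
  if (flip) Qm <- flip_merged(Qm, Lq)

  # query coordinate in the aligned frame -> original forward frame interval
  to_fwd <- function(a, b) if (flip) c(Lq - b, Lq - a) else c(a, b)

  for (t in 2:nrow(m)) {
    r0 <- m$ref_pos[t - 1L]; r1 <- m$ref_pos[t]
    q0 <- m$query_pos[t - 1L]; q1 <- m$query_pos[t]
    rspan <- r1 - r0; qspan <- q1 - q0
    delta <- qspan - rspan
    n_extra <- sum(Qm$pos > q0 & Qm$pos < q1)
    n_missing <- sum(Rm$pos > r0 & Rm$pos < r1)
    qint <- to_fwd(q0, q1)
    if (n_extra >= 1L && delta > tol) {
      out <- rbind(out, discrepancy_row(
        "EXTRA_SEQUENCE", qid, c(r0, r1), qint, delta,
        sprintf("extra_labels=%d", n_extra)))
    } else if (n_missing >= 1L && -delta > tol) {
      out <- rbind(out, discrepancy_row(
        "MISSING_SEQUENCE", qid, c(r0, r1), qint, delta,
        sprintf("missing_labels=%d;map_gap_bp=%.0f", n_missing, rspan)))
    } else if (n_extra == 0L && n_missing == 0L && abs(delta) > tol) {
      crosses_gap <- crosses_annotation(scaffold, to_fwd(q0, q1))
      if (delta > 0 && crosses_gap) {
        out <- rbind(out, discrepancy_row(
          "EXTRA_SEQUENCE", qid, c(r0, r1), qint, delta, "length_only;junction"))
      } else if (delta < 0 && crosses_gap) {
        out <- rbind(out, discrepancy_row(
          "MISSING_SEQUENCE", qid, c(r0, r1), qint, delta,
          sprintf("undersized_gap;map_gap_bp=%.0f", rspan)))
      } else {
        out <- rbind(out, discrepancy_row(
          "INTERVAL_MISMATCH", qid, c(r0, r1), qint, delta,
          sprintf("assembly=%.0f;map=%.0f", qspan, rspan)))
      }
    }
  }

  # scaffold ends extending past the aligned span
  q_lo <- min(m$query_pos); q_hi <- max(m$query_pos)
  n_before <- sum(Qm$pos < q_lo); n_after <- sum(Qm$pos > q_hi)
  if (n_before >= 1L && q_lo > tol)
    out <- rbind(out, discrepancy_row(
      "UNALIGNED_END", qid, c(m$ref_pos[1], m$ref_pos[1]), to_fwd(0, q_lo),
      q_lo, sprintf("labels=%d", n_before)))
  if (n_after >= 1L && (Lq - q_hi) > tol)
    out <- rbind(out, discrepancy_row(
      "UNALIGNED_END", qid, c(m$ref_pos[nrow(m)], m$ref_pos[nrow(m)]),
      to_fwd(q_hi, Lq), Lq - q_hi, sprintf("labels=%d", n_after)))
  out
}

crosses_annotation <- function(map, qint) {
  g <- map$gaps
  if (is.null(g) || !nrow(g)) return(FALSE)
  any(g[, 1] < qint[2] & g[, 2] > qint[1])
}

uncovered_segments <- function(genome_map, aligned_spans, min_labels, tol) {
  out <- empty_discrepancies()
  L <- genome_map$length_bp
  cov <- merge_intervals(aligned_spans)
  Rm <- merged_labels(genome_map)
  # complement of covered spans
  segs <- interval_complement(cov, L)
  for (k in seq_len(nrow(segs))) {
    s <- segs[k, 1]; e <- segs[k, 2]
    nl <- sum(Rm$pos >= s & Rm$pos <= e)
    if (nl >= min_labels && (e - s) > tol)
      out <- rbind(out, discrepancy_row(
        "MISSING_SEQUENCE", NA_character_, c(s, e), c(NA_real_, NA_real_),
        -(e - s), sprintf("uncovered;labels=%d", nl)))
  }
  out
}

merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  out
}

interval_complement <- function(iv, L) {
  if (!nrow(iv)) return(matrix(c(0, L), ncol = 2))
  starts <- c(0, iv[, 2])
  ends <- c(iv[, 1], L)
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

intersect_len <- function(a, b) {
  # total length of intersection of interval a with interval set b
  if (!nrow(b)) return(0)
  sum(pmax(0, pmin(a[2], b[, 2]) - pmax(a[1], b[, 1])))
}

completeness_report <- function(disc, aligned_spans, total_ref_bp, exclusions) {
  excl <- if (is.null(exclusions)) empty_gaps()
          else merge_intervals(matrix(as.numeric(exclusions), ncol = 2))
  cov <- merge_intervals(aligned_spans)
  # subtract discrepant genome-map intervals from the aligned span
  bad <- disc[disc$kind %in% c("MISSING_SEQUENCE", "INTERVAL_MISMATCH",
                               "HIGH_DENSITY_REGION"), c("ref_start", "ref_end")]
  bad <- merge_intervals(as.matrix(bad))
  aligned <- 0
  if (nrow(cov)) for (k in seq_len(nrow(cov))) {
    a <- cov[k, ]
    len <- (a[2] - a[1]) - intersect_len(a, bad) - intersect_len(a, excl)
    aligned <- aligned + max(len, 0)
  }
  denom <- total_ref_bp - sum(excl[, 2] - excl[, 1])
  structure(list(aligned_ref_bp = aligned, total_ref_bp = total_ref_bp,
                 fraction = if (denom > 0) aligned / denom else NA_real_,
                 excluded = excl),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness: %.1f%% (%.0f / %.0f bp aligned%s)>\n",
              100 * x$fraction, x$aligned_ref_bp,
              x$total_ref_bp - sum(x$excluded[, 2] - x$excluded[, 1]),
              if (nrow(x$excluded)) sprintf(", %d exclusion(s)", nrow(x$excluded)) else ""))
  invisible(x)
}

#' Anchor unplaced scaffolds into genome-map gaps
#'
#' Each unplaced scaffold map is aligned in fit mode against every gap
#' window (gap plus flank margin) of the genome map. A placement is accepted
#' when the best alignment passes the acceptance thresholds and beats the
#' runner-up scaffold for that gap by at least `ambiguity_margin`; gaps
#' claimed by two indistinguishable scaffolds are reported ambiguous and
#' left unfilled. Placements are made greedily by score so no two scaffolds
#' claim the same gap and no scaffold is placed twice.
#'
#' @param unplaced list of [reference_map()] scaffolds.
#' @param genome_map a [consensus_map()].
#' @param gaps two-column matrix of genome-map gap intervals (typically the
#'   MISSING_SEQUENCE calls of [compare_assembly()]).
#' @param params an [alignment_params()].
#' @param flank_margin_bp window extension on each side of a gap.
#' @param ambiguity_margin minimum score separation between competing
#'   scaffolds.
#' @return data frame: scaffold_id, gap_start, gap_end, status
#'   (placed/ambiguous/unanchorable/unplaced), position, orientation, score,
#'   residual_gap_bp.
#' @export
anchor_scaffolds <- function(unplaced, genome_map, gaps,
                             params = alignment_params(),
                             flank_margin_bp = 20000, ambiguity_margin = 5) {
  if (inherits(unplaced, "reference_map")) unplaced <- list(unplaced)
  gaps <- matrix(as.numeric(gaps), ncol = 2)
  ids <- vapply(unplaced, map_id_of, character(1))
  L <- genome_map$length_bp

  res <- data.frame(scaffold_id = ids, gap_start = NA_real_, gap_end = NA_real_,
                    status = "unplaced", position = NA_real_,
                    orientation = NA_character_, score = NA_real_,
                    residual_gap_bp = NA_real_, stringsAsFactors = FALSE)
  no_labels <- vapply(unplaced, function(m) n_labels(m) == 0L, logical(1))
  res$status[no_labels] <- "unanchorable"
  if (all(no_labels) || !nrow(gaps)) return(res)

  cand <- list()
  for (g in seq_len(nrow(gaps))) {
    w0 <- max(0, gaps[g, 1] - flank_margin_bp)
    w1 <- min(L, gaps[g, 2] + flank_margin_bp)
    sub <- window_map(genome_map, w0, w1)
    if (n_labels(sub) == 0L) next
    for (s in which(!no_labels)) {
      aln <- align_maps(unplaced[[s]], sub, mode = "fit", params)
      if (aln$accepted)
        cand[[length(cand) + 1L]] <- list(gap = g, scaf = s, aln = aln, w0 = w0)
    }
  }
  if (!length(cand)) return(res)

  # per-gap ambiguity: two scaffolds within ambiguity_margin
  ambiguous <- rep(FALSE, length(cand))
  for (g in unique(vapply(cand, `[[`, integer(1), "gap"))) {
    k <- which(vapply(cand, `[[`, integer(1), "gap") == g)
    if (length(k) >= 2L) {
      sc <- vapply(cand[k], function(x) x$aln$score, numeric(1))
      o <- order(sc, decreasing = TRUE)
      if (sc[o[1]] - sc[o[2]] < ambiguity_margin) ambiguous[k[o[1:2]]] <- TRUE
    }
  }
  for (k in which(ambiguous)) {
    s <- cand[[k]]$scaf; g <- cand[[k]]$gap
    res$status[s] <- "ambiguous"
    res$gap_start[s] <- gaps[g, 1]; res$gap_end[s] <- gaps[g, 2]
    res$score[s] <- cand[[k]]$aln$score
  }

  ok <- which(!ambiguous)
  ok <- ok[order(vapply(cand[ok], function(x) x$aln$score, numeric(1)), decreasing = TRUE)]
  gap_used <- rep(FALSE, nrow(gaps)); scaf_used <- rep(FALSE, length(unplaced))
  for (k in ok) {
    g <- cand[[k]]$gap; s <- cand[[k]]$scaf
    if (gap_used[g] || scaf_used[s] || res$status[s] == "ambiguous") next
    gap_used[g] <- TRUE; scaf_used[s] <- TRUE
    aln <- cand[[k]]$aln
    res$status[s] <- "placed"
    res$gap_start[s] <- gaps[g, 1]; res$gap_end[s] <- gaps[g, 2]
    res$position[s] <- cand[[k]]$w0 + aln$offset_bp
    res$orientation[s] <- aln$orientation
    res$score[s] <- aln$score
    res$residual_gap_bp[s] <- (gaps[g, 2] - gaps[g, 1]) - unplaced[[s]]$length_bp
  }
  res
}

# restrict a consensus map to [w0, w1), shifting coordinates to the window
window_map <- function(map, w0, w1) {
  if (inherits(map, "consensus_map")) {
    pk <- lapply(map$peaks, function(df) {
      df <- df[df$position >= w0 & df$position < w1, , drop = FALSE]
      df$position <- df$position - w0
      df
    })
    consensus_map(paste0(map$map_id, sprintf("[%d,%d)", round(w0), round(w1))),
                  max(w1 - w0, 1), pk, n_molecules = map$n_molecules)
  } else {
    labs <- lapply(map$labels, function(p) p[p >= w0 & p < w1] - w0)
    reference_map(paste0(map$map_id, sprintf("[%d,%d)", round(w0), round(w1))),
                  max(w1 - w0, 1), labs, gaps = empty_gaps())
  }
}

#' Detect high-density label regions (tandem-repeat signatures)
#'
#' Tandem arrays carrying a nick site per unit produce label densities beyond
#' the optical resolution: individual molecules carry many labels in a short
#' span, but the labels do not cluster into discrete consensus peaks. A
#' window is slid over the consensus frame and flagged where the mean
#' per-molecule label count exceeds the consensus peak count by a factor of
#' `density_threshold` or more; adjacent flagged windows are merged and
#' region bounds are refined to the span of the contributing molecule labels.
#'
#' @param molecules the cluster members underlying the consensus.
#' @param consensus the cluster's [consensus_map()].
#' @param orientations per-molecule orientation into the consensus frame
#'   ("forward"/"flipped"); required — unoriented molecules are a validation
#'   error.
#' @param channel label channel scanned (default 1).
#' @param window_bp sliding window width (default 3000).
#' @param step_bp window step (default `window_bp / 4`).
#' @param density_threshold flag factor of molecule labels over consensus
#'   peaks (default 1.5).
#' @param min_mean_labels minimum mean per-molecule label count in a flagged
#'   window (guards against empty-peak windows with stray false labels).
#' @param run_gap_bp maximum same-molecule label gap inside a dense run
#'   (default 2x the optical resolution).
#' @param min_run minimum labels in a dense run (default 4).
#' @param run_frac fraction of covering molecules that must carry a dense
#'   run through the window (default 0.35).
#' @param resolution_bp optical resolution used to scale `run_gap_bp`.
#' @param unit_length_bp optional repeat-unit length; when given, estimated
#'   copy number = region length / unit length is reported.
#'
#' @details Two complementary window triggers are used. The count trigger
#' flags windows where the mean per-molecule label count exceeds the
#' consensus peak count by `density_threshold`; it catches arrays whose
#' labels fail to form consensus peaks at all. A regular array can however
#' masquerade as a lattice of pseudo-peaks (merge midpoints quantize to
#' half-unit positions), which defeats the count trigger; the run trigger
#' therefore also flags windows where at least `run_frac` of the covering
#' molecules carry a run of `min_run`+ labels spaced within `run_gap_bp` —
#' the per-molecule signature of label density at the optical resolution
#' limit.
#' @return discrepancy data frame (kind HIGH_DENSITY_REGION) with region
#'   intervals in the consensus frame.
#' @export
detect_label_repeats <- function(molecules, consensus, orientations,
                                 channel = 1L, window_bp = 3000,
                                 step_bp = window_bp / 4,
                                 density_threshold = 1.5,
                                 min_mean_labels = 2,
                                 run_gap_bp = 2 * resolution_bp,
                                 min_run = 4L, run_frac = 0.35,
                                 resolution_bp = 1000,
                                 unit_length_bp = NULL) {
  nm_assert(!missing(orientations) && !is.null(orientations) &&
              length(orientations) == length(molecules),
            "molecules must be oriented to the consensus frame (one orientation each)")
  nm_assert(all(orientations %in% c("forward", "flipped")),
            "orientations must be 'forward' or 'flipped'")
  L <- consensus$length_bp
  per_mol <- lapply(seq_along(molecules), function(i) {
    p <- map_positions(molecules[[i]], channel)
    if (orientations[i] == "flipped") p <- rev(molecules[[i]]$length_bp - p)
    p * (L / molecules[[i]]$length_bp)   # rescale into the consensus frame
  })
  peaks <- map_positions(consensus, channel)

  # labels belonging to a dense per-molecule run (>= min_run labels, all
  # gaps <= run_gap_bp)
  runs <- lapply(per_mol, function(p) {
    if (length(p) < min_run) return(numeric(0))
    grp <- cumsum(c(1, as.numeric(diff(p) > run_gap_bp)))
    sizes <- table(grp)
    p[grp %in% as.integer(names(sizes)[sizes >= min_run])]
  })

  starts <- seq(0, max(L - window_bp, 0), by = step_bp)
  flagged <- logical(length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- s + window_bp
    counts <- vapply(per_mol, function(p) sum(p >= s & p < e), numeric(1))
    mean_ct <- mean(counts)
    peak_ct <- sum(peaks >= s & peaks < e)
    count_trigger <- mean_ct >= min_mean_labels &&
      mean_ct / max(peak_ct, 1) >= density_threshold
    n_cover <- sum(counts > 0)
    n_run <- sum(vapply(runs, function(p) any(p >= s & p < e), logical(1)))
    run_trigger <- n_cover >= 5L && n_run / n_cover >= run_frac
    flagged[k] <- count_trigger || run_trigger
  }
  if (!any(flagged)) return(empty_discrepancies())

  iv <- cbind(starts[flagged], starts[flagged] + window_bp)
  regions <- merge_intervals(iv)
  out <- empty_discrepancies()
  pooled <- unlist(per_mol)
  pooled_runs <- unlist(runs)
  n_mol <- length(per_mol)
  for (k in seq_len(nrow(regions))) {
    s <- regions[k, 1]; e <- regions[k, 2]
    inside <- pooled_runs[pooled_runs >= s & pooled_runs < e]
    if (length(inside) < 10L) inside <- pooled[pooled >= s & pooled < e]
    if (!length(inside)) next
    # region bounds at the half-plateau crossings of the dense-run label
    # density profile: run labels vanish outside the array (isolated sites
    # do not form runs), and the crossing is unbiased under symmetric
    # sizing-noise smear of the edges
    src <- if (length(pooled_runs)) pooled_runs else pooled
    grid <- seq(max(0, s - 2000), min(L, e + 2000), by = 100)
    dens <- vapply(grid, function(g)
      sum(src >= g - 500 & src < g + 500) / n_mol, numeric(1))
    plateau <- stats::quantile(dens[grid >= s & grid <= e], 0.75, names = FALSE)
    above <- which(dens >= plateau / 2)
    if (!length(above)) next
    lo <- grid[min(above)]; hi <- grid[max(above)]
    len <- hi - lo
    ev <- sprintf("mean_labels_per_molecule=%.2f",
                  mean(vapply(per_mol, function(p) sum(p >= lo & p < hi), numeric(1))))
    if (!is.null(unit_length_bp))
      ev <- paste0(ev, sprintf(";copies=%.1f", len / unit_length_bp))
    out <- rbind(out, discrepancy_row("HIGH_DENSITY_REGION", NA_character_,
                                      c(lo, hi), c(NA_real_, NA_real_), len, ev))
  }
  out
}
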