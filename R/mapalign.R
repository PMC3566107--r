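# Ordered two-color map alignment (dynamic programming) and merging of
# per-clone consensus maps into a region genome map.

#' Alignment scoring parameters
#'
#' The score of a monotone matching is
#' `n_match * match_bonus - sum(interval penalties) - skip costs`, where the
#' interval penalty for a matched flanking interval pair is
#' `min((dlen)^2 / (2 * (sigma2_per_bp * ref_len + sigma0_sq)),
#' outlier_penalty)` — a chi-square term whose variance grows linearly with
#' the reference interval length (the standard sizing-error model for
#' ordered-map alignment), capped so that a single structural discrepancy
#' (a misassembled interval, an assembly gap) costs a bounded amount and the
#' chain continues through it instead of breaking. Skipping a reference
#' label inside the aligned span costs `miss_penalty`, skipping a query
#' label costs `false_penalty`. An alignment is accepted when its score
#' reaches `min_score` and it matches at least `min_labels` labels.
#'
#' The variance defaults reflect consensus-map peak accuracy (sd ~150-300
#' bp), which keeps random label coincidences penalized well beyond the
#' match bonus while true matched intervals cost well under one bonus unit.
#'
#' @param match_bonus reward per matched label pair.
#' @param sigma2_per_bp sizing variance per bp of reference interval (bp).
#' @param sigma0_sq fixed sizing variance floor (bp^2); default `2 * 150^2`,
#'   two peak-position error terms.
#' @param miss_penalty cost of an unmatched reference label inside the span.
#' @param false_penalty cost of an unmatched query label inside the span.
#' @param outlier_penalty cap on a single interval penalty (structural
#'   discrepancies cost this much and no more).
#' @param min_score acceptance threshold on the score.
#' @param min_labels minimum matched labels for acceptance (default 5).
#' @param lookback dynamic-programming band: maximum labels skipped between
#'   consecutive matches on either map. `Inf` gives the exact optimum.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match_bonus = 4, sigma2_per_bp = 3,
                             sigma0_sq = 2 * 150^2, miss_penalty = 3,
                             false_penalty = 3, outlier_penalty = 12,
                             min_score = 15, min_labels = 5L, lookback = 10) {
  p <- list(match_bonus = match_bonus, sigma2_per_bp = sigma2_per_bp,
            sigma0_sq = sigma0_sq, miss_penalty = miss_penalty,
            false_penalty = false_penalty, outlier_penalty = outlier_penalty,
            min_score = min_score,
            min_labels = as.integer(min_labels), lookback = lookback)
  nm_assert(all(vapply(p[1:7], is_scalar_number, logical(1))),
            "alignment params must be finite numbers")
  nm_assert(p$sigma0_sq > 0 && p$sigma2_per_bp >= 0, "variance terms must be positive")
  nm_assert(p$lookback >= 1, "lookback must be >= 1")
  structure(p, class = "alignment_params")
}

# Flatten a map's channels into one position-ordered label list.
merged_labels <- function(map) {
  chans <- map_channels(map)
  pos <- unlist(lapply(chans, function(ch) map_positions(map, ch)))
  chv <- unlist(lapply(chans, function(ch) rep(ch, length(map_positions(map, ch)))))
  idx <- unlist(lapply(chans, function(ch) seq_along(map_positions(map, ch))))
  o <- order(pos, chv)
  list(pos = pos[o], channel = chv[o], index = idx[o])
}

#' Align two ordered two-color maps
#'
#' Dynamic program over the position-ordered union of both channels' labels.
#' Matching two labels requires equal channels; matches must be jointly
#' monotone in position. `mode = "fit"` anchors the whole query inside the
#' reference (query labels outside the aligned span are penalized, reference
#' ends are free); `mode = "overlap"` is a dovetail alignment with free ends
#' on both maps. Both query orientations are tried; ties are broken toward
#' more matched labels, then smaller absolute offset.
#'
#' @param query,ref [reference_map()] or [consensus_map()] objects.
#' @param mode "fit" or "overlap".
#' @param params an [alignment_params()] object.
#' @return an object of class `map_alignment` with fields `query_id`,
#'   `ref_id`, `mode`, `orientation`, `score`, `accepted`, `matches` (data
#'   frame: channel, per-channel ref/query label indices and positions),
#'   `offset_bp`, `aligned_ref_span`, `unmatched_ref`, `unmatched_query`.
#'   When no scoring matching exists the result has `accepted = FALSE` and
#'   zero matches (an explicit unaligned result, not an error).
#' @export
align_maps <- function(query, ref, mode = c("overlap", "fit"),
                       params = alignment_params()) {
  mode <- match.arg(mode)
  nm_assert(inherits(params, "alignment_params"), "params must be alignment_params")
  shared <- intersect(map_channels(query), map_channels(ref))
  nm_assert(length(shared) >= 1L, "maps share no label channel")

  R <- merged_labels(ref)
  Qf <- merged_labels(query)
  best <- NULL
  for (orient in c("forward", "flipped")) {
    Q <- if (orient == "forward") Qf else flip_merged(Qf, query$length_bp)
    cur <- align_dp(R, Q, mode, params)
    cur$orientation <- orient
    if (is.null(best) || better_alignment(cur, best)) best <- cur
  }
  finish_alignment(best, query, ref, mode, params)
}

flip_merged <- function(M, length_bp) {
  n <- length(M$pos)
  list(pos = rev(length_bp - M$pos), channel = rev(M$channel), index = rev(M$index))
}

better_alignment <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$n_match != b$n_match) return(a$n_match > b$n_match)
  abs(a$offset) < abs(b$offset)
}

# Core DP. R, Q: merged label lists. Returns raw score/trace in merged index
# space of the given orientation.
align_dp <- function(R, Q, mode, p) {
  n <- length(R$pos); m <- length(Q$pos)
  empty <- list(score = -Inf, n_match = 0L, pairs = NULL, offset = Inf)
  if (n == 0L || m == 0L) return(empty)
  K <- min(p$lookback, max(n, m))
  S <- matrix(-Inf, n, m)
  Pi <- matrix(0L, n, m); Pj <- matrix(0L, n, m)

  for (i in seq_len(n)) {
    js <- which(Q$channel == R$channel[i])
    for (j in js) {
      start_val <- if (mode == "fit") -p$false_penalty * (j - 1L) else 0
      best_val <- start_val; bi <- 0L; bj <- 0L
      i0 <- max(1L, i - K); j0 <- max(1L, j - K)
      if (i > 1L && j > 1L) {
        ir <- i0:(i - 1L); jr <- j0:(j - 1L)
        Sw <- S[ir, jr, drop = FALSE]
        if (any(is.finite(Sw))) {
          a <- R$pos[i] - R$pos[ir]            # ref interval lengths
          b <- Q$pos[j] - Q$pos[jr]
          pen <- pmin(outer(a, b, "-")^2 / (2 * (p$sigma2_per_bp * a + p$sigma0_sq)),
                      p$outlier_penalty)
          val <- Sw - pen -
            p$miss_penalty * (i - ir - 1L) -
            matrix(p$false_penalty * (j - jr - 1L), length(ir), length(jr), byrow = TRUE)
          k <- which.max(val)
          if (val[k] > best_val) {
            best_val <- val[k]
            bi <- ir[(k - 1L) %% length(ir) + 1L]
            bj <- jr[(k - 1L) %/% length(ir) + 1L]
          }
        }
      }
      S[i, j] <- p$match_bonus + best_val
      Pi[i, j] <- bi; Pj[i, j] <- bj
    }
  }

  final <- S
  if (mode == "fit") {
    final <- final - matrix(p$false_penalty * (m - col(final)), n, m)
    final[!is.finite(S)] <- -Inf
  }
  if (!any(is.finite(final))) return(empty)
  k <- which.max(final)
  ei <- (k - 1L) %% n + 1L; ej <- (k - 1L) %/% n + 1L
  # traceback
  pairs <- matrix(integer(0), ncol = 2)
  i <- ei; j <- ej
  while (i > 0L) {
    pairs <- rbind(c(i, j), pairs)
    ii <- Pi[i, j]; jj <- Pj[i, j]
    i <- ii; j <- jj
  }
  offset <- mean(R$pos[pairs[, 1]] - Q$pos[pairs[, 2]])
  list(score = final[k], n_match = nrow(pairs), pairs = pairs, offset = offset)
}

finish_alignment <- function(raw, query, ref, mode, params) {
  R <- merged_labels(ref)
  Qf <- merged_labels(query)
  accepted <- is.finite(raw$score) && raw$score >= params$min_score &&
    raw$n_match >= params$min_labels
  if (!is.finite(raw$score) || raw$n_match == 0L) {
    return(structure(list(
      query_id = map_id_of(query), ref_id = map_id_of(ref), mode = mode,
      orientation = "forward", score = raw$score, accepted = FALSE,
      n_match = 0L,
      matches = data.frame(channel = integer(0), ref_index = integer(0),
                           query_index = integer(0), ref_pos = numeric(0),
                           query_pos = numeric(0)),
      offset_bp = NA_real_, aligned_ref_span = c(NA_real_, NA_real_),
      unmatched_ref = R, unmatched_query = Qf), class = "map_alignment"))
  }
  Q <- if (raw$orientation == "forward") Qf else flip_merged(Qf, query$length_bp)
  pi <- raw$pairs[, 1]; pj <- raw$pairs[, 2]
  matches <- data.frame(
    channel = R$channel[pi],
    ref_index = R$index[pi],
    query_index = Q$index[pj],
    ref_pos = R$pos[pi],
    query_pos = Q$pos[pj])
  span <- range(R$pos[pi])
  un_ref <- lapply(sort(unique(R$channel)), function(ch)
    setdiff(which(map_positions(ref, ch) >= 0), matches$ref_index[matches$channel == ch]))
  names(un_ref) <- sort(unique(R$channel))
  un_qry <- lapply(sort(unique(Qf$channel)), function(ch)
    setdiff(seq_along(map_positions(query, ch)), matches$query_index[matches$channel == ch]))
  names(un_qry) <- sort(unique(Qf$channel))
  structure(list(
    query_id = map_id_of(query), ref_id = map_id_of(ref), mode = mode,
    orientation = raw$orientation, score = raw$score, accepted = accepted,
    n_match = raw$n_match, matches = matches, offset_bp = raw$offset,
    aligned_ref_span = span, unmatched_ref = un_ref, unmatched_query = un_qry,
    query_length = query$length_bp, ref_length = ref$length_bp),
    class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf("<map_alignment %s ~ %s (%s, %s): score %.2f, %d matches%s>\n",
              x$query_id, x$ref_id, x$mode, x$orientation, x$score, x$n_match,
              if (x$accepted) "" else " [not accepted]"))
  invisible(x)
}

#' Merge per-clone consensus maps into a region genome map
#'
#' All-pairs dovetail alignments between clone maps; accepted overlaps form
#' a graph whose maps are placed greedily along a maximum-weight spanning
#' tree (highest-scoring overlap first), composing offsets and orientations.
#' Matched peaks are merged by support-weighted averaging. Clones with no
#' acceptable overlap to any placed neighbor start a new segment, and a
#' break (no overlap evidence between neighbors) is recorded at the seam.
#'
#' @param clone_maps list of [consensus_map()] (>= 1).
#' @param params an [alignment_params()].
#' @param resolution_bp minimum same-channel peak separation in the merged
#'   map (default 1000).
#' @param segment_gap_bp nominal spacer placed between unjoined segments.
#' @param offset_tol_bp tolerance for declaring a redundant overlap
#'   contradictory (default 5000).
#' @return an object of class `genome_map`: `consensus` (merged
#'   [consensus_map()]), `tiling` (data frame clone_id/start/end/orientation),
#'   `breaks` (positions without overlap evidence), `alignments` (accepted
#'   pairwise overlaps).
#' @export
merge_consensus <- function(clone_maps, params = alignment_params(),
                            resolution_bp = 1000, segment_gap_bp = 10000,
                            offset_tol_bp = 5000) {
  nm_assert(is.list(clone_maps) && length(clone_maps) >= 1L, "need >= 1 clone map")
  for (m in clone_maps) nm_assert(inherits(m, "consensus_map") || inherits(m, "reference_map"),
                                  "clone maps must be consensus or reference maps")
  nmaps <- length(clone_maps)
  ids <- vapply(clone_maps, map_id_of, character(1))
  nm_assert(!anyDuplicated(ids), "clone map ids must be unique")

  # all-pairs overlap alignments
  edges <- list()
  if (nmaps > 1L) {
    for (i in seq_len(nmaps - 1L)) for (j in (i + 1L):nmaps) {
      aln <- align_maps(clone_maps[[j]], clone_maps[[i]], mode = "overlap", params)
      if (aln$accepted)
        edges[[length(edges) + 1L]] <- list(ref = i, qry = j, aln = aln)
    }
  }
  scores <- vapply(edges, function(e) e$aln$score, numeric(1))

  placed <- rep(FALSE, nmaps)
  start <- rep(NA_real_, nmaps)
  orient <- rep(NA_character_, nmaps)
  segment <- rep(NA_integer_, nmaps)
  lens <- vapply(clone_maps, `[[`, numeric(1), "length_bp")
  seg <- 0L
  used_edge <- rep(FALSE, length(edges))

  # Alignment geometry. With w = aln orientation and delta = aln offset
  # (ref coordinate of the aligned query frame's origin), a query label at
  # forward coordinate x sits at ref coordinate delta + x (w forward) or
  # delta + Lq - x (w flipped). Global frame: global(u) = s + u for a
  # forward-placed map, s + L - u for a flipped one.
  place_from_edge <- function(e, new_is_qry) {
    delta <- e$aln$offset_bp; w <- e$aln$orientation
    if (new_is_qry) {
      i <- e$ref; j <- e$qry
      if (orient[i] == "forward") {
        orient[j] <<- if (w == "forward") "forward" else "flipped"
        start[j] <<- start[i] + delta
      } else {
        orient[j] <<- if (w == "forward") "flipped" else "forward"
        start[j] <<- start[i] + lens[i] - delta - lens[j]
      }
      segment[j] <<- segment[i]
    } else {
      q <- e$qry; r <- e$ref
      if ((orient[q] == "forward") == (w == "forward")) {
        orient[r] <<- "forward"
        start[r] <<- start[q] - delta
      } else {
        orient[r] <<- "flipped"
        start[r] <<- start[q] + delta + lens[q] - lens[r]
      }
      segment[r] <<- segment[q]
    }
  }

  while (any(!placed)) {
    if (!any(placed)) {
      root <- which(!placed)[1]
    } else {
      cand <- order(scores, decreasing = TRUE)
      grown <- FALSE
      for (k in cand) {
        e <- edges[[k]]
        if (used_edge[k]) next
        if (placed[e$ref] && !placed[e$qry]) {
          place_from_edge(e, TRUE); placed[e$qry] <- TRUE; used_edge[k] <- TRUE
          grown <- TRUE; break
        }
        if (placed[e$qry] && !placed[e$ref]) {
          place_from_edge(e, FALSE); placed[e$ref] <- TRUE; used_edge[k] <- TRUE
          grown <- TRUE; break
        }
      }
      if (grown) next
      root <- which(!placed)[1]   # no edge reaches the rest: new segment
    }
    seg <- seg + 1L
    segment[root] <- seg
    start[root] <- 0; orient[root] <- "forward"; placed[root] <- TRUE
  }

  # redundant-edge consistency check: a strong edge disagreeing with the
  # placement is a genuine contradiction
  for (k in seq_along(edges)) {
    if (used_edge[k]) next
    e <- edges[[k]]
    if (segment[e$ref] != segment[e$qry]) next
    pred <- predict_offset(start, orient, lens, e)
    if (abs(pred$delta) > offset_tol_bp && e$aln$score >= max(scores[used_edge], -Inf)) {
      nm_pipeline_error("contradictory overlaps among maps %s, %s (offset error %.0f bp)",
                        ids[e$ref], ids[e$qry], pred$delta)
    }
  }

  # lay segments out left to right in input order, recording breaks
  out_start <- rep(NA_real_, nmaps); cursor <- 0; breaks <- numeric(0)
  for (s in seq_len(seg)) {
    in_seg <- which(segment == s)
    shift <- cursor - min(start[in_seg])
    out_start[in_seg] <- start[in_seg] + shift
    cursor <- max(out_start[in_seg] + lens[in_seg])
    if (s < seg) { breaks <- c(breaks, cursor); cursor <- cursor + segment_gap_bp }
  }

  # pool peaks in global coordinates
  chans <- sort(unique(unlist(lapply(clone_maps, map_channels))))
  pooled <- lapply(chans, function(ch) {
    rows <- do.call(rbind, lapply(seq_len(nmaps), function(i) {
      m <- clone_maps[[i]]
      pk <- if (inherits(m, "consensus_map")) m$peaks[[as.character(ch)]] else NULL
      if (is.null(pk))
        pk <- data.frame(position = map_positions(m, ch), sd = 0, support = 1L)
      if (!nrow(pk)) return(NULL)
      pos <- if (orient[i] == "forward") out_start[i] + pk$position
             else out_start[i] + lens[i] - pk$position
      data.frame(position = pos, sd = pk$sd, support = pk$support)
    }))
    if (is.null(rows))
      return(data.frame(position = numeric(0), sd = numeric(0), support = integer(0)))
    rows <- rows[order(rows$position), , drop = FALSE]
    merge_peaks(rows, resolution_bp)
  })
  names(pooled) <- chans

  total_len <- max(out_start + lens)
  tiling <- data.frame(clone_id = ids, start = out_start,
                       end = out_start + lens, orientation = orient,
                       segment = segment)
  tiling <- tiling[order(tiling$start), ]
  rownames(tiling) <- NULL
  structure(list(
    consensus = consensus_map("genome_map", total_len, pooled,
                              n_molecules = max(vapply(clone_maps, function(m)
                                if (inherits(m, "consensus_map")) m$n_molecules else 1L,
                                integer(1)))),
    tiling = tiling, breaks = breaks,
    alignments = lapply(edges[used_edge], `[[`, "aln")),
    class = "genome_map")
}

predict_offset <- function(start, orient, lens, e) {
  # compare observed alignment offset with the offset implied by placements;
  # an orientation relation that cannot hold is an infinite discrepancy
  i <- e$ref; j <- e$qry
  w <- e$aln$orientation
  expected_oj <- if (orient[i] == "forward") {
    if (w == "forward") "forward" else "flipped"
  } else {
    if (w == "forward") "flipped" else "forward"
  }
  if (orient[j] != expected_oj) return(list(delta = Inf))
  pred <- if (orient[i] == "forward") start[j] - start[i]
          else start[i] + lens[i] - start[j] - lens[j]
  list(delta = e$aln$offset_bp - pred)
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map: %.1f bp, %d clones, %d segment(s), %d peaks>\n",
              x$consensus$length_bp, nrow(x$tiling), max(x$tiling$segment),
              n_labels(x$consensus)))
  invisible(x)
}
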