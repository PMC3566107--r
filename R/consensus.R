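# Consensus-map construction: pairwise molecule similarity, hierarchical
# clustering, and histogram/Gaussian peak fitting per cluster.

#' Pairwise molecule distance matrix
#'
#' Each molecule's channel-1 labels are rasterized into a Gaussian-smoothed
#' occupancy vector over fixed bins on a common length-normalized axis
#' (molecules are full-length clones, so no offset search is needed). The
#' distance between two molecules is the minimum over query orientations
#' (forward, flipped) of the Euclidean norm of the vector difference; the
#' minimizing orientation is recorded for every pair.
#'
#' Molecules with zero channel-1 labels cannot be compared: they are flagged
#' and given infinite distance to all others (excluded from clustering).
#'
#' @param molecules list of [molecule_map()] (>= 2).
#' @param bin_width_bp raster bin width in bp on the common axis (default 2000).
#' @param kernel_sd_bins Gaussian smoothing bandwidth in bins (default 1).
#' @return an object of class `pairwise_result`: `distance` (symmetric
#'   matrix), `orientation` (character matrix, orientation of column molecule
#'   relative to row molecule), `flagged` (logical vector).
#' @export
pairwise_distance <- function(molecules, bin_width_bp = 2000, kernel_sd_bins = 1) {
  nm_assert(is.list(molecules) && length(molecules) >= 2L, "need >= 2 molecules")
  nm_assert(is_scalar_number(bin_width_bp) && bin_width_bp > 0, "bin_width_bp must be > 0")
  ids <- vapply(molecules, `[[`, character(1), "molecule_id")
  lens <- vapply(molecules, `[[`, numeric(1), "length_bp")
  ref_len <- median(lens)
  nbins <- max(8L, as.integer(ceiling(ref_len / bin_width_bp)))
  centers <- (seq_len(nbins) - 0.5)

  V <- t(vapply(molecules, function(m) {
    p <- map_positions(m, 1L)
    if (!length(p)) return(rep(NA_real_, nbins))
    u <- p / m$length_bp * nbins          # label positions in bin units
    rowSums(vapply(u, function(x) stats::dnorm(centers, x, kernel_sd_bins),
                   numeric(nbins)))
  }, numeric(nbins)))
  flagged <- apply(V, 1L, function(r) anyNA(r))
  V[flagged, ] <- 0

  sq <- rowSums(V^2)
  Vr <- V[, rev(seq_len(nbins)), drop = FALSE]
  d2f <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(V), 0)
  d2r <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(V, Vr), 0)
  D <- sqrt(pmin(d2f, d2r))
  O <- matrix(ifelse(d2r < d2f, "flipped", "forward"), nrow(D), ncol(D))
  # a molecule is 'forward' relative to itself even if palindromic
  diag(O) <- "forward"
  if (any(flagged)) {
    D[flagged, ] <- Inf; D[, flagged] <- Inf
  }
  diag(D) <- 0
  dimnames(D) <- dimnames(O) <- list(ids, ids)
  structure(list(distance = D, orientation = O,
                 flagged = setNames(flagged, ids),
                 bin_width_bp = bin_width_bp, n_bins = nbins),
            class = "pairwise_result")
}

#' Cluster molecules by map similarity
#'
#' Agglomerative hierarchical clustering of the pairwise distance matrix,
#' with the tree cut at a fixed height. Orientations are propagated within
#' each cluster relative to the cluster's first molecule. Clusters smaller
#' than `min_support` are flagged unusable (too few molecules to build a
#' reliable consensus).
#'
#' @param pairwise a `pairwise_result` from [pairwise_distance()].
#' @param linkage one of "average", "complete", "single".
#' @param cut_height tree cut height. The default (NULL) selects the cut by
#'   silhouette: candidate cuts between the top merge heights are scored by
#'   mean silhouette width, the finest cut within 0.05 of the best is taken,
#'   and if no cut reaches a mean silhouette of 0.3 the pool is kept as one
#'   cluster. This behaves correctly both for mixed BAC pools (distinct
#'   clone patterns) and for single-clone pools (where any cut below the
#'   within-noise distance would shatter the pool).
#' @param min_support minimum usable cluster size (default 5).
#' @return an object of class `cluster_result`: `assignments` (named integer
#'   vector, NA for flagged molecules), `orientations` (named character),
#'   `usable` (logical per cluster), `cut_height`, `distance`.
#' @export
cluster_molecules <- function(pairwise, linkage = c("average", "complete", "single"),
                              cut_height = NULL, min_support = 5L) {
  nm_assert(inherits(pairwise, "pairwise_result"), "pairwise must come from pairwise_distance()")
  linkage <- match.arg(linkage)
  D <- pairwise$distance
  ids <- rownames(D)
  ok <- !pairwise$flagged
  if (!any(ok)) nm_pipeline_error("no usable molecules: all flagged (zero channel-1 labels)")

  Dok <- D[ok, ok, drop = FALSE]
  assignments <- setNames(rep(NA_integer_, length(ids)), ids)
  if (sum(ok) == 1L) {
    assignments[ok] <- 1L
    if (is.null(cut_height)) cut_height <- 0
  } else {
    hc <- hclust(as.dist(Dok), method = linkage)
    if (is.null(cut_height)) cut_height <- silhouette_cut(hc, Dok)
    assignments[ok] <- cutree(hc, h = cut_height)
  }
  orientations <- setNames(rep(NA_character_, length(ids)), ids)
  for (cl in unique(assignments[!is.na(assignments)])) {
    members <- ids[!is.na(assignments) & assignments == cl]
    first <- members[1]
    orientations[members] <- pairwise$orientation[first, members]
  }
  sizes <- table(assignments)
  usable <- setNames(as.integer(sizes) >= min_support, names(sizes))
  structure(list(assignments = assignments, orientations = orientations,
                 usable = usable, cut_height = cut_height,
                 min_support = as.integer(min_support), distance = D),
            class = "cluster_result")
}

# Mean silhouette width of a partition of the distance matrix.
mean_silhouette <- function(D, asg) {
  n <- length(asg)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- asg[i]
    mates <- asg == own & seq_len(n) != i
    if (!any(mates)) { s[i] <- 0; next }
    a <- mean(D[i, mates])
    b <- min(vapply(setdiff(unique(asg), own),
                    function(cl) mean(D[i, asg == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Default cut-height selection: score candidate cuts between the top merge
# heights by mean silhouette; prefer the finest cut within `tol` of the
# best; below `min_sil` keep a single cluster.
silhouette_cut <- function(hc, D, min_sil = 0.3, tol = 0.05, top = 8L) {
  hs <- sort(hc$height)
  n <- length(hs)
  if (n < 2L) return(max(hs) + 1e-9)
  lo <- max(1L, n - top)
  cands <- unique((hs[(lo + 1L):n] + hs[lo:(n - 1L)]) / 2)
  sils <- vapply(cands, function(ct) {
    asg <- cutree(hc, h = ct)
    if (length(unique(asg)) < 2L) return(-Inf)
    mean_silhouette(D, asg)
  }, numeric(1))
  best <- max(sils)
  if (!is.finite(best) || best < min_sil) return(max(hs) + 1e-9)
  # candidates are ordered coarse -> fine as height decreases
  ok <- which(sils >= best - tol)
  cands[ok[which.min(cands[ok])]]
}

#' Build a consensus map from an oriented molecule cluster
#'
#' Pools label positions across the cluster's molecules (flipped molecules
#' are mirrored into the common frame; channel 1 defines the frame and
#' channel 2 is overlaid in the same frame), histograms them, detects
#' candidate peaks as local maxima above a molecule-support threshold, fits
#' a Gaussian to each candidate's +/-3-bin neighborhood by least squares
#' (falling back to the moment estimate from the raw pooled positions when
#' the fit is degenerate, e.g. a noiseless spike), and merges fitted peaks
#' closer than the optical resolution by support-weighted averaging.
#' Consensus length is the median molecule length.
#'
#' @param molecules list of [molecule_map()] belonging to one cluster.
#' @param orientations character vector ("forward"/"flipped") per molecule;
#'   default all forward.
#' @param hist_bin_bp histogram bin width in bp (default 500).
#' @param resolution_bp minimum separation of same-channel peaks (default 1000).
#' @param support_frac fraction of molecules a candidate bin must reach
#'   (default 0.3).
#' @param label_sd_bp instrument label-sizing accuracy (bp); used by the
#'   doublet refinement to recognize overdispersed peaks.
#' @param doublet_refine attempt resolution-aware doublet deconvolution of
#'   overdispersed peaks (see Details); default TRUE.
#' @param map_id identifier for the consensus map.
#'
#' @details Two same-channel sites separated by little more than the optical
#' resolution produce a pooled label density that is *unimodal*: molecules
#' where both labels were detected contribute two side modes, but molecules
#' where the labels merged contribute a narrow midpoint component that fills
#' the valley. Such a doublet is still recognizable because its fitted
#' Gaussian is overdispersed relative to the instrument sizing accuracy.
#' Peaks with fitted sd beyond 1.2x `label_sd_bp` are therefore re-fit with
#' a three-component mixture derived from the imaging model — two sites at
#' `mu +/- s/2` (sd `label_sd_bp`) plus a midpoint component at `mu` (sd
#' `label_sd_bp/sqrt(2)`) whose weight is the merge probability implied by
#' `s` and `resolution_bp` — profiling the site separation `s` by maximum
#' likelihood. When the fitted separation reaches the optical resolution and
#' beats the single-site model decisively, the peak is split in two.
#' @return a [consensus_map()].
#' @export
build_consensus <- function(molecules, orientations = NULL, hist_bin_bp = 500,
                            resolution_bp = 1000, support_frac = 0.3,
                            label_sd_bp = 500, doublet_refine = TRUE,
                            map_id = "consensus") {
  nm_assert(is.list(molecules) && length(molecules) >= 1L, "empty cluster")
  n <- length(molecules)
  if (is.null(orientations)) orientations <- rep("forward", n)
  nm_assert(length(orientations) == n, "one orientation per molecule required")
  nm_assert(all(orientations %in% c("forward", "flipped")),
            "orientations must be 'forward' or 'flipped'")

  lens <- vapply(molecules, `[[`, numeric(1), "length_bp")
  L <- median(lens)
  chans <- sort(unique(unlist(lapply(molecules, function(m) names(m$labels)))))
  threshold <- support_frac * n

  peaks <- lapply(chans, function(ch) {
    # positions of every molecule mapped into the common (forward) frame,
    # rescaled to the consensus length: molecules are full-length clones, so
    # rescaling cancels the per-molecule stretch variation exactly
    per_mol <- lapply(seq_len(n), function(i) {
      p <- map_positions(molecules[[i]], ch)
      if (orientations[i] == "flipped") p <- rev(molecules[[i]]$length_bp - p)
      p * (L / molecules[[i]]$length_bp)
    })
    pooled <- unlist(per_mol)
    if (!length(pooled))
      return(data.frame(position = numeric(0), sd = numeric(0), support = integer(0)))
    df <- fit_channel_peaks(pooled, per_mol, L, hist_bin_bp, resolution_bp, threshold)
    if (doublet_refine && nrow(df))
      df <- refine_doublets(df, pooled, per_mol, resolution_bp, label_sd_bp)
    df
  })
  names(peaks) <- chans
  consensus_map(map_id, L, peaks, n_molecules = n)
}

# Histogram + candidate detection + Gaussian fitting for one channel.
fit_channel_peaks <- function(pooled, per_mol, L, bin, resolution, threshold) {
  hi <- max(L, max(pooled)) + bin
  breaks <- seq(0, hi + bin, by = bin)
  counts <- tabulate(findInterval(pooled, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  nb <- length(counts)
  pad <- c(0, counts, 0)
  # Candidate = local maximum of the histogram. Bin counts split a site's
  # labels across neighboring bins, so the decisive support test is taken on
  # the +/-3-bin window (fraction of molecules contributing a label there),
  # with a loose count floor to skip flat false-label noise.
  floor_ct <- max(1, threshold / 2)
  is_max <- counts >= floor_ct &
    counts >= pad[seq_len(nb)] &         # >= left neighbor
    counts > pad[seq_len(nb) + 2L]       # >  right neighbor (plateau -> leftmost)
  cand <- which(is_max)
  if (!length(cand))
    return(data.frame(position = numeric(0), sd = numeric(0), support = integer(0)))

  fits <- lapply(cand, function(b) {
    lo <- breaks[max(b - 3L, 1L)]
    hi2 <- breaks[min(b + 4L, nb + 1L)]
    in_win <- pooled >= lo & pooled < hi2
    raw <- pooled[in_win]
    support <- sum(vapply(per_mol, function(p) any(p >= lo & p < hi2), logical(1)))
    if (support < threshold) return(NULL)
    est <- gaussian_ls_fit(breaks, counts, b, nb)
    if (is.null(est)) est <- c(mean(raw), if (length(raw) > 1L) sd(raw) else 0)
    c(position = est[1], sd = est[2], support = support)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    return(data.frame(position = numeric(0), sd = numeric(0), support = integer(0)))
  df <- as.data.frame(do.call(rbind, fits))
  df <- df[order(df$position), , drop = FALSE]
  merge_peaks(df, resolution)
}

# Least-squares Gaussian fit to the +/-3-bin neighborhood of candidate bin b.
# Returns c(mu, sd) or NULL when the fit is degenerate or fails.
gaussian_ls_fit <- function(breaks, counts, b, nb) {
  idx <- max(b - 3L, 1L):min(b + 3L, nb)
  x <- (breaks[idx] + breaks[idx + 1L]) / 2
  y <- counts[idx]
  if (sum(y > 0) < 3L) return(NULL)
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(max(sum(y * (x - mu0)^2) / sum(y), 1))
  fit <- tryCatch(
    suppressWarnings(nls(y ~ a * exp(-(x - mu0q)^2 / (2 * s^2)),
                         start = list(a = max(y), mu0q = mu0, s = s0),
                         control = list(warnOnly = TRUE, maxiter = 50))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  mu <- unname(cf["mu0q"]); s <- abs(unname(cf["s"]))
  # reject fits that wandered out of the neighborhood
  if (!is.finite(mu) || mu < x[1] - diff(breaks[1:2]) || mu > x[length(x)] + diff(breaks[1:2]))
    return(NULL)
  c(mu, s)
}

# Resolution-aware doublet deconvolution. For each overdispersed peak, fit
# a three-component mixture implied by the imaging model (two sites s apart
# plus the merged-label midpoint component) by profiling s over a grid with
# maximum likelihood on the raw pooled positions; split the peak when the
# fitted separation reaches the optical resolution and clearly beats the
# single-site model.
refine_doublets <- function(df, pooled, per_mol, resolution, label_sd,
                            sd_trigger = 1.2, min_loglik_gain = 5,
                            label_efficiency = 0.85) {
  out <- list()
  for (k in seq_len(nrow(df))) {
    pk <- df[k, ]
    half_win <- 2500 + pk$sd
    isolated <- all(abs(df$position[-k] - pk$position) > half_win + resolution)
    if (!is.finite(pk$sd) || pk$sd < sd_trigger * label_sd || !isolated) {
      out[[length(out) + 1L]] <- pk
      next
    }
    fit <- doublet_mle(pk$position, half_win, per_mol, resolution, label_sd,
                       label_efficiency)
    if (!is.null(fit) && fit$s >= resolution && fit$gain >= min_loglik_gain) {
      lo <- fit$mu - fit$s / 2; hi <- fit$mu + fit$s / 2
      sup_l <- sum(vapply(per_mol, function(p) any(abs(p - lo) < resolution), logical(1)))
      sup_r <- sum(vapply(per_mol, function(p) any(abs(p - hi) < resolution), logical(1)))
      out[[length(out) + 1L]] <- data.frame(
        position = c(lo, hi), sd = rep(label_sd, 2),
        support = pmax(c(sup_l, sup_r), 1L))
    } else {
      out[[length(out) + 1L]] <- pk
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$position), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-molecule maximum-likelihood doublet fit around a candidate center.
# Molecule configurations inside the window: one label (either the merged
# midpoint, sd sigma/sqrt(2), or a lone survivor of label dropout) or two
# labels (midpoint Gaussian times the *truncated* separation density — the
# surviving pairs are exactly those whose apparent separation exceeded the
# optical resolution, which skews their separation outward and is why a
# naive mixture fit overestimates s). Profile s on a grid; compare against
# the single-site model with false labels uniform over the window.
doublet_mle <- function(center, half_win, per_mol, resolution, sigma, eff) {
  obs <- lapply(per_mol, function(p) p[abs(p - center) <= half_win])
  obs <- obs[lengths(obs) %in% c(1L, 2L)]
  if (length(obs) < 10L) return(NULL)
  mu <- mean(unlist(obs))
  sigma_m <- sigma / sqrt(2)
  sep_sd <- sigma * sqrt(2)
  rho <- 1 / (2 * half_win)                  # false-label density in window
  ones <- as.numeric(unlist(obs[lengths(obs) == 1L]))
  twos <- obs[lengths(obs) == 2L]
  mids <- vapply(twos, mean, numeric(1))
  seps <- vapply(twos, function(y) abs(diff(y)), numeric(1))

  ll_doublet <- function(s) {
    w_m <- stats::pnorm(resolution, s, sep_sd) - stats::pnorm(-resolution, s, sep_sd)
    l1 <- eff^2 * w_m * stats::dnorm(ones, mu, sigma_m) +
      eff * (1 - eff) * (stats::dnorm(ones, mu - s / 2, sigma) +
                           stats::dnorm(ones, mu + s / 2, sigma))
    # soft truncation edge: consensus-frame rescaling jitters apparent
    # separations slightly around the merge threshold
    l2 <- eff^2 * stats::dnorm(mids, mu, sigma_m) *
      stats::dnorm(seps, s, sep_sd) * stats::pnorm(seps, resolution, 100)
    sum(log(pmax(l1, 1e-300))) + sum(log(pmax(l2, 1e-300)))
  }
  ll_single <- {
    l1 <- eff * stats::dnorm(ones, mu, sigma)
    l2 <- vapply(twos, function(y) {
      d <- stats::dnorm(y, mu, sigma)
      eff * max(d) * rho                     # nearer label true, other false
    }, numeric(1))
    sum(log(pmax(l1, 1e-300))) + sum(log(pmax(l2, 1e-300)))
  }
  grid <- seq(0, 2 * half_win, by = 50)
  ll <- vapply(grid, ll_doublet, numeric(1))
  s_hat <- grid[which.max(ll)]
  list(mu = mu, s = s_hat, gain = max(ll) - ll_single)
}

# Merge same-channel peaks closer than `resolution` (support-weighted mean).
merge_peaks <- function(df, resolution) {
  if (nrow(df) <= 1L) return(df)
  repeat {
    gaps <- diff(df$position)
    if (!length(gaps) || min(gaps) >= resolution) break
    i <- which.min(gaps)
    w <- df$support[i:(i + 1L)]
    merged <- data.frame(
      position = sum(df$position[i:(i + 1L)] * w) / sum(w),
      sd = sqrt(sum(w * df$sd[i:(i + 1L)]^2) / sum(w)),
      support = max(w))
    df <- rbind(df[seq_len(i - 1L), , drop = FALSE], merged,
                df[-seq_len(i + 1L), , drop = FALSE])
  }
  rownames(df) <- NULL
  df
}

#' Cluster a molecule pool and build all usable consensus maps
#'
#' Convenience wrapper: [pairwise_distance()] then [cluster_molecules()] then
#' [build_consensus()] for every usable cluster.
#'
#' @inheritParams pairwise_distance
#' @inheritParams cluster_molecules
#' @inheritParams build_consensus
#' @param id_prefix prefix for consensus map ids.
#' @return list with `consensus` (list of [consensus_map()]) and `clusters`
#'   (the `cluster_result`).
#' @export
consensus_from_pool <- function(molecules, bin_width_bp = 2000,
                                linkage = "average", cut_height = NULL,
                                min_support = 5L, hist_bin_bp = 500,
                                resolution_bp = 1000, support_frac = 0.3,
                                id_prefix = "cluster") {
  pw <- pairwise_distance(molecules, bin_width_bp)
  cl <- cluster_molecules(pw, linkage, cut_height, min_support)
  ids <- vapply(molecules, `[[`, character(1), "molecule_id")
  usable_cl <- names(cl$usable)[cl$usable]
  cons <- lapply(usable_cl, function(k) {
    members <- which(!is.na(cl$assignments[ids]) & cl$assignments[ids] == as.integer(k))
    build_consensus(molecules[members], unname(cl$orientations[ids[members]]),
                    hist_bin_bp, resolution_bp, support_frac,
                    map_id = sprintf("%s%s", id_prefix, k))
  })
  names(cons) <- paste0(id_prefix, usable_cl)
  list(consensus = cons, clusters = cl)
}
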