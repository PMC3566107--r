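# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths: the motif oracle
# slides a character window, the distance oracle loops over bins, the
# alignment oracle enumerates every monotone matching recursively.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_chr <- function(x) chartr("ACGTN", "TGCAN",
                             paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Brute-force window-scan motif oracle: 0-based starts of motif occurrences
# on the forward strand plus occurrences of the reverse complement, by
# direct character comparison (no regex).
oracle_motif_sites <- function(seq, motif) {
  hits <- function(s, m) {
    sc <- strsplit(s, "")[[1]]
    mc <- strsplit(m, "")[[1]]
    n <- length(sc); k <- length(mc)
    if (n < k) return(integer(0))
    ok <- rep(TRUE, n - k + 1L)
    for (j in seq_len(k)) ok <- ok & sc[j:(n - k + j)] == mc[j]
    which(ok) - 1L
  }
  sort(unique(c(hits(seq, motif), hits(seq, rc_chr(motif)))))
}

# Plain-loop recomputation of the length-normalized smoothed-bin distance.
oracle_pair_distance <- function(m1, m2, bin_width, ref_len, kernel_sd = 1) {
  nbins <- max(8L, as.integer(ceiling(ref_len / bin_width)))
  centers <- seq_len(nbins) - 0.5
  vec <- function(m) {
    v <- numeric(nbins)
    for (p in m$labels[["1"]]) {
      u <- p / m$length_bp * nbins
      for (b in seq_len(nbins)) v[b] <- v[b] + dnorm(centers[b], u, kernel_sd)
    }
    v
  }
  v1 <- vec(m1); v2 <- vec(m2)
  min(sqrt(sum((v1 - v2)^2)), sqrt(sum((v1 - rev(v2))^2)))
}

# Exhaustive enumeration oracle for ordered two-color map alignment.
# Re-implements the scoring independently and enumerates every jointly
# monotone same-channel matching for both query orientations.
oracle_align_score <- function(query, ref, mode, p) {
  merged <- function(map, flip = FALSE) {
    pos <- c(); ch <- c()
    for (cc in names(map$labels)) {
      pos <- c(pos, map$labels[[cc]]); ch <- c(ch, rep(as.integer(cc), length(map$labels[[cc]])))
    }
    o <- order(pos, ch)
    pos <- pos[o]; ch <- ch[o]
    if (flip) { pos <- rev(map$length_bp - pos); ch <- rev(ch) }
    list(pos = pos, ch = ch)
  }
  score_matching <- function(R, Q, m) {
    # m: k x 2 matrix of merged indices (ref, qry), increasing in both
    k <- nrow(m)
    sc <- k * p$match_bonus
    if (k > 1L) for (t in 2:k) {
      rl <- R$pos[m[t, 1]] - R$pos[m[t - 1, 1]]
      ql <- Q$pos[m[t, 2]] - Q$pos[m[t - 1, 2]]
      pen <- min((rl - ql)^2 / (2 * (p$sigma2_per_bp * rl + p$sigma0_sq)),
                 p$outlier_penalty)
      sc <- sc - pen -
        p$miss_penalty * (m[t, 1] - m[t - 1, 1] - 1L) -
        p$false_penalty * (m[t, 2] - m[t - 1, 2] - 1L)
    }
    if (mode == "fit")   # query labels outside the matched range
      sc <- sc - p$false_penalty * ((m[1, 2] - 1L) + (length(Q$pos) - m[k, 2]))
    sc
  }
  best <- -Inf
  for (flip in c(FALSE, TRUE)) {
    R <- merged(ref); Q <- merged(query, flip)
    n <- length(R$pos); m <- length(Q$pos)
    if (n == 0L || m == 0L) next
    # recursive enumeration of matchings starting after (i0, j0)
    recur <- function(i0, j0, pairs) {
      if (nrow(pairs) > 0L) best <<- max(best, score_matching(R, Q, pairs))
      if (i0 >= n || j0 >= m) return()
      for (i in (i0 + 1L):n) for (j in (j0 + 1L):m) {
        if (R$ch[i] == Q$ch[j]) recur(i, j, rbind(pairs, c(i, j)))
      }
    }
    recur(0L, 0L, matrix(integer(0), ncol = 2))
  }
  best
}

# Small random two-color map for alignment oracle tests (<= 6 labels total;
# channel 1 always populated so any two maps share a channel).
rand_small_map <- function(id, max_per_channel = 3L) {
  len <- runif(1, 30000, 80000)
  labs <- list("1" = sort(runif(sample(1:max_per_channel, 1), 0, len - 1)))
  k2 <- sample(0:max_per_channel, 1)
  if (k2 > 0) labs[["2"]] <- sort(runif(k2, 0, len - 1))
  reference_map(id, len, labs)
}

# Noise-free simulation parameters.
quiet_params <- function(n = 10L, seed = 1L) {
  simulation_params(coverage_per_clone = n, label_efficiency = 1,
                    false_label_rate = 0, sizing_sd_bp = 0,
                    optical_resolution_bp = 0, stretch_sd = 0,
                    flip_probability = 0, seed = seed)
}
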