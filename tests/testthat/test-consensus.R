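make_pool <- function(refs, n_each, seed = 1, flip = 0.5) {
  mols <- list()
  for (k in seq_along(refs)) {
    p <- simulation_params(coverage_per_clone = n_each, flip_probability = flip,
                           seed = seed + k)
    mols <- c(mols, simulate_molecules(refs[[k]], p, id_prefix = refs[[k]]$map_id))
  }
  mols
}

test_that("pairwise distance: identity, mirror, and oracle agreement", {
  m1 <- molecule_map("a", 50000, list("1" = c(5000, 20000, 41000)))
  m2 <- molecule_map("b", 50000, list("1" = c(5000, 20000, 41000)))
  mirror <- molecule_map("c", 50000, list("1" = c(9000, 30000, 45000)))
  pw <- pairwise_distance(list(m1, m2, mirror))
  expect_equal(pw$distance["a", "b"], 0)
  expect_equal(pw$orientation["a", "b"], "forward")
  expect_equal(pw$distance["a", "c"], 0, tolerance = 1e-10)
  expect_equal(pw$orientation["a", "c"], "flipped")

  set.seed(31)
  mols <- lapply(1:6, function(i)
    molecule_map(paste0("m", i), 60000, list("1" = sort(runif(5, 0, 60000)))))
  pw2 <- pairwise_distance(mols, bin_width_bp = 2000)
  ref_len <- median(vapply(mols, `[[`, numeric(1), "length_bp"))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(pw2$distance[i, j],
                 oracle_pair_distance(mols[[i]], mols[[j]], 2000, ref_len),
                 tolerance = 1e-8)
  }
})

test_that("molecules without channel-1 labels are flagged, not fatal", {
  m1 <- molecule_map("a", 50000, list("1" = c(5000, 20000)))
  m2 <- molecule_map("b", 50000, list("1" = numeric(0), "2" = c(10000)))
  pw <- pairwise_distance(list(m1, m2))
  expect_true(pw$flagged["b"])
  expect_equal(pw$distance["a", "b"], Inf)
  expect_error(cluster_molecules(pairwise_distance(list(m2, m2))),
               "no usable molecules", class = "nanomapr_pipeline_error")
})

test_that("clustering separates blocks and recovers truth clones", {
  # block-diagonal distances -> exact clusters
  D <- matrix(10, 10, 10); D[1:5, 1:5] <- 0; D[6:10, 6:10] <- 0; diag(D) <- 0
  ids <- paste0("m", 1:10)
  dimnames(D) <- list(ids, ids)
  pw <- structure(list(distance = D,
                       orientation = matrix("forward", 10, 10, dimnames = list(ids, ids)),
                       flagged = setNames(rep(FALSE, 10), ids)),
                  class = "pairwise_result")
  cl <- cluster_molecules(pw, cut_height = 5)
  expect_equal(length(unique(cl$assignments)), 2L)
  expect_equal(length(unique(cl$assignments[1:5])), 1L)

  # all-zero matrix -> one cluster
  D0 <- matrix(0, 10, 10, dimnames = list(ids, ids))
  pw0 <- structure(list(distance = D0, orientation = pw$orientation,
                        flagged = pw$flagged), class = "pairwise_result")
  expect_equal(length(unique(cluster_molecules(pw0)$assignments)), 1L)

  # three simulated clones, mixed pool: truth recovery (Rand index)
  set.seed(12)
  refs <- lapply(1:3, function(k) find_nick_sites(rand_dna(120000),
                                                  map_id = paste0("clone", k)))
  mols <- make_pool(refs, 30, seed = 100)
  pw3 <- pairwise_distance(mols)
  cl3 <- cluster_molecules(pw3)
  truth <- vapply(mols, function(m) m$truth$source_id, character(1))
  got <- cl3$assignments[vapply(mols, `[[`, character(1), "molecule_id")]
  same_truth <- outer(truth, truth, "==")
  same_got <- outer(got, got, "==")
  rand_index <- mean(same_truth[upper.tri(same_truth)] == same_got[upper.tri(same_got)])
  expect_gte(rand_index, 0.95)
})

test_that("noiseless cluster gives exact peaks with full support", {
  ref <- reference_map("r", 40000, list("1" = c(4000, 15000, 30000),
                                        "2" = c(9000, 22000)))
  mols <- simulate_molecules(ref, quiet_params(8))
  cons <- build_consensus(mols, map_id = "c")
  expect_equal(cons$peaks[["1"]]$position, c(4000, 15000, 30000))
  expect_equal(cons$peaks[["2"]]$position, c(9000, 22000))
  expect_equal(cons$peaks[["1"]]$sd, rep(0, 3))
  expect_equal(cons$peaks[["1"]]$support, rep(8, 3))
  expect_equal(cons$length_bp, 40000)
})

test_that("default-noise cluster recovers every isolated site within 1 kb", {
  set.seed(6)
  ref <- find_nick_sites(rand_dna(150000), map_id = "r")
  p <- simulation_params(coverage_per_clone = 100, seed = 60)
  mols <- simulate_molecules(ref, p)
  pw <- pairwise_distance(mols)
  cl <- cluster_molecules(pw)
  ids <- vapply(mols, `[[`, character(1), "molecule_id")
  cons <- build_consensus(mols, unname(cl$orientations[ids]), map_id = "c")
  # the consensus frame orientation is arbitrary: evaluate the better frame
  frame_err <- function(pk, tr) mean(vapply(pk, function(x) min(abs(x - tr)), numeric(1)))
  for (ch in c("1", "2")) {
    tr <- ref$labels[[ch]]
    pk <- cons$peaks[[ch]]$position
    err <- min(frame_err(pk, tr), frame_err(cons$length_bp - pk, tr))
    expect_lt(err, 1000)
    # every isolated site (>= 2 kb from neighbors) has a peak within 1 kb
    use <- if (err == frame_err(pk, tr)) pk else cons$length_bp - pk
    iso <- tr[vapply(seq_along(tr), function(i)
      all(abs(tr[i] - tr[-i]) > 2000), logical(1))]
    for (site in iso)
      expect_lt(min(abs(use - site)), 1000)
  }
})

test_that("sites 1.5 kb apart resolve; 0.8 kb apart merge", {
  two_peak <- function(sep, seed) {
    ref <- reference_map("r", 60000, list("1" = c(20000, 20000 + sep, 40000)))
    p <- simulation_params(coverage_per_clone = 200, seed = seed,
                           flip_probability = 0)
    mols <- simulate_molecules(ref, p)
    cons <- build_consensus(mols, rep("forward", 200))
    pk <- cons$peaks[["1"]]$position
    sum(pk > 15000 & pk < 25000 + sep)
  }
  expect_equal(two_peak(1500, 41), 2)
  expect_equal(two_peak(800, 41), 1)
})

test_that("mirroring every molecule mirrors the consensus", {
  ref <- reference_map("r", 40000, list("1" = c(4000, 15000, 30000)))
  mols <- simulate_molecules(ref, quiet_params(6))
  cons <- build_consensus(mols, map_id = "c")
  flipped <- lapply(mols, function(m) {
    m$labels <- lapply(m$labels, function(p) rev(m$length_bp - p))
    m
  })
  cons_f <- build_consensus(flipped, map_id = "cf")
  expect_equal(sort(cons$length_bp - cons_f$peaks[["1"]]$position),
               cons$peaks[["1"]]$position)
  expect_equal(cons_f$peaks[["1"]]$support, rev(cons$peaks[["1"]]$support))
})

test_that("peak count is bounded by pooled labels over support threshold", {
  set.seed(8)
  for (rep in 1:5) {
    ref <- find_nick_sites(rand_dna(100000), map_id = "r")
    mols <- simulate_molecules(ref, simulation_params(coverage_per_clone = 30,
                                                      seed = rep, flip_probability = 0))
    cons <- build_consensus(mols, rep("forward", 30))
    pooled <- sum(vapply(mols, function(m) sum(lengths(m$labels)), numeric(1)))
    expect_lte(n_labels(cons), pooled / 5)
  }
})
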