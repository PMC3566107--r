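test_that("BNX round-trip preserves molecules to 0.1 bp", {
  set.seed(14)
  ref <- find_nick_sites(rand_dna(120000), map_id = "r")
  mols <- simulate_molecules(ref, simulation_params(coverage_per_clone = 100, seed = 2))
  path <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(mols, path)
  back <- read_bnx(path)
  expect_length(back, 100)
  for (k in seq_along(mols)) {
    expect_equal(back[[k]]$molecule_id, mols[[k]]$molecule_id)
    expect_equal(back[[k]]$length_bp, mols[[k]]$length_bp, tolerance = 0.1)
    for (ch in names(mols[[k]]$labels))
      expect_equal(back[[k]]$labels[[ch]], mols[[k]]$labels[[ch]],
                   tolerance = 0.11)
  }
})

test_that("an empty molecule list writes headers only and reads back empty", {
  path <- withr::local_tempfile(fileext = ".bnx")
  write_bnx(list(), path)
  expect_true(all(startsWith(readLines(path), "#")))
  expect_length(read_bnx(path), 0)
})

test_that("a hand-written BNX fixture parses to its literal values", {
  path <- withr::local_tempfile(fileext = ".bnx")
  writeLines(c("# nanomap-dialect=1",
               "0\tmolA\t50000.0",
               "1\t1\t1001.0\t25001.5",
               "1\t2\t40001.0",
               "0\tmolB\t30000.0",
               "1\t1\t15000.5"), path)
  mols <- read_bnx(path)
  expect_length(mols, 2)
  expect_equal(mols[[1]]$molecule_id, "molA")
  expect_equal(mols[[1]]$length_bp, 50000)
  expect_equal(mols[[1]]$labels[["1"]], c(1000, 25000.5))   # disk is 1-based
  expect_equal(mols[[1]]$labels[["2"]], 40000)
  expect_equal(mols[[2]]$labels[["1"]], 14999.5)
})

test_that("malformed BNX input errors with a line number", {
  path <- withr::local_tempfile(fileext = ".bnx")
  writeLines(c("0\tm1\t1000", "1\t1\t2000"), path)   # position beyond length
  expect_error(read_bnx(path), "line 2", class = "nanomapr_validation_error")
  writeLines(c("9\tm1\t1000"), path)
  expect_error(read_bnx(path), "line 1", class = "nanomapr_validation_error")
})

test_that("digesting a two-motif sequence writes 1-based CMAP positions", {
  m <- find_nick_sites("GCTCTTCAAAAACCTCAGC", map_id = "tiny")
  path <- withr::local_tempfile(fileext = ".cmap")
  write_cmap(m, path)
  rows <- read.table(path, sep = "\t", comment.char = "#")
  expect_equal(nrow(rows), 2)
  expect_equal(rows$V5, c(1, 2))        # channels
  expect_equal(rows$V6, c(1, 13))       # 0-based 0 and 12, +1 on disk
  back <- read_cmap(path)[[1]]
  expect_equal(back$labels[["1"]], 0)
  expect_equal(back$labels[["2"]], 12)
})

test_that("CMAP round-trips are stable for reference and consensus maps", {
  ref <- find_nick_sites(rand_dna(50000), map_id = "ref1")
  p1 <- withr::local_tempfile(fileext = ".cmap")
  write_cmap(ref, p1)
  back <- read_cmap(p1)[[1]]
  expect_s3_class(back, "reference_map")
  expect_equal(back$labels, lapply(ref$labels, as.numeric))

  cons <- consensus_map("c1", 60000,
                        list("1" = data.frame(position = c(1000.25, 30000.5),
                                              sd = c(120.5, 90), support = c(30, 28)),
                             "2" = data.frame(position = 15000.75, sd = 200.1,
                                              support = 25)),
                        n_molecules = 30)
  p2 <- withr::local_tempfile(fileext = ".cmap")
  p3 <- withr::local_tempfile(fileext = ".cmap")
  write_cmap(cons, p2)
  back2 <- read_cmap(p2)[[1]]
  expect_s3_class(back2, "consensus_map")
  write_cmap(back2, p3)
  expect_identical(readLines(p2), readLines(p3))   # bitwise-stable rewrite
})

test_that("duplicate SiteID in a CMAP is rejected", {
  path <- withr::local_tempfile(fileext = ".cmap")
  writeLines(c("# nanomap-dialect=1",
               "m1\t1000.0\t2\t1\t1\t100.0\t0.0\t0",
               "m1\t1000.0\t2\t1\t1\t200.0\t0.0\t0"), path)
  expect_error(read_cmap(path), "duplicate SiteID",
               class = "nanomapr_validation_error")
})

test_that("XMAP write/read preserves the alignment relation", {
  ref <- find_nick_sites(rand_dna(80000), map_id = "refm")
  aln <- align_maps(ref, ref, mode = "fit")
  path <- withr::local_tempfile(fileext = ".xmap")
  write_xmap(aln, path)
  line <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  expect_match(line, "\\+")                       # forward orientation
  back <- read_xmap(path)[[1]]
  expect_equal(back$query_id, "refm")
  expect_equal(back$orientation, "forward")
  expect_equal(nrow(back$matches), aln$n_match)
  expect_equal(back$matches$channel, aln$matches$channel)
  expect_equal(back$score, aln$score, tolerance = 0.01)
})

test_that("run configuration round-trips losslessly", {
  cfg <- run_config(seed = 42)
  cfg$simulation$label_efficiency <- 0.9
  cfg$alignment$min_score <- 20
  cfg$consensus$resolution_bp <- 1200
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$seed, 42L)
  expect_equal(back$simulation$label_efficiency, 0.9)
  expect_equal(back$alignment$min_score, 20)
  expect_equal(back$consensus$resolution_bp, 1200)
  expect_equal(vapply(back$channels, `[[`, character(1), "motif"),
               c("GCTCTTC", "CCTCAGC"))
})

test_that("FASTA and AGP writers produce readable output", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(s1 = "ACGTACGT", s2 = "GCTCTTC"), path)
  back <- read_fasta(path)
  expect_equal(unname(back), c("ACGTACGT", "GCTCTTC"))

  tiling <- data.frame(clone_id = c("a", "b"), start = c(0, 150),
                       end = c(100, 250), orientation = c("forward", "flipped"))
  agp <- withr::local_tempfile(fileext = ".agp")
  write_agp(tiling, "obj", agp)
  lines <- readLines(agp)
  expect_equal(lines[1], "##agp-version\t2.1")
  f <- strsplit(lines[-1], "\t")
  expect_equal(vapply(f, `[[`, character(1), 5), c("W", "N", "W"))
  expect_equal(f[[3]][9], "-")
})
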