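# End-to-end synthetic scenario: a region with planted tandem arrays, a
# tiling clone set, a deliberately corrupted assembly, and the full
# map-construction + validation + correction workflow.

#' Generate a random DNA sequence
#'
#' @param n length in bp.
#' @return an upper-case DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

motif_free_dna <- function(n, channels = default_channels()) {
  repeat {
    s <- random_dna(n)
    hits <- vapply(channels, function(ch)
      length(fixed_matches(s, ch$motif)) + length(fixed_matches(s, revcomp(ch$motif))),
      numeric(1))
    if (sum(hits) == 0) return(s)
  }
}

#' Build the synthetic demo region
#'
#' A random region sequence with two planted tandem arrays (direct repeats
#' of a unit carrying one channel-1 site; the second array inverted), plus a
#' corrupted draft assembly of the same region with four planted defects:
#' an extra (wrongly scaffolded) contig, an 85-kb deletion bridged by an
#' N-gap, a motif-free interval expansion, and a collapse of the first
#' tandem array to a single unit.
#'
#' @param seed integer seed.
#' @param region_bp region length (default 2.1 Mb).
#' @param unit_bp tandem repeat unit length (default 670).
#' @param copies1,copies2 copies in the two arrays (defaults 14 and 12).
#' @param extra_bp length of the planted extra contig (default 8000).
#' @param gap_bp length of the planted deletion (default 85000).
#' @param expansion_bp length of the planted interval expansion (default 3063).
#' @return list: `truth_seq`, `assembly_seq`, `unplaced_seqs` (the deleted
#'   segment, as the unplaced scaffold pool), `repeat_unit`, `events`
#'   (planted-truth table).
#' @export
demo_region <- function(seed = 1L, region_bp = 2.1e6, unit_bp = 670,
                        copies1 = 14L, copies2 = 12L, extra_bp = 8000,
                        gap_bp = 85000, expansion_bp = 3063) {
  set.seed(derive_seed(seed, 101L))
  channels <- default_channels()

  # repeat unit: one channel-1 site, otherwise motif-free
  unit <- paste0(motif_free_dna(100, channels), "GCTCTTC",
                 motif_free_dna(unit_bp - 107, channels))
  arr1 <- strrep(unit, copies1)
  arr2 <- strrep(revcomp(unit), copies2)

  pos_arr1 <- round(region_bp * 0.24)
  pos_arr2 <- round(region_bp * 0.24) + nchar(arr1) + 30000
  pos_expand <- round(region_bp * 0.40)
  pos_extra <- round(region_bp * 0.57)
  pos_gap <- round(region_bp * 0.71)

  backbone <- random_dna(region_bp - nchar(arr1) - nchar(arr2))
  truth <- paste0(substr(backbone, 1, pos_arr1), arr1,
                  substr(backbone, pos_arr1 + 1, pos_arr2 - nchar(arr1)),
                  arr2,
                  substr(backbone, pos_arr2 - nchar(arr1) + 1, nchar(backbone)))

  # corrupted assembly: apply edits right-to-left so earlier coordinates hold
  extra <- paste0(motif_free_dna(round(extra_bp / 2) - 14, channels),
                  "GCTCTTC", motif_free_dna(500, channels), "GCTCTTC",
                  motif_free_dna(extra_bp - round(extra_bp / 2) - 500, channels))
  asm <- truth
  deleted <- substr(asm, pos_gap + 1, pos_gap + gap_bp)
  asm <- paste0(substr(asm, 1, pos_gap), strrep("N", 100),
                substr(asm, pos_gap + gap_bp + 1, nchar(asm)))
  asm <- paste0(substr(asm, 1, pos_extra), extra,
                substr(asm, pos_extra + 1, nchar(asm)))
  asm <- paste0(substr(asm, 1, pos_expand), motif_free_dna(expansion_bp, channels),
                substr(asm, pos_expand + 1, nchar(asm)))
  # collapse array 1 to a single unit
  a1_start <- pos_arr1
  asm <- paste0(substr(asm, 1, a1_start), unit,
                substr(asm, a1_start + nchar(arr1) + 1, nchar(asm)))

  events <- data.frame(
    kind = c("HIGH_DENSITY_REGION", "INTERVAL_MISMATCH", "EXTRA_SEQUENCE",
             "MISSING_SEQUENCE"),
    truth_pos = c(pos_arr1, pos_expand, pos_extra, pos_gap),
    truth_size = c(nchar(arr1), expansion_bp, extra_bp, -gap_bp),
    stringsAsFactors = FALSE)

  list(truth_seq = truth, assembly_seq = asm,
       unplaced_seqs = c(gapfill_scaffold = deleted),
       repeat_unit = unit, unit_bp = unit_bp,
       copies = c(copies1, copies2), events = events)
}

#' Split a region into an overlapping clone tiling
#'
#' @param region_map [reference_map()] of the region.
#' @param n_clones number of clones (default 27).
#' @param mean_len_bp,sd_len_bp clone length distribution (default 150 kb
#'   +/- 15 kb, the typical BAC insert range).
#' @param seed integer seed.
#' @return list of [reference_map()] clone maps (labels restricted and
#'   shifted to the clone interval) plus a truth tiling data frame.
#' @export
clone_tiling <- function(region_map, n_clones = 27L, mean_len_bp = 150000,
                         sd_len_bp = 15000, seed = 1L) {
  set.seed(derive_seed(seed, 202L))
  L <- region_map$length_bp
  step <- (L - mean_len_bp) / max(n_clones - 1L, 1L)
  starts <- pmax(0, round((seq_len(n_clones) - 1L) * step))
  lens <- pmin(pmax(round(rnorm(n_clones, mean_len_bp, sd_len_bp)), 100000), 220000)
  ends <- pmin(starts + lens, L)
  starts <- pmax(0, pmin(starts, ends - 100000))
  clones <- lapply(seq_len(n_clones), function(k) {
    window_map(region_map, starts[k], ends[k])
  })
  for (k in seq_len(n_clones)) clones[[k]]$map_id <- sprintf("clone%02d", k)
  list(clones = clones,
       tiling = data.frame(clone_id = sprintf("clone%02d", seq_len(n_clones)),
                           start = starts, end = ends))
}

#' Run the full synthetic end-to-end scenario
#'
#' Generates the demo region, simulates per-clone molecule pools, builds a
#' consensus map per clone, merges them into a genome map, in-silico-digests
#' the corrupted assembly, detects high-density repeat regions, classifies
#' discrepancies, anchors the unplaced scaffold into the 85-kb gap, applies
#' the indicated corrections to the assembly sequence, and recomputes
#' completeness. Deterministic per seed.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing); NULL skips file
#'   output.
#' @param region_bp region length (default 2.1 Mb).
#' @param n_clones clones in the tiling (default 27).
#' @param coverage molecules per clone pool (default 60).
#' @param sim_params [simulation_params()] template; its seed is re-derived
#'   per clone.
#' @param aln_params [alignment_params()].
#' @param quiet suppress progress messages.
#' @return list: `genome_map`, `discrepancies`, `placements`,
#'   `completeness_before`, `completeness_after`, `repeats`, `events`
#'   (planted truth), `files`.
#' @export
end2end_demo <- function(seed = 1L, out_dir = NULL, region_bp = 2.1e6,
                         n_clones = 27L, coverage = 60L,
                         sim_params = simulation_params(),
                         aln_params = alignment_params(),
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- "setup"
  tryCatch({
    stage <- "region generation"
    say("[%s] seed=%d", stage, seed)
    region <- demo_region(seed, region_bp = region_bp)
    truth_map <- find_nick_sites(region$truth_seq, map_id = "truth_region")

    stage <- "clone tiling"
    tiles <- clone_tiling(truth_map, n_clones = n_clones, seed = seed)

    stage <- "molecule simulation"
    say("[%s] %d clones x %d molecules", stage, n_clones, coverage)
    pools <- lapply(seq_along(tiles$clones), function(k) {
      p <- sim_params
      p$coverage_per_clone <- as.integer(coverage)
      p$seed <- derive_seed(seed, 1000L + k)
      simulate_molecules(tiles$clones[[k]], p)
    })

    stage <- "consensus construction"
    per_clone <- lapply(seq_along(pools), function(k) {
      pw <- pairwise_distance(pools[[k]])
      cl <- cluster_molecules(pw, min_support = max(5L, coverage %/% 3L))
      ids <- vapply(pools[[k]], `[[`, character(1), "molecule_id")
      main <- names(which.max(table(cl$assignments)))
      members <- which(!is.na(cl$assignments[ids]) &
                         cl$assignments[ids] == as.integer(main))
      ori <- unname(cl$orientations[ids[members]])
      cons <- build_consensus(pools[[k]][members], ori,
                              map_id = tiles$clones[[k]]$map_id)
      list(consensus = cons, molecules = pools[[k]][members], orientations = ori)
    })

    stage <- "genome map merging"
    gm <- merge_consensus(lapply(per_clone, `[[`, "consensus"), aln_params)
    say("[%s] %d segment(s), %.2f Mb", stage, max(gm$tiling$segment),
        gm$consensus$length_bp / 1e6)

    stage <- "repeat detection"
    repeats <- detect_repeats_global(per_clone, gm, unit_bp = region$unit_bp)

    stage <- "assembly digestion"
    asm_map <- find_nick_sites(region$assembly_seq, map_id = "assembly")

    stage <- "assembly comparison"
    cmp <- compare_assembly(asm_map, gm$consensus, aln_params, repeats = repeats)

    stage <- "scaffold anchoring"
    gaps <- cmp$discrepancies[cmp$discrepancies$kind == "MISSING_SEQUENCE",
                              c("ref_start", "ref_end"), drop = FALSE]
    unplaced <- lapply(names(region$unplaced_seqs), function(id)
      find_nick_sites(region$unplaced_seqs[[id]], map_id = id))
    placements <- anchor_scaffolds(unplaced, gm$consensus, as.matrix(gaps), aln_params)

    stage <- "correction"
    corrected <- apply_demo_corrections(region, cmp$discrepancies, placements)
    cmp_after <- compare_assembly(find_nick_sites(corrected, map_id = "assembly_fixed"),
                                  gm$consensus, aln_params, repeats = repeats)
    say("[%s] completeness %.1f%% -> %.1f%%", stage,
        100 * cmp$completeness$fraction, 100 * cmp_after$completeness$fraction)

    files <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- c(
        genome_cmap = write_cmap(gm$consensus, file.path(out_dir, "genome.cmap")),
        assembly_cmap = write_cmap(asm_map, file.path(out_dir, "assembly.cmap")),
        discrepancies = write_discrepancies(cmp$discrepancies,
                                            file.path(out_dir, "discrepancies.tsv")),
        placements = {
          p <- file.path(out_dir, "placements.tsv")
          write.table(placements, p, sep = "\t", quote = FALSE, row.names = FALSE)
          p
        },
        agp = write_agp(gm$tiling, "genome_map", file.path(out_dir, "tiling.agp")),
        report = {
          p <- file.path(out_dir, "demo_report.json")
          jsonlite::write_json(list(
            seed = seed,
            completeness_before = cmp$completeness$fraction,
            completeness_after = cmp_after$completeness$fraction,
            n_discrepancies = nrow(cmp$discrepancies),
            kinds = sort(unique(cmp$discrepancies$kind))),
            p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
          p
        })
    }

    list(genome_map = gm, discrepancies = cmp$discrepancies,
         placements = placements,
         completeness_before = cmp$completeness,
         completeness_after = cmp_after$completeness,
         repeats = repeats, events = region$events, files = files)
  }, error = function(e) {
    nm_pipeline_error("end-to-end demo failed at stage '%s' (seed %d): %s",
                      stage, seed, conditionMessage(e))
  })
}

# Run detect_label_repeats per clone and lift regions to genome-map frame.
detect_repeats_global <- function(per_clone, gm, unit_bp = NULL, ...) {
  rows <- list()
  for (k in seq_along(per_clone)) {
    pc <- per_clone[[k]]
    tl <- gm$tiling[gm$tiling$clone_id == pc$consensus$map_id, ]
    if (!nrow(tl)) next
    d <- detect_label_repeats(pc$molecules, pc$consensus, pc$orientations,
                              unit_length_bp = unit_bp, ...)
    if (!nrow(d)) next
    # clone-consensus frame -> genome-map frame
    for (r in seq_len(nrow(d))) {
      if (tl$orientation == "forward") {
        s <- tl$start + d$ref_start[r]; e <- tl$start + d$ref_end[r]
      } else {
        s <- tl$end - d$ref_end[r]; e <- tl$end - d$ref_start[r]
      }
      d$ref_start[r] <- s; d$ref_end[r] <- e
    }
    rows[[length(rows) + 1L]] <- d
  }
  if (!length(rows)) return(empty_discrepancies())
  d <- do.call(rbind, rows)
  d <- d[order(d$ref_start), , drop = FALSE]
  # collapse duplicate calls of the same region from overlapping clones
  iv <- merge_intervals(cbind(d$ref_start, d$ref_end))
  out <- empty_discrepancies()
  for (k in seq_len(nrow(iv))) {
    hit <- d[d$ref_start < iv[k, 2] & d$ref_end > iv[k, 1], , drop = FALSE]
    best <- hit[which.max(hit$size_bp), , drop = FALSE]
    out <- rbind(out, best)
  }
  rownames(out) <- NULL
  out
}

# Sequence-level application of report-driven fixes for the demo scenario.
apply_demo_corrections <- function(region, discrepancies, placements) {
  asm <- region$assembly_seq
  # 1. excise surplus intervals (extra contigs, interval expansions),
  #    right-to-left so query coordinates stay valid
  surplus <- discrepancies[discrepancies$kind %in% c("EXTRA_SEQUENCE", "INTERVAL_MISMATCH") &
                             !is.na(discrepancies$query_start) &
                             discrepancies$size_bp > 0, , drop = FALSE]
  surplus <- surplus[order(surplus$query_start, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(surplus))) {
    mid <- (surplus$query_start[k] + surplus$query_end[k]) / 2
    cut <- round(c(mid - surplus$size_bp[k] / 2, mid + surplus$size_bp[k] / 2))
    asm <- paste0(substr(asm, 1, cut[1]), substr(asm, cut[2] + 1, nchar(asm)))
  }
  # 2. fill the N-gap with the anchored scaffold
  placed <- placements[placements$status == "placed", , drop = FALSE]
  if (nrow(placed)) {
    for (k in seq_len(nrow(placed))) {
      fill <- region$unplaced_seqs[[placed$scaffold_id[k]]]
      if (placed$orientation[k] == "flipped") fill <- revcomp(fill)
      nrun <- regexpr("N+", asm)
      if (nrun > 0)
        asm <- paste0(substr(asm, 1, nrun - 1), fill,
                      substr(asm, nrun + attr(nrun, "match.length"), nchar(asm)))
    }
  }
  # 3. re-expand the collapsed tandem array using the measured copy number
  hd <- discrepancies[discrepancies$kind == "HIGH_DENSITY_REGION", , drop = FALSE]
  if (nrow(hd)) {
    copies <- suppressWarnings(as.numeric(sub(".*copies=([0-9.]+).*", "\\1", hd$evidence)))
    copies <- max(copies[is.finite(copies)], 0)
    unit <- region$repeat_unit
    occ <- regexpr(unit, asm, fixed = TRUE)
    if (occ > 0 && copies >= 2) {
      asm <- paste0(substr(asm, 1, occ - 1), strrep(unit, round(copies)),
                    substr(asm, occ + nchar(unit), nchar(asm)))
    }
  }
  asm
}
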