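# Readers/writers for the on-disk text formats. One rule everywhere:
# in-memory coordinates are 0-based, on-disk positions are 1-based; +1 is
# applied on write and -1 on read, exactly once. All writers use stable
# ordering and fixed float formatting so files are diff-able across runs.

DIALECT_HEADER <- "# nanomap-dialect=1"

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences (first word of the
#'   header line is the name).
#' @export
read_fasta <- function(path) {
  nm_assert(file.exists(path), "no such file: %s", path)
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

## ---- BNX-style molecules -------------------------------------------------

#' Write molecules to a BNX-style file
#'
#' Dialect: '#' header lines; per molecule a '0' line
#' (`0 <TAB> molecule_id <TAB> length`) followed by one '1'-prefixed line per
#' channel (`1 <TAB> channel <TAB> positions...`). Positions are written
#' 1-based with 0.1-bp precision.
#'
#' @param molecules list of [molecule_map()].
#' @param path output path.
#' @param header extra named character vector echoed into the header.
#' @export
write_bnx <- function(molecules, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(DIALECT_HEADER, con)
  writeLines("# format=BNX", con)
  for (k in names(header)) writeLines(sprintf("# %s=%s", k, header[[k]]), con)
  for (m in molecules) {
    writeLines(paste("0", m$molecule_id, fmt_bp(m$length_bp), sep = "\t"), con)
    for (ch in names(m$labels)) {
      pos <- m$labels[[ch]] + 1           # 1-based on disk
      writeLines(paste(c("1", ch, fmt_bp(pos)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a BNX-style file
#'
#' @param path input path.
#' @return list of [molecule_map()].
#' @export
read_bnx <- function(path) {
  nm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  out <- list()
  cur_id <- NULL; cur_len <- NULL; cur_labels <- list()
  flush <- function() {
    if (!is.null(cur_id))
      out[[length(out) + 1L]] <<- molecule_map(cur_id, cur_len, cur_labels)
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "0") {
      flush()
      nm_assert(length(f) >= 3L, "malformed molecule line %d in %s", ln, path)
      cur_id <- f[2]; cur_len <- as.numeric(f[3]); cur_labels <- list()
      nm_assert(is.finite(cur_len) && cur_len > 0,
                "bad molecule length at line %d in %s", ln, path)
    } else if (f[1] == "1") {
      nm_assert(!is.null(cur_id), "label line %d before any molecule in %s", ln, path)
      nm_assert(length(f) >= 2L, "malformed label line %d in %s", ln, path)
      pos <- if (length(f) > 2L) as.numeric(f[-(1:2)]) - 1 else numeric(0)
      nm_assert(!anyNA(pos), "non-numeric position at line %d in %s", ln, path)
      nm_assert(!length(pos) || (min(pos) >= 0 && max(pos) <= cur_len),
                "position out of [0, length] at line %d in %s", ln, path)
      cur_labels[[f[2]]] <- pos
    } else {
      nm_validation_error("malformed line %d in %s: unknown record '%s'", ln, path, f[1])
    }
  }
  flush()
  out
}

#' Write per-label simulation ground truth
#'
#' @param molecules simulated molecules carrying `truth`.
#' @param path output TSV path (molecule_id, channel, position, provenance).
#' @export
write_truth <- function(molecules, path) {
  rows <- do.call(rbind, lapply(molecules, function(m) {
    if (is.null(m$truth)) return(NULL)
    do.call(rbind, lapply(names(m$labels), function(ch) {
      prov <- m$truth$provenance[[ch]]
      if (!length(m$labels[[ch]])) return(NULL)
      data.frame(molecule_id = m$molecule_id, channel = ch,
                 position = m$labels[[ch]] + 1,
                 provenance = ifelse(is.na(prov), "false", as.character(prov)),
                 orientation = m$truth$orientation,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- CMAP-style maps -----------------------------------------------------

#' Write maps to a CMAP-style file
#'
#' Tab-separated with columns CMapId, ContigLength, NumSites, SiteID,
#' LabelChannel, Position, StdDev, Coverage; one row per label site,
#' positions 1-based floating bp. Reference (in silico) maps carry StdDev
#' and Coverage 0.
#'
#' @param maps a map or list of [reference_map()]/[consensus_map()].
#' @param path output path.
#' @export
write_cmap <- function(maps, path) {
  if (inherits(maps, "reference_map") || inherits(maps, "consensus_map"))
    maps <- list(maps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(DIALECT_HEADER, con)
  writeLines("# format=CMAP", con)
  type <- if (inherits(maps[[1]], "consensus_map")) "consensus" else "reference"
  writeLines(sprintf("# MapType=%s", type), con)
  writeLines(paste("#h", "CMapId", "ContigLength", "NumSites", "SiteID",
                   "LabelChannel", "Position", "StdDev", "Coverage", sep = "\t"), con)
  for (m in maps) {
    rows <- cmap_rows(m)
    nm_assert(nrow(rows) > 0 || m$length_bp >= 0, "empty map %s", map_id_of(m))
    if (!nrow(rows)) next
    for (k in seq_len(nrow(rows))) {
      writeLines(paste(map_id_of(m), fmt_bp(m$length_bp), nrow(rows), k,
                       rows$channel[k], fmt_bp(rows$position[k] + 1),
                       fmt_bp(rows$sd[k]), rows$coverage[k], sep = "\t"), con)
    }
  }
  invisible(path)
}

cmap_rows <- function(m) {
  if (inherits(m, "consensus_map")) {
    rows <- do.call(rbind, lapply(names(m$peaks), function(ch) {
      pk <- m$peaks[[ch]]
      if (!nrow(pk)) return(NULL)
      data.frame(channel = as.integer(ch), position = pk$position,
                 sd = pk$sd, coverage = pk$support)
    }))
  } else {
    rows <- do.call(rbind, lapply(names(m$labels), function(ch) {
      p <- m$labels[[ch]]
      if (!length(p)) return(NULL)
      data.frame(channel = as.integer(ch), position = as.numeric(p),
                 sd = 0, coverage = 0L)
    }))
  }
  if (is.null(rows))
    return(data.frame(channel = integer(0), position = numeric(0),
                      sd = numeric(0), coverage = integer(0)))
  rows[order(rows$position, rows$channel), , drop = FALSE]
}

#' Read a CMAP-style file
#'
#' @param path input path.
#' @param as "auto" (use the MapType header), "reference" or "consensus".
#' @return named list of maps.
#' @export
read_cmap <- function(path, as = c("auto", "reference", "consensus")) {
  as <- match.arg(as)
  nm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (as == "auto") {
    mt <- grep("^# MapType=", hdr, value = TRUE)
    as <- if (length(mt) && grepl("consensus", mt[1])) "consensus" else "reference"
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) return(list())
  f <- strsplit(body, "\t", fixed = TRUE)
  nm_assert(all(lengths(f) == 8L), "malformed CMAP row in %s", path)
  df <- data.frame(
    map_id = vapply(f, `[[`, character(1), 1),
    length = as.numeric(vapply(f, `[[`, character(1), 2)),
    site_id = as.integer(vapply(f, `[[`, character(1), 4)),
    channel = vapply(f, `[[`, character(1), 5),
    position = as.numeric(vapply(f, `[[`, character(1), 6)) - 1,
    sd = as.numeric(vapply(f, `[[`, character(1), 7)),
    coverage = as.integer(vapply(f, `[[`, character(1), 8)),
    stringsAsFactors = FALSE)
  nm_assert(!anyNA(df$position), "non-numeric position in %s", path)
  out <- lapply(split(df, df$map_id), function(d) {
    nm_assert(!anyDuplicated(d$site_id), "duplicate SiteID in map %s of %s",
              d$map_id[1], path)
    d <- d[order(d$position, d$channel), ]
    nm_assert(all(diff(order(d$site_id)) != 0), "bad site ordering in %s", path)
    if (as == "consensus") {
      pk <- lapply(split(d, d$channel), function(x)
        data.frame(position = x$position, sd = x$sd,
                   support = pmax(x$coverage, 1L)))
      consensus_map(d$map_id[1], d$length[1], pk,
                    n_molecules = max(1L, max(d$coverage)))
    } else {
      labs <- lapply(split(d, d$channel), `[[`, "position")
      reference_map(d$map_id[1], d$length[1], labs)
    }
  })
  out[unique(df$map_id)]
}

## ---- XMAP-style alignments ----------------------------------------------

#' Write alignments to an XMAP-style file
#'
#' Columns: XmapEntryID, QryContigID, RefContigID, QryStartPos, QryEndPos,
#' RefStartPos, RefEndPos, Orientation (+/-), Confidence (raw score),
#' Alignment (match string of `(refSite,qrySite,channel)` triples, 1-based
#' per-channel site indices).
#'
#' @param alignments a `map_alignment` or list of them.
#' @param path output path.
#' @export
write_xmap <- function(alignments, path) {
  if (inherits(alignments, "map_alignment")) alignments <- list(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(DIALECT_HEADER, con)
  writeLines("# format=XMAP", con)
  writeLines(paste("#h", "XmapEntryID", "QryContigID", "RefContigID",
                   "QryStartPos", "QryEndPos", "RefStartPos", "RefEndPos",
                   "Orientation", "Confidence", "Alignment", sep = "\t"), con)
  k <- 0L
  for (a in alignments) {
    k <- k + 1L
    if (a$n_match == 0L) {
      writeLines(paste(k, a$query_id, a$ref_id, 0, 0, 0, 0, "+",
                       formatC(a$score, format = "f", digits = 2), ".",
                       sep = "\t"), con)
      next
    }
    m <- a$matches
    cig <- paste0(sprintf("(%d,%d,%d)", m$ref_index, m$query_index, m$channel),
                  collapse = "")
    writeLines(paste(
      k, a$query_id, a$ref_id,
      fmt_bp(min(m$query_pos) + 1), fmt_bp(max(m$query_pos) + 1),
      fmt_bp(a$aligned_ref_span[1] + 1), fmt_bp(a$aligned_ref_span[2] + 1),
      if (a$orientation == "forward") "+" else "-",
      formatC(a$score, format = "f", digits = 2), cig, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an XMAP-style file
#'
#' Returns alignment skeletons (ids, orientation, score, matched site index
#' triples); full positional detail requires re-aligning the maps.
#'
#' @param path input path.
#' @return list of alignment records.
#' @export
read_xmap <- function(path) {
  nm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    nm_assert(length(f) == 10L, "malformed XMAP row in %s", path)
    matches <- if (f[10] == ".") {
      data.frame(ref_index = integer(0), query_index = integer(0), channel = integer(0))
    } else {
      trip <- regmatches(f[10], gregexpr("\\(([0-9]+),([0-9]+),([0-9]+)\\)", f[10]))[[1]]
      parts <- do.call(rbind, strsplit(gsub("[()]", "", trip), ","))
      data.frame(ref_index = as.integer(parts[, 1]),
                 query_index = as.integer(parts[, 2]),
                 channel = as.integer(parts[, 3]))
    }
    list(query_id = f[2], ref_id = f[3],
         query_span = as.numeric(f[4:5]) - 1, ref_span = as.numeric(f[6:7]) - 1,
         orientation = if (f[8] == "+") "forward" else "flipped",
         score = as.numeric(f[9]), matches = matches)
  })
}

## ---- run configuration ---------------------------------------------------

#' Default run configuration
#'
#' Flat list of every tunable parameter: channels, simulation, consensus,
#' alignment and assembly-check settings plus the master seed. Round-trips
#' losslessly through [write_config()]/[read_config()].
#'
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    channels = default_channels(),
    simulation = simulation_params(seed = seed),
    consensus = list(bin_width_bp = 2000, hist_bin_bp = 500,
                     resolution_bp = 1000, cut_height = NA_real_,
                     min_support = 5L, support_frac = 0.3),
    alignment = alignment_params(),
    asmcheck = list(tol_bp = NA_real_, density_threshold = 1.5,
                    window_bp = 3000),
    seed = as.integer(seed)), class = "run_config")
}

#' Write a run configuration file
#'
#' One `key = value` pair per line, grouped by dotted prefixes.
#'
#' @param config a [run_config()].
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- c(DIALECT_HEADER, "# format=config")
  for (ch in config$channels)
    lines <- c(lines, sprintf("channel.%d.motif = %s", ch$channel_id, ch$motif),
               sprintf("channel.%d.name = %s", ch$channel_id, ch$display_name))
  flat <- function(prefix, x) {
    unlist(lapply(names(x), function(k) {
      v <- x[[k]]
      if (is.numeric(v) || is.character(v) || is.logical(v))
        sprintf("%s.%s = %s", prefix, k, format(v, digits = 12))
      else character(0)
    }))
  }
  lines <- c(lines, flat("simulation", unclass(config$simulation)),
             flat("consensus", config$consensus),
             flat("alignment", unclass(config$alignment)),
             flat("asmcheck", config$asmcheck),
             sprintf("seed = %d", config$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  nm_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  get_num <- function(key, default) {
    i <- match(key, keys)
    if (is.na(i)) return(default)
    if (vals[i] == "NA") return(NA_real_)
    as.numeric(vals[i])
  }
  cfg <- run_config(seed = as.integer(get_num("seed", 1)))
  ch_keys <- grep("^channel\\.[0-9]+\\.motif$", keys)
  if (length(ch_keys)) {
    cfg$channels <- lapply(ch_keys, function(i) {
      id <- as.integer(sub("^channel\\.([0-9]+)\\..*$", "\\1", keys[i]))
      nk <- match(sprintf("channel.%d.name", id), keys)
      channel_spec(id, vals[i], if (is.na(nk)) paste0("channel", id) else vals[nk])
    })
  }
  for (k in names(unclass(cfg$simulation)))
    cfg$simulation[[k]] <- get_num(paste0("simulation.", k), cfg$simulation[[k]])
  cfg$simulation$coverage_per_clone <- as.integer(cfg$simulation$coverage_per_clone)
  cfg$simulation$seed <- as.integer(cfg$simulation$seed)
  validate_simulation_params(cfg$simulation)
  for (k in names(cfg$consensus))
    cfg$consensus[[k]] <- get_num(paste0("consensus.", k), cfg$consensus[[k]])
  for (k in names(unclass(cfg$alignment)))
    cfg$alignment[[k]] <- get_num(paste0("alignment.", k), cfg$alignment[[k]])
  cfg$alignment$min_labels <- as.integer(cfg$alignment$min_labels)
  for (k in names(cfg$asmcheck))
    cfg$asmcheck[[k]] <- get_num(paste0("asmcheck.", k), cfg$asmcheck[[k]])
  cfg
}

## ---- reports -------------------------------------------------------------

#' Write a discrepancy report
#'
#' @param discrepancies discrepancy data frame from [compare_assembly()].
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @export
write_discrepancies <- function(discrepancies, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(discrepancies, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    write.table(discrepancies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write an AGP v2.1 layout
#'
#' Serializes a tiling/placement table as AGP v2.1 components (W lines) with
#' N-gap lines between non-adjacent components.
#'
#' @param tiling data frame with clone_id/start/end/orientation columns
#'   (0-based coordinates).
#' @param object_id AGP object name.
#' @param path output path.
#' @export
write_agp <- function(tiling, object_id, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  part <- 0L; cursor <- 0
  tiling <- tiling[order(tiling$start), , drop = FALSE]
  for (k in seq_len(nrow(tiling))) {
    gap <- tiling$start[k] - cursor
    if (gap > 0) {
      part <- part + 1L
      writeLines(paste(object_id, round(cursor) + 1, round(tiling$start[k]),
                       part, "N", round(gap), "scaffold", "yes", "map", sep = "\t"), con)
    }
    part <- part + 1L
    comp_len <- tiling$end[k] - tiling$start[k]
    writeLines(paste(object_id, round(tiling$start[k]) + 1, round(tiling$end[k]),
                     part, "W", tiling$clone_id[k], 1, round(comp_len),
                     if (identical(tiling$orientation[k], "flipped")) "-" else "+",
                     sep = "\t"), con)
    cursor <- max(cursor, tiling$end[k])
  }
  invisible(path)
}
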