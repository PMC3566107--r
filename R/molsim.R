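# Single-molecule simulator: synthetic nanochannel label data with ground
# truth, used as the package's test-data factory.

#' Simulation parameter set
#'
#' All coordinates are emitted in calibrated bp: the physical stretch to
#' ~85% of B-DNA contour length cancels out of calibrated coordinates, so
#' `stretch_mean` only enters the nm-scale report (see [report_stretch()]).
#' Only per-molecule stretch *variation* (`stretch_sd`) appears as
#' multiplicative length noise.
#'
#' @param coverage_per_clone molecules simulated per clone (positive integer).
#' @param label_efficiency probability in (0, 1] that a true site yields a
#'   label, per site and channel.
#' @param false_label_rate expected false labels per 100 kb per channel (>= 0).
#' @param sizing_sd_bp Gaussian label-position noise scale in bp (>= 0).
#' @param optical_resolution_bp minimum same-channel separation below which
#'   labels merge into one spot (>= 0).
#' @param stretch_mean nominal fraction of B-DNA contour length reached in
#'   the nanochannel (default 0.85).
#' @param stretch_sd per-molecule scale variation (>= 0).
#' @param flip_probability probability a molecule is imaged in reverse
#'   orientation.
#' @param seed integer seed; fully determines the simulator output.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(coverage_per_clone = 100L,
                              label_efficiency = 0.85,
                              false_label_rate = 1.0,
                              sizing_sd_bp = 500,
                              optical_resolution_bp = 1000,
                              stretch_mean = 0.85,
                              stretch_sd = 0.02,
                              flip_probability = 0.5,
                              seed = 1L) {
  p <- list(coverage_per_clone = as.integer(coverage_per_clone),
            label_efficiency = label_efficiency,
            false_label_rate = false_label_rate,
            sizing_sd_bp = sizing_sd_bp,
            optical_resolution_bp = optical_resolution_bp,
            stretch_mean = stretch_mean,
            stretch_sd = stretch_sd,
            flip_probability = flip_probability,
            seed = as.integer(seed))
  validate_simulation_params(p)
  structure(p, class = "simulation_params")
}

validate_simulation_params <- function(p) {
  nm_assert(p$coverage_per_clone >= 1L, "coverage_per_clone must be >= 1")
  nm_assert(is_scalar_number(p$label_efficiency) &&
              p$label_efficiency > 0 && p$label_efficiency <= 1,
            "label_efficiency must be in (0, 1]")
  nm_assert(is_scalar_number(p$false_label_rate) && p$false_label_rate >= 0,
            "false_label_rate must be >= 0")
  nm_assert(is_scalar_number(p$sizing_sd_bp) && p$sizing_sd_bp >= 0,
            "sizing_sd_bp must be >= 0")
  nm_assert(is_scalar_number(p$optical_resolution_bp) && p$optical_resolution_bp >= 0,
            "optical_resolution_bp must be >= 0")
  nm_assert(is_scalar_number(p$stretch_mean) && p$stretch_mean > 0 && p$stretch_mean <= 1,
            "stretch_mean must be in (0, 1]")
  nm_assert(is_scalar_number(p$stretch_sd) && p$stretch_sd >= 0, "stretch_sd must be >= 0")
  nm_assert(is_scalar_number(p$flip_probability) &&
              p$flip_probability >= 0 && p$flip_probability <= 1,
            "flip_probability must be in [0, 1]")
  nm_assert(is_scalar_number(p$seed), "seed must be a number")
  invisible(p)
}

#' Simulate single-molecule maps from a reference map
#'
#' Generates `coverage_per_clone` full-length molecules from the source map
#' (Cre-linearized full BAC clones), applying the noise model in a fixed
#' order: label dropout, false labels, Gaussian positional noise, per-molecule
#' scale factor, optical-resolution merging, and orientation flip. Ground
#' truth (source interval, orientation, per-label provenance) is attached to
#' every molecule. The output is fully determined by `params$seed`.
#'
#' @param source a [reference_map()], length >= 1 kb.
#' @param params a [simulation_params()] object.
#' @param id_prefix prefix for molecule ids.
#' @return list of [molecule_map()] with `truth` populated.
#' @export
simulate_molecules <- function(source, params, id_prefix = source$map_id) {
  nm_assert(inherits(source, "reference_map"), "source must be a reference_map")
  nm_assert(inherits(params, "simulation_params"), "params must be simulation_params")
  validate_simulation_params(params)
  nm_assert(source$length_bp >= 1000, "source must be at least 1 kb long")

  chans <- names(source$labels)
  L <- source$length_bp
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)

  lapply(seq_len(params$coverage_per_clone), function(i) {
    scale <- if (params$stretch_sd > 0) max(rnorm(1, 1, params$stretch_sd), 0.5) else 1
    flip <- runif(1) < params$flip_probability
    mol_len <- L * scale

    labs <- list(); prov <- list()
    for (ch in chans) {
      true_pos <- as.numeric(source$labels[[ch]])
      keep <- if (length(true_pos)) runif(length(true_pos)) < params$label_efficiency else logical(0)
      pos <- true_pos[keep]
      src_idx <- which(keep)
      n_fp <- rpois(1, params$false_label_rate * L / 1e5)
      fp <- if (n_fp > 0) runif(n_fp, 0, L) else numeric(0)
      pos <- c(pos, fp)
      origin <- c(src_idx, rep(NA_integer_, n_fp))   # NA provenance = false label
      if (params$sizing_sd_bp > 0 && length(pos))
        pos <- pos + rnorm(length(pos), 0, params$sizing_sd_bp)
      pos <- pos * scale
      pos <- pmin(pmax(pos, 0), mol_len)
      o <- order(pos)
      pos <- pos[o]; origin <- origin[o]
      m <- merge_close_labels(pos, params$optical_resolution_bp, origin)
      pos <- m$position; origin <- m$provenance
      if (flip) {
        pos <- rev(mol_len - pos)
        origin <- rev(origin)
      }
      # enforce strict increase after merging (numerical ties)
      if (length(pos) > 1L) {
        ok <- c(TRUE, diff(pos) > 0)
        pos <- pos[ok]; origin <- origin[ok]
      }
      labs[[ch]] <- pos
      prov[[ch]] <- origin
    }
    molecule_map(sprintf("%s_mol%04d", id_prefix, i), mol_len, labs,
                 truth = list(source_id = source$map_id,
                              interval = c(0, L),
                              orientation = if (flip) "flipped" else "forward",
                              scale = scale,
                              provenance = prov))
  })
}

# Greedy left-to-right merging of same-channel labels closer than `res`;
# each merged group is emitted at the arithmetic mean of its members. A new
# group opens when a label lies >= res from the current group's *first*
# label: an isolated close pair merges to its midpoint, while a long dense
# run (a labeled tandem array) collapses to spots spaced about one
# resolution apart rather than to a single label — matching how an extended
# run of emitters is imaged. Provenance of a merged group: first
# contributing true-site index, or NA for a pure false-label group.
merge_close_labels <- function(pos, res, provenance = rep(NA_integer_, length(pos))) {
  if (length(pos) <= 1L || res <= 0)
    return(list(position = pos, provenance = provenance))
  grp <- integer(length(pos))
  g <- 1L; anchor <- pos[1]
  grp[1] <- 1L
  for (k in 2:length(pos)) {
    if (pos[k] - anchor >= res) { g <- g + 1L; anchor <- pos[k] }
    grp[k] <- g
  }
  merged <- as.numeric(tapply(pos, grp, mean))
  prov <- as.integer(tapply(provenance, grp, function(v) {
    tv <- v[!is.na(v)]
    if (length(tv)) tv[1] else NA_integer_
  }))
  list(position = merged, provenance = prov)
}

#' Apparent molecule length in nanometers
#'
#' Converts a calibrated molecule length to its apparent physical length in
#' the nanochannel: `length_bp * 0.34 nm/bp * stretch_mean`, with 0.34 nm/bp
#' the B-DNA helical rise and `stretch_mean` the fraction of the B-DNA
#' contour length the confined molecule reaches (85% in 45-nm channels).
#'
#' @param params a [simulation_params()] (uses `stretch_mean`).
#' @param molecule_length_bp molecule length in bp (> 0).
#' @return apparent length in nm.
#' @examples
#' report_stretch(simulation_params(), 1e5)  # 28900 nm
#' @export
report_stretch <- function(params, molecule_length_bp) {
  nm_assert(inherits(params, "simulation_params"), "params must be simulation_params")
  nm_assert(is_scalar_number(molecule_length_bp) && molecule_length_bp > 0,
            "molecule_length_bp must be > 0")
  molecule_length_bp * 0.34 * params$stretch_mean
}
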