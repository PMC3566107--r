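# Label channels: a nicking motif bound to a dye color.

#' Define a label channel
#'
#' A channel binds a nicking-endonuclease recognition motif to a label color
#' channel number. Channel 1 is conventionally the green (Nt.BspQI, GCTCTTC)
#' channel and channel 2 the red (Nt.BbvCI, CCTCAGC) channel.
#'
#' @param channel_id small positive integer identifying the color channel.
#' @param motif recognition motif, a DNA string over A/C/G/T, length >= 4.
#' @param display_name human-readable enzyme/dye name.
#' @return an object of class `channel_spec`.
#' @examples
#' channel_spec(1, "GCTCTTC", "Nt.BspQI")
#' @export
channel_spec <- function(channel_id, motif, display_name = paste0("channel", channel_id)) {
  nm_assert(is_scalar_number(channel_id) && channel_id >= 1 && channel_id == round(channel_id),
            "channel_id must be a positive integer, got %s", format(channel_id))
  nm_assert(is.character(motif) && length(motif) == 1L, "motif must be a single string")
  motif <- toupper(motif)
  nm_assert(nchar(motif) >= 4L, "motif '%s' shorter than 4 bp", motif)
  nm_assert(grepl("^[ACGT]+$", motif), "motif '%s' contains non-ACGT characters", motif)
  structure(list(channel_id = as.integer(channel_id), motif = motif,
                 display_name = as.character(display_name)),
            class = "channel_spec")
}

#' Default two-color channel set
#'
#' The standard two-enzyme setup: Nt.BspQI (GCTCTTC, green, channel 1) and
#' Nt.BbvCI (CCTCAGC, red, channel 2).
#'
#' @return a list of two `channel_spec` objects.
#' @export
default_channels <- function() {
  list(channel_spec(1L, "GCTCTTC", "Nt.BspQI"),
       channel_spec(2L, "CCTCAGC", "Nt.BbvCI"))
}

validate_channels <- function(channels) {
  nm_assert(is.list(channels) && length(channels) >= 1L, "need at least one channel")
  for (ch in channels)
    nm_assert(inherits(ch, "channel_spec"), "channels must be channel_spec objects")
  ids <- vapply(channels, `[[`, integer(1), "channel_id")
  nm_assert(!anyDuplicated(ids), "channel ids must be unique, got %s",
            paste(ids, collapse = ","))
  channels
}

channel_ids <- function(channels) {
  vapply(channels, `[[`, integer(1), "channel_id")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel %d: %s (%s)>\n", x$channel_id, x$motif, x$display_name))
  invisible(x)
}
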