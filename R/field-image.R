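#' Multi-channel imaging field container
#'
#' A light S3 container for one imaged field: a named list of 2-D intensity
#' matrices (all the same shape, finite, non-negative) plus well/field
#' identity and optional pixel-size metadata.
#'
#' @param channels named list of numeric matrices (e.g. `nucleus`, `fa`,
#'   `actin`, `cytoplasm`, `membrane`).
#' @param well_id,field_id identifiers.
#' @param pixel_size_um optional pixel size in micrometres.
#' @return object of class `field_image`.
#' @export
field_image <- function(channels, well_id = "", field_id = "",
                        pixel_size_um = NA_real_) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a named list of matrices")
  shapes <- vapply(channels, function(ch) {
    assert_image(ch)
    if (any(ch < 0)) stop("channel intensities must be >= 0")
    dim(ch)
  }, integer(2))
  if (ncol(shapes) > 1 && any(shapes != shapes[, 1]))
    stop("all channels must share an identical shape")
  structure(list(channels = channels, well_id = well_id, field_id = field_id,
                 pixel_size_um = pixel_size_um),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  sh <- dim(x$channels[[1]])
  cat(sprintf("<field_image %s/%s: %d x %d, channels: %s>\n",
              x$well_id, x$field_id, sh[1], sh[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(field, name) {
  if (!inherits(field, "field_image")) stop("not a field_image")
  if (!name %in% names(field$channels))
    stop(sprintf("missing channel '%s' in field %s/%s", name,
                 field$well_id, field$field_id), call. = FALSE)
  field$channels[[name]]
}

#' Time-lapse movie container
#'
#' @param frames list of numeric matrices of constant shape (>= 2 frames).
#' @param frame_interval acquisition interval in minutes (default 2).
#' @return object of class `fa_movie`.
#' @export
fa_movie <- function(frames, frame_interval = 2) {
  if (!is.list(frames) || length(frames) < 2)
    stop("a movie needs at least 2 frames")
  d1 <- dim(frames[[1]])
  for (f in frames) {
    assert_image(f)
    if (!identical(dim(f), d1)) stop("frames must have constant shape")
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "fa_movie")
}

#' @export
print.fa_movie <- function(x, ...) {
  sh <- dim(x$frames[[1]])
  cat(sprintf("<fa_movie: %d frames of %d x %d, every %g min (%g min total)>\n",
              length(x$frames), sh[1], sh[2], x$frame_interval,
              x$frame_interval * (length(x$frames) - 1)))
  invisible(x)
}
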