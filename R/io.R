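# File I/O: minimal baseline TIFF (grayscale, uncompressed, little-endian,
# 8/16-bit, single- or multi-page), CSV tables with a schema-version
# stamp, and flat key=value config files.  No TIFF package exists in this
# R stack, so the subset of baseline TIFF needed for grayscale microscopy
# stacks is implemented here directly.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write a grayscale TIFF
#'
#' Writes one matrix (or a list of same-shaped matrices as a multi-page
#' stack) as uncompressed little-endian grayscale TIFF.  Values are
#' rounded and clipped to the unsigned range of `bits`.
#'
#' @param img numeric matrix or list of matrices.
#' @param path output file.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  pages <- if (is.matrix(img)) list(img) else img
  stopifnot(length(pages) >= 1, bits %in% c(8L, 16L))
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL); w2(42L)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  offset <- 8L
  maxval <- 2^bits - 1
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    stopifnot(is.matrix(m))
    nr <- nrow(m); nc <- ncol(m)
    nbytes <- nr * nc * (bits / 8L)
    ifd_off <- offset
    data_off <- ifd_off + ifd_size
    w4(ifd_off)                     # pointer to this IFD (header or prev)
    seek(con, ifd_off)
    w2(n_entries)
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count); w4(value)
    }
    entry(TIFF_TAGS["width"], 4L, 1L, nc)
    entry(TIFF_TAGS["length"], 4L, 1L, nr)
    entry(TIFF_TAGS["bits"], 3L, 1L, bits)
    entry(TIFF_TAGS["compression"], 3L, 1L, 1L)
    entry(TIFF_TAGS["photometric"], 3L, 1L, 1L)
    entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
    entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, nr)
    entry(TIFF_TAGS["strip_byte_counts"], 4L, 1L, nbytes)
    entry(TIFF_TAGS["sample_format"], 3L, 1L, 1L)
    next_ptr_pos <- seek(con)       # position of the next-IFD pointer
    w4(0L)                          # patched by the next page
    vals <- as.integer(pmin(pmax(round(t(m)), 0), maxval))  # row-major
    if (bits == 16L) vals <- ifelse(vals > 32767L, vals - 65536L, vals)
    writeBin(vals, con, size = bits / 8L, endian = "little")
    offset <- data_off + nbytes
    if (offset %% 2L == 1L) { writeBin(as.raw(0), con); offset <- offset + 1L }
    seek(con, next_ptr_pos)
  }
  w4(0L)                            # terminate IFD chain
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Reads uncompressed grayscale baseline TIFF (8/16-bit, any strip
#' layout, II or MM byte order).  Multi-page files return a list of
#' matrices.
#'
#' @param path TIFF file.
#' @param as_list always return a list even for one page.
#' @return numeric matrix, or list of matrices for a stack.
#' @export
read_tiff <- function(path, as_list = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read TIFF: '%s' not found", path))
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 8) stop(sprintf("truncated TIFF: %s", path))
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop(sprintf("not a TIFF file: %s", path))
  rd <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size >= 4L)  # 1/2-byte reads unsigned
  magic <- rd(2, 2)
  if (magic != 42) stop(sprintf("not a TIFF file: %s", path))
  ifd <- rd(4, 4)
  pages <- list()
  while (ifd != 0) {
    n_entries <- rd(ifd, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- rd(base, 2); type <- rd(base + 2, 2); count <- rd(base + 4, 4)
      size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(size)) next
      inline <- size * count <= 4
      if (inline) {
        val <- rd(base + 8, size, count)
      } else {
        off <- rd(base + 8, 4)
        val <- rd(off, size, count)
      }
      tags[[as.character(tag)]] <- val
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags)))
      stop(sprintf("unsupported TIFF (missing required tags): %s", path))
    nc <- tags[["256"]]; nr <- tags[["257"]]
    bits <- if (!is.null(tags[["258"]])) tags[["258"]][1] else 1L
    comp <- if (!is.null(tags[["259"]])) tags[["259"]] else 1L
    if (comp != 1) stop(sprintf("unsupported TIFF compression %d: %s", comp, path))
    if (!bits %in% c(8L, 16L))
      stop(sprintf("unsupported TIFF bit depth %d: %s", bits, path))
    offs <- tags[["273"]]; counts <- tags[["279"]]
    vals <- unlist(lapply(seq_along(offs), function(i)
      rd(offs[i], bits / 8L, counts[i] / (bits / 8L))))
    if (length(vals) != nr * nc) stop(sprintf("truncated TIFF data: %s", path))
    pages[[length(pages) + 1L]] <- matrix(vals, nr, nc, byrow = TRUE)
    ifd <- rd(ifd + 2 + n_entries * 12, 4)
  }
  if (!length(pages)) stop(sprintf("TIFF has no pages: %s", path))
  if (length(pages) == 1 && !as_list) pages[[1]] else pages
}

#' Write / read a multi-channel field as TIFF
#'
#' Channels are stored as pages in a fixed, recorded order.
#'
#' @param field a [field_image()].
#' @param path TIFF path.
#' @return `write_field_tiff`: the path; `read_field_tiff`: a
#'   [field_image()].
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "field_image"))
  write_tiff(field$channels, path)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param channels channel names for the pages, in page order.
#' @param well_id,field_id identity for the restored field.
#' @export
read_field_tiff <- function(path, channels = c("nucleus", "fa"),
                            well_id = "", field_id = "") {
  pages <- read_tiff(path, as_list = TRUE)
  if (length(pages) != length(channels))
    stop(sprintf("expected %d channel page(s), found %d in %s",
                 length(channels), length(pages), path))
  names(pages) <- channels
  field_image(pages, well_id = well_id, field_id = field_id)
}

#' Read a movie stack from TIFF
#'
#' @param path multi-page TIFF.
#' @param frame_interval minutes per frame (default 2).
#' @return an [fa_movie()].
#' @export
read_stack <- function(path, frame_interval = 2) {
  fa_movie(read_tiff(path, as_list = TRUE), frame_interval)
}

#' @rdname read_stack
#' @param movie an [fa_movie()].
#' @export
write_stack <- function(movie, path) {
  stopifnot(inherits(movie, "fa_movie"))
  write_tiff(movie$frames, path)
  invisible(path)
}

SCHEMA_VERSION <- "1"

#' CSV tables with a schema-version stamp
#'
#' Every table the pipeline writes carries `schema_version` (and, via
#' [run_pipeline()], the run's seed and config hash) so outputs are
#' self-describing and round-trip through the package's own readers.
#'
#' @param df data.frame.
#' @param path CSV path.
#' @param meta named character vector of extra stamp columns.
#' @return `path` / the data.frame (stamp columns removed on read).
#' @export
write_table_csv <- function(df, path, meta = NULL) {
  df$schema_version <- SCHEMA_VERSION
  if (!is.null(meta)) for (k in names(meta)) df[[k]] <- meta[[k]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read table: '%s' not found", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$schema_version <- NULL
  df
}

#' Flat key = value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment.  Values are
#' parsed as numeric or logical where possible, comma-separated values
#' become vectors.  Keys use dots for grouping (e.g. `fa_quant.mode`).
#'
#' @param config named list (vectors serialised comma-separated).
#' @param path file path.
#' @return `read_config`: named list.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(config[[k]], collapse = ", ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop(sprintf("bad config line: '%s'", ln))
    key <- trimws(kv[2])
    parts <- trimws(strsplit(kv[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    val <- if (!anyNA(num)) num
           else if (all(tolower(parts) %in% c("true", "false")))
             tolower(parts) == "true"
           else parts
    out[[key]] <- val
  }
  out
}

#' Plate-layout files
#'
#' CSV with columns `well_id`, `role`, `gene` (role vocabulary: sample,
#' mock, neg_ctrl, pos_ctrl, death_ctrl).
#'
#' @param layout layout data.frame.
#' @param path CSV path.
#' @return `read_layout`: validated layout data.frame.
#' @export
write_layout <- function(layout, path) {
  write_table_csv(check_layout(layout), path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  check_layout(read_table_csv(path))
}
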