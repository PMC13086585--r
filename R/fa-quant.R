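# Focal-adhesion segmentation and per-field quantification, in two
# dialects: the genome-wide screen pipeline (size window 50-5,000 px, no
# circularity filter) and the per-cell confocal macro (50-500 px,
# circularity 0.00-0.95, edge-excluded nuclei maxima).

#' FA quantification parameters
#'
#' Bundles the processing constants of the FA pipeline.  The `mode` presets
#' pin the two dialects:
#' * `screen`: size window \[50, 5000\] px, no circularity filter, no edge
#'   exclusion for nuclei maxima;
#' * `percell`: size window \[50, 500\] px, circularity in \[0.00, 0.95\]
#'   and nuclei edge exclusion on.
#'
#' Size bounds are inclusive at both ends.  Filter "radius" follows the
#' Fiji convention: the median radius defines the pixel disc, the Gaussian
#' radius is used as sigma.  The "noise level" of the screen's maxima
#' detector and the "prominence" of the Fiji macro are unified as one
#' prominence threshold (default 100).
#'
#' @param mode `"screen"` or `"percell"`.
#' @param median_radius median-filter disc radius (default 2).
#' @param rollball_radius rolling-ball radius (default 1).
#' @param sliding_paraboloid use the paraboloid element (default TRUE).
#' @param threshold_method global threshold (default `"otsu"`).
#' @param min_area,max_area inclusive FA size window in px^2.
#' @param circularity_range length-2 range or `NULL` for no filter.
#' @param nucleus_smooth_radius Gaussian sigma for the nucleus channel
#'   (default 20).
#' @param maxima_threshold prominence threshold for nuclei maxima
#'   (default 100).
#' @param edge_exclude_nuclei reject border-region nuclei maxima.
#' @param focus_threshold minimum local focus score (default 0.03).
#' @param focus_window focus-score window in px (default 64).
#' @param max_structures raw-object ceiling above which a field counts as
#'   oversegmented (default 20000).
#' @param min_nuclei fields with this many nuclei or fewer are excluded
#'   (default 2).
#' @param n_bins histogram bins for thresholding (default 256).
#' @return object of class `fa_quant_params`.
#' @export
fa_quant_params <- function(mode = c("screen", "percell"),
                            median_radius = 2, rollball_radius = 1,
                            sliding_paraboloid = TRUE,
                            threshold_method = "otsu",
                            min_area = NULL, max_area = NULL,
                            circularity_range = NULL,
                            nucleus_smooth_radius = 20,
                            maxima_threshold = 100,
                            edge_exclude_nuclei = NULL,
                            focus_threshold = 0.03, focus_window = 64L,
                            max_structures = 20000L, min_nuclei = 2L,
                            n_bins = 256L) {
  mode <- match.arg(mode)
  if (mode == "screen") {
    if (is.null(min_area)) min_area <- 50
    if (is.null(max_area)) max_area <- 5000
    if (is.null(edge_exclude_nuclei)) edge_exclude_nuclei <- FALSE
  } else {
    if (is.null(min_area)) min_area <- 50
    if (is.null(max_area)) max_area <- 500
    if (is.null(circularity_range)) circularity_range <- c(0, 0.95)
    if (is.null(edge_exclude_nuclei)) edge_exclude_nuclei <- TRUE
  }
  p <- as.list(environment())
  class(p) <- "fa_quant_params"
  p
}

#' Preprocess the FA channel
#'
#' Median filter (disc of `median_radius`) followed by rolling-ball /
#' sliding-paraboloid background subtraction; output clipped at 0.
#'
#' @param img 2-D FA-channel matrix.
#' @param params an [fa_quant_params()].
#' @return preprocessed matrix of the same shape.
#' @export
preprocess_fa_channel <- function(img, params = fa_quant_params()) {
  assert_image(img)
  med <- median_filter(img, params$median_radius)
  rolling_ball(med, params$rollball_radius,
               params$sliding_paraboloid)$subtracted
}

#' Segment focal adhesions
#'
#' Global Otsu threshold on the preprocessed channel, 8-connected
#' components, inclusive size filter and (per-cell mode) circularity
#' filter.  Circularity is \eqn{4\pi A / P^2} with the perimeter from Moore
#' boundary tracing; discretisation values above 1 are clipped to 1 before
#' filtering.
#'
#' @param img preprocessed 2-D matrix (see [preprocess_fa_channel()]).
#' @param params an [fa_quant_params()].
#' @return list: `labels` (filtered label image, consecutive positive
#'   labels), `records` (per-FA data.frame with `label`, `area`,
#'   `centroid_row/col`, `circularity`), `n_raw` (component count before
#'   any filtering).
#' @export
segment_fas <- function(img, params = fa_quant_params()) {
  assert_image(img)
  thr_fun <- threshold_fun(params$threshold_method)
  thr <- thr_fun(img, params$n_bins)
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                records = data.frame(label = integer(), area = integer(),
                                     centroid_row = numeric(),
                                     centroid_col = numeric(),
                                     circularity = numeric()),
                n_raw = 0L)
  if (is.na(thr)) return(empty)
  lab <- label_components(img > thr, connectivity = 8L)
  n_raw <- max(lab)
  if (n_raw == 0) return(empty)
  props <- region_props(lab, perimeter = TRUE)
  keep <- props$area >= params$min_area & props$area <= params$max_area
  if (!is.null(params$circularity_range))
    keep <- keep & props$circularity >= params$circularity_range[1] &
                   props$circularity <= params$circularity_range[2]
  props <- props[keep, , drop = FALSE]
  relab <- matrix(0L, nrow(img), ncol(img))
  if (nrow(props)) {
    map <- integer(n_raw)
    map[props$label] <- seq_len(nrow(props))
    sel <- lab > 0
    relab[sel] <- map[lab[sel]]
    props$label <- seq_len(nrow(props))
  }
  rownames(props) <- NULL
  out <- props[, c("label", "area", "centroid_row", "centroid_col",
                   "circularity")]
  list(labels = relab, records = out, n_raw = n_raw)
}

#' Count nuclei by smoothed prominence maxima
#'
#' Gaussian-smooths the nucleus channel (sigma `nucleus_smooth_radius`) and
#' counts prominence maxima at the `maxima_threshold` noise level,
#' optionally rejecting border-region maxima.  Prominence is offset-free,
#' so the count is invariant under adding a constant to the channel.
#'
#' @param img nucleus-channel matrix.
#' @param params an [fa_quant_params()].
#' @return integer count; use [find_nuclei()] for positions.
#' @export
count_nuclei <- function(img, params = fa_quant_params()) {
  nrow(find_nuclei(img, params))
}

#' @rdname count_nuclei
#' @export
find_nuclei <- function(img, params = fa_quant_params()) {
  assert_image(img)
  sm <- gaussian_blur(img, params$nucleus_smooth_radius)
  find_maxima(sm, params$maxima_threshold,
              exclude_edge = params$edge_exclude_nuclei)
}

#' Local focus score
#'
#' Tiles the image into non-overlapping `window` x `window` squares and
#' averages the per-tile normalised variance \eqn{\mathrm{var}/\mathrm{mean}^2}.
#' Strictly 0 for a constant image and monotonically degraded by defocus
#' blur; fields scoring below 0.03 in the nucleus channel are flagged
#' out-of-focus.  This is a documented proxy for the CellProfiler local
#' focus score (whose exact formula is not restated here); the 0.03
#' default threshold is kept.
#'
#' @param img 2-D matrix.
#' @param window tile edge length in pixels (>= 2, <= both image dims).
#' @return dimensionless score >= 0.
#' @export
focus_score <- function(img, window = 64L) {
  assert_image(img)
  if (window < 2) stop("window must be >= 2 px")
  if (window > nrow(img) || window > ncol(img))
    stop("window larger than image")
  nr_t <- nrow(img) %/% window
  nc_t <- ncol(img) %/% window
  scores <- numeric(0)
  for (i in seq_len(nr_t))
    for (j in seq_len(nc_t)) {
      tile <- img[((i - 1) * window + 1):(i * window),
                  ((j - 1) * window + 1):(j * window)]
      m <- mean(tile)
      scores <- c(scores, if (m > 0) var(as.vector(tile)) / m^2 else 0)
    }
  mean(scores)
}

#' Quantify one field
#'
#' Runs the full per-field pipeline: preprocess the FA channel, segment
#' FAs, count nuclei, compute the focus score on the nucleus channel, and
#' set the QC flags: `focus_fail` (score < `focus_threshold`),
#' `oversegmented` (raw structure count > `max_structures`), `low_nuclei`
#' (nuclei <= `min_nuclei`).  An excluded field (any flag set) carries no
#' FAs-per-cell value.
#'
#' @param field a [field_image()] with `fa` and `nucleus` channels.
#' @param params an [fa_quant_params()].
#' @return object of class `field_quant`: `n_fas`, `fa_areas`, `n_nuclei`,
#'   `fas_per_cell`, `focus`, `qc` (named logical), `excluded`, plus ids.
#' @export
quantify_field <- function(field, params = fa_quant_params()) {
  fa_img <- get_channel(field, "fa")
  nuc_img <- get_channel(field, "nucleus")
  pre <- preprocess_fa_channel(fa_img, params)
  seg <- suppressWarnings(segment_fas(pre, params))
  n_nuclei <- count_nuclei(nuc_img, params)
  fscore <- focus_score(nuc_img, params$focus_window)
  qc <- c(focus_fail = fscore < params$focus_threshold,
          oversegmented = seg$n_raw > params$max_structures,
          low_nuclei = n_nuclei <= params$min_nuclei)
  excluded <- any(qc)
  fpc <- if (!excluded && n_nuclei > 0) nrow(seg$records) / n_nuclei
         else NA_real_
  structure(list(well_id = field$well_id, field_id = field$field_id,
                 n_fas = nrow(seg$records), fa_areas = seg$records$area,
                 n_nuclei = n_nuclei, fas_per_cell = fpc, focus = fscore,
                 n_raw = seg$n_raw, qc = qc, excluded = excluded),
            class = "field_quant")
}

#' @export
print.field_quant <- function(x, ...) {
  cat(sprintf(
    "<field_quant %s/%s: %d FAs, %d nuclei, FAs/cell %s%s>\n",
    x$well_id, x$field_id, x$n_fas, x$n_nuclei,
    ifelse(is.na(x$fas_per_cell), "NA", sprintf("%.2f", x$fas_per_cell)),
    if (x$excluded)
      paste0(", EXCLUDED: ", paste(names(x$qc)[x$qc], collapse = "+"))
    else ""))
  invisible(x)
}

#' @export
as.data.frame.field_quant <- function(x, ...) {
  data.frame(well_id = x$well_id, field_id = x$field_id, n_fas = x$n_fas,
             fa_area_mean = if (length(x$fa_areas)) mean(x$fa_areas)
                            else NA_real_,
             n_nuclei = x$n_nuclei, fas_per_cell = x$fas_per_cell,
             focus = x$focus,
             focus_fail = unname(x$qc["focus_fail"]),
             oversegmented = unname(x$qc["oversegmented"]),
             low_nuclei = unname(x$qc["low_nuclei"]),
             excluded = x$excluded, stringsAsFactors = FALSE)
}

#' Quantify a list of fields into a long table
#'
#' @param fields list of [field_image()].
#' @param params an [fa_quant_params()].
#' @return list: `table` (one row per field), `fa_areas` (per-field list
#'   of FA areas, named by `well/field`).
#' @export
quantify_fields <- function(fields, params = fa_quant_params()) {
  qs <- lapply(fields, quantify_field, params = params)
  tab <- do.call(rbind, lapply(qs, as.data.frame))
  areas <- lapply(qs, `[[`, "fa_areas")
  names(areas) <- paste(tab$well_id, tab$field_id, sep = "/")
  list(table = tab, fa_areas = areas)
}
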