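# Cell-spreading and protrusive-area morphometry.  The protrusive readout
# exploits that elevated parts of a cell accumulate more cytoplasmic
# fluorescence than the flat peripheral lamella: total area comes from a
# plasma-membrane mask, elevated area from a cytoplasm-intensity mask, and
# protrusive area is their difference per watershed-separated cell.

#' Morphometry parameters
#'
#' @param spread_blur Gaussian sigma for the F-actin spreading mask
#'   (default 4).
#' @param spread_threshold threshold method for spreading (default
#'   `"triangle"`).
#' @param spread_min_object minimum retained object size in px^2
#'   (default 500; smaller objects are excluded).
#' @param prot_blur Gaussian sigma for membrane/cytoplasm masks
#'   (default 1).
#' @param prot_threshold threshold method for the outline and elevated
#'   masks (default `"huang"`, the Huang2 fuzzy-entropy criterion; any
#'   method name or a manual numeric threshold).
#' @param elev_threshold optional separate threshold (method or number)
#'   for the elevated mask; `NULL` (default) reuses `prot_threshold`.
#' @param marker_blur Gaussian sigma for watershed markers (default 25).
#' @param marker_prominence prominence for marker maxima (default 100).
#' @param nucleus_smooth_radius,maxima_threshold nuclei detection for the
#'   spreading denominator (defaults 20 and 100).
#' @param n_bins histogram bins (default 256).
#' @return object of class `morphology_params`.
#' @export
morphology_params <- function(spread_blur = 4, spread_threshold = "triangle",
                              spread_min_object = 500,
                              prot_blur = 1, prot_threshold = "huang",
                              elev_threshold = NULL,
                              marker_blur = 25, marker_prominence = 100,
                              nucleus_smooth_radius = 20,
                              maxima_threshold = 100, n_bins = 256L) {
  stopifnot(spread_blur > 0, prot_blur > 0, marker_blur > 0,
            spread_min_object >= 1)
  structure(as.list(environment()), class = "morphology_params")
}

#' Mean cell-spreading area
#'
#' Cell masks from the F-actin channel: Gaussian blur (sigma
#' `spread_blur`) then Triangle threshold; objects smaller than
#' `spread_min_object` px are excluded; the retained mask area is divided
#' by the nuclei count (smoothed-prominence maxima of the nucleus
#' channel).  Invariant under rescaling the actin intensities (the
#' threshold follows the histogram).
#'
#' @param actin,nucleus 2-D channel matrices.
#' @param params a [morphology_params()].
#' @return list: `area_per_cell` (px^2/cell, NA when no nuclei),
#'   `total_area`, `n_objects`, `n_nuclei`, `flag_no_nuclei`.
#' @export
spreading_area <- function(actin, nucleus, params = morphology_params()) {
  assert_image(actin); assert_image(nucleus)
  thr_fun <- threshold_fun(params$spread_threshold)
  sm <- gaussian_blur(actin, params$spread_blur)
  thr <- thr_fun(sm, params$n_bins)
  if (is.na(thr)) {
    total <- 0; nobj <- 0L
  } else {
    lab <- label_components(sm > thr, connectivity = 8L)
    props <- region_props(lab)
    props <- props[props$area >= params$spread_min_object, , drop = FALSE]
    total <- sum(props$area); nobj <- nrow(props)
  }
  qp <- fa_quant_params("screen",
                        nucleus_smooth_radius = params$nucleus_smooth_radius,
                        maxima_threshold = params$maxima_threshold)
  n_nuc <- count_nuclei(nucleus, qp)
  list(area_per_cell = if (n_nuc > 0) total / n_nuc else NA_real_,
       total_area = total, n_objects = nobj, n_nuclei = n_nuc,
       flag_no_nuclei = n_nuc == 0)
}

#' Marker-controlled watershed cell segmentation
#'
#' Mask: Huang threshold of the membrane channel blurred at sigma
#' `prot_blur` (holes filled).  Markers: prominence maxima of the
#' cytoplasm channel blurred at sigma `marker_blur`; markers outside the
#' mask are dropped, the rest are labelled 1..k in (row, col) scan order.
#' Flooding: Meyer's watershed of the *unprocessed, inverted* cytoplasm
#' channel restricted to the mask, 8-connected, ties resolved first-come
#' deterministically.
#'
#' @param cytoplasm,membrane 2-D channel matrices.
#' @param params a [morphology_params()].
#' @return list: `labels` (cell label image), `markers` (data.frame of
#'   seed positions, 0-based), `mask` (logical outline mask).
#' @export
segment_cells_watershed <- function(cytoplasm, membrane,
                                    params = morphology_params()) {
  assert_image(cytoplasm); assert_image(membrane)
  thr_fun <- threshold_fun(params$prot_threshold)
  msm <- gaussian_blur(membrane, params$prot_blur)
  thr <- thr_fun(msm, params$n_bins)
  if (is.na(thr)) {
    warning("blank membrane channel: no cells")
    return(list(labels = matrix(0L, nrow(membrane), ncol(membrane)),
                markers = data.frame(row = integer(), col = integer()),
                mask = matrix(FALSE, nrow(membrane), ncol(membrane))))
  }
  mask <- fill_holes(msm > thr)
  mk <- find_maxima(gaussian_blur(cytoplasm, params$marker_blur),
                    params$marker_prominence)
  inside <- mask[cbind(mk$row + 1L, mk$col + 1L)]
  mk <- mk[inside, , drop = FALSE]
  mk <- mk[order(mk$row, mk$col), , drop = FALSE]
  if (!nrow(mk)) {
    warning("no markers inside the cell mask: zero cells")
    return(list(labels = matrix(0L, nrow(membrane), ncol(membrane)),
                markers = mk, mask = mask))
  }
  markers <- matrix(0L, nrow(cytoplasm), ncol(cytoplasm))
  markers[cbind(mk$row + 1L, mk$col + 1L)] <- seq_len(nrow(mk))
  inv <- max(cytoplasm) - cytoplasm
  labels <- .cpp_watershed(inv, markers, mask)
  list(labels = labels, markers = mk, mask = mask)
}

#' Per-cell protrusive area
#'
#' For each watershed cell: total area is its label region (within the
#' membrane mask); elevated area is the overlap with the cytoplasm mask
#' (blur sigma `prot_blur`, Huang threshold) clipped to the cell, so the
#' partition `total = elevated + protrusive` holds exactly and protrusive
#' area can never be negative.  Elevated pixels outside every watershed
#' cell are ignored.
#'
#' @param cytoplasm,membrane 2-D channel matrices.
#' @param params a [morphology_params()].
#' @return data.frame: `cell_label`, `total_area`, `elevated_area`,
#'   `protrusive_area`; attribute `labels` carries the cell label image.
#' @export
protrusive_area <- function(cytoplasm, membrane,
                            params = morphology_params()) {
  seg <- segment_cells_watershed(cytoplasm, membrane, params)
  labs <- sort(unique(seg$labels[seg$labels > 0]))
  if (!length(labs)) {
    out <- data.frame(cell_label = integer(), total_area = integer(),
                      elevated_area = integer(), protrusive_area = integer())
    attr(out, "labels") <- seg$labels
    return(out)
  }
  thr_fun <- threshold_fun(params$elev_threshold %||% params$prot_threshold)
  csm <- gaussian_blur(cytoplasm, params$prot_blur)
  cthr <- thr_fun(csm, params$n_bins)
  elevated_mask <- if (is.na(cthr))
    matrix(FALSE, nrow(cytoplasm), ncol(cytoplasm)) else csm > cthr
  total <- tabulate(seg$labels[seg$labels > 0], nbins = max(labs))[labs]
  elev_lab <- seg$labels[seg$labels > 0 & elevated_mask]
  elevated <- tabulate(elev_lab, nbins = max(labs))[labs]
  out <- data.frame(cell_label = labs, total_area = as.integer(total),
                    elevated_area = as.integer(elevated),
                    protrusive_area = as.integer(total - elevated))
  attr(out, "labels") <- seg$labels
  out
}
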