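# Plate-level screening statistics: Z'-factor QC, plate-wise Z-scores,
# primary hit calling, secondary confirmation and screen reporting.

#' Screening thresholds
#'
#' @param z_count_threshold Z-score cut for FAs per cell (default 4.2,
#'   strict >).
#' @param z_area_threshold Z-score cut for FA area (default 3.5, strict >).
#' @param viability_min_cells minimum cells per well; wells below are
#'   excluded as low-viability (default 50).
#' @param confirm_min_increase secondary-screen confirmation floor as a
#'   fractional increase over mock (default 0.30, inclusive).
#' @param zprime_warn plates with Z' below this are flagged, not dropped
#'   (default 0.5).
#' @return object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(z_count_threshold = 4.2,
                              z_area_threshold = 3.5,
                              viability_min_cells = 50,
                              confirm_min_increase = 0.30,
                              zprime_warn = 0.5) {
  stopifnot(z_count_threshold > 0, z_area_threshold > 0,
            viability_min_cells > 0, confirm_min_increase > 0,
            zprime_warn > 0)
  structure(as.list(environment()), class = "screen_thresholds")
}

#' Z'-factor assay-window statistic
#'
#' \eqn{Z' = 1 - 3(\sigma_p + \sigma_n) / |\mu_p - \mu_n|} with sample
#' (n-1) standard deviations.  Symmetric in group order, invariant under a
#' common affine rescaling, and always <= 1.
#'
#' @param positive,negative numeric vectors of control-well readouts
#'   (each length >= 2).
#' @return dimensionless Z'-factor.
#' @export
zprime <- function(positive, negative) {
  if (length(positive) < 2 || length(negative) < 2)
    stop("each control group needs >= 2 values")
  mu_p <- mean(positive); mu_n <- mean(negative)
  if (mu_p == mu_n) stop("separation undefined: control means are equal")
  1 - 3 * (sd(positive) + sd(negative)) / abs(mu_p - mu_n)
}

#' Plate-wise Z-scores
#'
#' \eqn{z_w = (x_w - \mu_{ref}) / \sigma_{ref}} within one plate.  The
#' reference population is either all non-excluded sample wells (default;
#' robust to sparse controls) or the mock wells; the choice is recorded in
#' the output attributes.  Excluded wells receive no score.
#'
#' @param plate plate table (one row per well; see
#'   [simulate_plate_values()] / [aggregate_wells()] for the schema).
#' @param parameter `"fas_per_cell"` or `"fa_area_mean"`.
#' @param reference `"sample"` or `"mock"`.
#' @return the plate table with a `z` column (NA for excluded wells);
#'   attributes `reference`, `mu_ref`, `sd_ref`.
#' @export
plate_zscores <- function(plate,
                          parameter = c("fas_per_cell", "fa_area_mean"),
                          reference = c("sample", "mock")) {
  parameter <- match.arg(parameter)
  reference <- match.arg(reference)
  excl <- if ("excluded" %in% names(plate)) plate$excluded else FALSE
  ref <- plate$role == reference & !excl & !is.na(plate[[parameter]])
  if (sum(ref) < 2)
    stop(sprintf("reference population '%s' has fewer than 2 usable wells",
                 reference))
  x_ref <- plate[[parameter]][ref]
  mu <- mean(x_ref); s <- sd(x_ref)
  if (s == 0) stop("reference SD is zero")
  out <- plate
  out$z <- (plate[[parameter]] - mu) / s
  out$z[excl | is.na(plate[[parameter]])] <- NA_real_
  attr(out, "reference") <- reference
  attr(out, "mu_ref") <- mu
  attr(out, "sd_ref") <- s
  out
}

#' Primary-screen hit calling
#'
#' A gene is a hit iff `z_count > z_count_threshold` **or**
#' `z_area > z_area_threshold` (strict inequalities) **and** its well
#' passed the viability floor (`cell_count >= viability_min_cells`).
#' Low-viability wells are excluded with reason `"viability"`; an optional
#' logical `artifact` marker excludes wells with reason `"artifact"`
#' (a pass-through for the screen's manual staining-artifact review).
#' Cell counts are mandatory: a missing count is an error, not an
#' exclusion.
#'
#' @param zscores data.frame with `gene`, `z_count`, `z_area` and
#'   optionally `artifact`.
#' @param thresholds a [screen_thresholds()].
#' @param cell_counts named numeric vector (names = genes) or a data.frame
#'   with `gene`, `cell_count`.
#' @return data.frame: `gene`, `z_count`, `z_area`, `cell_count`, `hit`,
#'   `exclusion_reason` (`"none"`, `"viability"`, `"artifact"`).
#' @export
call_hits <- function(zscores, thresholds = screen_thresholds(),
                      cell_counts) {
  stopifnot(all(c("gene", "z_count", "z_area") %in% names(zscores)))
  if (is.data.frame(cell_counts))
    cell_counts <- setNames(cell_counts$cell_count, cell_counts$gene)
  cc <- cell_counts[zscores$gene]
  if (any(is.na(cc)))
    stop(sprintf("missing cell count for gene(s): %s",
                 paste(zscores$gene[is.na(cc)], collapse = ", ")))
  artifact <- if ("artifact" %in% names(zscores)) zscores$artifact
              else rep(FALSE, nrow(zscores))
  viable <- cc >= thresholds$viability_min_cells
  reason <- rep("none", nrow(zscores))
  reason[!viable] <- "viability"
  reason[artifact] <- "artifact"
  over <- (!is.na(zscores$z_count) &
             zscores$z_count > thresholds$z_count_threshold) |
          (!is.na(zscores$z_area) &
             zscores$z_area > thresholds$z_area_threshold)
  data.frame(gene = zscores$gene, z_count = zscores$z_count,
             z_area = zscores$z_area, cell_count = as.numeric(cc),
             hit = over & reason == "none",
             exclusion_reason = reason, stringsAsFactors = FALSE,
             row.names = NULL)
}

# per-gene fold change vs the plate's mock mean, for one parameter
fold_vs_mock <- function(plate, parameter) {
  mock <- plate$role == "mock" & !is.na(plate[[parameter]])
  if (!any(mock)) stop("replicate has no mock wells")
  mu <- mean(plate[[parameter]][mock])
  if (mu == 0) stop("mock mean is zero")
  samp <- plate[plate$role == "sample", , drop = FALSE]
  setNames(samp[[parameter]] / mu, samp$gene)
}

#' Secondary-screen confirmation
#'
#' Normalises each replicate to its mock wells, averages the two fold
#' changes per gene, and confirms genes whose mean fold change is at least
#' `1 + confirm_min_increase` (inclusive: a 30% average increase
#' confirms) in either FAs per cell or FA area.  A gene missing from one
#' replicate is reported as unconfirmable (`confirmed = NA`), never
#' silently dropped.
#'
#' @param rep1,rep2 plate tables of the two replicates.
#' @param thresholds a [screen_thresholds()].
#' @return data.frame: `gene`, `fold_count`, `fold_area` (replicate
#'   means), `confirmed` (logical, NA when unconfirmable).
#' @export
secondary_confirm <- function(rep1, rep2,
                              thresholds = screen_thresholds()) {
  f1c <- fold_vs_mock(rep1, "fas_per_cell")
  f2c <- fold_vs_mock(rep2, "fas_per_cell")
  f1a <- fold_vs_mock(rep1, "fa_area_mean")
  f2a <- fold_vs_mock(rep2, "fa_area_mean")
  genes <- union(names(f1c), names(f2c))
  fc <- (f1c[genes] + f2c[genes]) / 2
  fa <- (f1a[genes] + f2a[genes]) / 2
  floor_ <- 1 + thresholds$confirm_min_increase
  eps <- 1e-9                               # numerically safe inclusive >=
  confirmed <- fc >= floor_ - eps | fa >= floor_ - eps
  data.frame(gene = genes, fold_count = as.numeric(fc),
             fold_area = as.numeric(fa), confirmed = as.logical(confirmed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate per-field quantifications to wells
#'
#' Well FAs-per-cell is the mean over non-excluded fields; well FA area is
#' the mean of all per-FA areas pooled over the well's non-excluded
#' fields; cell count is the total nuclei over non-excluded fields (the
#' viability readout).  Wells whose fields are all excluded are excluded.
#'
#' @param field_table per-field table from [quantify_fields()].
#' @param fa_areas per-field list of FA areas from [quantify_fields()].
#' @param layout plate layout data.frame (`well_id`, `role`, `gene`).
#' @param plate_id plate identifier for the output rows.
#' @return plate table: one row per layout well with `plate_id`,
#'   `well_id`, `role`, `gene`, `fas_per_cell`, `fa_area_mean`,
#'   `cell_count`, `excluded_fields`, `excluded`.
#' @export
aggregate_wells <- function(field_table, fa_areas, layout,
                            plate_id = "P1") {
  layout <- check_layout(layout)
  rows <- lapply(seq_len(nrow(layout)), function(w) {
    wid <- layout$well_id[w]
    ft <- field_table[field_table$well_id == wid, , drop = FALSE]
    ok <- ft[!ft$excluded, , drop = FALSE]
    pooled <- unlist(fa_areas[paste(ok$well_id, ok$field_id, sep = "/")])
    data.frame(plate_id = plate_id, well_id = wid, role = layout$role[w],
               gene = layout$gene[w],
               fas_per_cell = if (nrow(ok)) mean(ok$fas_per_cell)
                              else NA_real_,
               fa_area_mean = if (length(pooled)) mean(pooled)
                              else NA_real_,
               cell_count = if (nrow(ok)) sum(ok$n_nuclei) else 0L,
               excluded_fields = sum(ft$excluded),
               excluded = nrow(ok) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-screen report
#'
#' Per plate: the Z'-factor from the mock and positive-control wells
#' (FAs per cell), flagged (not dropped) when below `zprime_warn`;
#' plate-wise Z-scores for both parameters; then hit calling over all
#' sample wells.  Exclusion tallies are returned alongside.
#'
#' @param plates list of plate tables.
#' @param thresholds a [screen_thresholds()].
#' @param reference Z-score reference population (see [plate_zscores()]).
#' @return list of class `screen_report`: `plate_qc` (per-plate Z' and
#'   flag), `zscore_table` (per sample well), `hit_table`, `exclusions`
#'   (tally by reason).
#' @export
screen_report <- function(plates, thresholds = screen_thresholds(),
                          reference = "sample") {
  if (!length(plates)) stop("need >= 1 plate")
  qc <- do.call(rbind, lapply(plates, function(p) {
    zp <- zprime(p$fas_per_cell[p$role == "pos_ctrl"],
                 p$fas_per_cell[p$role == "mock"])
    data.frame(plate_id = p$plate_id[1], zprime = zp,
               low_quality = zp < thresholds$zprime_warn,
               stringsAsFactors = FALSE)
  }))
  ztabs <- lapply(plates, function(p) {
    zc <- plate_zscores(p, "fas_per_cell", reference)
    za <- plate_zscores(p, "fa_area_mean", reference)
    s <- zc$role == "sample"
    data.frame(plate_id = p$plate_id[1], well_id = zc$well_id[s],
               gene = zc$gene[s], z_count = zc$z[s], z_area = za$z[s],
               cell_count = p$cell_count[s], excluded = zc$excluded[s],
               stringsAsFactors = FALSE)
  })
  ztab <- do.call(rbind, ztabs)
  rownames(ztab) <- NULL
  # hit calling per plate so replicate genes keep their own cell counts
  hits <- do.call(rbind, lapply(ztabs, function(zt) {
    u <- !zt$excluded
    call_hits(zt[u, c("gene", "z_count", "z_area")], thresholds,
              setNames(zt$cell_count[u], zt$gene[u]))
  }))
  rownames(hits) <- NULL
  excl <- table(factor(hits$exclusion_reason,
                       levels = c("none", "viability", "artifact")))
  structure(list(plate_qc = qc, zscore_table = ztab, hit_table = hits,
                 exclusions = c(as.list(excl),
                                list(excluded_wells = sum(ztab$excluded)))),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report: %d plate(s), Z' %s; %d hit(s) / %d genes>\n",
              nrow(x$plate_qc),
              paste(sprintf("%.3f", x$plate_qc$zprime), collapse = ", "),
              sum(x$hit_table$hit), nrow(x$hit_table)))
  invisible(x)
}
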