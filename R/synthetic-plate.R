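# Synthetic plate generation: image-backed small plates and a fast
# value-level screen simulator for statistics-scale experiments.

ROLE_LEVELS <- c("sample", "mock", "neg_ctrl", "pos_ctrl", "death_ctrl")

well_name <- function(row, col) sprintf("%s%02d", LETTERS[row], col)

#' Default screening-plate layout
#'
#' Builds a rectangular plate layout with control wells in the two outer
#' columns (their exact coordinates on the original screening plates are
#' not published, so the default is a convention, and any layout can be
#' supplied as a data.frame).  Control roles cycle through mock, neg_ctrl,
#' pos_ctrl and death_ctrl down the outer columns; every other well is a
#' sample well with a synthetic gene label.
#'
#' @param n_rows,n_cols plate dimensions (default 16 x 24, a 384-well
#'   plate).
#' @param control_cols columns reserved for controls (default first and
#'   last).
#' @param genes optional character vector of gene labels for sample wells
#'   (recycled/truncated to fit; default GENE0001, ...).
#' @return data.frame with `well_id`, `row`, `col`, `role`, `gene`.
#' @export
plate_layout <- function(n_rows = 16L, n_cols = 24L,
                         control_cols = c(1L, n_cols), genes = NULL) {
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  g <- g[order(g$col, g$row), ]
  ctrl <- g$col %in% control_cols
  roles <- rep("sample", nrow(g))
  roles[ctrl] <- rep(c("mock", "neg_ctrl", "pos_ctrl", "death_ctrl"),
                     length.out = sum(ctrl))
  n_samp <- sum(!ctrl)
  if (is.null(genes)) genes <- sprintf("GENE%04d", seq_len(n_samp))
  gene <- rep(NA_character_, nrow(g))
  gene[!ctrl] <- rep_len(genes, n_samp)
  out <- data.frame(well_id = well_name(g$row, g$col), row = g$row,
                    col = g$col, role = roles, gene = gene,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

check_layout <- function(layout) {
  need <- c("well_id", "role")
  if (!all(need %in% names(layout)))
    stop("layout must have columns well_id and role (and gene for samples)")
  bad <- setdiff(unique(layout$role), ROLE_LEVELS)
  if (length(bad))
    stop(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(layout$well_id)) stop("layout wells must be unique")
  if (!"gene" %in% names(layout)) layout$gene <- NA_character_
  layout
}

#' Specification for a synthetic screening plate
#'
#' @param layout plate layout data.frame (see [plate_layout()]).
#' @param effect_model data.frame with `gene`, `count_mult`, `area_mult`:
#'   per-gene multiplicative effects on FA count and FA area.  Genes not
#'   listed get multiplier 1.
#' @param fields_per_well imaged fields per well (default 2).
#' @param base_field_spec the [synth_field_spec()] used for every field;
#'   per-well seeds are derived deterministically from `seed`.
#' @param pos_ctrl_count_mult FA-count boost of the positive control
#'   (default 2; a stronger boost overcrowds the default 256-px field).
#' @param death_n_nuclei nuclei per field in death-control wells (default
#'   1, so a well stays far below the 50-cell viability floor).
#' @param seed integer seed.
#' @return object of class `synth_plate_spec`.
#' @export
synth_plate_spec <- function(layout = plate_layout(),
                             effect_model = NULL,
                             fields_per_well = 2L,
                             base_field_spec = synth_field_spec(),
                             pos_ctrl_count_mult = 2,
                             death_n_nuclei = 1L,
                             seed = 1L) {
  layout <- check_layout(layout)
  if (sum(layout$role == "mock") < 2 || sum(layout$role == "neg_ctrl") < 2)
    stop("layout needs >= 2 mock and >= 2 neg_ctrl wells")
  if (is.null(effect_model))
    effect_model <- data.frame(gene = character(), count_mult = numeric(),
                               area_mult = numeric())
  structure(as.list(environment()), class = "synth_plate_spec")
}

well_seed <- function(seed, k) as.integer((seed + 7919 * k) %% 2147483629)

#' Generate an image-backed synthetic plate
#'
#' Every well's fields are generated from the base field spec with the
#' well's role/gene effect applied: sample wells scale the per-cell FA
#' count mean by the gene's `count_mult` and the FA area distribution by
#' `area_mult`; positive controls boost FA count; death controls carry
#' `death_n_nuclei` nuclei per field (below the viability floor); mock and
#' negative controls use the base spec unchanged.
#'
#' @param spec a [synth_plate_spec()].
#' @param plate_id identifier stamped on the output.
#' @return list with `fields` (list of [field_image()]), `truth` (per-well
#'   data.frame of planted effects and true counts) and `field_truth`
#'   (list of per-field ground truths).
#' @export
make_plate <- function(spec, plate_id = "P1") {
  stopifnot(inherits(spec, "synth_plate_spec"))
  layout <- spec$layout
  fields <- list(); field_truth <- list()
  rows <- vector("list", nrow(layout))
  for (w in seq_len(nrow(layout))) {
    role <- layout$role[w]; gene <- layout$gene[w]
    cm <- 1; am <- 1
    if (role == "sample" && !is.na(gene) &&
        gene %in% spec$effect_model$gene) {
      i <- match(gene, spec$effect_model$gene)
      cm <- spec$effect_model$count_mult[i]
      am <- spec$effect_model$area_mult[i]
    } else if (role == "pos_ctrl") cm <- spec$pos_ctrl_count_mult
    fs <- spec$base_field_spec
    fs$n_fas_per_cell$mean <- fs$n_fas_per_cell$mean * cm
    fs$fa_area_px$mean <- fs$fa_area_px$mean * am
    fs$fa_area_px$min <- fs$fa_area_px$min * min(1, am)
    fs$fa_area_px$max <- fs$fa_area_px$max * max(1, am)
    if (role == "death_ctrl") fs$n_nuclei <- spec$death_n_nuclei
    tot_fa <- 0L; tot_nuc <- 0L
    for (f in seq_len(spec$fields_per_well)) {
      fs$seed <- well_seed(spec$seed, (w - 1L) * spec$fields_per_well + f)
      made <- NULL
      for (attempt in 0:4) {
        # an unlucky overdispersed draw can exceed the field's geometric
        # capacity; resample that field with a derived seed (deterministic)
        made <- tryCatch(make_field(fs, well_id = layout$well_id[w],
                                    field_id = sprintf("f%02d", f)),
                         error = function(e)
                           if (grepl("too crowded", conditionMessage(e)) &&
                               attempt < 4) NULL else stop(e))
        if (!is.null(made)) break
        fs$seed <- well_seed(fs$seed, 9973L)
      }
      fields[[length(fields) + 1L]] <- made$field
      field_truth[[length(field_truth) + 1L]] <- made$truth
      tot_fa <- tot_fa + made$truth$n_fas
      tot_nuc <- tot_nuc + made$truth$n_nuclei
    }
    rows[[w]] <- data.frame(plate_id = plate_id, well_id = layout$well_id[w],
                            role = role, gene = gene, count_mult = cm,
                            area_mult = am, true_n_fas = tot_fa,
                            true_n_nuclei = tot_nuc,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(fields = fields, truth = truth, field_truth = field_truth)
}

#' Fast value-level screen simulator
#'
#' Simulates per-well readouts (FAs per cell, mean FA area, cell count)
#' directly, without rendering images, so that screen-scale statistics
#' (hundreds of wells, many replicate screens) stay cheap.  The stated
#' world: well-to-well readouts are Gaussian around the plate mean with a
#' 10% coefficient of variation (typical day-to-day spread of an
#' established high-content assay), cell counts are Poisson around 300
#' cells/well, death controls collapse to ~20 cells, and the positive
#' control shifts FAs per cell by `pos_shift_sd` reference SDs.  Planted
#' gene effects are expressed as shifts in units of the well-to-well SD.
#'
#' @param layout plate layout data.frame.
#' @param planted data.frame with `gene`, `shift_sd_count`,
#'   `shift_sd_area` (shifts in SD units; absent genes get 0).
#' @param base_fpc mean FAs per cell (default 20).
#' @param cv well-to-well coefficient of variation (default 0.10).
#' @param base_area mean FA area in px^2 (default 250).
#' @param mean_cells mean cells per well (default 300).
#' @param pos_shift_sd positive-control shift (default +10 SD).
#' @param plate_id plate identifier.
#' @param seed integer seed.
#' @return a plate table (see [aggregate_wells()] for the schema) plus a
#'   `planted` attribute carrying the ground truth.
#' @export
simulate_plate_values <- function(layout = plate_layout(), planted = NULL,
                                  base_fpc = 20, cv = 0.10, base_area = 250,
                                  mean_cells = 300, pos_shift_sd = 10,
                                  plate_id = "P1", seed = 1L) {
  layout <- check_layout(layout)
  with_seed(seed, {
    n <- nrow(layout)
    sd_fpc <- cv * base_fpc
    sd_area <- cv * base_area
    shift_c <- numeric(n); shift_a <- numeric(n)
    if (!is.null(planted) && nrow(planted)) {
      i <- match(layout$gene, planted$gene)
      hit <- !is.na(i)
      shift_c[hit] <- planted$shift_sd_count[i[hit]]
      shift_a[hit] <- planted$shift_sd_area[i[hit]]
    }
    shift_c[layout$role == "pos_ctrl"] <- pos_shift_sd
    fpc <- rnorm(n, base_fpc + shift_c * sd_fpc, sd_fpc)
    area <- rnorm(n, base_area + shift_a * sd_area, sd_area)
    cells <- rpois(n, ifelse(layout$role == "death_ctrl", 20, mean_cells))
    out <- data.frame(plate_id = plate_id, well_id = layout$well_id,
                      role = layout$role, gene = layout$gene,
                      fas_per_cell = pmax(fpc, 0),
                      fa_area_mean = pmax(area, 1),
                      cell_count = cells, excluded_fields = 0L,
                      excluded = FALSE, stringsAsFactors = FALSE)
    attr(out, "planted") <- planted
    out
  })
}
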