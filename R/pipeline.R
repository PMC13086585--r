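# Pipeline orchestration: reproducible runs that chain the synthetic
# generators and analysis stages, with every output table stamped with the
# run's seed and config hash.

config_hash <- function(config) {
  # order-independent hash of the flattened key=value representation;
  # I/O locations are excluded so identical analyses produce identical
  # stamped tables wherever they are written
  config <- config[setdiff(names(config),
                           c("out_dir", "in_dir", "in_file", "in_stack"))]
  keys <- sort(names(config))
  txt <- paste(keys, vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  sprintf("%08x", h)
}

default_run_config <- function() {
  list(stage = "simulate-screen", out_dir = "fa_run", seed = 1,
       plates = 1, fields_per_well = 2, layout_rows = 8, layout_cols = 6,
       mode = "screen", frame_interval = 2,
       # image-backed wells carry biological + camera variability
       fa_count_mean = 10, fa_count_dispersion = 15, noise_sd = 30)
}

#' Run a pipeline stage from a configuration
#'
#' Stages: `simulate-screen` (generate an image-backed plate per the
#' layout, quantify every field, aggregate wells, compute Z' / Z-scores /
#' hits and write all tables), `quantify` (a directory of two-page
#' nucleus+FA TIFFs to a per-field table), `screen` (a per-well table plus
#' layout to Z' report, Z-scores and hit table), `spreading`,
#' `protrusion` and `dynamics` (per-image/movie morphometry or track
#' tables).  The effective configuration is written next to the outputs
#' and every table is stamped with the seed and config hash, so a rerun
#' with an identical config reproduces identical tables.
#'
#' @param config named list; see `vignette("fascreenkit-methods")`.
#'   Recognised keys depend on the stage (`stage`, `out_dir`, `seed`,
#'   `in_dir`, `layout`, `wells_table`, `plates`, `fields_per_well`,
#'   `layout_rows`, `layout_cols`, `mode`, `frame_interval`).
#' @return invisibly, a character vector of files written.
#' @export
run_pipeline <- function(config) {
  config <- modifyList(default_run_config(), config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  meta <- c(seed = as.character(seed), config_hash = config_hash(config))
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_table_csv(df, p, meta = meta)
    written <<- c(written, p)
  }
  stage <- config$stage
  if (stage == "simulate-screen") {
    lay <- plate_layout(config$layout_rows, config$layout_cols)
    params <- fa_quant_params(config$mode)
    th <- screen_thresholds()
    plates <- list()
    base_fs <- synth_field_spec(
      n_fas_per_cell = list(mean = config$fa_count_mean,
                            dispersion = config$fa_count_dispersion),
      noise_sd = config$noise_sd)
    for (p in seq_len(config$plates)) {
      spec <- synth_plate_spec(layout = lay,
                               fields_per_well = as.integer(config$fields_per_well),
                               base_field_spec = base_fs,
                               seed = well_seed(seed, p))
      made <- make_plate(spec, plate_id = sprintf("P%d", p))
      q <- quantify_fields(made$fields, params)
      q$table$plate_id <- sprintf("P%d", p)
      emit(q$table, sprintf("fields_P%d.csv", p))
      plates[[p]] <- aggregate_wells(q$table, q$fa_areas, lay,
                                     plate_id = sprintf("P%d", p))
      emit(made$truth, sprintf("truth_P%d.csv", p))
    }
    emit(do.call(rbind, plates), "wells.csv")
    rep <- screen_report(plates, th)
    emit(rep$plate_qc, "plate_qc.csv")
    emit(rep$zscore_table, "zscores.csv")
    emit(rep$hit_table, "hits.csv")
  } else if (stage == "quantify") {
    if (is.null(config$in_dir)) stop("quantify requires in_dir")
    files <- sort(list.files(config$in_dir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(files)) stop(sprintf("no TIFF files in %s", config$in_dir))
    params <- fa_quant_params(config$mode)
    fields <- lapply(files, function(f)
      read_field_tiff(f, well_id = sub("_f[0-9]+$", "",
                                       tools::file_path_sans_ext(basename(f))),
                      field_id = sub("^.*_(f[0-9]+)$", "\\1",
                                     tools::file_path_sans_ext(basename(f)))))
    q <- quantify_fields(fields, params)
    emit(q$table, "fields.csv")
    areas <- do.call(rbind, lapply(names(q$fa_areas), function(k) {
      a <- q$fa_areas[[k]]
      if (!length(a)) return(NULL)
      data.frame(field = k, area = a)
    }))
    if (!is.null(areas)) emit(areas, "fa_areas.csv")
  } else if (stage == "screen") {
    if (is.null(config$layout)) stop("layout required")
    if (is.null(config$wells_table)) stop("screen requires wells_table")
    lay <- read_layout(config$layout)
    wells <- read_table_csv(config$wells_table)
    plates <- split(wells, wells$plate_id)
    rep <- screen_report(plates, screen_thresholds())
    emit(rep$plate_qc, "plate_qc.csv")
    emit(rep$zscore_table, "zscores.csv")
    emit(rep$hit_table, "hits.csv")
  } else if (stage == "dynamics") {
    if (is.null(config$in_stack)) stop("dynamics requires in_stack")
    movie <- read_stack(config$in_stack, config$frame_interval)
    params <- dynamics_params()
    dc <- correct_drift(movie, params)
    cropped <- autocrop(crop_movie(dc$movie, dc$valid_bbox), params)
    tracks <- track_fas(cropped$movie, params)
    emit(dc$offsets, "drift.csv")
    emit(merge(tracks$obs, tracks$tracks, by = "track_id"), "tracks.csv")
    emit(summarize_dynamics(tracks, config$frame_interval, params),
         "dynamics_summary.csv")
  } else if (stage %in% c("protrusion", "spreading")) {
    if (is.null(config$in_file)) stop(sprintf("%s requires in_file", stage))
    if (stage == "protrusion") {
      fi <- read_field_tiff(config$in_file, c("cytoplasm", "membrane"))
      out <- protrusive_area(fi$channels$cytoplasm, fi$channels$membrane)
      emit(out, "protrusion.csv")
    } else {
      fi <- read_field_tiff(config$in_file, c("nucleus", "actin"))
      sp <- spreading_area(fi$channels$actin, fi$channels$nucleus)
      emit(data.frame(area_per_cell = sp$area_per_cell,
                      total_area = sp$total_area, n_nuclei = sp$n_nuclei),
           "spreading.csv")
    }
  } else stop(sprintf("unknown stage '%s'", stage))
  cfg_path <- file.path(out_dir, "run_config.cfg")
  write_config(c(config, list(config_hash = unname(meta["config_hash"]))),
               cfg_path)
  invisible(c(written, cfg_path))
}

#' Command-line entry point
#'
#' `fa-screenkit <stage> [--key value ...]`: every `--key value` pair goes
#' into the run config (see [run_pipeline()]).  An installed copy lives at
#' `system.file("cli", "fa-screenkit", package = "fascreenkit")`.
#'
#' @param args character vector (default: the process command line).
#' @return exit status, invisibly (0 on success).
#' @export
fa_screenkit_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: fa-screenkit <stage> [--key value ...]\n",
            "stages: simulate-screen quantify screen spreading protrusion dynamics")
    return(invisible(2L))
  }
  config <- list(stage = args[1])
  args <- args[-1]
  if (length(args) %% 2 != 0) stop("options must come in --key value pairs")
  for (i in if (length(args)) seq(1, length(args), by = 2) else integer(0)) {
    key <- sub("^--", "", args[i])
    val <- args[i + 1]
    num <- suppressWarnings(as.numeric(val))
    config[[key]] <- if (!is.na(num)) num else val
  }
  status <- tryCatch({ run_pipeline(config); 0L },
                     error = function(e) { message("error: ",
                                                   conditionMessage(e)); 1L })
  invisible(status)
}
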