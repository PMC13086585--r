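# Time-lapse FA dynamics: rigid drift correction, auto-cropping,
# per-frame segmentation, overlap tracking (splitting off), exponential
# assembly/disassembly rate fitting and novel-FA counting.

#' FA-dynamics parameters
#'
#' @param drift_min_grey only pixels at or above this grey value enter the
#'   drift cross-correlation (default 120).
#' @param drift_max_shift per-step shift clamp in px (default 20).
#' @param crop_blur Gaussian sigma for the auto-crop mask (default 15).
#' @param seg_threshold_sd segmentation threshold in background SDs above
#'   the background level of the high-pass-filtered frame (default 2).
#' @param min_fa_size minimum FA size in px^2 (default 10).
#' @param min_phase_frames minimum frames per kinetic phase for a rate fit
#'   (default 5).
#' @param dog_small,dog_large difference-of-Gaussians sigmas of the
#'   high-pass filter (defaults 0 and 8; 0 = no small-scale smoothing, so
#'   noiseless foregrounds coincide with object footprints).
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(drift_min_grey = 120, drift_max_shift = 20,
                            crop_blur = 15, seg_threshold_sd = 2,
                            min_fa_size = 10, min_phase_frames = 5,
                            dog_small = 0, dog_large = 8) {
  stopifnot(seg_threshold_sd > 0, min_fa_size >= 1, drift_max_shift >= 0)
  structure(as.list(environment()), class = "dynamics_params")
}

# integer shift (dy, dx) such that b ~= translate(a, dy, dx), by FFT
# cross-correlation of the two images; shifts wrap into [-n/2, n/2)
xcorr_shift <- function(a, b) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  cc <- Re(stats::fft(Fb * Conj(Fa), inverse = TRUE))
  k <- which.max(cc)
  nr <- nrow(a); nc <- ncol(a)
  dy <- (k - 1) %% nr
  dx <- (k - 1) %/% nr
  if (dy >= nr / 2) dy <- dy - nr
  if (dx >= nc / 2) dx <- dx - nc
  c(dy, dx)
}

#' Rigid drift correction
#'
#' Estimates per-step integer (drow, dcol) offsets between consecutive
#' frames by cross-correlation of the frames masked to pixels >=
#' `drift_min_grey` (others zeroed), clamps each step component to
#' +/- `drift_max_shift`, accumulates the steps into a drift path and
#' translates every frame back to the first frame's reference (zero
#' fill).  Integer-pixel only (no subpixel registration).
#'
#' @param movie an [fa_movie()].
#' @param params a [dynamics_params()].
#' @return list: `movie` (corrected), `offsets` (data.frame per frame:
#'   `frame` 0-based, `drow_step`, `dcol_step`, `drow`, `dcol`
#'   cumulative).
#' @export
correct_drift <- function(movie, params = dynamics_params()) {
  stopifnot(inherits(movie, "fa_movie"))
  nf <- length(movie$frames)
  steps <- matrix(0, nf, 2)
  for (f in 2:nf) {
    a <- movie$frames[[f - 1]]; b <- movie$frames[[f]]
    am <- a * (a >= params$drift_min_grey)
    bm <- b * (b >= params$drift_min_grey)
    if (all(am == 0) || all(bm == 0)) {
      warning(sprintf("frame %d has no pixels >= %g: zero offset", f - 1,
                      params$drift_min_grey))
      next
    }
    s <- xcorr_shift(am, bm)
    steps[f, ] <- pmax(pmin(s, params$drift_max_shift),
                       -params$drift_max_shift)
  }
  cum <- apply(steps, 2, cumsum)
  frames <- vector("list", nf)
  for (f in seq_len(nf))
    frames[[f]] <- .cpp_translate_int(movie$frames[[f]],
                                      as.integer(-cum[f, 1]),
                                      as.integer(-cum[f, 2]), 0)
  nr <- nrow(movie$frames[[1]]); nc <- ncol(movie$frames[[1]])
  valid <- c(r0 = max(1, 1 - min(cum[, 1])), r1 = min(nr, nr - max(cum[, 1])),
             c0 = max(1, 1 - min(cum[, 2])), c1 = min(nc, nc - max(cum[, 2])))
  list(movie = fa_movie(frames, movie$frame_interval),
       offsets = data.frame(frame = seq_len(nf) - 1L,
                            drow_step = steps[, 1], dcol_step = steps[, 2],
                            drow = cum[, 1], dcol = cum[, 2]),
       valid_bbox = valid)
}

#' Crop a movie to a bounding box
#'
#' Typical use: crop a drift-corrected movie to its `valid_bbox` (the
#' region covered by every frame) to discard the black padding the
#' translation introduced, before auto-cropping and tracking.
#'
#' @param movie an [fa_movie()].
#' @param bbox named vector (r0, r1, c0, c1), 1-based inclusive.
#' @return cropped [fa_movie()].
#' @export
crop_movie <- function(movie, bbox) {
  stopifnot(inherits(movie, "fa_movie"), bbox["r0"] <= bbox["r1"],
            bbox["c0"] <= bbox["c1"])
  fa_movie(lapply(movie$frames, function(fr)
    fr[bbox["r0"]:bbox["r1"], bbox["c0"]:bbox["c1"], drop = FALSE]),
    movie$frame_interval)
}

#' Auto-crop a movie to its cell footprint
#'
#' Maximum-intensity projection, Gaussian blur (`crop_blur`), Triangle
#' threshold, hole filling, keep the largest 8-connected component, then
#' crop all frames to that component's bounding box.  An empty mask
#' returns the movie uncropped with a warning.
#'
#' @param movie an [fa_movie()] (drift-corrected).
#' @param params a [dynamics_params()].
#' @return list: `movie` (cropped), `bbox` (r0, r1, c0, c1; 1-based,
#'   inclusive).
#' @export
autocrop <- function(movie, params = dynamics_params()) {
  stopifnot(inherits(movie, "fa_movie"))
  mp <- Reduce(pmax, movie$frames)
  sm <- gaussian_blur(mp, params$crop_blur)
  thr <- suppressWarnings(triangle_threshold(sm))
  mask <- if (is.na(thr)) matrix(FALSE, nrow(sm), ncol(sm)) else sm > thr
  if (!any(mask)) {
    warning("auto-crop mask is empty: movie returned uncropped")
    return(list(movie = movie,
                bbox = c(r0 = 1L, r1 = nrow(sm), c0 = 1L, c1 = ncol(sm))))
  }
  lab <- label_components(fill_holes(mask), connectivity = 8L)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  sel <- which(lab == big, arr.ind = TRUE)
  r0 <- min(sel[, 1]); r1 <- max(sel[, 1])
  c0 <- min(sel[, 2]); c1 <- max(sel[, 2])
  frames <- lapply(movie$frames, function(fr) fr[r0:r1, c0:c1, drop = FALSE])
  list(movie = fa_movie(frames, movie$frame_interval),
       bbox = c(r0 = r0, r1 = r1, c0 = c0, c1 = c1))
}

# segment one frame: DoG high-pass, then threshold at background median +
# seg_threshold_sd * background SD (MAD-based, robust to the sparse bright
# foreground); components below min_fa_size are dropped.
segment_frame <- function(frame, params) {
  hp <- dog_filter(frame, params$dog_small, params$dog_large)
  bg_mid <- median(hp)
  bg_sd <- mad(hp)
  thr <- bg_mid + params$seg_threshold_sd * bg_sd
  lab <- label_components(hp > thr, connectivity = 8L)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_fa_size)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      keep <- which(sizes >= params$min_fa_size)
      map <- integer(length(sizes)); map[keep] <- seq_along(keep)
      lab[lab > 0] <- map[lab[lab > 0]]
    }
  }
  lab
}

#' Track focal adhesions through a movie
#'
#' Per frame, the foreground is the difference-of-Gaussians high-pass of
#' the frame thresholded at background + `seg_threshold_sd` background SDs
#' (median/MAD background estimate); components smaller than `min_fa_size`
#' are dropped.  Objects are linked between consecutive frames by pixel
#' overlap: a track continues onto the overlapping object that is mutually
#' largest (by object area, ties to the lower label).  Many-to-one
#' overlaps are merges: the larger predecessor survives, the others end
#' `into_merge`.  One-to-many overlaps with FA splitting off keep the
#' parent on the largest fragment; remaining fragments start new tracks
#' flagged `from_split`.  Zero-overlap objects start tracks with origin
#' `birth` (or `first_frame` in frame 0); there is no gap closing.
#'
#' Per-object mean intensity is measured on the raw frame after
#' subtracting the frame median (an offset-free background reference).
#' For kinetics it is re-measured over a fixed per-track reference region
#' (the track's largest segmented footprint) so that the
#' threshold-dependent size of the per-frame region cannot bend the
#' log-intensity slope; per-frame `area` still reports the segmented
#' region.
#'
#' @param movie an [fa_movie()] (drift-corrected).
#' @param params a [dynamics_params()].
#' @return list of class `fa_tracks`: `tracks` (per-track data.frame:
#'   `track_id`, `start_frame`, `end_frame`, `origin`, `end`), `obs`
#'   (long data.frame: `track_id`, `frame`, `area`, `mean_intensity`,
#'   `centroid_row`, `centroid_col`), `n_frames`.
#' @export
track_fas <- function(movie, params = dynamics_params()) {
  stopifnot(inherits(movie, "fa_movie"))
  nf <- length(movie$frames)
  tracks <- data.frame(track_id = integer(), start_frame = integer(),
                       end_frame = integer(), origin = character(),
                       end = character(), stringsAsFactors = FALSE)
  obs <- list()
  pix_by_frame <- vector("list", nf)       # per frame: label -> pixel idx
  next_id <- 0L
  prev_lab <- NULL
  prev_track_of <- integer(0)   # label -> track id in previous frame
  prev_area <- integer(0)
  for (f in seq_len(nf)) {
    fr0 <- f - 1L
    lab <- segment_frame(movie$frames[[f]], params)
    n_obj <- max(lab)
    raw <- movie$frames[[f]]
    props <- if (n_obj > 0)
      region_props(lab, intensity = raw - median(raw)) else NULL
    track_of <- integer(n_obj)
    if (n_obj > 0) {
      if (!is.null(prev_lab) && length(prev_track_of)) {
        both <- prev_lab > 0 & lab > 0
        if (any(both)) {
          ov <- table(prev = prev_lab[both], cur = lab[both])
          prev_ids <- as.integer(rownames(ov))
          cur_ids <- as.integer(colnames(ov))
          cur_area <- props$area
          # main predecessor of each current object: overlapping
          # predecessor with the largest area (ties: lower label)
          main_pred <- sapply(seq_along(cur_ids), function(j) {
            cand <- prev_ids[ov[, j] > 0]
            if (!length(cand)) return(NA_integer_)
            cand[order(-prev_area[cand], cand)][1]
          })
          # main successor of each predecessor: overlapping current
          # object with the largest area (ties: lower label)
          main_succ <- sapply(seq_along(prev_ids), function(i) {
            cand <- cur_ids[ov[i, ] > 0]
            if (!length(cand)) return(NA_integer_)
            cand[order(-cur_area[cand], cand)][1]
          })
          for (j in seq_along(cur_ids)) {
            p <- main_pred[j]
            if (!is.na(p) && !is.na(main_succ[match(p, prev_ids)]) &&
                main_succ[match(p, prev_ids)] == cur_ids[j]) {
              track_of[cur_ids[j]] <- prev_track_of[p]   # continuation
            } else if (!is.na(p)) {
              # fragment of a split: new track
              next_id <- next_id + 1L
              tracks <- rbind(tracks, data.frame(
                track_id = next_id, start_frame = fr0, end_frame = fr0,
                origin = "from_split", end = "last_frame",
                stringsAsFactors = FALSE))
              track_of[cur_ids[j]] <- next_id
            }
          }
          # predecessors whose track did not continue: merged or died
          for (i in seq_along(prev_ids)) {
            tid <- prev_track_of[prev_ids[i]]
            if (!tid %in% track_of) {
              overlapped <- any(ov[i, ] > 0)
              tracks$end[tracks$track_id == tid] <-
                if (overlapped) "into_merge" else "death"
            }
          }
        }
      }
      # objects with no assigned track: births
      for (l in which(track_of == 0L)) {
        next_id <- next_id + 1L
        tracks <- rbind(tracks, data.frame(
          track_id = next_id, start_frame = fr0, end_frame = fr0,
          origin = if (fr0 == 0L) "first_frame" else "birth",
          end = "last_frame", stringsAsFactors = FALSE))
        track_of[l] <- next_id
      }
      tracks$end_frame[tracks$track_id %in% track_of] <- fr0
      obs[[f]] <- data.frame(track_id = track_of[props$label], frame = fr0,
                             label = props$label, area = props$area,
                             mean_intensity = props$mean_intensity,
                             centroid_row = props$centroid_row,
                             centroid_col = props$centroid_col)
      fg <- lab > 0
      pix_by_frame[[f]] <- split(which(fg), lab[fg])
    }
    # tracks alive in the previous frame that vanished entirely
    if (!is.null(prev_lab) && length(prev_track_of)) {
      gone <- setdiff(prev_track_of, if (n_obj > 0) track_of else integer(0))
      for (tid in gone)
        if (tracks$end[tracks$track_id == tid] == "last_frame")
          tracks$end[tracks$track_id == tid] <- "death"
    }
    prev_lab <- lab
    prev_track_of <- track_of
    prev_area <- if (n_obj > 0) props$area else integer(0)
  }
  obs <- if (length(obs)) do.call(rbind, obs) else
    data.frame(track_id = integer(), frame = integer(), label = integer(),
               area = integer(), mean_intensity = numeric(),
               centroid_row = numeric(), centroid_col = numeric())
  rownames(obs) <- NULL
  # re-measure each track's mean intensity over a fixed reference region
  # (its largest segmented footprint): the threshold-dependent per-frame
  # region size then cannot bend the log-intensity slope
  frame_med <- vapply(movie$frames, median, numeric(1))
  for (tid in tracks$track_id) {
    rows <- which(obs$track_id == tid)
    ref <- rows[which.max(obs$area[rows])]
    roi <- pix_by_frame[[obs$frame[ref] + 1L]][[as.character(obs$label[ref])]]
    for (r in rows) {
      f <- obs$frame[r] + 1L
      obs$mean_intensity[r] <- mean(movie$frames[[f]][roi]) - frame_med[f]
    }
  }
  obs$label <- NULL
  structure(list(tracks = tracks, obs = obs, n_frames = nf),
            class = "fa_tracks")
}

#' @export
print.fa_tracks <- function(x, ...) {
  cat(sprintf("<fa_tracks: %d track(s) over %d frames>\n",
              nrow(x$tracks), x$n_frames))
  invisible(x)
}

#' Fit assembly and disassembly rates of one track
#'
#' The peak frame is the argmax of mean intensity (first on ties); the
#' assembly phase runs from the track start to the peak, the disassembly
#' phase from the peak to the end (both inclusive).  Each rate is the
#' least-squares slope of log mean intensity versus time in minutes over
#' its phase; both are reported as magnitudes (1/min).  A phase shorter
#' than `min_phase_frames` frames yields `NA`.
#'
#' @param track_obs one track's rows from the `obs` table of
#'   [track_fas()] (columns `frame`, `mean_intensity`).
#' @param frame_interval minutes per frame (default 2).
#' @param params a [dynamics_params()].
#' @return list: `assembly_rate`, `disassembly_rate` (1/min, NA when the
#'   phase is too short), `peak_frame`.
#' @export
fit_rates <- function(track_obs, frame_interval = 2,
                      params = dynamics_params()) {
  stopifnot(all(c("frame", "mean_intensity") %in% names(track_obs)))
  track_obs <- track_obs[order(track_obs$frame), , drop = FALSE]
  if (any(track_obs$mean_intensity <= 0))
    stop("non-positive mean intensities: log-slope undefined")
  if (var(track_obs$mean_intensity) == 0)  # constant track: flat phases
    return(list(assembly_rate = 0, disassembly_rate = 0,
                peak_frame = track_obs$frame[1]))
  pk <- which.max(track_obs$mean_intensity)
  t_min <- track_obs$frame * frame_interval
  logi <- log(track_obs$mean_intensity)
  phase_slope <- function(idx) {
    if (length(idx) < params$min_phase_frames) return(NA_real_)
    if (var(logi[idx]) == 0) return(0)
    unname(coef(lm(logi[idx] ~ t_min[idx]))[2])
  }
  asm <- phase_slope(seq_len(pk))
  dis <- phase_slope(pk:nrow(track_obs))
  list(assembly_rate = asm, disassembly_rate = abs(dis), peak_frame =
         track_obs$frame[pk])
}

#' Count novel FAs
#'
#' Novel FAs are tracks that begin after the first frame and do not stem
#' from a merge or split event, i.e. tracks with origin `birth` only
#' (tracks present in the first frame and `from_split` tracks are
#' filtered out; tracks created by a merge never exist as new tracks
#' under this linker).  Reports the total per movie and the mean number
#' of starting tracks per frame.
#'
#' @param tracks an `fa_tracks` object (or its `tracks` data.frame).
#' @param n_frames number of frames in the movie (taken from the object
#'   when omitted).
#' @return list: `total`, `per_frame_mean`.
#' @export
count_novel_fas <- function(tracks, n_frames = NULL) {
  tdf <- if (inherits(tracks, "fa_tracks")) tracks$tracks else tracks
  if (is.null(n_frames)) {
    if (!inherits(tracks, "fa_tracks"))
      stop("n_frames required when passing a bare track table")
    n_frames <- tracks$n_frames
  }
  total <- sum(tdf$origin == "birth")
  list(total = total, per_frame_mean = total / n_frames)
}

#' Per-movie dynamics summary
#'
#' Median assembly and disassembly rates over the tracks whose phases are
#' long enough to fit, plus the novel-FA statistics.
#'
#' @param tracks an `fa_tracks` object.
#' @param frame_interval minutes per frame (default 2).
#' @param params a [dynamics_params()].
#' @return data.frame with one row: `n_tracks`, `assembly_rate`,
#'   `disassembly_rate` (medians, 1/min), `novel_total`,
#'   `novel_per_frame`.
#' @export
summarize_dynamics <- function(tracks, frame_interval = 2,
                               params = dynamics_params()) {
  stopifnot(inherits(tracks, "fa_tracks"))
  asm <- dis <- numeric(0)
  for (tid in tracks$tracks$track_id) {
    to <- tracks$obs[tracks$obs$track_id == tid, , drop = FALSE]
    if (nrow(to) < 2 || any(to$mean_intensity <= 0)) next
    r <- fit_rates(to, frame_interval, params)
    if (!is.na(r$assembly_rate)) asm <- c(asm, r$assembly_rate)
    if (!is.na(r$disassembly_rate)) dis <- c(dis, r$disassembly_rate)
  }
  novel <- count_novel_fas(tracks)
  data.frame(n_tracks = nrow(tracks$tracks),
             assembly_rate = if (length(asm)) median(asm) else NA_real_,
             disassembly_rate = if (length(dis)) median(dis) else NA_real_,
             novel_total = novel$total,
             novel_per_frame = novel$per_frame_mean)
}
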