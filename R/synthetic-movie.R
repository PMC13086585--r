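# Synthetic eGFP-paxillin-style time-lapse generator: scheduled adhesion
# birth/growth/decay/death with log-linear intensity kinetics, optional
# planted merges/splits and rigid drift.

bresenham <- function(p0, p1) {
  # integer line between two (row, col) points, inclusive
  d <- p1 - p0
  n <- max(abs(d), 1)
  t <- seq(0, 1, length.out = n + 1)
  unique(cbind(round(p0[1] + t * d[1]), round(p0[2] + t * d[2])))
}

dilate_px <- function(px, shape, r = 1L) {
  dr <- rep(-r:r, times = 2L * r + 1L)
  dc <- rep(-r:r, each = 2L * r + 1L)
  R <- outer(px[, 1], dr, "+")
  C <- outer(px[, 2], dc, "+")
  keep <- R >= 1 & R <= shape[1] & C >= 1 & C <= shape[2]
  idx <- unique((C[keep] - 1L) * shape[1] + R[keep])
  cbind((idx - 1L) %% shape[1] + 1L, (idx - 1L) %/% shape[1] + 1L)
}

#' Scheduled adhesion events for a synthetic movie
#'
#' Each row describes one adhesion: where it sits (`row`, `col`, ellipse
#' `area`/`ratio`/`theta`), when it exists (`birth`, `peak`, `death`,
#' 0-based frame indices, inclusive), and its kinetics: the noiseless mean
#' intensity at frame f is `peak_intensity * exp(assembly_rate * (t_f -
#' t_peak))` during assembly (so it rises towards the peak) and
#' `peak_intensity * exp(-disassembly_rate * (t_f - t_peak))` during
#' disassembly, with rates in 1/min.
#'
#' @param birth,peak,death frame indices (vectors, recycled).
#' @param assembly_rate,disassembly_rate per-minute log-slopes (>= 0).
#' @param peak_intensity plateau intensity above background.
#' @param row,col footprint centres.
#' @param area,ratio,theta footprint ellipse parameters.
#' @return data.frame of events with an `id` column.
#' @export
movie_events <- function(birth, peak, death, assembly_rate = 0.05,
                         disassembly_rate = 0.03, peak_intensity = 1500,
                         row, col, area = 60, ratio = 1.5, theta = 0) {
  df <- data.frame(birth = birth, peak = peak, death = death,
                   assembly_rate = assembly_rate,
                   disassembly_rate = disassembly_rate,
                   peak_intensity = peak_intensity,
                   row = row, col = col, area = area, ratio = ratio,
                   theta = theta)
  df$id <- seq_len(nrow(df))
  if (any(df$birth > df$peak | df$peak > df$death))
    stop("need birth <= peak <= death for every event")
  df
}

#' Specification for a synthetic FA time-lapse movie
#'
#' Defaults emulate a 4-h TIRF acquisition at one frame every 2 min
#' (120 frames).  When `events` is `NULL` a random schedule is drawn:
#' `first_frame_fas` adhesions already present at t = 0 plus `n_births`
#' adhesions born during the movie, with assembly/disassembly log-slopes
#' around 0.03-0.08 per min (the order of magnitude reported for paxillin
#' adhesions).
#'
#' @param image_shape (rows, cols), default 128 x 128.
#' @param n_frames number of frames (default 120).
#' @param frame_interval minutes between frames (default 2).
#' @param events data.frame from [movie_events()], or `NULL` for random.
#' @param first_frame_fas adhesions present at t = 0 (random mode).
#' @param n_births adhesions born after t = 0 (random mode).
#' @param drift_path n_frames x 2 matrix of per-frame (drow, dcol) integer
#'   drift steps (first row must be 0); `NULL` = no drift.
#' @param drift_bound declared per-frame drift bound (default 20 px).
#' @param merges data.frame (`a`, `b`, `frame`): from `frame` on, events a
#'   and b are rendered as one bridged object with a's kinetics; b's own
#'   schedule ends at `frame - 1`.
#' @param splits data.frame (`id`, `frame`, `off_row`, `off_col`,
#'   `area2`): event `id` carries a bridged secondary lobe (offset by
#'   `off_row`/`off_col`, ellipse area `area2`) until `frame - 1`; from
#'   `frame` the bridge disappears and the two lobes separate.
#' @param background_level constant offset (default 10, below the 120-grey
#'   drift-mask floor).
#' @param noise_sd additive Gaussian noise (default 0).
#' @param bit_depth declared bit depth (default 16).
#' @param seed integer seed.
#' @return object of class `synth_movie_spec`.
#' @export
synth_movie_spec <- function(image_shape = c(128L, 128L), n_frames = 120L,
                             frame_interval = 2, events = NULL,
                             first_frame_fas = 3L, n_births = 6L,
                             drift_path = NULL, drift_bound = 20,
                             merges = NULL, splits = NULL,
                             background_level = 10, noise_sd = 0,
                             bit_depth = 16L, seed = 1L) {
  stopifnot(n_frames >= 2, frame_interval > 0)
  if (!is.null(drift_path)) {
    drift_path <- as.matrix(drift_path)
    stopifnot(nrow(drift_path) == n_frames, ncol(drift_path) == 2)
    if (any(abs(drift_path) > drift_bound))
      stop("drift step exceeds the declared bound")
    if (any(drift_path[1, ] != 0)) stop("first drift step must be (0, 0)")
  }
  structure(as.list(environment()), class = "synth_movie_spec")
}

event_intensity <- function(ev, frame, interval) {
  t <- (frame - ev$peak) * interval
  if (frame <= ev$peak) ev$peak_intensity * exp(ev$assembly_rate * t)
  else ev$peak_intensity * exp(-ev$disassembly_rate * t)
}

#' Generate a synthetic movie with ground truth
#'
#' Renders the scheduled events onto each frame (uniform intensity over the
#' footprint, exactly the scheduled kinetics before noise), applies the
#' rigid drift path as integer translation, then noise.  Concurrent events
#' with overlapping footprints are an error unless declared as a merge.
#'
#' @param spec a [synth_movie_spec()].
#' @return list with `movie` (an [fa_movie()]) and `truth` (event table,
#'   drift path with cumulative offsets, merge/split tables, expected novel
#'   birth count).
#' @export
make_movie <- function(spec) {
  stopifnot(inherits(spec, "synth_movie_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    nf <- spec$n_frames
    ev <- spec$events
    if (is.null(ev)) {
      n <- spec$first_frame_fas + spec$n_births
      birth <- c(rep(0L, spec$first_frame_fas),
                 sort(sample(1:(max(2, nf - 30)), spec$n_births,
                             replace = TRUE)))
      life <- pmin(nf - 1L - birth, round(runif(n, 30, 80)))
      peak <- birth + pmax(1L, round(life * runif(n, 0.3, 0.6)))
      death <- pmin(nf - 1L, birth + life)
      pos_r <- round(runif(n, 15, nr - 15))
      pos_c <- round(runif(n, 15, nc - 15))
      ev <- movie_events(birth, pmin(peak, death), death,
                         assembly_rate = runif(n, 0.03, 0.08),
                         disassembly_rate = runif(n, 0.02, 0.06),
                         peak_intensity = runif(n, 800, 2000),
                         row = pos_r, col = pos_c,
                         area = round(runif(n, 40, 90)),
                         ratio = runif(n, 1.2, 2.5),
                         theta = runif(n, 0, pi))
    }
    if (any(ev$birth < 0 | ev$death >= nf))
      stop("event frames must lie within [0, n_frames)")
    # footprints
    fp <- lapply(seq_len(nrow(ev)), function(i)
      raster_ellipse(c(ev$row[i], ev$col[i]), ev$area[i], ev$ratio[i],
                     ev$theta[i], c(nr, nc)))
    merges <- spec$merges
    splits <- spec$splits
    merge_partner <- function(i) {
      if (is.null(merges)) return(integer(0))
      c(merges$b[merges$a == i], merges$a[merges$b == i])
    }
    # overlap validation (2-px separation unless a declared merge pair)
    if (nrow(ev) > 1) {
      occ <- matrix(0L, nr, nc)
      for (i in seq_len(nrow(ev))) {
        px <- dilate_px(fp[[i]], c(nr, nc), 1L)
        prev <- unique(occ[px]); prev <- prev[prev > 0]
        bad <- setdiff(prev, merge_partner(i))
        if (length(bad))
          stop(sprintf("events %d and %d overlap without a declared merge",
                       bad[1], ev$id[i]))
        occ[fp[[i]]] <- ev$id[i]
      }
    }
    # split lobes and bridges
    split_fp <- list()
    if (!is.null(splits)) for (s in seq_len(nrow(splits))) {
      i <- splits$id[s]
      ctr2 <- c(ev$row[i] + splits$off_row[s], ev$col[i] + splits$off_col[s])
      lobe2 <- raster_ellipse(ctr2, splits$area2[s], 1.2, 0, c(nr, nc))
      bridge <- dilate_px(bresenham(c(ev$row[i], ev$col[i]), ctr2),
                          c(nr, nc), 1L)
      split_fp[[s]] <- list(lobe2 = lobe2, bridge = bridge)
    }
    # drift: cumulative offsets
    steps <- if (is.null(spec$drift_path)) matrix(0L, nf, 2)
             else spec$drift_path
    cum <- apply(steps, 2, cumsum)
    frames <- vector("list", nf)
    maxval <- 2^spec$bit_depth - 1
    for (f in seq_len(nf)) {
      fr0 <- f - 1L                       # 0-based frame index
      img <- matrix(spec$background_level, nr, nc)
      paint <- function(px, val) {
        if (!nrow(px)) return()
        px2 <- cbind(px[, 1] + cum[f, 1], px[, 2] + cum[f, 2])
        keep <- px2[, 1] >= 1 & px2[, 1] <= nr & px2[, 2] >= 1 & px2[, 2] <= nc
        img[px2[keep, , drop = FALSE]] <<- spec$background_level + val
      }
      for (i in seq_len(nrow(ev))) {
        # merged-away partner: schedule truncated at the merge frame
        dies_into <- if (!is.null(merges)) merges$frame[merges$b == i] else numeric(0)
        last <- if (length(dies_into)) min(ev$death[i], dies_into[1] - 1L)
                else ev$death[i]
        alive <- fr0 >= ev$birth[i] && fr0 <= last
        val <- if (alive) event_intensity(ev[i, ], fr0, spec$frame_interval)
        if (alive) {
          paint(fp[[i]], val)
          # absorbed partners and bridge, painted with the survivor's value
          if (!is.null(merges)) {
            mm <- which(merges$a == i & merges$frame <= fr0)
            for (m in mm) {
              j <- merges$b[m]
              paint(fp[[j]], val)
              paint(dilate_px(bresenham(c(ev$row[i], ev$col[i]),
                                        c(ev$row[j], ev$col[j])),
                              c(nr, nc), 1L), val)
            }
          }
          if (!is.null(splits)) {
            ss <- which(splits$id == i)
            for (s in ss) {
              paint(split_fp[[s]]$lobe2, val)
              if (fr0 < splits$frame[s]) paint(split_fp[[s]]$bridge, val)
            }
          }
        }
      }
      if (spec$noise_sd > 0) img <- img + rnorm(length(img), 0, spec$noise_sd)
      img[img < 0] <- 0; img[img > maxval] <- maxval
      frames[[f]] <- img
    }
    movie <- fa_movie(frames, spec$frame_interval)
    merged_b <- if (!is.null(merges)) merges$b else integer(0)
    split_ids <- if (!is.null(splits)) splits$id else integer(0)
    truth <- list(events = ev,
                  footprint_areas = vapply(fp, nrow, integer(1)),
                  drift_steps = steps, drift_cum = cum,
                  merges = merges, splits = splits,
                  n_first_frame = sum(ev$birth == 0),
                  n_novel = sum(ev$birth > 0))
    list(movie = movie, truth = truth)
  })
}
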