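# Time-lapse dynamics: drift, cropping, tracking, kinetics, novel FAs.

test_that("drift correction recovers planted paths exactly and clamps", {
  ev <- movie_events(0, 6, 11, row = 70, col = 60, area = 80,
                     peak_intensity = 2000)
  dp <- matrix(0L, 12, 2); dp[2:12, 1] <- 3L; dp[2:12, 2] <- -2L
  mv <- make_movie(synth_movie_spec(n_frames = 12, events = ev,
                                    drift_path = dp, seed = 2))
  dc <- correct_drift(mv$movie)
  expect_equal(dc$offsets$drow_step[-1], rep(3, 11))
  expect_equal(dc$offsets$dcol_step[-1], rep(-2, 11))
  expect_equal(dc$offsets$drow, cumsum(c(0, rep(3, 11))))
  # static movie: all offsets zero
  mv0 <- make_movie(synth_movie_spec(n_frames = 6, events =
    movie_events(0, 3, 5, row = 60, col = 60, area = 80,
                 peak_intensity = 2000), seed = 3))
  dc0 <- correct_drift(mv0$movie)
  expect_true(all(dc0$offsets$drow == 0 & dc0$offsets$dcol == 0))
  # one oversized step is clamped at the configured maximum
  dp2 <- matrix(0L, 3, 2); dp2[2, 1] <- 18L
  mv2 <- make_movie(synth_movie_spec(n_frames = 3, events =
    movie_events(0, 1, 2, row = 60, col = 60, area = 80,
                 peak_intensity = 2000), drift_path = dp2, seed = 4))
  dc2 <- correct_drift(mv2$movie, dynamics_params(drift_max_shift = 10))
  expect_equal(dc2$offsets$drow_step[2], 10)
  # frames with nothing above the grey floor warn and get zero offset
  dim_movie <- fa_movie(list(matrix(50, 40, 40), matrix(50, 40, 40)))
  expect_warning(dcd <- correct_drift(dim_movie), "no pixels")
  expect_equal(dcd$offsets$drow_step[2], 0)
})

test_that("autocrop keeps the largest blurred component's bounding box", {
  # one bright block in the corner of a large dark field
  fr <- lapply(1:4, function(i) {
    m <- matrix(5, 200, 200); m[20:60, 20:70] <- 900; m
  })
  ac <- autocrop(fa_movie(fr))
  expect_true(ac$bbox["r0"] < 20 && ac$bbox["r1"] > 60)
  expect_true(ac$bbox["r1"] < 140)               # tight: far side excluded
  expect_true(ac$bbox["c1"] < 150)
  # two components, one much larger: box bounds only the larger
  fr2 <- lapply(1:4, function(i) {
    m <- matrix(5, 220, 220)
    m[20:100, 20:100] <- 900                     # large
    m[190:200, 190:200] <- 900                   # small
    m
  })
  ac2 <- autocrop(fa_movie(fr2))
  expect_true(ac2$bbox["r1"] < 180 && ac2$bbox["c1"] < 180)
  # blank movie: uncropped with a warning
  blank <- fa_movie(list(matrix(7, 64, 64), matrix(7, 64, 64)))
  expect_warning(ac3 <- autocrop(blank), "empty")
  expect_equal(unname(ac3$bbox), c(1, 64, 1, 64))
})

test_that("tracking: single object, size floor, origins and ends", {
  ev <- movie_events(10, 30, 60, row = 50, col = 50, area = 60,
                     peak_intensity = 1500)
  mv <- make_movie(synth_movie_spec(image_shape = c(100L, 100L),
                                    n_frames = 70, events = ev, seed = 5))
  tr <- track_fas(mv$movie)
  expect_equal(nrow(tr$tracks), 1L)
  expect_equal(tr$tracks$origin, "birth")
  expect_equal(tr$tracks$start_frame, 10L)
  expect_equal(tr$tracks$end_frame, 60L)
  expect_equal(tr$tracks$end, "death")
  # contiguous frame range
  frames <- sort(tr$obs$frame[tr$obs$track_id == 1])
  expect_equal(frames, 10:60)
  # every foreground pixel belongs to one track per frame: areas positive
  expect_true(all(tr$obs$area >= 10))
  # an 8-px speck never tracks (below the ten-pixel floor)
  sp <- movie_events(0, 5, 19, row = 50, col = 50, area = 8, ratio = 1,
                     peak_intensity = 1500)
  mvs <- make_movie(synth_movie_spec(image_shape = c(100L, 100L),
                                     n_frames = 20, events = sp, seed = 6))
  # the rendered footprint is ~8 px; the DoG core is smaller still
  expect_lt(mvs$truth$footprint_areas[1], 10)
  trs <- track_fas(mvs$movie)
  expect_equal(nrow(trs$tracks), 0L)
})

test_that("merge linking matches the hand-enumerated fixture", {
  # two adhesions alive from frame 0; they merge at frame 15
  ev <- movie_events(birth = c(0, 0), peak = c(10, 10), death = c(39, 39),
                     row = c(50, 50), col = c(40, 58),
                     area = c(120, 60), peak_intensity = c(1800, 1500))
  merges <- data.frame(a = 1L, b = 2L, frame = 15L)
  mv <- make_movie(synth_movie_spec(image_shape = c(100L, 100L),
                                    n_frames = 40, events = ev,
                                    merges = merges, seed = 7))
  tr <- track_fas(mv$movie)
  expect_equal(nrow(tr$tracks), 2L)
  # hand enumeration: both tracks start in frame 0; from frame 15 one
  # object overlaps both; the larger predecessor (track of event 1)
  # survives, the smaller ends into_merge at frame 14
  big <- tr$tracks[which.max(tr$tracks$end_frame), ]
  small <- tr$tracks[which.min(tr$tracks$end_frame), ]
  expect_equal(big$end_frame, 39L)
  expect_equal(small$end_frame, 14L)
  expect_equal(small$end, "into_merge")
  expect_equal(big$origin, "first_frame")
  expect_equal(small$origin, "first_frame")
  # per-frame object count: 2 before the merge, 1 after
  n_at <- function(f) length(unique(tr$obs$track_id[tr$obs$frame == f]))
  expect_equal(n_at(5), 2L)
  expect_equal(n_at(20), 1L)
})

test_that("split linking: parent keeps the largest fragment", {
  ev <- movie_events(0, 10, 39, row = 50, col = 50, area = 150,
                     peak_intensity = 1800)
  splits <- data.frame(id = 1L, frame = 20L, off_row = 0L, off_col = 22L,
                       area2 = 50)
  mv <- make_movie(synth_movie_spec(image_shape = c(100L, 100L),
                                    n_frames = 40, events = ev,
                                    splits = splits, seed = 8))
  tr <- track_fas(mv$movie)
  expect_equal(nrow(tr$tracks), 2L)
  parent <- tr$tracks[tr$tracks$origin == "first_frame", ]
  frag <- tr$tracks[tr$tracks$origin == "from_split", ]
  expect_equal(nrow(parent), 1L)
  expect_equal(nrow(frag), 1L)
  expect_equal(frag$start_frame, 20L)
  expect_equal(parent$end_frame, 39L)
  # the parent's post-split area is the larger fragment
  a_parent <- tr$obs$area[tr$obs$track_id == parent$track_id &
                          tr$obs$frame == 25]
  a_frag <- tr$obs$area[tr$obs$track_id == frag$track_id &
                        tr$obs$frame == 25]
  expect_gt(a_parent, a_frag)
})

test_that("rate fitting recovers planted exponentials", {
  # direct synthetic track: 100*exp(0.05 t) up, then decay at 0.03
  frames <- 0:59
  t_min <- frames * 2
  peak_t <- 60
  inten <- ifelse(t_min <= peak_t, 100 * exp(0.05 * (t_min - peak_t)),
                  100 * exp(-0.03 * (t_min - peak_t)))
  to <- data.frame(frame = frames, mean_intensity = inten)
  r <- fit_rates(to, frame_interval = 2)
  expect_equal(r$assembly_rate, 0.05, tolerance = 1e-9)
  expect_equal(r$disassembly_rate, 0.03, tolerance = 1e-9)
  # constant track: both rates zero
  rc <- fit_rates(data.frame(frame = 0:19, mean_intensity = 500), 2)
  expect_equal(rc$assembly_rate, 0)
  expect_equal(rc$disassembly_rate, 0)
  # too-short phases yield NA
  rs <- fit_rates(data.frame(frame = 0:5, mean_intensity = c(1, 2, 4, 8, 4, 2)),
                  2, dynamics_params(min_phase_frames = 5))
  expect_true(is.na(rs$assembly_rate))
  # non-positive intensity errors
  expect_error(fit_rates(data.frame(frame = 0:9,
                                    mean_intensity = c(rep(5, 9), 0)), 2),
               "non-positive")
})

test_that("rates recovered < 5% error at SNR >= 10 through the full pipeline", {
  # SNR 10 = peak over noise SD; the camera offset (600) sits 4 sigma
  # above zero so the 16-bit clip cannot rectify the noise
  set.seed(99)
  for (s in 1:3) {
    a_true <- runif(1, 0.035, 0.06)
    d_true <- runif(1, 0.025, 0.045)
    ev <- movie_events(0, 12, 42, assembly_rate = a_true,
                       disassembly_rate = d_true, peak_intensity = 1500,
                       row = 50, col = 50, area = 80)
    mv <- make_movie(synth_movie_spec(image_shape = c(100L, 100L),
                                      n_frames = 48, events = ev,
                                      background_level = 600,
                                      noise_sd = 150, seed = 40 + s))
    tr <- track_fas(mv$movie)
    main <- tr$tracks$track_id[which.max(
      tapply(tr$obs$area, tr$obs$track_id, sum)[as.character(tr$tracks$track_id)])]
    to <- tr$obs[tr$obs$track_id == main, ]
    r <- fit_rates(to, 2)
    expect_lt(abs(r$assembly_rate - a_true) / a_true, 0.05)
    expect_lt(abs(r$disassembly_rate - d_true) / d_true, 0.05)
  }
})

test_that("novel-FA counting filters first-frame and split/merge tracks", {
  tdf <- data.frame(track_id = 1:5, start_frame = c(0, 0, 12, 20, 30),
                    end_frame = 40,
                    origin = c("first_frame", "first_frame", "from_split",
                               "birth", "birth"),
                    end = "last_frame")
  cn <- count_novel_fas(tdf, n_frames = 100)
  expect_equal(cn$total, 2L)
  expect_equal(cn$per_frame_mean, 0.02)
  # all first-frame: zero
  tdf2 <- tdf; tdf2$origin <- "first_frame"
  expect_equal(count_novel_fas(tdf2, 100)$total, 0L)
  # invariant under track-id relabelling
  tdf3 <- tdf; tdf3$track_id <- c(9, 3, 7, 1, 5)
  expect_equal(count_novel_fas(tdf3, 100)$total, 2L)
})

test_that("scheduled births are recovered as novel FAs", {
  set.seed(2)
  ms <- synth_movie_spec(image_shape = c(160L, 160L), n_frames = 60,
                         first_frame_fas = 3L, n_births = 6L, seed = 17)
  mv <- make_movie(ms)
  tr <- track_fas(mv$movie)
  cn <- count_novel_fas(tr)
  expect_equal(cn$total, mv$truth$n_novel)
  expect_equal(sum(tr$tracks$origin == "first_frame"),
               mv$truth$n_first_frame)
})

test_that("drift correction + valid-crop preserves tracking results", {
  ev <- movie_events(c(0, 5), c(6, 10), c(11, 11),
                     row = c(70, 40), col = c(60, 75),
                     area = c(80, 50), peak_intensity = c(2000, 1500))
  dp <- matrix(0L, 12, 2); dp[2:12, 1] <- 3L; dp[2:12, 2] <- -2L
  mvD <- make_movie(synth_movie_spec(n_frames = 12, events = ev,
                                     drift_path = dp, seed = 2))
  mv0 <- make_movie(synth_movie_spec(n_frames = 12, events = ev, seed = 2))
  dc <- correct_drift(mvD$movie)
  trA <- track_fas(autocrop(crop_movie(dc$movie, dc$valid_bbox))$movie)
  trB <- track_fas(autocrop(mv0$movie)$movie)
  expect_equal(nrow(trA$tracks), nrow(trB$tracks))
  expect_equal(trA$tracks$start_frame, trB$tracks$start_frame)
  expect_equal(trA$tracks$end_frame, trB$tracks$end_frame)
  expect_equal(trA$tracks$origin, trB$tracks$origin)
})
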