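# The synthetic generators: bookkeeping, determinism and the planted-truth
# invariants every downstream test relies on.

test_that("empty field is constant at background level", {
  spec <- synth_field_spec(n_nuclei = 0L, noise_sd = 0, seed = 1)
  mf <- make_field(spec)
  expect_equal(mf$field$channels$nucleus, matrix(200, 256, 256))
  expect_equal(mf$field$channels$fa, matrix(200, 256, 256))
  expect_equal(mf$truth$n_fas, 0L)
  expect_equal(mf$truth$n_nuclei, 0L)
})

test_that("field ground truth is exact bookkeeping", {
  spec <- synth_field_spec(n_nuclei = 4L,
                           n_fas_per_cell = list(mean = 10, dispersion = Inf),
                           seed = 3)
  mf <- make_field(spec)
  expect_equal(mf$truth$n_nuclei, 4L)
  expect_equal(mf$truth$n_fas, 40L)
  expect_equal(length(mf$truth$fa_areas), 40L)
  expect_true(all(mf$truth$fa_areas >= 100 & mf$truth$fa_areas <= 400))
  expect_true(is.integer(mf$truth$fas$area))
})

test_that("same spec + same seed is bit-identical; different seed differs", {
  spec <- synth_field_spec(seed = 9, noise_sd = 25)
  a <- make_field(spec); b <- make_field(spec)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth$fa_areas, b$truth$fa_areas)
  spec2 <- synth_field_spec(seed = 10, noise_sd = 25)
  expect_false(identical(make_field(spec2)$field$channels,
                         a$field$channels))
})

test_that("planted footprints are pairwise disjoint and intensities in range", {
  for (s in c(2, 21)) {
    spec <- synth_field_spec(seed = s)
    mf <- make_field(spec)
    fa <- mf$field$channels$fa
    # noiseless FA channel: pixel counts at the plateau level must equal
    # the summed planted areas exactly (disjointness => no overpainting)
    expect_equal(sum(fa == 200 + 3000), sum(mf$truth$fa_areas))
    expect_true(all(fa >= 0 & fa <= 65535))
    expect_true(all(mf$field$channels$nucleus >= 0 &
                    mf$field$channels$nucleus <= 65535))
  }
})

test_that("impossible placement raises the field-too-crowded error", {
  spec <- synth_field_spec(image_shape = c(64L, 64L), n_nuclei = 6L, seed = 1)
  expect_error(make_field(spec), "too crowded")
})

test_that("plate generation honours roles and effect multipliers", {
  lay <- plate_layout(4, 4)
  expect_gte(sum(lay$role == "mock"), 2)
  expect_gte(sum(lay$role == "neg_ctrl"), 2)
  eff <- data.frame(gene = "GENE0001", count_mult = 3, area_mult = 1)
  spec <- synth_plate_spec(layout = lay, effect_model = eff,
                           fields_per_well = 1L,
                           base_field_spec = synth_field_spec(
                             n_nuclei = 3L,
                             n_fas_per_cell = list(mean = 5, dispersion = Inf)),
                           seed = 5)
  made <- make_plate(spec)
  tr <- made$truth
  # identity effect: unlisted genes have multiplier 1 and base counts
  base_rows <- tr$role == "sample" & tr$gene != "GENE0001"
  expect_true(all(tr$count_mult[base_rows] == 1))
  expect_true(all(tr$true_n_fas[base_rows] == 3 * 5))
  # planted 3x gene triples the true count by construction
  g1 <- tr[tr$gene == "GENE0001" & !is.na(tr$gene), ]
  expect_equal(g1$count_mult, 3)
  expect_equal(g1$true_n_fas, 3L * 3L * 5L)
  # death control stays below the 50-cell viability floor
  expect_true(all(tr$true_n_nuclei[tr$role == "death_ctrl"] < 50))
  # unknown role errors
  bad <- lay; bad$role[1] <- "mystery"
  expect_error(synth_plate_spec(layout = bad), "unknown role")
})

test_that("movie events follow the scheduled kinetics exactly before noise", {
  ev <- movie_events(birth = 10, peak = 30, death = 60,
                     assembly_rate = 0.05, disassembly_rate = 0.03,
                     peak_intensity = 100, row = 40, col = 40, area = 60)
  spec <- synth_movie_spec(image_shape = c(80L, 80L), n_frames = 70,
                           events = ev, background_level = 0, seed = 1)
  mv <- make_movie(spec)
  fp_area <- mv$truth$footprint_areas[1]
  # absent before birth
  expect_true(all(mv$movie$frames[[10]] == 0))
  # present from the birth frame (frame index 10 -> list element 11)
  expect_gt(sum(mv$movie$frames[[11]] > 0), 0)
  # assembly phase: mean over footprint equals peak*exp(r*(t - t_peak))
  for (f0 in c(10, 20, 30)) {
    fr <- mv$movie$frames[[f0 + 1]]
    expected <- 100 * exp(0.05 * (f0 - 30) * 2)
    expect_equal(sum(fr) / fp_area, expected, tolerance = 1e-9)
  }
  # disassembly phase
  fr <- mv$movie$frames[[51]]
  expect_equal(sum(fr) / fp_area, 100 * exp(-0.03 * (50 - 30) * 2),
               tolerance = 1e-9)
  # dead after death frame
  expect_true(all(mv$movie$frames[[62]] == 0))
  # zero assembly rate -> flat plateau during assembly
  ev0 <- movie_events(0, 20, 30, assembly_rate = 0, peak_intensity = 500,
                      row = 40, col = 40, area = 60)
  mv0 <- make_movie(synth_movie_spec(image_shape = c(80L, 80L), n_frames = 31,
                                     events = ev0, background_level = 0,
                                     seed = 1))
  m5 <- sum(mv0$movie$frames[[5]]) / mv0$truth$footprint_areas[1]
  m15 <- sum(mv0$movie$frames[[15]]) / mv0$truth$footprint_areas[1]
  expect_equal(m5, 500); expect_equal(m15, 500)
})

test_that("planted drift moves centroids and overlap validation fires", {
  dp <- matrix(0L, 6, 2); dp[2:6, 2] <- 5L       # +5 px/frame in x
  ev <- movie_events(0, 2, 5, row = 40, col = 20, area = 60,
                     peak_intensity = 1000)
  mv <- make_movie(synth_movie_spec(image_shape = c(80L, 80L), n_frames = 6,
                                    events = ev, drift_path = dp,
                                    background_level = 0, seed = 1))
  centroid_col <- function(fr) {
    w <- which(fr > 0, arr.ind = TRUE); mean(w[, 2])
  }
  c1 <- centroid_col(mv$movie$frames[[1]])
  for (f in 2:6)
    expect_equal(centroid_col(mv$movie$frames[[f]]) - c1, 5 * (f - 1))
  # overlapping concurrent events must be declared as a merge
  ev2 <- movie_events(c(0, 0), c(2, 2), c(5, 5), row = c(40, 41),
                      col = c(40, 42), area = 60, peak_intensity = 1000)
  expect_error(make_movie(synth_movie_spec(image_shape = c(80L, 80L),
                                           n_frames = 6, events = ev2,
                                           seed = 1)),
               "overlap")
  # drift beyond the declared bound is rejected
  bad <- matrix(0L, 6, 2); bad[3, 1] <- 25L
  expect_error(synth_movie_spec(n_frames = 6, drift_path = bad),
               "bound")
})

test_that("value-level plate simulator encodes roles and planted shifts", {
  lay <- plate_layout()
  pt <- simulate_plate_values(lay, planted = data.frame(
    gene = "GENE0007", shift_sd_count = 8, shift_sd_area = 0), seed = 2)
  expect_equal(nrow(pt), 384)
  expect_true(all(pt$cell_count[pt$role == "death_ctrl"] < 50))
  base <- pt$fas_per_cell[pt$role == "sample" & pt$gene != "GENE0007"]
  hit <- pt$fas_per_cell[pt$gene == "GENE0007" & !is.na(pt$gene)]
  expect_gt(hit, mean(base) + 5 * sd(base))
  expect_identical(pt, simulate_plate_values(lay, planted = data.frame(
    gene = "GENE0007", shift_sd_count = 8, shift_sd_area = 0), seed = 2))
})
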