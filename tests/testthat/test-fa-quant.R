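# FA segmentation and per-field quantification, both dialects.

test_that("mode presets pin the two dialects", {
  sc <- fa_quant_params("screen")
  expect_equal(c(sc$min_area, sc$max_area), c(50, 5000))
  expect_null(sc$circularity_range)
  expect_false(sc$edge_exclude_nuclei)
  pc <- fa_quant_params("percell")
  expect_equal(c(pc$min_area, pc$max_area), c(50, 500))
  expect_equal(pc$circularity_range, c(0, 0.95))
  expect_true(pc$edge_exclude_nuclei)
})

test_that("preprocessing flattens background and keeps objects", {
  img <- matrix(150, 64, 64)
  img[20:29, 20:35] <- 150 + 2000
  pre <- preprocess_fa_channel(img, fa_quant_params("screen"))
  expect_true(all(pre >= 0))
  expect_equal(dim(pre), c(64, 64))
  expect_lt(max(pre[1:10, 1:10]), 1)       # background removed
  expect_gt(pre[24, 27], 1500)             # object interior survives
  expect_error(preprocess_fa_channel(array(0, c(4, 4, 2))), "matrix")
})

test_that("segmentation size filter is inclusive at both bounds", {
  cases <- data.frame(h = c(7, 5, 20, 50),
                      w = c(7, 10, 25, 100),
                      mode = c("screen", "screen", "percell", "screen"),
                      kept = c(FALSE, TRUE, TRUE, TRUE))
  # areas: 49 removed / 50 kept / 500 kept (percell) / 5000 kept (screen);
  # the 5001-px case follows below
  for (i in 1:4) {
    img <- rect_image(max(60, cases$h[i] + 10), max(120, cases$w[i] + 10),
                      5, 5, cases$h[i], cases$w[i], 1000, bg = 0)
    seg <- segment_fas(img, fa_quant_params(cases$mode[i]))
    expect_equal(nrow(seg$records) == 1, cases$kept[i],
                 info = sprintf("area %d", cases$h[i] * cases$w[i]))
    if (cases$kept[i])
      expect_equal(seg$records$area, cases$h[i] * cases$w[i])
  }
  img <- rect_image(20, 1680, 5, 5, 3, 1667, 1000)
  expect_equal(nrow(segment_fas(img, fa_quant_params("screen"))$records), 0L)
})

test_that("two disks plus a sub-threshold speck give two records", {
  img <- matrix(0, 128, 128)
  img <- img + disc_image(128, 128, c(30, 30), 6, 1000)   # ~113 px
  img <- img + disc_image(128, 128, c(90, 90), 6, 1000)
  img[60:62, 60:63] <- 1000                               # 12-px speck
  seg <- segment_fas(img, fa_quant_params("screen"))
  expect_equal(nrow(seg$records), 2L)
  expect_true(all(seg$records$area > 100))
  # 600-px blob in percell mode exceeds the 500-px cap
  big <- disc_image(80, 80, c(40, 40), 14, 1000)          # ~615 px
  expect_gt(sum(big > 0), 500)
  expect_equal(nrow(segment_fas(big, fa_quant_params("percell"))$records), 0L)
  # blank image: zero records, degenerate-histogram warning
  expect_warning(seg0 <- segment_fas(matrix(0, 32, 32),
                                     fa_quant_params("screen")),
                 "degenerate")
  expect_equal(nrow(seg0$records), 0L)
})

test_that("circularity filter removes round objects when the cap demands", {
  img <- matrix(0, 128, 128)
  img <- img + disc_image(128, 128, c(30, 30), 8, 1000)   # round, ~200 px
  ell <- fascreenkit:::raster_ellipse(c(90, 90), 200, 3, 0.5, c(128, 128))
  img[ell] <- 1000                                        # elongated
  pr <- region_props(label_components(img > 500), perimeter = TRUE)
  cap <- mean(sort(pr$circularity))                       # between the two
  seg <- segment_fas(img, fa_quant_params("percell",
                                          circularity_range = c(0, cap)))
  expect_equal(nrow(seg$records), 1L)
  expect_lt(seg$records$circularity, cap)
})

test_that("nuclei counting: prominence, offset invariance, edge exclusion", {
  img <- gauss_blob(200, 200, c(50, 50), 8, 5000) +
         gauss_blob(200, 200, c(150, 60), 8, 5000) +
         gauss_blob(200, 200, c(100, 150), 8, 5000)
  p <- fa_quant_params("screen")
  expect_equal(count_nuclei(img, p), 3L)
  expect_equal(count_nuclei(img + 777, p), 3L)     # prominence is offset-free
  expect_equal(count_nuclei(matrix(0, 64, 64), p), 0L)
  # nucleus centred 2 px from the border: rejected with edge exclusion on
  edge <- gauss_blob(128, 128, c(3, 64), 8, 5000)
  expect_equal(count_nuclei(edge, fa_quant_params("percell")), 0L)
  expect_equal(count_nuclei(edge, p), 1L)
})

test_that("focus score: zero for constant, monotone under blur, window checks", {
  expect_equal(focus_score(matrix(42, 64, 64), 32), 0)
  chk <- matrix(rep(c(100, 900), length.out = 96 * 96), 96, 96)
  expect_gt(focus_score(chk, 32), focus_score(gaussian_blur(chk, 5), 32))
  expect_error(focus_score(chk, 200), "larger than image")
  expect_error(focus_score(chk, 1), ">= 2")
})

test_that("quantify_field: ratio, exclusions and QC flags", {
  # 4 nuclei x 10 FAs, noiseless -> fas_per_cell exactly 10
  mf <- make_field(synth_field_spec(n_nuclei = 4L, seed = 12))
  q <- quantify_field(mf$field, fa_quant_params("screen"))
  expect_equal(q$n_fas, 40L)
  expect_equal(q$n_nuclei, 4L)
  expect_equal(q$fas_per_cell, 10)
  expect_false(q$excluded)
  # two nuclei -> excluded as low_nuclei, no fas_per_cell value
  mf2 <- make_field(synth_field_spec(n_nuclei = 2L, seed = 13))
  q2 <- quantify_field(mf2$field, fa_quant_params("screen"))
  expect_true(q2$excluded)
  expect_true(unname(q2$qc["low_nuclei"]))
  expect_true(is.na(q2$fas_per_cell))
  # defocused field -> focus_fail at the 0.03 default
  mf3 <- make_field(synth_field_spec(seed = 14, noise_sd = 30,
                                     blur_sigma_px = 40))
  q3 <- quantify_field(mf3$field, fa_quant_params("screen"))
  expect_lt(q3$focus, 0.03)
  expect_true(unname(q3$qc["focus_fail"]))
  expect_true(q3$excluded)
  # missing channel errors by name
  f <- field_image(list(fa = matrix(0, 32, 32)), "w", "f")
  expect_error(quantify_field(f), "nucleus")
})

test_that("oversegmented fields are excluded above the 20,000 raw-object cap", {
  dots <- matrix(0, 300, 300)
  dots[seq(2, 299, 2), seq(2, 299, 2)] <- 2000   # 149^2 = 22,201 specks
  nuc <- matrix(100, 300, 300) +
    gauss_blob(300, 300, c(150, 150), 8, 4000) +
    gauss_blob(300, 300, c(80, 80), 8, 4000) +
    gauss_blob(300, 300, c(220, 90), 8, 4000)
  f <- field_image(list(fa = dots, nucleus = nuc), "w", "f")
  q <- quantify_field(f, fa_quant_params("screen", median_radius = 0,
                                         focus_window = 32))
  expect_gt(q$n_raw, 20000)
  expect_true(unname(q$qc["oversegmented"]))
  expect_true(q$excluded)
})

test_that("fas_per_cell scales linearly with FA count", {
  a <- make_field(synth_field_spec(
    n_fas_per_cell = list(mean = 5, dispersion = Inf), seed = 31))
  b <- make_field(synth_field_spec(
    n_fas_per_cell = list(mean = 10, dispersion = Inf), seed = 31))
  qa <- quantify_field(a$field)
  qb <- quantify_field(b$field)
  expect_equal(qb$fas_per_cell, 2 * qa$fas_per_cell)
})
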