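# Screening statistics: closed forms, arithmetic identities, hit-calling
# semantics and simulated-screen recovery.

test_that("zprime matches its closed form and invariances", {
  expect_equal(zprime(c(9, 10, 11), c(-1, 0, 1)), 1 - 6 / 10)
  expect_equal(zprime(rep(5, 3), rep(1, 3)), 1)          # zero-SD groups
  expect_error(zprime(c(1, 1), c(1, 1)), "separation undefined")
  expect_error(zprime(1, c(0, 1)), ">= 2")
  set.seed(4)
  a <- rnorm(8, 10); b <- rnorm(8, 2)
  expect_equal(zprime(a, b), zprime(b, a))               # symmetric
  expect_equal(zprime(3 * a + 7, 3 * b + 7), zprime(a, b))  # affine
  expect_lte(zprime(a, b), 1)
})

test_that("plate z-scores: definition, exact moments, error cases", {
  pt <- simulate_plate_values(seed = 6)
  z <- plate_zscores(pt, "fas_per_cell", "sample")
  s <- pt$role == "sample"
  expect_equal(mean(z$z[s]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[s]), 1, tolerance = 1e-12)
  # a non-reference well exactly at mu_ref / mu_ref + 2 sd_ref scores 0 / 2
  mu <- attr(z, "mu_ref"); s_ref <- attr(z, "sd_ref")
  i <- which(pt$role == "mock")[1:2]
  pt2 <- pt
  pt2$fas_per_cell[i] <- c(mu, mu + 2 * s_ref)
  z2 <- plate_zscores(pt2, "fas_per_cell", "sample")
  expect_equal(z2$z[i], c(0, 2))
  # excluded wells carry no score
  pt3 <- pt; pt3$excluded[2] <- TRUE
  expect_true(is.na(plate_zscores(pt3, "fas_per_cell")$z[2]))
  # zero reference SD errors
  pt4 <- pt; pt4$fas_per_cell[pt4$role == "sample"] <- 20
  expect_error(plate_zscores(pt4, "fas_per_cell"), "SD is zero")
  # mock reference is supported and recorded
  zm <- plate_zscores(pt, "fas_per_cell", "mock")
  expect_equal(attr(zm, "reference"), "mock")
})

test_that("hit calling: strict thresholds, viability, monotonicity", {
  zs <- data.frame(gene = c("a", "b", "c", "d"),
                   z_count = c(4.3, 0, 4.2, 9),
                   z_area = c(0, 3.6, 0, 0))
  cc <- c(a = 500, b = 500, c = 500, d = 40)
  h <- call_hits(zs, cell_counts = cc)
  expect_equal(h$hit, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(h$exclusion_reason, c("none", "none", "none", "viability"))
  # invariant: hit implies no exclusion reason
  expect_true(all(h$exclusion_reason[h$hit] == "none"))
  # boundary: z_area exactly 3.5 is not a hit
  hb <- call_hits(data.frame(gene = "x", z_count = 0, z_area = 3.5),
                  cell_counts = c(x = 100))
  expect_false(hb$hit)
  # exactly 50 cells passes viability
  h50 <- call_hits(data.frame(gene = "x", z_count = 5, z_area = 0),
                   cell_counts = c(x = 50))
  expect_true(h50$hit)
  # monotone: raising any z never un-calls a hit
  set.seed(8)
  zr <- data.frame(gene = sprintf("g%02d", 1:40),
                   z_count = rnorm(40, 2, 2), z_area = rnorm(40, 2, 2))
  ccr <- setNames(rep(300, 40), zr$gene)
  h1 <- call_hits(zr, cell_counts = ccr)
  zr2 <- zr; zr2$z_count <- zr2$z_count + abs(rnorm(40))
  h2 <- call_hits(zr2, cell_counts = ccr)
  expect_true(all(h2$hit[h1$hit]))
  # missing cell counts are an error, not an exclusion
  expect_error(call_hits(zs, cell_counts = c(a = 1, b = 1, c = 1)),
               "missing cell count")
  # artifact pass-through excludes
  za <- data.frame(gene = "x", z_count = 9, z_area = 0, artifact = TRUE)
  ha <- call_hits(za, cell_counts = c(x = 500))
  expect_false(ha$hit); expect_equal(ha$exclusion_reason, "artifact")
})

test_that("secondary confirmation averages mock-normalised folds, inclusive", {
  mk_rep <- function(folds_count, folds_area = 1) {
    data.frame(plate_id = "P", well_id = sprintf("w%d", seq_len(length(folds_count) + 2)),
               role = c(rep("sample", length(folds_count)), "mock", "mock"),
               gene = c(names(folds_count), NA, NA),
               fas_per_cell = c(10 * folds_count, 10, 10),
               fa_area_mean = c(rep(200 * folds_area,
                                    length.out = length(folds_count)), 200, 200),
               cell_count = 300, excluded_fields = 0L, excluded = FALSE,
               stringsAsFactors = FALSE)
  }
  r1 <- mk_rep(c(g1 = 1.4, g2 = 1.25, g3 = 1.0))
  r2 <- mk_rep(c(g1 = 1.2, g2 = 1.25, g3 = 1.0))
  sc <- secondary_confirm(r1, r2)
  expect_equal(sc$confirmed[sc$gene == "g1"], TRUE)    # mean 1.3, inclusive
  expect_equal(sc$confirmed[sc$gene == "g2"], FALSE)   # mean 1.25
  expect_equal(sc$confirmed[sc$gene == "g3"], FALSE)   # no effect
  # a gene missing in one replicate is reported unconfirmable
  r2b <- mk_rep(c(g1 = 1.2, g2 = 1.25))
  sc2 <- secondary_confirm(r1, r2b)
  expect_true("g3" %in% sc2$gene)
  expect_true(is.na(sc2$confirmed[sc2$gene == "g3"]))
})

test_that("a planted +8 SD gene recovers z in [6, 10] on one plate", {
  lay <- plate_layout(15, 22, control_cols = c(1, 22))
  pt <- simulate_plate_values(lay, planted = data.frame(
    gene = "GENE0042", shift_sd_count = 8, shift_sd_area = 0), seed = 77)
  z <- plate_zscores(pt, "fas_per_cell", "sample")
  zg <- z$z[z$gene == "GENE0042" & !is.na(z$gene)]
  expect_gt(zg, 6); expect_lt(zg, 10)
  h <- call_hits(
    data.frame(gene = z$gene[z$role == "sample"],
               z_count = z$z[z$role == "sample"], z_area = 0),
    cell_counts = setNames(pt$cell_count[pt$role == "sample"],
                           pt$gene[pt$role == "sample"]))
  expect_true(h$hit[h$gene == "GENE0042"])
})

test_that("screen_report composes Z', z-scores and hit calling", {
  lay <- plate_layout(8, 6)
  plates <- lapply(1:3, function(p)
    simulate_plate_values(lay, plate_id = sprintf("P%d", p), seed = 30 + p))
  rep <- screen_report(plates)
  expect_equal(nrow(rep$plate_qc), 3)
  for (p in 1:3) {
    expect_equal(rep$plate_qc$zprime[p],
                 zprime(plates[[p]]$fas_per_cell[plates[[p]]$role == "pos_ctrl"],
                        plates[[p]]$fas_per_cell[plates[[p]]$role == "mock"]))
    # planted positive controls sit above the mock mean on every plate
    expect_gt(mean(plates[[p]]$fas_per_cell[plates[[p]]$role == "pos_ctrl"]),
              mean(plates[[p]]$fas_per_cell[plates[[p]]$role == "mock"]))
  }
  expect_true(all(c("gene", "z_count", "z_area", "hit") %in%
                  names(rep$hit_table)))
})

test_that("null z>4.2 false positives match the Gaussian tail estimate", {
  # 10 plates x 300 sample wells; expected count 3000 * 1.33e-5 = 0.04,
  # so with overwhelming probability no null well exceeds 4.2
  lay <- plate_layout(15, 22, control_cols = c(1, 22))
  n_over <- 0L
  for (p in 1:10) {
    pt <- simulate_plate_values(lay, plate_id = sprintf("P%d", p),
                                seed = 500 + p)
    z <- plate_zscores(pt, "fas_per_cell", "sample")
    n_over <- n_over + sum(z$z[pt$role == "sample"] > 4.2)
  }
  expect_lte(n_over, 2L)
})
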