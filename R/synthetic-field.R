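# Synthetic microscopy generator: fields of cells with nuclear blobs and
# peripheral focal-adhesion puncta, with exactly known planted ground truth.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Specification for one synthetic imaging field
#'
#' Defaults describe a subconfluent field of adherent cells imaged at
#' 16-bit: a handful of well-separated nuclei (Gaussian blobs), each cell
#' carrying a ring of elliptical FA puncta near its periphery.  Planted FA
#' areas are drawn from a truncated normal bounded to `fa_area_px[c("min",
#' "max")]`; the default interval [100, 600] px sits well inside the
#' screen-mode size window [50, 5000] so that planted objects survive the
#' segmentation size filter even after the radius-2 median filter erodes
#' their boundary.
#'
#' @param image_shape integer (rows, cols); default 256 x 256.
#' @param n_nuclei number of cells/nuclei (default 5).
#' @param nucleus_radius_px Gaussian blob sigma in pixels (default 8).
#' @param nucleus_peak blob peak intensity above background (default 5000).
#' @param n_fas_per_cell list(mean, dispersion): per-cell FA count; a
#'   negative-binomial draw with size = dispersion, deterministic (= mean)
#'   when dispersion is `Inf` (default mean 10, dispersion Inf).
#' @param fa_area_px list(mean, sd, min, max): planted FA pixel area.
#' @param fa_axis_ratio range of ellipse axis ratios (default c(1.2, 3)).
#' @param fa_peak FA plateau intensity above background (default 3000).
#' @param fa_ring_px distance band from the nucleus centre where FAs are
#'   placed (default c(25, 60)).
#' @param background_level camera offset (default 200).
#' @param noise_sd additive Gaussian noise sigma (default 0 = noiseless).
#' @param shot_noise also apply Poisson shot noise (default FALSE).
#' @param blur_sigma_px whole-field defocus blur sigma (default 0 = sharp).
#' @param channels channels to emit; subset of nucleus, fa, actin.
#' @param cell_radius_px radius of the actin cell disc (default 30).
#' @param actin_level actin intensity above background (default 1500).
#' @param bit_depth declared bit depth (default 16).
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return object of class `synth_field_spec`.
#' @export
synth_field_spec <- function(image_shape = c(256L, 256L),
                             n_nuclei = 5L,
                             nucleus_radius_px = 8,
                             nucleus_peak = 5000,
                             n_fas_per_cell = list(mean = 10, dispersion = Inf),
                             fa_area_px = list(mean = 150, sd = 50,
                                               min = 100, max = 400),
                             fa_axis_ratio = c(1.2, 2.5),
                             fa_peak = 3000,
                             fa_ring_px = c(25, 80),
                             background_level = 200,
                             noise_sd = 0,
                             shot_noise = FALSE,
                             blur_sigma_px = 0,
                             channels = c("nucleus", "fa"),
                             cell_radius_px = 30,
                             actin_level = 1500,
                             bit_depth = 16L,
                             seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 32),
            n_nuclei >= 0, fa_area_px$min <= fa_area_px$max,
            background_level >= 0, noise_sd >= 0)
  spec <- as.list(environment())
  class(spec) <- "synth_field_spec"
  spec
}

# Pixel set of a filled rotated ellipse of the target area.  Returns an
# n x 2 matrix of 1-based (row, col) indices; may be empty if off-image.
raster_ellipse <- function(center, area, ratio, theta, shape) {
  a <- sqrt(area * ratio / pi)            # semi-major
  b <- sqrt(area / (pi * ratio))          # semi-minor
  h <- ceiling(a) + 1L
  rr <- (center[1] - h):(center[1] + h)
  cc <- (center[2] - h):(center[2] + h)
  g <- expand.grid(row = rr, col = cc)
  dy <- g$row - center[1]; dx <- g$col - center[2]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  px <- as.matrix(g[keep, , drop = FALSE])
  px[px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2], ,
     drop = FALSE]
}

raster_disc <- function(center, radius, shape) {
  h <- ceiling(radius)
  rr <- (center[1] - h):(center[1] + h)
  cc <- (center[2] - h):(center[2] + h)
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  px <- as.matrix(g[keep, , drop = FALSE])
  px[px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2], ,
     drop = FALSE]
}

# truncated-normal draw with bounded rejection
rtrunc_norm <- function(mean, sd, lo, hi, max_try = 200L) {
  for (i in seq_len(max_try)) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  runif(1, lo, hi)
}

draw_fa_count <- function(dist) {
  if (!is.finite(dist$dispersion)) return(as.integer(round(dist$mean)))
  # truncate the overdispersed tail at 3x the mean: rare extreme draws
  # exceed what the field geometry can place disjointly
  min(rnbinom(1, size = dist$dispersion, mu = dist$mean),
      ceiling(3 * dist$mean))
}

#' Generate one synthetic field with ground truth
#'
#' Plants `n_nuclei` Gaussian nuclear blobs and, per cell, a set of filled
#' elliptical FA puncta in a peripheral ring.  All planted footprints are
#' pairwise disjoint (a 5-px exclusion margin is enforced between objects
#' so downstream 8-connected segmentation cannot fuse them) and kept at
#' least 3 px from the image border.  The returned ground truth records the
#' exact integer pixel area of every planted object; it is emitted at
#' generation time and never re-measured from pixels.
#'
#' @param spec a [synth_field_spec()].
#' @param well_id,field_id identifiers stored on the field.
#' @return list with elements `field` (a [field_image()]) and `truth`
#'   (class `fa_ground_truth`: `n_nuclei`, `nuclei`, `n_fas`, `fas`,
#'   `fa_areas`).
#' @export
make_field <- function(spec, well_id = "A01", field_id = "f01") {
  stopifnot(inherits(spec, "synth_field_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    margin <- 3L
    gap <- 3L
    forbidden <- matrix(FALSE, nr, nc)
    stamp <- function(px, pad) {
      forbidden[dilate_px(px, c(nr, nc), pad)] <<- TRUE
    }
    # --- nuclei ---------------------------------------------------------
    sep <- 70
    centers <- matrix(numeric(0), 0, 2)
    bmar <- max(margin, ceiling(2 * spec$nucleus_radius_px) + 8L)
    if (spec$n_nuclei > 0) {
      if (nr - 2 * bmar < 1 || nc - 2 * bmar < 1)
        stop("field too crowded: image too small for requested objects")
      for (i in seq_len(spec$n_nuclei)) {
        ok <- FALSE
        for (try in 1:500) {
          cand <- c(sample(bmar:(nr - bmar), 1), sample(bmar:(nc - bmar), 1))
          if (nrow(centers) == 0 ||
              min(sqrt(rowSums((t(t(centers) - cand))^2))) >= sep) {
            centers <- rbind(centers, cand); ok <- TRUE; break
          }
        }
        if (!ok) stop("field too crowded: could not place all nuclei")
      }
      for (i in seq_len(nrow(centers)))
        stamp(raster_disc(centers[i, ], 2 * spec$nucleus_radius_px,
                          c(nr, nc)), gap)
    }
    # --- FAs ------------------------------------------------------------
    fas <- list()
    if (spec$n_nuclei > 0) {
      for (cell in seq_len(spec$n_nuclei)) {
        n_fa <- draw_fa_count(spec$n_fas_per_cell)
        for (k in seq_len(n_fa)) {
          placed <- FALSE
          for (try in 1:1200) {
            # prefer the peripheral ring; widen it when crowded, and as a
            # last resort place anywhere free in the field
            ctr <- if (try <= 400) {
              ang <- runif(1, 0, 2 * pi)
              rad <- runif(1, spec$fa_ring_px[1], spec$fa_ring_px[2])
              round(centers[cell, ] + rad * c(sin(ang), cos(ang)))
            } else if (try <= 800) {
              ang <- runif(1, 0, 2 * pi)
              rad <- runif(1, spec$fa_ring_px[1], 2 * spec$fa_ring_px[2])
              round(centers[cell, ] + rad * c(sin(ang), cos(ang)))
            } else {
              c(sample.int(nr, 1), sample.int(nc, 1))
            }
            area <- rtrunc_norm(spec$fa_area_px$mean, spec$fa_area_px$sd,
                                spec$fa_area_px$min, spec$fa_area_px$max)
            ratio <- runif(1, spec$fa_axis_ratio[1], spec$fa_axis_ratio[2])
            theta <- runif(1, 0, pi)
            px <- raster_ellipse(ctr, area, ratio, theta, c(nr, nc))
            if (nrow(px) == 0) next
            # fully inside the border margin and off limits of other objects
            if (min(px[, 1]) <= margin || max(px[, 1]) > nr - margin ||
                min(px[, 2]) <= margin || max(px[, 2]) > nc - margin) next
            if (any(forbidden[px])) next
            if (nrow(px) < spec$fa_area_px$min ||
                nrow(px) > spec$fa_area_px$max) next
            stamp(px, gap)
            fas[[length(fas) + 1L]] <-
              list(cell = cell, center = ctr, pixels = px,
                   area = nrow(px), axis_ratio = ratio, theta = theta)
            placed <- TRUE
            break
          }
          if (!placed)
            stop("field too crowded: could not place all FAs")
        }
      }
    }
    # --- channels -------------------------------------------------------
    bg <- spec$background_level
    chans <- list()
    if ("nucleus" %in% spec$channels) {
      nucleus <- matrix(bg, nr, nc)
      if (nrow(centers) > 0) {
        rowg <- matrix(seq_len(nr), nr, nc)
        colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
        for (i in seq_len(nrow(centers))) {
          d2 <- (rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2
          nucleus <- nucleus +
            spec$nucleus_peak * exp(-d2 / (2 * spec$nucleus_radius_px^2))
        }
      }
      chans$nucleus <- nucleus
    }
    if ("fa" %in% spec$channels) {
      fa_ch <- matrix(bg, nr, nc)
      for (f in fas) fa_ch[f$pixels] <- bg + spec$fa_peak
      chans$fa <- fa_ch
    }
    if ("actin" %in% spec$channels) {
      actin <- matrix(bg, nr, nc)
      cell_px <- vector("list", max(1, spec$n_nuclei))
      if (nrow(centers) > 0)
        for (i in seq_len(nrow(centers))) {
          px <- raster_disc(centers[i, ], spec$cell_radius_px, c(nr, nc))
          actin[px] <- bg + spec$actin_level
          cell_px[[i]] <- px
        }
      chans$actin <- actin
      cell_areas <- vapply(cell_px, function(p) if (is.null(p)) 0L
                           else nrow(p), integer(1))
    } else cell_areas <- NULL
    # --- degradation ----------------------------------------------------
    maxval <- 2^spec$bit_depth - 1
    chans <- lapply(chans, function(ch) {
      if (spec$blur_sigma_px > 0) ch <- gaussian_blur(ch, spec$blur_sigma_px)
      if (spec$shot_noise) ch <- matrix(rpois(length(ch), pmax(ch, 0)),
                                        nrow(ch), ncol(ch))
      if (spec$noise_sd > 0) ch <- ch + rnorm(length(ch), 0, spec$noise_sd)
      ch[ch < 0] <- 0; ch[ch > maxval] <- maxval
      ch
    })
    field <- field_image(chans, well_id = well_id, field_id = field_id)
    fa_df <- if (length(fas))
      data.frame(cell = vapply(fas, `[[`, 1L, "cell"),
                 row = vapply(fas, function(f) f$center[1], numeric(1)),
                 col = vapply(fas, function(f) f$center[2], numeric(1)),
                 area = vapply(fas, `[[`, 1L, "area"),
                 axis_ratio = vapply(fas, `[[`, 1, "axis_ratio"))
    else data.frame(cell = integer(), row = numeric(), col = numeric(),
                    area = integer(), axis_ratio = numeric())
    truth <- structure(list(
      n_nuclei = spec$n_nuclei,
      nuclei = if (nrow(centers)) data.frame(row = centers[, 1],
                                             col = centers[, 2])
               else data.frame(row = numeric(), col = numeric()),
      n_fas = length(fas),
      fas = fa_df,
      fa_areas = fa_df$area,
      cell_areas = cell_areas,
      well_id = well_id, field_id = field_id), class = "fa_ground_truth")
    list(field = field, truth = truth)
  })
}
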