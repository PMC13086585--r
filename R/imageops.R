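#' @useDynLib fascreenkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd mad median var quantile coef lm
#'   rnbinom setNames fft dnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a 2-D numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("%s contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

#' Gaussian blur of a 2-D image
#'
#' Separable Gaussian convolution with replicate edge handling.  Following
#' the Fiji convention used throughout this package, a filter "radius" given
#' in pixel units is interpreted as the Gaussian sigma.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation of the kernel in pixels (> 0).
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  assert_image(img)
  if (sigma <= 0) stop("sigma must be > 0")
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  .cpp_sep_convolve(img, k)
}

#' Median filter over a pixelated disc
#'
#' Disc membership follows the ImageJ rank-filter rule
#' \eqn{dx^2 + dy^2 \le r^2 + 1} (radius 2 gives the 13-pixel disc).
#'
#' @param img numeric matrix.
#' @param radius disc radius in pixels.
#' @return filtered matrix.
#' @export
median_filter <- function(img, radius) {
  assert_image(img)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(img)            # ImageJ convention: radius 0 = no-op
  .cpp_median_disc(img, radius)
}

#' Rolling-ball / sliding-paraboloid background estimation
#'
#' Morphological background: the upper envelope of every placement of the
#' structuring element (a ball cap of the given radius, or the paraboloid
#' \eqn{z = d^2 / (2r)} when `sliding_paraboloid` is on) pushed up against
#' the intensity surface from below, i.e. a grey-scale opening.  The
#' paraboloid separates into 1-D parabolas and is computed exactly in
#' O(n) per scan line.
#'
#' @param img numeric matrix.
#' @param radius structuring-element radius in pixels.
#' @param sliding_paraboloid use the paraboloid element (default `TRUE`).
#' @return list with `background` and `subtracted` (clipped at 0) matrices.
#' @export
rolling_ball <- function(img, radius, sliding_paraboloid = TRUE) {
  assert_image(img)
  bg <- if (sliding_paraboloid) .cpp_paraboloid_background(img, radius)
        else .cpp_ball_background(img, radius)
  sub <- img - bg
  sub[sub < 0] <- 0
  list(background = bg, subtracted = sub)
}

#' Label connected components of a mask
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @param connectivity 4 or 8 (default 8, the ImageJ Analyze Particles
#'   convention for foreground).
#' @return integer matrix of labels (0 = background), labels consecutive in
#'   first-encounter order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.logical(mask)) mask <- mask != 0
  storage.mode(mask) <- "logical"
  .cpp_label_components(mask, as.integer(connectivity))
}

#' Fill holes in a binary mask
#'
#' Background components (4-connected) not touching the image border are
#' converted to foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  if (!is.logical(mask)) mask <- mask != 0
  bg <- label_components(!mask, connectivity = 4L)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- bg > 0 & !(bg %in% border)
  mask | hole
}

#' Prominence-based local maxima
#'
#' Finds intensity summits and their topographic prominence (height above
#' the highest saddle connecting the summit to higher terrain; the global
#' summit's prominence is its height above the image minimum).  Summits are
#' accepted when prominence >= `threshold`.  With `exclude_edge`, a summit
#' is rejected when the connected region at level `value - threshold`
#' containing it touches the image border (the summit lies within one
#' tolerance step of the edge).
#'
#' @param img numeric matrix.
#' @param threshold minimum prominence ("noise level") for acceptance.
#' @param exclude_edge reject border-region maxima (default `FALSE`).
#' @return data.frame with 0-based `row`, `col`, `value`, `prominence`.
#' @export
find_maxima <- function(img, threshold, exclude_edge = FALSE) {
  assert_image(img)
  pk <- .cpp_maxima_prominence(img)
  pk <- pk[pk$prominence >= threshold & pk$prominence > 0, , drop = FALSE]
  if (exclude_edge && nrow(pk)) {
    keep <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      lev <- pk$value[i] - threshold
      reg <- label_components(img >= lev, connectivity = 8L)
      l <- reg[pk$row[i] + 1L, pk$col[i] + 1L]
      touches <- any(reg[1, ] == l) || any(reg[nrow(reg), ] == l) ||
                 any(reg[, 1] == l) || any(reg[, ncol(reg)] == l)
      keep[i] <- !touches
    }
    pk <- pk[keep, , drop = FALSE]
  }
  rownames(pk) <- NULL
  pk
}

#' Difference-of-Gaussians high-pass filter
#'
#' With `sigma_small = 0` the image itself minus its large-scale blur is
#' returned (a pure background-subtraction high-pass): on a noiseless
#' image the response is then strictly positive exactly on bright-object
#' footprints, which keeps segmented areas equal to planted areas.
#'
#' @param img numeric matrix.
#' @param sigma_small,sigma_large the two Gaussian scales
#'   (0 <= small < large).
#' @return high-pass filtered matrix (can be negative).
#' @export
dog_filter <- function(img, sigma_small = 0, sigma_large = 8) {
  if (sigma_small >= sigma_large) stop("sigma_small must be < sigma_large")
  small <- if (sigma_small > 0) gaussian_blur(img, sigma_small) else img
  small - gaussian_blur(img, sigma_large)
}

# --- histogram-based automatic thresholds ----------------------------------

# 256-bin histogram over the min-max range; returns counts and bin centres.
image_histogram <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (rng[1] == rng[2])
    return(list(counts = c(length(img), rep(0L, n_bins - 1L)),
                centers = rep(rng[1], n_bins), degenerate = TRUE))
  width <- diff(rng) / n_bins
  idx <- pmin(floor((img - rng[1]) / width), n_bins - 1)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  list(counts = counts, centers = centers, degenerate = FALSE)
}

#' Automatic histogram thresholds (Otsu, Triangle, Huang)
#'
#' All three operate on a 256-bin histogram of the image rescaled to its
#' min--max range and return an intensity value; foreground is `img > t`.
#' Otsu maximises between-class variance; Triangle maximises the distance
#' between the histogram and the chord from its peak to the far tail
#' (orientation auto-detected); Huang minimises the fuzzy entropy of class
#' memberships (the "Huang2" dialect of Fiji is the same criterion).
#' A degenerate single-valued histogram returns `NA` with a warning.
#'
#' @param img numeric matrix.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold intensity, or `NA_real_` for a degenerate histogram.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  h <- image_histogram(img, n_bins)
  if (h$degenerate) { warning("degenerate histogram: single grey value"); return(NA_real_) }
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$centers)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)                     # split after bin k
  (h$centers[k] + h$centers[k + 1L]) / 2
}

#' @rdname otsu_threshold
#' @export
triangle_threshold <- function(img, n_bins = 256L) {
  h <- image_histogram(img, n_bins)
  if (h$degenerate) { warning("degenerate histogram: single grey value"); return(NA_real_) }
  counts <- as.numeric(h$counts)
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # flip so the long tail is to the right of the peak
  flipped <- (peak - lo) > (hi - peak)
  if (flipped) { counts <- rev(counts); peak <- length(counts) - peak + 1L
                 tail_end <- length(counts) - lo + 1L } else tail_end <- hi
  # perpendicular distance from the chord (peak, h_peak) -- (tail_end,
  # h_tail): |cross product| of the chord with each histogram point
  xs <- peak:tail_end
  if (length(xs) < 3) return(h$centers[if (flipped) n_bins - peak + 1L else peak])
  d <- abs((tail_end - peak) * (counts[xs] - counts[peak]) -
           (counts[tail_end] - counts[peak]) * (xs - peak))
  k <- xs[which.max(d)]
  if (flipped) k <- length(counts) - k + 1L
  h$centers[k]
}

#' @rdname otsu_threshold
#' @export
huang_threshold <- function(img, n_bins = 256L) {
  h <- image_histogram(img, n_bins)
  if (h$degenerate) { warning("degenerate histogram: single grey value"); return(NA_real_) }
  counts <- as.numeric(h$counts)
  x <- h$centers
  nz <- which(counts > 0)
  first <- nz[1]; last <- nz[length(nz)]
  w <- cumsum(counts)
  s <- cumsum(counts * x)
  total_w <- w[length(w)]; total_s <- s[length(s)]
  cscale <- x[last] - x[first]           # membership scale (Huang's C)
  best <- Inf; best_k <- first
  for (k in first:(last - 1L)) {
    w0 <- w[k]; w1 <- total_w - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- s[k] / w0
    mu1 <- (total_s - s[k]) / w1
    ent <- 0
    for (i in first:last) {
      if (counts[i] == 0) next
      mu_c <- if (i <= k) mu0 else mu1
      m <- 1 / (1 + abs(x[i] - mu_c) / cscale)   # membership in [0.5, 1]
      if (m > 0 && m < 1)
        ent <- ent - counts[i] * (m * log(m) + (1 - m) * log(1 - m))
    }
    if (ent < best) { best <- ent; best_k <- k }
  }
  (x[best_k] + x[best_k + 1L]) / 2
}

threshold_fun <- function(method) {
  if (is.numeric(method)) {               # manual threshold override
    force(method)
    return(function(img, n_bins = 256L) method)
  }
  switch(tolower(method),
         otsu = otsu_threshold,
         triangle = triangle_threshold,
         huang = , huang2 = huang_threshold,
         stop(sprintf("unknown threshold method '%s'", method)))
}

# --- region properties ------------------------------------------------------

# Perimeter of one labelled object by Moore boundary tracing: orthogonal
# steps count 1, diagonal steps sqrt(2) (for <= 2 px objects, falls back to
# the exposed-edge count).  Used for the circularity statistic.
trace_perimeter <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 1) return(4 * 0.5 * sqrt(2))           # point-like: ~ small circle
  if (n == 2) return(2 + sqrt(2))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  # start: topmost-leftmost boundary pixel, in padded coords
  start <- pts[order(pts[, 1], pts[, 2])[1], ] + 1L
  # Moore tracing, clockwise, backtrack convention
  dirs <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
                c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))
  cur <- start; backtrack <- 5L                    # came from the left
  per <- 0; first_step <- NULL; steps <- 0L
  repeat {
    found <- FALSE
    for (t in 0:7) {
      d <- (backtrack + t) %% 8L
      nb <- cur + dirs[d + 1L, ]
      if (pad[nb[1], nb[2]]) {
        per <- per + if (sum(abs(dirs[d + 1L, ])) == 2) sqrt(2) else 1
        backtrack <- (d + 6L) %% 8L                # re-enter behind the move
        cur <- nb; found <- TRUE
        break
      }
    }
    if (!found) return(4)                          # isolated pixel cluster
    steps <- steps + 1L
    if (all(cur == start) && steps > 1L) break
    if (steps > 8L * n + 8L) break                 # safety
  }
  per
}

#' Region properties of a label image
#'
#' @param labels integer label matrix (0 = background).
#' @param intensity optional intensity matrix for per-object mean intensity.
#' @param perimeter compute traced perimeters (needed for circularity).
#' @return data.frame: `label`, `area`, `centroid_row`, `centroid_col`
#'   (0-based), optionally `mean_intensity`, `perimeter`, `circularity`
#'   (\eqn{4\pi A / P^2}, clipped at 1).
#' @export
region_props <- function(labels, intensity = NULL, perimeter = FALSE) {
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs))
    return(data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  idx <- which(labels > 0)
  l <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels)
  cols <- (idx - 1L) %/% nrow(labels)
  area <- as.integer(tabulate(l, nbins = max(labs))[labs])
  cr <- tapply(rows, l, mean)[as.character(labs)]
  cc <- tapply(cols, l, mean)[as.character(labs)]
  out <- data.frame(label = labs, area = area,
                    centroid_row = as.numeric(cr), centroid_col = as.numeric(cc))
  if (!is.null(intensity))
    out$mean_intensity <- as.numeric(tapply(intensity[idx], l, mean)[as.character(labs)])
  if (perimeter) {
    per <- vapply(labs, function(lb) {
      sel <- which(labels == lb, arr.ind = TRUE)
      r0 <- range(sel[, 1]); c0 <- range(sel[, 2])
      sub <- labels[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE] == lb
      trace_perimeter(sub)
    }, numeric(1))
    out$perimeter <- per
    out$circularity <- pmin(1, 4 * pi * out$area / per^2)
  }
  rownames(out) <- NULL
  out
}
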