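# Brute-force oracles and small fixture builders.  Every oracle here is an
# independent re-derivation (explicit enumeration / naive algorithm) of a
# quantity the package computes by a faster route; oracles never call the
# code path they check.

# --- rolling-ball oracle ----------------------------------------------------
# Background by explicitly pushing the structuring element up against the
# surface at every placement: bg(x) = max over placements p of
# (apex_p + se_p(x)), apex_p = min_y (f(y) - se_p(y)).  O(n^2 m^2): use on
# <= 64 x 64 images only.
oracle_rollball <- function(img, radius, paraboloid = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  bg <- matrix(-Inf, nr, nc)
  for (ci in 1:nr) for (cj in 1:nc) {
    d2 <- outer((1:nr - ci)^2, (1:nc - cj)^2, "+")
    se <- if (paraboloid) -d2 / (2 * radius)
          else { s <- -(radius - sqrt(pmax(radius^2 - d2, 0)))
                 s[d2 > radius^2] <- -Inf; s }
    apex <- min(img - se)
    bg <- pmax(bg, apex + se)
  }
  bg
}

# --- prominence oracle ------------------------------------------------------
# Enumerates strict local maxima (no plateaus in the fixtures used) and
# computes each one's prominence by threshold descent: the prominence of
# peak m is v(m) minus the highest level L at which the connected
# component of {img >= L} containing m also contains a strictly higher
# pixel; the global maximum gets v - min(img).
oracle_prominences <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  peaks <- list()
  for (i in 1:nr) for (j in 1:nc) {
    v <- img[i, j]
    nb <- img[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    if (sum(nb == v) == 1 && all(nb <= v))
      peaks[[length(peaks) + 1L]] <- c(i, j, v)
  }
  if (!length(peaks)) return(numeric(0))
  levels <- sort(unique(as.vector(img)), decreasing = TRUE)
  vapply(peaks, function(p) {
    v <- p[3]
    if (v == max(img)) return(v - min(img))
    for (L in levels[levels <= v]) {
      comp <- label_components(img >= L, connectivity = 8L)
      me <- comp[p[1], p[2]]
      if (any(img[comp == me] > v)) return(v - L)
    }
    v - min(img)
  }, numeric(1))
}

# --- watershed oracle -------------------------------------------------------
# Min-max path assignment: each pixel goes to the seed reachable by the
# 8-connected path minimising the maximum `input` value en route
# (iterative relaxation to a fixed point).  Pixels whose best costs tie
# between seeds are reported so the caller can exempt them.
oracle_minmax_watershed <- function(input, seeds, mask) {
  nr <- nrow(input); nc <- ncol(input)
  k <- max(seeds)
  cost <- array(Inf, c(nr, nc, k))
  for (s in 1:k) {
    w <- which(seeds == s, arr.ind = TRUE)
    cost[w[1], w[2], s] <- input[w[1], w[2]]
  }
  moves <- expand.grid(dr = -1:1, dc = -1:1)
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  repeat {
    changed <- FALSE
    for (s in 1:k) {
      for (it in 1:2) {
        ord_i <- if (it == 1) 1:nr else nr:1
        ord_j <- if (it == 1) 1:nc else nc:1
        for (i in ord_i) for (j in ord_j) {
          if (!mask[i, j]) next
          best <- cost[i, j, s]
          for (m in seq_len(nrow(moves))) {
            ii <- i + moves$dr[m]; jj <- j + moves$dc[m]
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            if (!mask[ii, jj]) next
            cand <- max(cost[ii, jj, s], input[i, j])
            if (cand < best) best <- cand
          }
          if (best < cost[i, j, s]) { cost[i, j, s] <- best; changed <- TRUE }
        }
      }
    }
    if (!changed) break
  }
  lab <- matrix(0L, nr, nc); tie <- matrix(FALSE, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (!mask[i, j]) next
    cs <- cost[i, j, ]
    if (all(!is.finite(cs))) next
    lab[i, j] <- which.min(cs)
    tie[i, j] <- sum(cs == min(cs)) > 1
  }
  list(labels = lab, ties = tie)
}

# --- fixture builders -------------------------------------------------------
disc_image <- function(nr, nc, center, radius, value, bg = 0) {
  img <- matrix(bg, nr, nc)
  d2 <- outer((1:nr - center[1])^2, (1:nc - center[2])^2, "+")
  img[d2 <= radius^2] <- value
  img
}

gauss_blob <- function(nr, nc, center, sigma, peak) {
  d2 <- outer((1:nr - center[1])^2, (1:nc - center[2])^2, "+")
  peak * exp(-d2 / (2 * sigma^2))
}

# axis-aligned filled rectangle, exact pixel count = h * w
rect_image <- function(nr, nc, top, left, h, w, value, bg = 0) {
  img <- matrix(bg, nr, nc)
  img[top:(top + h - 1), left:(left + w - 1)] <- value
  img
}
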