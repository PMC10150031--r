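# Independent brute-force oracles used to validate the geometric
# primitives.  Deliberately naive implementations: they share no code
# with the package internals.

# exact Euclidean distance of every foreground pixel to the nearest
# background pixel, by exhaustive search over background pixels
brute_distance_transform <- function(mask) {
  fg <- which(mask != 0, arr.ind = TRUE)
  bg <- which(mask == 0, arr.ind = TRUE)
  d <- matrix(0, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(fg))) {
    d[fg[k, 1L], fg[k, 2L]] <-
      sqrt(min((bg[, 1L] - fg[k, 1L])^2 + (bg[, 2L] - fg[k, 2L])^2))
  }
  d
}

# inscribed circle by exhaustive per-pixel nearest-background search,
# ties broken smallest row then smallest col (0-based center coords)
brute_inscribed_circle <- function(mask) {
  d <- brute_distance_transform(mask)
  dmax <- max(d)
  cand <- which(d == dmax, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  list(center = c(x = unname(cand[1L, 2L] - 1), y = unname(cand[1L, 1L] - 1)),
       radius = dmax)
}

# component count by queue-based flood fill
flood_fill_components <- function(mask, connectivity = 8L) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  if (connectivity == 8L) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  count <- 0L
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (mask[r, cc] != 0 && !seen[r, cc]) {
      count <- count + 1L
      queue <- list(c(r, cc)); seen[r, cc] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (k in seq_len(nrow(nb))) {
          rr <- p[1L] + nb[k, 1L]; ck <- p[2L] + nb[k, 2L]
          if (rr >= 1L && rr <= nrow(mask) && ck >= 1L && ck <= ncol(mask) &&
              mask[rr, ck] != 0 && !seen[rr, ck]) {
            seen[rr, ck] <- TRUE
            queue[[length(queue) + 1L]] <- c(rr, ck)
          }
        }
      }
    }
  }
  count
}

# O(n^3) minimum enclosing circle: smallest circle through 2 or 3
# support points that contains all points
brute_min_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  contains_all <- function(ctr, r) {
    all(sqrt((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2) <= r + 1e-7)
  }
  best <- list(center = c(NA, NA), radius = Inf)
  if (n == 1L) return(list(center = as.numeric(pts[1L, ]), radius = 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best$radius && contains_all(ctr, r))
      best <- list(center = as.numeric(ctr), radius = r)
  }
  if (n >= 3L) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cc <- pts[k, ]
    den <- 2 * (a[1L] * (b[2L] - cc[2L]) + b[1L] * (cc[2L] - a[2L]) +
                cc[1L] * (a[2L] - b[2L]))
    if (abs(den) < 1e-12) next
    ux <- (sum(a^2) * (b[2L] - cc[2L]) + sum(b^2) * (cc[2L] - a[2L]) +
           sum(cc^2) * (a[2L] - b[2L])) / den
    uy <- (sum(a^2) * (cc[1L] - b[1L]) + sum(b^2) * (a[1L] - cc[1L]) +
           sum(cc^2) * (b[1L] - a[1L])) / den
    r <- sqrt(sum((a - c(ux, uy))^2))
    if (r < best$radius && contains_all(c(ux, uy), r))
      best <- list(center = c(ux, uy), radius = r)
  }
  best
}

# Otsu threshold by exhaustive scan over all 256 gray levels,
# maximizing between-class variance of the 8-bit histogram
brute_otsu_level <- function(gray01) {
  bins <- pmin(255L, pmax(0L, as.integer(floor(gray01 * 256))))
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  mu_total <- sum((0:255) * p)
  best_t <- 0L; best_v <- -1
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)])
    if (w0 <= 0 || w0 >= 1) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    v <- w0 * (1 - w0) * (mu0 - (mu_total - w0 * mu0) / (1 - w0))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t   # class boundary: levels <= best_t are "background" bin side
}

shoelace_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  i2 <- c(seq_len(nrow(poly))[-1L], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

poly_perimeter <- function(poly) {
  i2 <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(sqrt((poly[i2, 1L] - poly[, 1L])^2 + (poly[i2, 2L] - poly[, 2L])^2))
}

# random connected blob: union of a few random discs on a small canvas
random_blob <- function(h = 64L, w = 64L, ndisc = 4L) {
  m <- matrix(0L, h, w)
  r0 <- stats::runif(1L, h * 0.3, h * 0.7)
  c0 <- stats::runif(1L, w * 0.3, w * 0.7)
  for (i in seq_len(ndisc)) {
    rad <- stats::runif(1L, 3, min(h, w) / 5)
    rr <- pmin(h - 2, pmax(2, r0 + stats::runif(1L, -h / 5, h / 5)))
    cc <- pmin(w - 2, pmax(2, c0 + stats::runif(1L, -w / 5, w / 5)))
    g <- expand.grid(r = 1:h, c = 1:w)
    hit <- (g$r - rr)^2 + (g$c - cc)^2 <= rad^2
    m[cbind(g$r[hit], g$c[hit])] <- 1L
    r0 <- rr; c0 <- cc
  }
  m[1, ] <- 0L; m[h, ] <- 0L; m[, 1] <- 0L; m[, w] <- 0L
  m
}

# crossing straight ribbons with known hidden overlap, built directly
# from column/row bands (independent of the generator)
band_cross_sample <- function(h = 120L, w = 120L, width = 20L) {
  v <- matrix(0L, h, w); v[, 51:(50 + width)] <- 1L
  hz <- matrix(0L, h, w); hz[51:(50 + width), ] <- 1L
  vis_v <- as_binary_mask(v * (1L - hz))
  list(sample = shred_sample(list(instance_mask(hz, "S1", 1L),
                                  instance_mask(vis_v, "S2", 2L))),
       true_overlap = width * width,
       v_full = v, h_full = hz)
}
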