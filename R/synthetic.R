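#' Configuration for the synthetic overlapped-ribbon generator
#'
#' Shreds are modeled as ribbons: quadratic Bezier spines dilated by a
#' disc of half the ribbon width.  The generator emulates the overlap
#' taxonomy observed on an inspection line: `"inter-overlapped"` (one
#' ribbon partially covering another, splitting the covered ribbon's
#' visible mask into fragments), `"adhesion"` (borders touching with at
#' most a sliver of overlap) and `"none"` (two separate ribbons).
#'
#' @param image_shape integer `(height, width)` of the canvas.
#' @param width_range ribbon width range in pixels, drawn uniformly.
#' @param curvature spread (pixels) of the middle control point's
#'   perpendicular offset; 0 gives straight ribbons.
#' @param overlap_type one of `"inter-overlapped"`, `"adhesion"`,
#'   `"none"`.
#' @param min_fragments minimum number of visible fragments required of
#'   the covered ribbon for inter-overlapped samples.
#' @param max_retries resampling budget before the generator gives up.
#' @param adhesion_max_frac maximum overlap area for adhesion samples, as
#'   a fraction of the smaller ribbon's area.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(image_shape = c(192L, 192L),
                             width_range = c(14, 24),
                             curvature = 25,
                             overlap_type = c("inter-overlapped", "adhesion", "none"),
                             min_fragments = 2L,
                             max_retries = 25L,
                             adhesion_max_frac = 0.05) {
  overlap_type <- match.arg(overlap_type)
  stopifnot(all(width_range > 0), max_retries >= 1L)
  structure(list(image_shape = as.integer(image_shape),
                 width_range = as.numeric(width_range),
                 curvature = as.numeric(curvature),
                 overlap_type = overlap_type,
                 min_fragments = as.integer(min_fragments),
                 max_retries = as.integer(max_retries),
                 adhesion_max_frac = adhesion_max_frac),
            class = "generator_config")
}

with_local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  fn()
}

#' Rasterize a ribbon from its spine control points
#'
#' The quadratic Bezier spine through `p0`, `p1`, `p2` is sampled at
#' sub-pixel spacing; a pixel belongs to the ribbon when its center lies
#' within `width / 2` of the spine (computed on a 2x supersampled
#' Euclidean distance transform, so half-pixel spine positions are
#' honored).  A straight ribbon of length L and width w therefore has
#' the stadium area `w * L + pi * (w / 2)^2` up to discretization.
#'
#' @param p0,p1,p2 numeric `(x, y)` control points (0-based pixel
#'   coordinates).
#' @param width ribbon width in pixels.
#' @param shape integer `(height, width)` of the canvas.
#' @return a binary mask; if clipping at the canvas border splits the
#'   ribbon, only the largest component is kept so the result is a single
#'   connected component.
#' @export
ribbon_from_spine <- function(p0, p1, p2, width, shape) {
  shape <- as.integer(shape)
  h <- shape[1L]; w <- shape[2L]
  bez <- function(t) {
    cbind((1 - t)^2 * p0[1L] + 2 * t * (1 - t) * p1[1L] + t^2 * p2[1L],
          (1 - t)^2 * p0[2L] + 2 * t * (1 - t) * p1[2L] + t^2 * p2[2L])
  }
  rough <- bez(seq(0, 1, length.out = 64L))
  len <- sum(sqrt(rowSums(diff(rough)^2)))
  n <- max(64L, ceiling(len / 0.35))
  pts <- bez(seq(0, 1, length.out = n))
  # 2x supersampled distance field: spine coordinates keep half-pixel
  # precision, so even widths render symmetrically off-lattice
  cols <- round(2 * pts[, 1L]); rows <- round(2 * pts[, 2L])
  keep <- cols >= 0 & cols <= 2 * (w - 1) & rows >= 0 & rows <= 2 * (h - 1)
  if (!any(keep)) return(matrix(0L, h, w))
  bg <- matrix(1L, 2L * h - 1L, 2L * w - 1L)
  bg[cbind(rows[keep] + 1L, cols[keep] + 1L)] <- 0L
  d <- EBImage::distmap(bg, metric = "euclidean")
  d <- matrix(as.numeric(d), 2L * h - 1L, 2L * w - 1L)
  dpix <- d[seq(1L, 2L * h - 1L, by = 2L), seq(1L, 2L * w - 1L, by = 2L)] / 2
  mask <- as_binary_mask(dpix <= width / 2 - 1e-6)
  comps <- connected_components(mask)
  if (length(comps) > 1L) mask <- comps[[1L]]
  mask
}

draw_spine <- function(config, angle = NULL, center = NULL) {
  shape <- config$image_shape
  diag_len <- sqrt(sum(shape^2))
  if (is.null(center))
    center <- c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2) +
      stats::runif(2L, -0.12, 0.12) * rev(shape)
  if (is.null(angle)) angle <- stats::runif(1L, 0, pi)
  dirv <- c(cos(angle), sin(angle))
  perp <- c(-dirv[2L], dirv[1L])
  half <- 0.65 * diag_len
  p0 <- center - half * dirv
  p2 <- center + half * dirv
  p1 <- center + stats::runif(1L, -config$curvature, config$curvature) * perp
  list(p0 = p0, p1 = p1, p2 = p2, angle = angle, center = center, perp = perp)
}

#' Generate a single ribbon mask
#'
#' Control points and width are drawn from a seeded generator; the same
#' `(seed, config)` always yields the identical mask.
#'
#' @param seed integer seed.
#' @param config a [generator_config()].
#' @return a binary mask with exactly one connected component.
#' @export
make_ribbon <- function(seed, config = generator_config()) {
  with_local_seed(seed, function() {
    for (k in seq_len(config$max_retries)) {
      sp <- draw_spine(config)
      if (sqrt(sum((sp$p2 - sp$p0)^2)) < 1) next  # degenerate spine: resample
      width <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
      m <- ribbon_from_spine(sp$p0, sp$p1, sp$p2, width, config$image_shape)
      if (mask_area(m) > 0L) return(m)
    }
    stop("could not generate a non-empty ribbon")
  })
}

shift_mask <- function(mask, dr, dc) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  idx <- which(mask != 0L, arr.ind = TRUE)
  r <- idx[, 1L] + dr; c_ <- idx[, 2L] + dc
  keep <- r >= 1L & r <= h & c_ >= 1L & c_ <= w
  out[cbind(r[keep], c_[keep])] <- 1L
  out
}

masks_touch <- function(a, b) {
  if (!any(a != 0L) || !any(b != 0L)) return(FALSE)
  bg <- 1L - a
  if (!any(bg != 0L)) return(TRUE)
  d <- EBImage::distmap(bg, metric = "euclidean")
  min(matrix(as.numeric(d), nrow(a), ncol(a))[b == 1L]) <= sqrt(2) + 1e-9
}

#' Generate one overlapped two-ribbon sample with amodal ground truth
#'
#' Ribbon 1 is on top (fully visible); ribbon 2's visible mask is its
#' amodal mask minus ribbon 1.  The generator resamples (up to
#' `max_retries`) until the configured overlap type's constraints hold:
#' for inter-overlapped, the ribbons intersect and the covered ribbon's
#' visible mask has at least `min_fragments` components; for adhesion,
#' the masks touch with overlap at most `adhesion_max_frac` of the
#' smaller ribbon; for none, the ribbons are separated.
#'
#' @inheritParams make_ribbon
#' @return a list of class `synthetic_sample`: `shred1_full`,
#'   `shred2_full` (amodal masks), `sample` (a [shred_sample()] of the
#'   visible instances), `true_overlap`, `true_overlap_area`, `seed`.
#' @export
make_overlapped_sample <- function(seed, config = generator_config()) {
  with_local_seed(seed, function() {
    for (k in seq_len(config$max_retries)) {
      res <- switch(config$overlap_type,
                    "inter-overlapped" = attempt_inter(config),
                    "adhesion" = attempt_adhesion(config),
                    "none" = attempt_none(config))
      if (!is.null(res)) {
        res$seed <- as.integer(seed %% 2147483647)
        return(res)
      }
    }
    stop(sprintf("retries exhausted: could not satisfy '%s' constraints",
                 config$overlap_type))
  })
}

finish_sample <- function(s1, s2, config) {
  ov <- as_binary_mask(s1 * s2)
  vis2 <- as_binary_mask(s2 * (1L - s1))
  smp <- shred_sample(list(instance_mask(s1, "S1", 1L),
                           instance_mask(vis2, "S2", 2L)),
                      config$image_shape)
  structure(list(shred1_full = s1, shred2_full = s2, sample = smp,
                 true_overlap = ov, true_overlap_area = mask_area(ov),
                 seed = NA_integer_),
            class = "synthetic_sample")
}

attempt_inter <- function(config) {
  sp1 <- draw_spine(config)
  w1 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  s1 <- ribbon_from_spine(sp1$p0, sp1$p1, sp1$p2, w1, config$image_shape)
  ang2 <- sp1$angle + pi / 2 + stats::runif(1L, -pi / 6, pi / 6)
  sp2 <- draw_spine(config, angle = ang2)
  w2 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  s2 <- ribbon_from_spine(sp2$p0, sp2$p1, sp2$p2, w2, config$image_shape)
  if (!mask_area(s1) || !mask_area(s2)) return(NULL)
  if (!any(s1 * s2 != 0L)) return(NULL)
  vis2 <- as_binary_mask(s2 * (1L - s1))
  comps <- connected_components(vis2)
  if (length(comps) < config$min_fragments) return(NULL)
  if (length(comps) >= 2L && mask_area(comps[[2L]]) < 25L) return(NULL)
  finish_sample(s1, s2, config)
}

attempt_none <- function(config) {
  # parallel-ish ribbons placed in opposite halves of the canvas
  shape <- config$image_shape
  ctr <- c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2)
  phi <- stats::runif(1L, 0, 2 * pi)
  off <- 0.22 * sqrt(sum(shape^2)) * c(cos(phi), sin(phi))
  ang <- phi + pi / 2
  sp1 <- draw_spine(config, angle = ang + stats::runif(1L, -pi / 16, pi / 16),
                    center = ctr - off)
  w1 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  s1 <- ribbon_from_spine(sp1$p0, sp1$p1, sp1$p2, w1, config$image_shape)
  sp2 <- draw_spine(config, angle = ang + stats::runif(1L, -pi / 16, pi / 16),
                    center = ctr + off)
  w2 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  s2 <- ribbon_from_spine(sp2$p0, sp2$p1, sp2$p2, w2, config$image_shape)
  if (!mask_area(s1) || !mask_area(s2)) return(NULL)
  if (any(s1 * s2 != 0L) || masks_touch(s1, s2)) return(NULL)
  finish_sample(s1, s2, config)
}

attempt_adhesion <- function(config) {
  sp1 <- draw_spine(config)
  w1 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  s1 <- ribbon_from_spine(sp1$p0, sp1$p1, sp1$p2, w1, config$image_shape)
  w2 <- stats::runif(1L, config$width_range[1L], config$width_range[2L])
  ang2 <- sp1$angle + stats::runif(1L, -pi / 12, pi / 12)
  offset <- (w1 + w2) * 1.5 + 10
  ctr2 <- sp1$center + offset * sp1$perp
  sp2 <- draw_spine(config, angle = ang2, center = ctr2)
  s2 <- ribbon_from_spine(sp2$p0, sp2$p1, sp2$p2, w2, config$image_shape)
  if (!mask_area(s1) || !mask_area(s2)) return(NULL)
  if (any(s1 * s2 != 0L)) return(NULL)       # must start separated
  dr <- as.integer(round(-sp1$perp[2L])); dc <- as.integer(round(-sp1$perp[1L]))
  prev <- s2
  for (i in seq_len(sum(config$image_shape))) {
    cur <- shift_mask(prev, dr, dc)
    if (mask_area(cur) < mask_area(s2) * 0.8) return(NULL)  # slid off canvas
    ovl <- sum(s1 * cur)
    if (ovl > 0L || masks_touch(s1, cur)) {
      lim <- config$adhesion_max_frac * min(mask_area(s1), mask_area(cur))
      if (ovl <= lim) return(finish_sample(s1, cur, config))
      return(finish_sample(s1, prev, config))  # previous step: touching, tiny overlap
    }
    prev <- cur
  }
  NULL
}

#' Run the synthetic overlap-recovery benchmark
#'
#' Generates `n` seeded samples, measures the visible composite area AD
#' from the visible instance masks, recovers the hidden area CD with
#' [cot_pipeline()], forms AAR and CAR against the true amodal areas,
#' and summarizes.  Each sample uses an independent random stream keyed
#' by `(seed, i)`, so sample `i` is the same regardless of `n`.
#'
#' @param n number of samples.
#' @inheritParams make_ribbon
#' @return list with `summary` (an `area_summary`) and `records` (one
#'   [area_record()] row per sample, plus `true_overlap_area`).
#' @export
run_benchmark <- function(n, seed, config = generator_config()) {
  stopifnot(n >= 1L)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_overlapped_sample((seed + 7919 * i) %% 2147483647, config)
    a1 <- mask_area(s$shred1_full); a2 <- mask_area(s$shred2_full)
    ad <- sum(vapply(s$sample$instances, function(x) mask_area(x$mask), integer(1L)))
    cd <- cot_pipeline(s$sample)$cd
    rec <- area_record(sprintf("syn-%03d", i), a1, a2, ad, cd)
    rec$true_overlap_area <- s$true_overlap_area
    records[[i]] <- rec
  }
  records <- do.call(rbind, records)
  list(summary = summarize_area_records(records), records = records)
}
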