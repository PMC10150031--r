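#' Region-proposal anchor configuration
#'
#' Anchors are parameterized by a size (the square root of their area) and
#' an aspect ratio `height / width`, area-preserving:
#' `width = size / sqrt(ratio)`, `height = size * sqrt(ratio)`, so every
#' anchor's area equals `size^2` regardless of ratio.  The improved
#' configuration for small elongated objects uses sizes
#' `[32, 64, 128, 256]` and ratios `[0.5, 1, 1.5, 2]` (16 anchors per
#' position); the legacy configuration uses `[128, 256, 512]` and
#' `[0.5, 1, 2]` (9 per position).
#'
#' @param sizes anchor sizes in pixels.
#' @param aspect_ratios height/width ratios.
#' @return a list of class `anchor_config`.
#' @export
anchor_config <- function(sizes = c(32, 64, 128, 256),
                          aspect_ratios = c(0.5, 1, 1.5, 2)) {
  if (any(sizes <= 0) || any(aspect_ratios <= 0))
    stop("sizes and aspect ratios must be positive")
  structure(list(sizes = as.numeric(sizes),
                 aspect_ratios = as.numeric(aspect_ratios)),
            class = "anchor_config")
}

#' @rdname anchor_config
#' @export
legacy_anchor_config <- function() {
  anchor_config(sizes = c(128, 256, 512), aspect_ratios = c(0.5, 1, 2))
}

#' Number of anchors generated at each feature-map position
#' @param config an [anchor_config()].
#' @return integer count `|sizes| * |aspect_ratios|`.
#' @export
anchors_per_position <- function(config) {
  length(config$sizes) * length(config$aspect_ratios)
}

#' Generate anchors over a feature-map grid
#'
#' One anchor per (position, size, ratio).  Position `(row, col)` of a
#' feature map with the given stride maps to image-plane center
#' `(col * stride, row * stride)`; each stride cell covers
#' `stride x stride` image pixels (area 16 for the stride-4 level).
#'
#' @param config an [anchor_config()].
#' @param stride feature-map stride in image pixels.
#' @param grid integer `(rows, cols)` of the feature map.
#' @return data frame with columns `center_x`, `center_y`, `width`,
#'   `height`, `size`, `ratio`; `nrow = rows * cols * sizes * ratios`.
#' @export
generate_anchors <- function(config, stride, grid) {
  stopifnot(stride >= 1, all(grid >= 1))
  pos <- expand.grid(col = seq_len(grid[2L]) - 1L, row = seq_len(grid[1L]) - 1L)
  par <- expand.grid(size = config$sizes, ratio = config$aspect_ratios)
  out <- merge(pos, par, by = NULL)
  data.frame(center_x = out$col * stride,
             center_y = out$row * stride,
             width = out$size / sqrt(out$ratio),
             height = out$size * sqrt(out$ratio),
             size = out$size,
             ratio = out$ratio)
}

#' Fraction of boxes covered by some anchor at IoU > 0.5
#'
#' For each ground-truth box, the best intersection-over-union against
#' the co-centered anchor set (all sizes x ratios) is computed; the box
#' counts as covered when that best IoU exceeds `iou_threshold`.  A
#' diagnostic for choosing anchor parameters against the observed
#' width/height statistics of the target objects.
#'
#' @param config an [anchor_config()].
#' @param widths,heights equal-length vectors of box dimensions (pixels).
#' @param iou_threshold coverage cut-off.
#' @return covered fraction in `[0, 1]`.
#' @export
anchor_coverage <- function(config, widths, heights, iou_threshold = 0.5) {
  if (!length(widths) || length(widths) != length(heights))
    stop("widths and heights must be non-empty and of equal length")
  par <- expand.grid(size = config$sizes, ratio = config$aspect_ratios)
  aw <- par$size / sqrt(par$ratio)
  ah <- par$size * sqrt(par$ratio)
  best <- vapply(seq_along(widths), function(i) {
    inter <- pmin(aw, widths[i]) * pmin(ah, heights[i])
    union <- aw * ah + widths[i] * heights[i] - inter
    max(inter / union)
  }, numeric(1L))
  mean(best > iou_threshold)
}
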