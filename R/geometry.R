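#' Common external tangent trapezoid of two circles
#'
#' Given the two maximum inscribed circles fitted in the fragments of an
#' occluded object, the hidden region is modeled by the quadrilateral
#' bounded by the two common external tangent lines and closed by the
#' chords joining the tangent points on each circle.  With `u` the unit
#' vector from center 1 to center 2 and `d` the center distance, the two
#' tangent-line unit normals satisfy `n . u = (r2 - r1) / d` with opposite
#' perpendicular components; the tangent point on circle `i` is
#' `center_i - r_i * n`.
#'
#' @param c1,c2 lists with `center` (numeric `(x, y)`) and `radius`, as
#'   returned by [max_inscribed_circle()].
#' @return a list of class `tangent_construction` with elements `l0`
#'   (the center segment), `l1`, `l2` (each a list `point`, `direction`)
#'   and `quad`, a 4x2 matrix of vertices ordered counter-clockwise.
#' @section Degenerate configurations: when the center distance does not
#'   exceed `|r1 - r2|` one circle lies inside the other's span and no
#'   external tangents exist; a condition of class `tangent_degenerate`
#'   is signalled so that callers can fall back (see [cot_pipeline()]).
#' @examples
#' tc <- external_tangent_quad(list(center = c(0, 0), radius = 5),
#'                             list(center = c(20, 0), radius = 5))
#' tc$quad
#' @export
external_tangent_quad <- function(c1, c2) {
  p1 <- as.numeric(c1$center); r1 <- as.numeric(c1$radius)
  p2 <- as.numeric(c2$center); r2 <- as.numeric(c2$radius)
  d <- sqrt(sum((p2 - p1)^2))
  if (d <= abs(r1 - r2) + 1e-12)
    stop(structure(class = c("tangent_degenerate", "error", "condition"),
                   list(message = sprintf(
                     "external tangents do not exist (d = %.6g <= |r1 - r2| = %.6g)",
                     d, abs(r1 - r2)), call = sys.call())))
  u <- (p2 - p1) / d
  uperp <- c(-u[2L], u[1L])
  s <- (r2 - r1) / d                  # n . u for both external tangents
  t <- sqrt(max(0, 1 - s^2))
  n_a <- s * u + t * uperp
  n_b <- s * u - t * uperp
  quad <- rbind(p1 - r1 * n_a,
                p2 - r2 * n_a,
                p2 - r2 * n_b,
                p1 - r1 * n_b)
  if (polygon_signed_area(quad) < 0) quad <- quad[4:1, , drop = FALSE]
  tangent_dir <- function(n) c(-n[2L], n[1L])
  structure(list(
    l0 = list(p1 = p1, p2 = p2),
    l1 = list(point = p1 - r1 * n_a, direction = tangent_dir(n_a), normal = n_a),
    l2 = list(point = p1 - r1 * n_b, direction = tangent_dir(n_b), normal = n_b),
    quad = unname(quad)), class = "tangent_construction")
}

polygon_signed_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  i2 <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

#' Rasterize a polygon to a binary mask
#'
#' A pixel `(row, col)` is set iff its integer-coordinate center
#' `(x = col, y = row)` is inside the polygon under the even-odd rule, or
#' lies on its boundary (boundary-inclusive).  Degenerate (zero-area)
#' polygons rasterize to an empty mask.
#'
#' @param poly an n x 2 matrix of `(x, y)` vertices, `n >= 3`.
#' @param shape integer `(height, width)` of the target mask.
#' @return a binary mask matrix.
#' @export
rasterize_polygon <- function(poly, shape) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  shape <- as.integer(shape)
  h <- shape[1L]; w <- shape[2L]
  mask <- matrix(0L, h, w)
  if (abs(polygon_signed_area(poly)) < 1e-9) return(mask)
  c0 <- max(0L, floor(min(poly[, 1L])));  c1 <- min(w - 1L, ceiling(max(poly[, 1L])))
  r0 <- max(0L, floor(min(poly[, 2L])));  r1 <- min(h - 1L, ceiling(max(poly[, 2L])))
  if (c0 > c1 || r0 > r1) return(mask)
  grid <- expand.grid(x = c0:c1, y = r0:r1)
  px <- grid$x; py <- grid$y
  inside <- rep(FALSE, length(px))
  onbd <- rep(FALSE, length(px))
  n <- nrow(poly)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (px < xint))
    }
    # boundary: distance from pixel center to the closed segment
    vx <- x2 - x1; vy <- y2 - y1
    len2 <- vx * vx + vy * vy
    if (len2 < eps) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      tt <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
      d2 <- (px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2
    }
    onbd <- onbd | (d2 <= eps)
  }
  keep <- inside | onbd
  mask[cbind(grid$y[keep] + 1L, grid$x[keep] + 1L)] <- 1L
  mask
}

#' Minimum enclosing circle of a mask's foreground pixels
#'
#' Smallest circle containing the centers of all foreground pixels,
#' computed by Welzl's move-to-front algorithm on the convex hull of the
#' pixel set.  Used by the preprocessing stage to crop a photograph to
#' the object it contains.
#'
#' @param mask a binary mask with at least one foreground pixel.
#' @return list with `center` (numeric `(x, y)`) and `radius`.
#' @export
min_enclosing_circle <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no foreground pixels")
  enclosing_circle_points(cbind(x = idx[, 2L] - 1, y = idx[, 1L] - 1))
}

#' @rdname min_enclosing_circle
#' @param pts an n x 2 matrix of `(x, y)` points.
#' @export
enclosing_circle_points <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (!nrow(pts)) stop("no points")
  if (nrow(pts) > 3L) {
    hull <- grDevices::chull(pts[, 1L], pts[, 2L])
    pts <- pts[hull, , drop = FALSE]
  }
  # deterministic pseudo-shuffle keeps Welzl near its expected runtime
  ord <- order((seq_len(nrow(pts)) * 2654435761) %% 4294967296)
  pts <- pts[ord, , drop = FALSE]
  welzl(pts)
}

circle_from <- function(P) {
  n <- nrow(P)
  if (n == 0L) return(list(center = c(0, 0), radius = -1))
  if (n == 1L) return(list(center = as.numeric(P[1L, ]), radius = 0))
  if (n == 2L) return(list(center = as.numeric((P[1L, ] + P[2L, ]) / 2),
                           radius = sqrt(sum((P[1L, ] - P[2L, ])^2)) / 2))
  a <- P[1L, ]; b <- P[2L, ]; cc <- P[3L, ]
  d <- 2 * (a[1L] * (b[2L] - cc[2L]) + b[1L] * (cc[2L] - a[2L]) +
            cc[1L] * (a[2L] - b[2L]))
  if (abs(d) < 1e-12) {           # collinear: widest pair as diameter
    prs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    best <- NULL
    for (pr in prs) {
      cand <- circle_from(P[pr, , drop = FALSE])
      if (is.null(best) || cand$radius > best$radius) best <- cand
    }
    return(best)
  }
  ux <- (sum(a^2) * (b[2L] - cc[2L]) + sum(b^2) * (cc[2L] - a[2L]) +
         sum(cc^2) * (a[2L] - b[2L])) / d
  uy <- (sum(a^2) * (cc[1L] - b[1L]) + sum(b^2) * (a[1L] - cc[1L]) +
         sum(cc^2) * (b[1L] - a[1L])) / d
  list(center = c(ux, uy), radius = sqrt(sum((a - c(ux, uy))^2)))
}

in_circle <- function(p, circ) {
  circ$radius >= 0 &&
    sqrt(sum((as.numeric(p) - circ$center)^2)) <= circ$radius * (1 + 1e-10) + 1e-10
}

welzl <- function(P, R = P[0L, , drop = FALSE]) {
  if (nrow(P) == 0L || nrow(R) == 3L) return(circle_from(R))
  p <- P[nrow(P), , drop = FALSE]
  D <- welzl(P[-nrow(P), , drop = FALSE], R)
  if (in_circle(p, D)) return(D)
  welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
}
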