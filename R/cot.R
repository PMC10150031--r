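#' Connected components of a binary mask
#'
#' 8-connectivity labelling, returned as a list of single-component masks
#' ordered by decreasing area; ties are broken by the top-left-most
#' foreground pixel (smallest row, then smallest column).  Labelling uses
#' a 4-connectivity pass (`EBImage::bwlabel`) followed by a union-find
#' merge of diagonally adjacent labels, so thin diagonal necks do not
#' split an object spuriously.
#'
#' @param mask a binary mask matrix.
#' @return list of binary masks, one per component, largest first.
#' @export
connected_components <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask != 0L)) return(list())
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    a <- lab[-h, -w]; b <- lab[-1L, -1L]       # \ diagonal neighbours
    c_ <- lab[-h, -1L]; d <- lab[-1L, -w]      # / diagonal neighbours
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(c_), as.vector(d)))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    parent <- seq_len(nlab)
    for (k in seq_len(nrow(pairs))) {
      ra <- pairs[k, 1L]; rb <- pairs[k, 2L]
      while (parent[ra] != ra) ra <- parent[ra]
      while (parent[rb] != rb) rb <- parent[rb]
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- seq_len(nlab)
    for (i in seq_len(nlab)) {
      r <- i
      while (parent[r] != r) r <- parent[r]
      root[i] <- r
    }
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  ids <- sort(unique(lab[lab > 0L]))
  comps <- lapply(ids, function(i) as_binary_mask(lab == i))
  areas <- vapply(comps, mask_area, integer(1L))
  # tie-break: first foreground pixel in row-major (row, col) order
  first_px <- vapply(comps, function(m) {
    idx <- which(t(m) != 0L)[1L]           # t(): row-major scan
    as.numeric(idx)
  }, numeric(1L))
  comps[order(-areas, first_px)]
}

#' Classify an instance as occluded or unoccluded
#'
#' An instance whose visible mask forms a single connected contour is
#' unoccluded; a visible mask split into two or more components indicates
#' that a covering object hides part of it.
#'
#' @param instance an [instance_mask()] (or bare binary mask).
#' @return `"unoccluded"` or `"occluded"`.
#' @export
classify_occlusion <- function(instance) {
  mask <- if (inherits(instance, "instance_mask")) instance$mask else instance
  n <- length(connected_components(mask))
  if (n == 0L) stop("empty instance mask")
  if (n == 1L) "unoccluded" else "occluded"
}

#' Maximum inscribed circle of a mask component
#'
#' The center is the foreground pixel maximizing the exact Euclidean
#' distance to the nearest background pixel (distance-transform argmax);
#' the radius is that maximum distance.  Ties are broken deterministically
#' by smallest row, then smallest column.
#'
#' @param component a binary mask with at least one foreground pixel and
#'   at least one background pixel.
#' @return list with `center` (numeric `(x, y)`, 0-based pixel
#'   coordinates) and `radius` in pixels.
#' @export
max_inscribed_circle <- function(component) {
  component <- as_binary_mask(component)
  if (!any(component != 0L)) stop("empty component")
  if (all(component != 0L)) stop("component has no background pixel")
  d <- EBImage::distmap(component, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(component), ncol(component))
  dmax <- max(d)
  cand <- which(d == dmax, arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  list(center = c(x = unname(cand[1L, 2L] - 1), y = unname(cand[1L, 1L] - 1)),
       radius = dmax)
}

#' Intersect a fitted region with the covering instance
#'
#' @param fitted_mask binary mask of the fitted (candidate hidden) region.
#' @param covering an [instance_mask()] (or bare mask) of the covering
#'   object.
#' @return list with `overlap_mask` (the intersection) and `cd`, its
#'   pixel area — the recovered hidden-overlap area.
#' @export
overlap_from_fit <- function(fitted_mask, covering) {
  cov <- if (inherits(covering, "instance_mask")) covering$mask else covering
  if (!identical(dim(fitted_mask), dim(cov)))
    stop("fitted mask and covering mask differ in shape")
  ov <- as_binary_mask(fitted_mask * cov)
  list(overlap_mask = ov, cd = mask_area(ov))
}

fit_hidden_region <- function(occ_mask, shape) {
  comps <- connected_components(occ_mask)
  comps <- comps[seq_len(min(2L, length(comps)))]
  if (length(comps) < 2L) stop("occluded instance must have >= 2 components")
  circles <- lapply(comps, max_inscribed_circle)
  tc <- tryCatch(external_tangent_quad(circles[[1L]], circles[[2L]]),
                 tangent_degenerate = function(e) NULL)
  if (is.null(tc)) {
    # conservative fallback: convex hull of the two chosen fragments
    idx <- which(as_binary_mask(comps[[1L]] | comps[[2L]]) != 0L, arr.ind = TRUE)
    pts <- cbind(idx[, 2L] - 1, idx[, 1L] - 1)
    hull <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
    fitted <- rasterize_polygon(hull, shape)
    quad <- hull
  } else {
    fitted <- rasterize_polygon(tc$quad, shape)
    quad <- tc$quad
  }
  list(fitted = fitted, circles = circles, quad = quad, tangent = tc)
}

#' Recover the hidden overlap between two instances
#'
#' Runs the full overlap-reconstruction pipeline on a two-instance sample:
#' classify each instance by its component count, take the TWO LARGEST
#' fragments of the occluded instance, fit the maximum inscribed circle in
#' each, span the common external tangent trapezoid between the circles,
#' rasterize it and intersect with the covering (unoccluded) instance.
#' The intersection is the recovered hidden region and its pixel area is
#' CD.
#'
#' When the tangent construction is degenerate (one circle inside the
#' other's span) the fitted region falls back to the convex hull of the
#' two fragments.  A sample with no occluded instance returns `cd = 0`
#' with empty masks (there is no hidden area to recover).  If both
#' instances are occluded, each is fitted against the other and the
#' recovered areas are summed, with a warning.
#'
#' @param sample a [shred_sample()] with exactly 2 instances.
#' @return an object of class `overlap_result`: list with
#'   `occluded_instance_id`, `fitted_mask`, `overlap_mask`, `cd`,
#'   `circles` and `quad` (`NULL` when nothing was fitted).
#' @export
cot_pipeline <- function(sample) {
  if (!inherits(sample, "shred_sample") || length(sample$instances) != 2L)
    stop("sample must contain exactly 2 instances")
  shape <- sample$image_shape
  status <- vapply(sample$instances, classify_occlusion, character(1L))
  empty <- matrix(0L, shape[1L], shape[2L])
  if (!any(status == "occluded")) {
    return(structure(list(occluded_instance_id = NA_integer_,
                          fitted_mask = empty, overlap_mask = empty,
                          cd = 0L, circles = NULL, quad = NULL),
                     class = "overlap_result"))
  }
  occ_idx <- which(status == "occluded")
  if (length(occ_idx) == 2L)
    warning("both instances are occluded; fitting each against the other")
  fitted_all <- empty; overlap_all <- empty
  cd <- 0L; circles <- NULL; quad <- NULL
  for (i in occ_idx) {
    other <- sample$instances[[if (i == 1L) 2L else 1L]]
    fit <- fit_hidden_region(sample$instances[[i]]$mask, shape)
    ov <- overlap_from_fit(fit$fitted, other)
    cd <- cd + ov$cd
    fitted_all <- as_binary_mask(fitted_all | fit$fitted)
    overlap_all <- as_binary_mask(overlap_all | ov$overlap_mask)
    if (is.null(circles)) { circles <- fit$circles; quad <- fit$quad }
  }
  structure(list(
    occluded_instance_id =
      if (length(occ_idx) == 1L) sample$instances[[occ_idx]]$instance_id
      else vapply(sample$instances[occ_idx], `[[`, integer(1L), "instance_id"),
    fitted_mask = fitted_all, overlap_mask = overlap_all,
    cd = as.integer(cd), circles = circles, quad = quad),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> occluded instance: %s, recovered area CD = %d px\n",
              paste(x$occluded_instance_id, collapse = "+"), x$cd))
  invisible(x)
}
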