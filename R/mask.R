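#' Binary masks and instance containers
#'
#' A binary mask is stored as a plain integer matrix with values in
#' \{0, 1\}; rows index the image's y (row) axis and columns its x
#' (column) axis.  Pixel coordinates are 0-based `(row, col)` throughout
#' the package, and polygon vertices are `(x = col, y = row)` floats, the
#' convention used by annotation tools such as LabelMe.
#'
#' @param x a logical or numeric matrix; any non-zero entry is foreground.
#' @return an integer matrix of 0/1 values with the same dimensions.
#' @examples
#' m <- as_binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' mask_area(m)
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) stop("mask must be a matrix")
  if (any(!is.finite(x))) stop("mask contains non-finite values")
  storage.mode(x) <- "integer"
  x[x != 0L] <- 1L
  x
}

#' Number of foreground pixels in a mask
#' @param mask a binary mask matrix.
#' @return integer pixel count.
#' @export
mask_area <- function(mask) as.integer(sum(mask != 0))

#' One object's visible mask with its class label
#'
#' @param mask binary mask matrix (the instance's visible pixels).
#' @param class_label character label, e.g. one of the four shred
#'   varieties `"G"`, `"P"`, `"Y"`, `"Z"` or a synthetic label.
#' @param instance_id integer identifier, unique within a sample.
#' @return an object of class `instance_mask`.
#' @export
instance_mask <- function(mask, class_label = "object", instance_id = 1L) {
  structure(
    list(mask = as_binary_mask(mask),
         class_label = as.character(class_label),
         instance_id = as.integer(instance_id)),
    class = "instance_mask")
}

#' A sample: the instance masks of one image
#'
#' Instances must share the image shape and be pairwise disjoint at pixel
#' level (each pixel belongs to at most one instance).
#'
#' @param instances list of [instance_mask()] objects.
#' @param image_shape integer `(height, width)`; defaults to the shape of
#'   the first instance.
#' @return an object of class `shred_sample`.
#' @export
shred_sample <- function(instances, image_shape = NULL) {
  if (!length(instances)) stop("sample needs at least one instance")
  if (is.null(image_shape)) image_shape <- dim(instances[[1L]]$mask)
  image_shape <- as.integer(image_shape)
  acc <- matrix(0L, image_shape[1L], image_shape[2L])
  for (inst in instances) {
    if (!inherits(inst, "instance_mask")) stop("instances must be instance_mask objects")
    if (!identical(dim(inst$mask), image_shape))
      stop("all instance masks must share image_shape")
    acc <- acc + inst$mask
  }
  if (any(acc > 1L)) stop("instance masks must be pairwise disjoint")
  structure(list(instances = instances, image_shape = image_shape),
            class = "shred_sample")
}

#' @export
print.shred_sample <- function(x, ...) {
  cat(sprintf("<shred_sample> %d x %d, %d instance(s)\n",
              x$image_shape[1L], x$image_shape[2L], length(x$instances)))
  for (inst in x$instances)
    cat(sprintf("  #%d [%s] area %d px\n", inst$instance_id,
                inst$class_label, mask_area(inst$mask)))
  invisible(x)
}
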