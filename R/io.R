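#' Read a binary mask from a PNG file
#'
#' Any pixel with non-zero intensity (any channel for RGB input) maps to
#' foreground.  On write, foreground is stored as 255 and background as 0
#' in an 8-bit grayscale PNG.
#'
#' @param path file path to an 8-bit grayscale or RGB PNG.
#' @return a binary mask matrix.
#' @seealso [write_mask_png()]
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(img) == 0L) stop("zero-size image: ", path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), max)
  as_binary_mask(img > 0)
}

#' @rdname read_mask_png
#' @param mask binary mask matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a LabelMe polygon annotation into a sample
#'
#' Each polygon in the JSON `shapes` list is rasterized with the
#' boundary-inclusive even-odd rule of [rasterize_polygon()].  Pixels
#' claimed by more than one polygon are assigned to the FIRST-listed
#' polygon (annotators draw the covering object first), which guarantees
#' that the resulting instance masks are pairwise disjoint.
#'
#' @param path path to a LabelMe-style JSON file with a `shapes` list of
#'   labeled polygons; vertices are `(x, y)` pixel coordinates.
#' @param image_shape integer `(height, width)` of the annotated image.
#' @return a [shred_sample()].
#' @export
read_labelme <- function(path, image_shape) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("LabelMe JSON lacks a 'shapes' key: ", path)
  image_shape <- as.integer(image_shape)
  claimed <- matrix(0L, image_shape[1L], image_shape[2L])
  instances <- list()
  id <- 0L
  for (sh in doc$shapes) {
    pts <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
    if (is.null(pts) || nrow(pts) < 3L) {
      warning("skipping polygon with fewer than 3 vertices")
      next
    }
    m <- rasterize_polygon(pts, image_shape)
    m[claimed == 1L] <- 0L                      # first-listed polygon wins
    claimed <- claimed + m
    id <- id + 1L
    lab <- if (is.null(sh$label)) "object" else sh$label
    instances[[id]] <- instance_mask(m, lab, id)
  }
  if (!length(instances)) stop("no usable polygons in ", path)
  shred_sample(instances, image_shape)
}

#' Read polygon-type COCO annotations for one image
#'
#' Minimal reader for COCO-style annotation JSON restricted to polygon
#' segmentations (no run-length encoding).  Overlap between annotations is
#' resolved first-wins by annotation order, as in [read_labelme()].
#'
#' @param path path to a COCO annotation JSON.
#' @param image_id id of the image to extract; defaults to the first
#'   listed image.
#' @return a [shred_sample()].
#' @export
read_coco <- function(path, image_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$images) || is.null(doc$annotations))
    stop("COCO JSON needs 'images' and 'annotations'")
  imgs <- doc$images
  if (is.null(image_id)) image_id <- imgs[[1L]]$id
  img <- NULL
  for (im in imgs) if (identical(im$id, image_id)) img <- im
  if (is.null(img)) stop("image id not found: ", image_id)
  shape <- c(img$height, img$width)
  cats <- list()
  for (ct in doc$categories %||% list()) cats[[as.character(ct$id)]] <- ct$name
  claimed <- matrix(0L, shape[1L], shape[2L])
  instances <- list()
  id <- 0L
  for (an in doc$annotations) {
    if (!identical(an$image_id, image_id)) next
    seg <- an$segmentation
    if (is.null(seg) || !is.list(seg)) stop("only polygon segmentations are supported")
    m <- matrix(0L, shape[1L], shape[2L])
    for (ring in seg) {
      xy <- as.numeric(unlist(ring))
      pts <- cbind(xy[c(TRUE, FALSE)], xy[c(FALSE, TRUE)])
      if (nrow(pts) >= 3L) m <- as_binary_mask(m | rasterize_polygon(pts, shape))
    }
    m[claimed == 1L] <- 0L
    claimed <- claimed + m
    id <- id + 1L
    lab <- cats[[as.character(an$category_id)]] %||% "object"
    instances[[id]] <- instance_mask(m, lab, id)
  }
  if (!length(instances)) stop("no annotations for image id ", image_id)
  shred_sample(instances, shape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a per-sample area record
#'
#' Records the constituent areas, the visible composite area AD, the
#' recovered hidden area CD, and the derived ratios AAR and CAR.
#'
#' @param sample_id character identifier.
#' @param area_1,area_2 amodal pixel areas of the covering and occluded
#'   objects.
#' @param ad visible composite pixel area (union of visible instances).
#' @param cd recovered hidden-overlap pixel area.
#' @return a one-row data frame with columns `sample_id`, `area_1`,
#'   `area_2`, `ad`, `cd`, `aar`, `car`.
#' @export
area_record <- function(sample_id, area_1, area_2, ad, cd) {
  stopifnot(area_1 > 0, area_2 > 0, ad >= 0, cd >= 0)
  data.frame(sample_id = as.character(sample_id),
             area_1 = area_1, area_2 = area_2, ad = ad, cd = cd,
             aar = aar(ad, area_1, area_2),
             car = car(ad, cd, area_1, area_2),
             stringsAsFactors = FALSE)
}

#' Write an area report to CSV or JSON
#'
#' CSV output has header `sample_id,area_1,area_2,ad,cd,aar,car` followed
#' by a final `Average` row carrying the mean AAR and CAR; ratio columns
#' are printed with 3 decimals (half-up).
#'
#' @param records data frame of area records ([area_record()] rows).
#' @param path output file; a `.json` extension selects JSON output.
#' @param digits decimals used for the ratio columns.
#' @export
write_area_report <- function(records, path, digits = 3L) {
  if (is.null(records) || !nrow(records)) stop("no records to write")
  out <- records
  out$aar <- sprintf(paste0("%.", digits, "f"), round_half_up(records$aar, digits))
  out$car <- sprintf(paste0("%.", digits, "f"), round_half_up(records$car, digits))
  avg <- data.frame(sample_id = "Average", area_1 = NA, area_2 = NA,
                    ad = NA, cd = NA,
                    aar = sprintf(paste0("%.", digits, "f"),
                                  round_half_up(mean(records$aar), digits)),
                    car = sprintf(paste0("%.", digits, "f"),
                                  round_half_up(mean(records$car), digits)),
                    stringsAsFactors = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(records = records,
                              average = list(aar = round_half_up(mean(records$aar), digits),
                                             car = round_half_up(mean(records$car), digits))),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(rbind(out, avg), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an area report (or ratio table) from CSV
#'
#' Accepts any CSV with numeric `aar` and `car` columns; an `Average`
#' trailer row, if present, is dropped.  The bundled reference table of 24
#' overlapped-sample measurements loads through this reader.
#'
#' @param path CSV file path.
#' @return data frame of per-sample rows.
#' @export
read_area_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("aar", "car") %in% names(df)))
    stop("report must have 'aar' and 'car' columns: ", path)
  idcol <- intersect(c("sample_id", "sample"), names(df))[1L]
  if (!is.na(idcol)) df <- df[tolower(df[[idcol]]) != "average", , drop = FALSE]
  df$aar <- as.numeric(df$aar)
  df$car <- as.numeric(df$car)
  df
}

#' Bundled reference tables
#'
#' `table_overlap_samples()` returns the 24 overlapped-sample reference
#' measurements (constituent shred ids, printed combined area, AAR, CAR);
#' `table_shred_areas()` the 20 single-shred reference areas;
#' `table_confidences()` the per-overlap-type recognition confidences with
#' their overlap group (self-winding, adhesion, inter-overlapped).
#'
#' @return a data frame.
#' @export
table_overlap_samples <- function() {
  utils::read.csv(system.file("extdata", "overlap_samples.csv",
                              package = "shredcot"),
                  stringsAsFactors = FALSE)
}

#' @rdname table_overlap_samples
#' @export
table_shred_areas <- function() {
  utils::read.csv(system.file("extdata", "shred_areas.csv",
                              package = "shredcot"),
                  stringsAsFactors = FALSE)
}

#' @rdname table_overlap_samples
#' @export
table_confidences <- function() {
  utils::read.csv(system.file("extdata", "recognition_confidences.csv",
                              package = "shredcot"),
                  stringsAsFactors = FALSE)
}
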