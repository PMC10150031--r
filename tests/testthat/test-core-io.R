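test_that("PNG mask round-trip is bit-exact and degenerate cases read correctly", {
  tmp <- withr::local_tempfile(fileext = ".png")

  black <- matrix(0L, 10, 10)
  write_mask_png(black, tmp)
  expect_equal(mask_area(read_mask_png(tmp)), 0L)

  one <- matrix(0L, 10, 10); one[4, 5] <- 1L   # pixel (3, 4) 0-based
  write_mask_png(one, tmp)
  back <- read_mask_png(tmp)
  expect_equal(mask_area(back), 1L)
  expect_equal(back[4, 5], 1L)

  set.seed(11)
  rnd <- matrix(rbinom(64 * 64, 1, 0.4), 64, 64)
  write_mask_png(rnd, tmp)
  expect_identical(read_mask_png(tmp), as_binary_mask(rnd))
})

test_that("binary mask constructor enforces 0/1 values and area is the 1-count", {
  m <- as_binary_mask(matrix(c(0, 2.5, 7, 0), 2, 2))
  expect_true(all(m %in% c(0L, 1L)))
  expect_equal(mask_area(m), 2L)
  expect_error(as_binary_mask(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_error(as_binary_mask(1:4), "matrix")
})

write_labelme_json <- function(shapes, path) {
  jsonlite::write_json(list(shapes = shapes), path, auto_unbox = TRUE, digits = NA)
}

test_that("LabelMe reader rasterizes polygons and first-listed polygon wins overlaps", {
  tmp <- withr::local_tempfile(fileext = ".json")

  # one 10x10 lattice square on a 20x20 canvas
  write_labelme_json(list(list(label = "G", points = list(
    c(0, 0), c(9, 0), c(9, 9), c(0, 9)))), tmp)
  smp <- read_labelme(tmp, c(20, 20))
  expect_length(smp$instances, 1)
  expect_equal(mask_area(smp$instances[[1]]$mask), 100L)
  expect_equal(smp$instances[[1]]$class_label, "G")

  # two disjoint triangles -> two disjoint instances
  write_labelme_json(list(
    list(label = "a", points = list(c(0, 0), c(6, 0), c(0, 6))),
    list(label = "b", points = list(c(12, 12), c(18, 12), c(12, 18)))), tmp)
  smp2 <- read_labelme(tmp, c(20, 20))
  expect_length(smp2$instances, 2)
  expect_equal(max(smp2$instances[[1]]$mask + smp2$instances[[2]]$mask), 1L)

  # two overlapping squares: second instance loses the contested pixels;
  # union area checked against a brute-force pixel loop
  sq1 <- rbind(c(2, 2), c(11, 2), c(11, 11), c(2, 11))
  sq2 <- rbind(c(7, 7), c(16, 7), c(16, 16), c(7, 16))
  write_labelme_json(list(list(label = "top", points = asplit(sq1, 1)),
                          list(label = "under", points = asplit(sq2, 1))), tmp)
  smp3 <- read_labelme(tmp, c(20, 20))
  in_square <- function(x, y, sq) x >= sq[1, 1] && x <= sq[2, 1] &&
                                  y >= sq[1, 2] && y <= sq[3, 2]
  union_px <- inter_px <- 0L
  for (y in 0:19) for (x in 0:19) {
    a <- in_square(x, y, sq1); b <- in_square(x, y, sq2)
    if (a || b) union_px <- union_px + 1L
    if (a && b) inter_px <- inter_px + 1L
  }
  m1 <- smp3$instances[[1]]$mask; m2 <- smp3$instances[[2]]$mask
  expect_equal(mask_area(m1), 100L)                       # first polygon intact
  expect_equal(mask_area(m2), 100L - inter_px)            # later polygon eroded
  expect_equal(mask_area(as_binary_mask(m1 | m2)), union_px)
  expect_true(all(m1 + m2 <= 1L))
})

test_that("LabelMe reader rejects malformed files and skips tiny polygons", {
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(version = "5.0"), tmp, auto_unbox = TRUE)
  expect_error(read_labelme(tmp, c(10, 10)), "shapes")

  write_labelme_json(list(
    list(label = "line", points = list(c(0, 0), c(5, 5))),
    list(label = "ok", points = list(c(0, 0), c(4, 0), c(0, 4)))), tmp)
  expect_warning(smp <- read_labelme(tmp, c(10, 10)), "fewer than 3")
  expect_length(smp$instances, 1)
})

test_that("COCO polygon reader builds disjoint instances with class labels", {
  tmp <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    images = list(list(id = 1L, height = 20L, width = 20L)),
    categories = list(list(id = 7L, name = "Y")),
    annotations = list(
      list(id = 1L, image_id = 1L, category_id = 7L,
           segmentation = list(as.numeric(t(rbind(c(0, 0), c(9, 0), c(9, 9), c(0, 9)))))),
      list(id = 2L, image_id = 1L, category_id = 7L,
           segmentation = list(as.numeric(t(rbind(c(5, 5), c(14, 5), c(14, 14), c(5, 14))))))))
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  smp <- read_coco(tmp)
  expect_length(smp$instances, 2)
  expect_equal(smp$instances[[1]]$class_label, "Y")
  expect_equal(mask_area(smp$instances[[1]]$mask), 100L)
  expect_true(all(smp$instances[[1]]$mask + smp$instances[[2]]$mask <= 1L))
})

test_that("area report writes an Average row of the mean ratios and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".csv")

  one <- area_record("s1", 100, 100, 200, 0)      # aar = car = 1
  write_area_report(one, tmp)
  lines <- readLines(tmp)
  expect_match(lines[length(lines)], "^Average,.*1\\.000,1\\.000$")

  two <- rbind(area_record("a", 100, 100, 80, 0),
               area_record("b", 100, 100, 160, 0)) # aar 0.4 and 0.8
  write_area_report(two, tmp)
  expect_match(readLines(tmp)[4], "^Average,.*0\\.600")

  back <- read_area_report(tmp)
  expect_equal(nrow(back), 2)                      # Average trailer dropped
  expect_equal(back$aar, c(0.4, 0.8))
})

test_that("reference table of 24 overlapped samples averages to the printed summary", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  ref <- table_overlap_samples()
  expect_equal(nrow(ref), 24)
  recs <- data.frame(sample_id = ref$sample_id, area_1 = 1, area_2 = 1,
                     ad = ref$aar * 2, cd = (ref$car - ref$aar) * 2,
                     aar = ref$aar, car = ref$car)
  write_area_report(recs, tmp)
  expect_match(readLines(tmp)[26], "^Average,.*0\\.812,0\\.900$")
})

test_that("sample constructor rejects overlapping or mismatched instances", {
  a <- matrix(0L, 5, 5); a[1:3, 1:3] <- 1L
  b <- matrix(0L, 5, 5); b[3:5, 3:5] <- 1L     # shares pixel (3,3)
  expect_error(shred_sample(list(instance_mask(a), instance_mask(b, , 2L))),
               "disjoint")
  d <- matrix(0L, 6, 5); d[6, 1] <- 1L
  expect_error(shred_sample(list(instance_mask(a), instance_mask(d, , 2L))),
               "image_shape")
})
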