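test_that("connected components: counts, areas and deterministic ordering", {
  rect <- matrix(0L, 20, 20); rect[5:12, 3:17] <- 1L
  expect_length(connected_components(rect), 1)

  two <- matrix(0L, 20, 20); two[2:6, 2:6] <- 1L; two[12:16, 12:16] <- 1L
  comps <- connected_components(two)
  expect_length(comps, 2)
  expect_equal(vapply(comps, mask_area, integer(1)), c(25L, 25L))
  expect_equal(comps[[1]][2, 2], 1L)   # tie broken by top-left-most pixel

  expect_length(connected_components(matrix(0L, 5, 5)), 0)
})

test_that("diagonally touching pixels form one component (8-connectivity)", {
  m <- matrix(0L, 6, 6)
  m[2, 2] <- 1L; m[3, 3] <- 1L; m[4, 4] <- 1L   # a pure diagonal
  expect_length(connected_components(m), 1)
  # staircase ribbon: 4-connectivity would split none, but a thin
  # anti-diagonal neck must also hold together
  m2 <- matrix(0L, 8, 8); m2[2:3, 2:3] <- 1L; m2[4, 4] <- 1L; m2[5:6, 5:6] <- 1L
  expect_length(connected_components(m2), 1)
})

test_that("component count matches the flood-fill oracle on random masks", {
  set.seed(21)
  for (rep in 1:8) {
    m <- matrix(rbinom(30 * 30, 1, 0.35), 30, 30)
    expect_equal(length(connected_components(m)), flood_fill_components(m, 8L))
  }
})

test_that("occlusion status follows the component count of the visible mask", {
  ribbon <- matrix(0L, 40, 40); ribbon[10:14, 5:35] <- 1L
  expect_equal(classify_occlusion(instance_mask(ribbon)), "unoccluded")

  split <- ribbon; split[, 18:22] <- 0L
  expect_equal(classify_occlusion(instance_mask(split)), "occluded")

  expect_error(classify_occlusion(matrix(0L, 5, 5)), "empty")
})

test_that("maximum inscribed circle recovers canonical shapes", {
  # filled disc radius 20 centered (30, 30) (0-based)
  g <- expand.grid(r = 0:60, c = 0:60)
  disc <- matrix(as.integer((g$r - 30)^2 + (g$c - 30)^2 <= 400), 61, 61)
  ic <- max_inscribed_circle(disc)
  expect_lt(max(abs(ic$center - c(30, 30))), 1 + 1e-9)
  expect_lt(abs(ic$radius - 20), 1 + 1e-9)

  # 41 x 21 rectangle: radius half the short side, center on the long midline
  rect <- matrix(0L, 40, 60); rect[10:30, 10:50] <- 1L
  ic2 <- max_inscribed_circle(rect)
  expect_lt(abs(ic2$radius - 10.5), 1 + 1e-9)
  expect_equal(unname(ic2$center["y"]), 19)     # midline row (0-based)

  expect_error(max_inscribed_circle(matrix(0L, 4, 4)), "empty")
  expect_error(max_inscribed_circle(matrix(1L, 4, 4)), "background")
})

test_that("inscribed circle equals the exhaustive nearest-background oracle", {
  set.seed(31)
  for (rep in 1:6) {
    m <- random_blob(48L, 48L)
    if (!any(m != 0L)) next
    got <- max_inscribed_circle(m)
    want <- brute_inscribed_circle(m)
    expect_equal(got$radius, want$radius)
    expect_equal(got$center, want$center)
  }
})

test_that("overlap extraction is the exact mask intersection", {
  a <- matrix(0L, 15, 15); a[1:5, 1:5] <- 1L
  b <- matrix(0L, 15, 15); b[10:14, 10:14] <- 1L
  expect_equal(overlap_from_fit(a, b)$cd, 0L)

  inner <- matrix(0L, 15, 15); inner[2:4, 2:4] <- 1L
  expect_equal(overlap_from_fit(inner, a)$cd, 9L)

  set.seed(8)
  x <- matrix(rbinom(225, 1, 0.5), 15, 15)
  y <- matrix(rbinom(225, 1, 0.5), 15, 15)
  brute <- 0L
  for (i in 1:15) for (j in 1:15) if (x[i, j] == 1L && y[i, j] == 1L) brute <- brute + 1L
  expect_equal(overlap_from_fit(x, y)$cd, brute)

  expect_error(overlap_from_fit(matrix(0L, 4, 4), matrix(0L, 5, 5)), "shape")
})

test_that("pipeline returns zero hidden area when nothing is occluded", {
  a <- matrix(0L, 40, 40); a[5:9, 2:38] <- 1L
  b <- matrix(0L, 40, 40); b[25:29, 2:38] <- 1L
  res <- cot_pipeline(shred_sample(list(instance_mask(a, "A", 1L),
                                        instance_mask(b, "B", 2L))))
  expect_equal(res$cd, 0L)
  expect_true(is.na(res$occluded_instance_id))
  expect_equal(mask_area(res$fitted_mask), 0L)
})

test_that("pipeline recovers the hidden band of a perpendicular crossing", {
  bc <- band_cross_sample(120L, 120L, 20L)
  res <- cot_pipeline(bc$sample)
  expect_equal(res$occluded_instance_id, 2L)
  # within +/- 20% of the true hidden 20x20 strip intersection
  expect_gt(res$cd, 0.8 * bc$true_overlap)
  expect_lt(res$cd, 1.2 * bc$true_overlap)
  # recovered overlap is a subset of the covering instance
  cov <- bc$sample$instances[[1]]$mask
  expect_true(all(res$overlap_mask <= cov))
  expect_equal(mask_area(res$overlap_mask), res$cd)
})

test_that("recovered area never lowers the ratio: CAR >= AAR on synthetic crossings", {
  for (s in c(2, 5, 9)) {
    syn <- make_overlapped_sample(s, generator_config())
    res <- cot_pipeline(syn$sample)
    a1 <- mask_area(syn$shred1_full); a2 <- mask_area(syn$shred2_full)
    ad <- sum(vapply(syn$sample$instances, function(x) mask_area(x$mask), integer(1)))
    expect_gte(car(ad, res$cd, a1, a2), aar(ad, a1, a2))
    expect_gte(res$cd, 0)
  }
})

test_that("pipeline handles two occluded instances by fitting both and warns", {
  # two crossing band pairs arranged so each instance is split by the other
  h <- 100L
  a <- matrix(0L, h, h); a[, 21:30] <- 1L; a[, 71:80] <- 1L
  b <- matrix(0L, h, h); b[41:50, ] <- 1L
  a_vis <- as_binary_mask(a * (1L - b))     # a split by b
  b_vis <- as_binary_mask(b * (1L - a))     # b split by a's two bands
  smp <- shred_sample(list(instance_mask(a_vis, "A", 1L),
                           instance_mask(b_vis, "B", 2L)))
  expect_warning(res <- cot_pipeline(smp), "both")
  expect_gt(res$cd, 0)
  expect_length(res$occluded_instance_id, 2)
})

test_that("pipeline rejects samples without exactly two instances", {
  a <- matrix(0L, 10, 10); a[2:4, 2:4] <- 1L
  expect_error(cot_pipeline(shred_sample(list(instance_mask(a)))), "exactly 2")
})
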