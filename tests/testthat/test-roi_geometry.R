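disc_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), times = n), n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

test_that("largest component wins, specks are dropped, holes are filled", {
  m <- matrix(FALSE, 60, 60)
  m[10:34, 10:29] <- TRUE                     # 500 px blob
  m[2, 2:6] <- TRUE; m[50, 2:6] <- TRUE; m[58, 50:54] <- TRUE  # 5 px specks
  core <- extract_avascular_region(m, min_area_px = 50, pixel_size_um = 10)
  expect_equal(core$area_px, 500)
  expect_equal(core$area_um2, 500 * 100)
  expect_true(all(core$mask[10:34, 10:29]))
  expect_false(any(core$mask[2, 2:6]))

  holed <- matrix(FALSE, 40, 40)
  holed[5:30, 5:30] <- TRUE
  holed[15:16, 15:19] <- FALSE                # 10 px hole
  filled <- extract_avascular_region(holed, 50, 10)
  expect_equal(filled$area_px, 26 * 26)
  expect_equal(filled$area_px, sum(holed) + 10)

  expect_error(extract_avascular_region(matrix(FALSE, 5, 5), 1, 10),
               "no avascular region")
  expect_error(extract_avascular_region(m, min_area_px = 1000, 10),
               "no avascular region")
})

test_that("equal-area tie goes to the first component in row-major order", {
  m <- matrix(FALSE, 30, 30)
  m[20:24, 3:7] <- TRUE        # blob A: top-left-most pixel (20, 3)
  m[4:8, 20:24] <- TRUE        # blob B: top-left-most pixel (4, 20)
  comp <- oracle_components(m)  # BFS flood-fill oracle
  expect_length(comp, 2)
  anchors <- vapply(comp, min, numeric(1))
  # row-major order: row 4 col 20 comes before row 20 col 3
  first_rm <- comp[[which.min(vapply(comp, function(px) {
    i <- (px - 1) %% 30 + 1; j <- (px - 1) %/% 30 + 1
    min((i - 1) * 30 + j)    # row-major rank
  }, numeric(1)))]]
  core <- extract_avascular_region(m, 1, 10)
  expect_equal(sort(which(core$mask)), first_rm)
  expect_true(core$mask[4, 20])
  expect_false(core$mask[20, 3])
})

test_that("annulus equals the brute-force Euclidean distance oracle", {
  n <- 128
  core <- disc_mask(n, 64.5, 64.5, 30)
  ann <- build_peripapillary_annulus(core, band_width_um = 640,
                                     pixel_size_um = 10)
  d <- oracle_distance_to_core(core)
  expect_identical(ann$mask, d > 0 & d <= 64 + 1e-9)
  expect_equal(ann$area_px, sum(d > 0 & d <= 64 + 1e-9))
  expect_equal(ann$band_width_um, 640)
  expect_false(any(ann$mask & core))           # disjoint from the core
})

test_that("annuli nest monotonically in band width", {
  core <- disc_mask(96, 40, 50, 18)
  a640 <- build_peripapillary_annulus(core, 640, 10)$mask
  a920 <- build_peripapillary_annulus(core, 920, 10)$mask
  a1960 <- build_peripapillary_annulus(core, 1960, 10)$mask
  expect_true(all(a640 <= a920))
  expect_true(all(a920 <= a1960))
  # border clipping: a core touching the edge still yields an in-grid annulus
  edge_core <- matrix(FALSE, 50, 50); edge_core[1:10, 1:10] <- TRUE
  a <- build_peripapillary_annulus(edge_core, 100, 10)
  expect_equal(dim(a$mask), c(50, 50))
  expect_gt(a$area_px, 0)
})

test_that("annulus area matches the continuous ring within discretisation", {
  n <- 400
  r <- 40; w <- 64                           # 640 um at 10 um/px
  core <- disc_mask(n, n / 2 + 0.5, n / 2 + 0.5, r)
  ann <- build_peripapillary_annulus(core, 640, 10)
  expect_equal(ann$area_px, pi * ((r + w)^2 - r^2), tolerance = 0.03)
})

test_that("band-width validation and um_to_px arithmetic", {
  core <- disc_mask(40, 20, 20, 8)
  expect_error(build_peripapillary_annulus(core, 5, 10), "below one pixel")
  expect_error(build_peripapillary_annulus(core, -1, 10), "positive")
  expect_error(build_peripapillary_annulus(matrix(FALSE, 5, 5), 100, 10),
               "empty")
  expect_equal(um_to_px(640, 3000 / 304), 640 / (3000 / 304))
  expect_equal(um_to_px(640, 3000 / 304), 64.85, tolerance = 1e-3)
  expect_equal(um_to_px(640, 10), 64)
  expect_equal(um_to_px(0, 10), 0)
  expect_error(um_to_px(-1, 10), "non-negative")
})
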