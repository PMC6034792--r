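test_that("read_image derives calibration from the field of view", {
  dir <- withr::local_tempdir()
  m <- matrix(sample(0:255, 304 * 304, replace = TRUE) / 255, 304, 304)
  png::writePNG(m, file.path(dir, "scan.png"))
  img <- read_image(file.path(dir, "scan.png"), field_of_view_mm = 3,
                    layer = "SCN", device_label = "Angioplex")
  expect_equal(img$pixel_size_um, 3000 / 304)
  expect_equal(img$pixel_size_um, 9.868, tolerance = 1e-3)
  expect_equal(img$pixels, m * 255, tolerance = 1e-9)
  expect_identical(img$layer, "SCN")

  m300 <- matrix(0.5, 300, 300)
  png::writePNG(m300, file.path(dir, "scan300.png"))
  expect_equal(read_image(file.path(dir, "scan300.png"), 3)$pixel_size_um, 10)
})

test_that("higher bit depths and RGB are collapsed to linear 8-bit gray", {
  dir <- withr::local_tempdir()
  vals <- matrix(c(0, 1000, 30000, 65535, 12345, 222), 2, 3)
  octadensity:::write_tiff_gray(vals, file.path(dir, "deep.tif"), bits = 16)
  img <- read_image(file.path(dir, "deep.tif"), 3)
  expect_equal(img$pixels, vals / 65535 * 255, tolerance = 1e-12) # linear oracle
  expect_equal(max(img$pixels), 255)

  v8 <- matrix(sample(0:255, 60, replace = TRUE), 6, 10)
  octadensity:::write_tiff_gray(v8, file.path(dir, "flat.tif"), bits = 8)
  expect_equal(read_image(file.path(dir, "flat.tif"), 3)$pixels, v8,
               tolerance = 1e-12)

  rgb <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  png::writePNG(rgb, file.path(dir, "rgb.png"))
  img <- read_image(file.path(dir, "rgb.png"), 3)
  dec <- png::readPNG(file.path(dir, "rgb.png"))
  expect_equal(img$pixels, (dec[, , 1] + dec[, , 2] + dec[, , 3]) / 3 * 255)
})

test_that("read_image rejects bad inputs", {
  expect_error(read_image("/nonexistent/file.png", 3), "not found")
  dir <- withr::local_tempdir()
  writeLines("not a png", file.path(dir, "bad.png"))
  expect_error(read_image(file.path(dir, "bad.png"), 3), "unreadable")
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "ok.png"))
  expect_error(read_image(file.path(dir, "ok.png"), 0), "positive")
  expect_error(octa_image(matrix(300, 2, 2), 10), "\\[0, 255\\]")
})

test_that("mask round-trips are bit-exact, including empty and full", {
  dir <- withr::local_tempdir()
  set.seed(4)
  m <- matrix(runif(40 * 30) > 0.6, 40, 30)
  for (mask in list(m, matrix(FALSE, 5, 5), matrix(TRUE, 5, 5))) {
    p <- file.path(dir, "m.png")
    write_mask(mask, p)
    expect_identical(read_mask(p), mask)
  }
  # 0/255 dialect on disk
  write_mask(matrix(TRUE, 2, 2), file.path(dir, "full.png"))
  expect_equal(png::readPNG(file.path(dir, "full.png")), matrix(1, 2, 2))
})

test_that("annotation round-trip is exact and validation names the class", {
  dir <- withr::local_tempdir()
  img <- octa_image(matrix(100, 20, 20), 10)
  lab <- matrix(0, 20, 20); lab[3:5, 3:5] <- 1; lab[10:13, 10:14] <- 2
  ann <- annotation_set(lab, "a1")
  write_annotations(ann, file.path(dir, "ann.png"))
  back <- read_annotations(file.path(dir, "ann.png"), img)
  expect_identical(back$label_image, lab)
  expect_equal(sum(back$label_image == 1), 9)
  expect_equal(sum(back$label_image == 2), 20)

  expect_error(annotation_set(matrix(0, 4, 4)), "avascular")
  only_av <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_error(annotation_set(only_av), "vascular")
  expect_error(annotation_set(matrix(c(1, 2, 3, 0), 2, 2)), "\\{0, 1, 2\\}")
  lab_small <- matrix(c(1, 2), 1, 2)
  expect_error(read_annotations({
    p <- file.path(dir, "small.png"); write_annotations(annotation_set(lab_small), p); p
  }, img), "does not match")
})

test_that("pixel size is invariant under 90-degree rotation", {
  dir <- withr::local_tempdir()
  m <- matrix(runif(64 * 64), 64, 64)
  rot <- t(m)[, rev(seq_len(64))]
  png::writePNG(m, file.path(dir, "a.png"))
  png::writePNG(rot, file.path(dir, "b.png"))
  a <- read_image(file.path(dir, "a.png"), 3)
  b <- read_image(file.path(dir, "b.png"), 3)
  expect_equal(a$pixel_size_um, b$pixel_size_um)
  expect_equal(sort(as.vector(a$pixels)), sort(as.vector(b$pixels)))
})

test_that("config round-trips through the flat key-value format", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(scales_um = c(10, 25.5, 40), ntree = 80L,
                         mtry = 4L, seed = 99L)
  p <- file.path(dir, "cfg.txt")
  write_config(cfg, p)
  expect_identical(read_config(p), cfg)
  # defaults (with NULL scales) round-trip too
  write_config(pipeline_config(), p)
  expect_identical(read_config(p), pipeline_config())
})
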