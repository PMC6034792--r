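# shared fixture: one small phantom with features and scribbles
rf_fixture <- function() {
  cached("rf_fixture", {
    ph <- generate_phantom(small_spec(seed = 21))
    scales <- default_scales(ph$image$pixel_size_um)
    stack <- compute_features(ph$image, scales)
    ann <- phantom_scribbles(ph$truth, seed = 5)
    list(ph = ph, stack = stack, ann = ann, scales = scales)
  })
}

test_that("perfectly separable annotations train to accuracy 1", {
  m <- matrix(220, 60, 60)
  m[20:40, 20:40] <- 10                       # dark avascular square
  img <- octa_image(m, 10)
  stack <- compute_features(img, c(20, 40))
  lab <- matrix(0, 60, 60)
  lab[25:35, 25:35] <- 1
  lab[2:8, 2:58] <- 2
  model <- train_pixel_classifier(stack, annotation_set(lab),
                                  small_config(seed = 1))
  expect_equal(model$training_accuracy, 1.0)
  seg <- predict(model, stack)
  truth <- m < 100
  expect_gte(dice_coefficient(seg$mask, truth), 0.9)
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  fx <- rf_fixture()
  lab <- fx$ann$label_image
  # balanced subset so chance level is exactly 1/2
  n_bal <- min(sum(lab == 1), sum(lab == 2))
  oob <- vapply(1:10, function(i) {
    set.seed(100 + i)
    idx <- c(sample(which(lab == 1), n_bal), sample(which(lab == 2), n_bal))
    shuffled <- matrix(0, nrow(lab), ncol(lab))
    shuffled[idx] <- sample(rep(c(1, 2), n_bal))  # permutation oracle
    model <- suppressWarnings(train_pixel_classifier(
      fx$stack, annotation_set(shuffled, "perm"),
      small_config(seed = i, ntree = 40L)))
    model$oob_accuracy
  }, numeric(1))
  expect_equal(mean(oob), 0.5, tolerance = 0.1)
})

test_that("training and prediction are deterministic given the seed", {
  fx <- rf_fixture()
  cfg <- small_config(seed = 33)
  m1 <- train_pixel_classifier(fx$stack, fx$ann, cfg)
  m2 <- train_pixel_classifier(fx$stack, fx$ann, cfg)
  expect_identical(m1$trees, m2$trees)
  held_out <- compute_features(generate_phantom(small_spec(seed = 22))$image,
                               fx$scales)
  p1 <- predict(m1, held_out)
  p2 <- predict(m2, held_out)
  expect_identical(p1$probability, p2$probability)
  expect_identical(p1$mask, p2$mask)
})

test_that("threshold semantics: any-vote at 0, unanimity at 1, ties avascular", {
  fx <- rf_fixture()
  model <- train_pixel_classifier(fx$stack, fx$ann, small_config())
  prob <- predict(model, fx$stack)$probability
  expect_identical(predict(model, fx$stack, threshold = 0)$mask, prob > 0)
  expect_identical(predict(model, fx$stack, threshold = 1)$mask, prob >= 1)
  thr <- sort(unique(as.vector(prob)))[2]      # attained probability level
  expect_identical(predict(model, fx$stack, threshold = thr)$mask,
                   prob >= thr)                # tie -> avascular
})

test_that("model transfers across avascular geometries (small-scale check)", {
  fx <- rf_fixture()
  model <- train_pixel_classifier(fx$stack, fx$ann, small_config())
  for (shape in c("ellipse", "irregular")) {
    ph2 <- generate_phantom(small_spec(seed = 40, avascular_shape = shape))
    seg <- predict(model, compute_features(ph2$image, fx$scales))
    core <- extract_avascular_region(seg, 30, ph2$image$pixel_size_um)
    expect_gte(dice_coefficient(core$mask, ph2$truth$avascular_mask), 0.8)
  }
})

test_that("mismatched feature stacks and bad annotations are rejected", {
  fx <- rf_fixture()
  model <- train_pixel_classifier(fx$stack, fx$ann, small_config())
  other <- compute_features(fx$ph$image, fx$scales[-1])
  expect_error(predict(model, other), "missing|match")
  lab <- fx$ann$label_image[1:10, 1:10]
  expect_error(
    suppressWarnings(train_pixel_classifier(fx$stack,
      annotation_set(pmax(lab, matrix(c(1, 2), 10, 10)), "tiny"),
      small_config())),
    "shape|match")
  few <- matrix(0, 128, 128); few[1, 1:5] <- 1; few[2, 1:5] <- 2
  expect_warning(train_pixel_classifier(fx$stack, annotation_set(few),
                                        small_config()), "fewer than 10")
})

test_that("classifier serialization round-trips with a version check", {
  fx <- rf_fixture()
  model <- train_pixel_classifier(fx$stack, fx$ann, small_config())
  p <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, p)
  back <- load_classifier(p)
  expect_identical(back$trees, model$trees)
  saveRDS(list(junk = 1), p)
  expect_error(load_classifier(p), "not a compatible")
})
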