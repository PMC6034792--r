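#' Train the random-forest pixel classifier from sparse annotations
#'
#' Fits an ensemble of CART trees on the annotated pixels only (balanced
#' per-class subsampling up to `config$sample_cap`, drawn with the config
#' seed). The classifier sees each pixel as its multi-scale feature vector;
#' the combination of features is optimised to reproduce the annotator's
#' labels. Training is fully deterministic given `(stack, annotations, seed)`.
#'
#' @param stack a [feature_stack] from [compute_features()].
#' @param annotations an [annotation_set] on the same grid.
#' @param config a [pipeline_config]; uses `ntree`, `mtry`, `max_depth`,
#'   `sample_cap` and `seed`.
#' @return An object of class `octa_classifier` with the fitted trees, the
#'   feature names it was trained on, out-of-bag and training accuracy, and
#'   the training seed. Class order is `{avascular, vascular}`.
#' @export
train_pixel_classifier <- function(stack, annotations, config = pipeline_config()) {
  stopifnot(inherits(stack, "feature_stack"),
            inherits(annotations, "annotation_set"))
  lab <- annotations$label_image
  check_same_shape(lab, stack$features[, , 1], "annotations", "feature stack")
  idx_av <- which(lab == 1)
  idx_va <- which(lab == 2)
  if (length(idx_av) == 0) stop("no annotated pixels for class avascular")
  if (length(idx_va) == 0) stop("no annotated pixels for class vascular")
  if (length(idx_av) < 10 || length(idx_va) < 10)
    warning("fewer than 10 annotated pixels in a class; training proceeds ",
            "but the classifier may be unstable")
  n_feat <- dim(stack$features)[3]
  Xall <- matrix(stack$features, ncol = n_feat)
  model <- with_seed(config$seed, {
    cap <- config$sample_cap
    if (length(idx_av) > cap) idx_av <- sort(sample(idx_av, cap))
    if (length(idx_va) > cap) idx_va <- sort(sample(idx_va, cap))
    X <- Xall[c(idx_av, idx_va), , drop = FALSE]
    y <- c(rep(0L, length(idx_av)), rep(1L, length(idx_va)))
    mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(n_feat)))
            else config$mtry
    fit <- .rf_fit(X, y, config$ntree, mtry, config$max_depth, 2L)
    prob0 <- .rf_predict_prob0(fit$trees, X)
    pred <- ifelse(prob0 >= 0.5, 0L, 1L)
    list(trees = fit$trees, oob_accuracy = fit$oob_accuracy,
         training_accuracy = mean(pred == y),
         n_train = c(avascular = length(idx_av), vascular = length(idx_va)))
  })
  structure(list(trees = model$trees,
                 feature_names = stack$feature_names,
                 classes = c("avascular", "vascular"),
                 seed = config$seed,
                 ntree = config$ntree,
                 oob_accuracy = model$oob_accuracy,
                 training_accuracy = model$training_accuracy,
                 n_train = model$n_train,
                 version = "octa_classifier/1"),
            class = "octa_classifier")
}

#' @export
print.octa_classifier <- function(x, ...) {
  cat(sprintf("octa_classifier: %d trees on %d features (seed %d)\n",
              x$ntree, length(x$feature_names), x$seed))
  cat(sprintf("  training accuracy %.4f, out-of-bag accuracy %.4f\n",
              x$training_accuracy, x$oob_accuracy))
  invisible(x)
}

#' Predict a per-pixel avascular probability map and binary segmentation
#'
#' The probability of the avascular class is the fraction of trees voting
#' for it; the binary mask is `probability >= threshold`, so ties at exactly
#' the threshold are assigned to the avascular class.
#'
#' @param object an `octa_classifier`.
#' @param stack a [feature_stack] whose feature names match the model's.
#' @param threshold probability threshold in `(0, 1)`; the boundary values
#'   0 and 1 are also accepted to express "any vote" / "unanimous only".
#' @param ... unused.
#' @return An object of class `segmentation_mask` with fields `mask`
#'   (logical, `TRUE` = avascular), `probability` and `threshold`.
#' @export
predict.octa_classifier <- function(object, stack, threshold = 0.5, ...) {
  stopifnot(inherits(stack, "feature_stack"))
  missing <- setdiff(object$feature_names, stack$feature_names)
  if (length(missing) > 0 ||
      !identical(object$feature_names, stack$feature_names))
    stop("feature stack does not match the model; missing or misordered: ",
         paste(if (length(missing)) missing else "(order differs)",
               collapse = ", "))
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  dims <- dim(stack$features)
  X <- matrix(stack$features, ncol = dims[3])
  prob <- matrix(.rf_predict_prob0(object$trees, X), nrow = dims[1])
  # threshold 0 means "any avascular vote"; elsewhere ties go to avascular
  mask <- if (threshold == 0) prob > 0 else prob >= threshold
  structure(list(mask = mask, probability = prob,
                 threshold = threshold),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d / %d px avascular (threshold %.2f)\n",
              sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' Serialized as a versioned binary file; the version string is checked on
#' load so stale models fail loudly rather than silently.
#'
#' @param model an `octa_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "octa_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "octa_classifier") ||
      !identical(model$version, "octa_classifier/1"))
    stop("not a compatible classifier file: ", path)
  model
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
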