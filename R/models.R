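#' Classifier specification
#'
#' Records the algorithm and its complete hyperparameter set. Defaults are
#' the settings used in the intraoperative study: a linear-kernel SVM
#' (C = 1), a random forest of 100 trees, and the patch-based 3D CNN
#' (9x9x25 input patches, two conv blocks of 128 and 256 filters with
#' 3x3x5 kernels and spectral-only max pooling, fully connected widths
#' 256/128 with dropout 0.3/0.5, AdamW with learning rate 5e-5 and weight
#' decay 0.01, mini-batches of 1024, two passes over the batch set).
#' Any field can be overridden through `...` (e.g. smaller filter counts
#' for quick desk-scale runs).
#'
#' @param algorithm One of `"svm"`, `"rf"`, `"cnn"`.
#' @param seed Integer seed used for training.
#' @param ... Hyperparameter overrides.
#' @return An `hsi_model_spec`.
#' @export
hsi_model_spec <- function(algorithm = c("svm", "rf", "cnn"), seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(cost = 1),
    rf  = list(num_trees = 100L),
    cnn = list(filters = c(128L, 256L), kernel = c(3L, 3L, 5L),
               pool_spectral = 2L, fc = c(256L, 128L),
               dropout = c(0.3, 0.5), batch_size = 1024L, passes = 2L,
               lr = 5e-5, weight_decay = 0.01, patch_size = 9L,
               head_scale = NULL))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop("unknown hyperparameter(s): ", paste(bad, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(c(list(algorithm = algorithm, seed = as.integer(seed)), defaults),
            class = "hsi_model_spec")
}

#' @export
print.hsi_model_spec <- function(x, ...) {
  cat("<hsi_model_spec>", x$algorithm, " seed", x$seed, "\n")
  hp <- x[setdiff(names(x), c("algorithm", "seed"))]
  str(hp, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Train a tissue classifier
#'
#' Fits the classifier described by `spec` on a labeled dataset: linear SVM
#' (via libsvm), random forest (via ranger, single-threaded and seeded so
#' repeated runs are identical), or the patch-based 3D CNN. The CNN
#' requires a patches dataset; SVM and RF require spectra.
#'
#' @param spec An `hsi_model_spec`.
#' @param data An `hsi_dataset`.
#' @return An `hsi_fit` with `spec`, the underlying `fit`, the class codes
#'   seen in training, and a dataset fingerprint.
#' @export
hsi_train <- function(spec, data) {
  stopifnot(inherits(spec, "hsi_model_spec"), inherits(data, "hsi_dataset"))
  if (nrow(data$x) == 0L) stop("empty training dataset")
  classes <- sort(unique(data$y))
  if (length(classes) < 2L) {
    stop("training data contains a single class (", classes,
         "); cannot fit a discriminator")
  }
  if (spec$algorithm == "cnn" && data$kind != "patches") {
    stop("the 3D CNN requires a patches dataset (got '", data$kind, "')")
  }
  if (spec$algorithm != "cnn" && data$kind != "spectra") {
    stop("svm/rf require a spectra dataset (got '", data$kind, "')")
  }
  fit <- switch(spec$algorithm,
    svm = {
      set.seed(spec$seed)
      e1071::svm(x = data$x, y = factor(data$y, levels = classes),
                 kernel = "linear", cost = spec$cost, scale = FALSE)
    },
    rf = {
      x <- data$x
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      ranger::ranger(x = x, y = factor(data$y, levels = classes),
                     num.trees = spec$num_trees, seed = spec$seed,
                     num.threads = 1L)
    },
    cnn = cnn_train(spec, data$x, data$y, data$patch_dim))
  structure(list(spec = spec, algorithm = spec$algorithm, fit = fit,
                 classes = classes,
                 fingerprint = dataset_fingerprint(data)),
            class = "hsi_fit")
}

dataset_fingerprint <- function(data) {
  list(n = nrow(data$x), p = ncol(data$x), kind = data$kind,
       label_table = as.vector(table(data$y)),
       checksum = round(sum(data$x), 6))
}

#' @export
print.hsi_fit <- function(x, ...) {
  cat("<hsi_fit>", x$algorithm, "on", x$fingerprint$n, x$fingerprint$kind,
      "samples, classes:", paste(x$classes, collapse = " "), "\n")
  invisible(x)
}

#' Predict labels (or class probabilities) for new samples
#'
#' @param object An `hsi_fit`.
#' @param newdata Feature matrix matching the training kind (N x 25
#'   spectra, or N x flattened-patch columns), or an `hsi_dataset`.
#' @param type `"class"` (integer labels) or `"prob"` (CNN only: softmax
#'   probabilities, one column per class).
#' @param ... Unused.
#' @return Integer label vector, or probability matrix for `type = "prob"`.
#' @export
predict.hsi_fit <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "hsi_dataset")) newdata$x else newdata
  if (object$algorithm == "cnn") {
    return(cnn_predict(object$fit, x, type = type))
  }
  if (type == "prob") {
    stop("probability output is only available for the cnn algorithm")
  }
  pred <- switch(object$algorithm,
    svm = stats::predict(object$fit, x),
    rf = {
      colnames(x) <- paste0("f", seq_len(ncol(x)))
      stats::predict(object$fit, data = x, num.threads = 1L)$predictions
    })
  as.integer(as.character(pred))
}

#' Classify every pixel of a cube
#'
#' Produces a classification map by predicting all pixels of a normalized
#' cube: per-pixel spectra for SVM/RF, or mirror-padded patches (identical
#' padding rule as in training) for the CNN.
#'
#' @param fit An `hsi_fit`.
#' @param cube Normalized-stage `hsi_cube`.
#' @return A `class_map`: integer rows x cols matrix of labels 1-5 with the
#'   model algorithm recorded as an attribute.
#' @export
predict_image <- function(fit, cube) {
  if (cube_stage(cube) != "normalized") {
    stop("whole-image prediction requires a normalized-stage cube (got '",
         cube_stage(cube), "')")
  }
  ds <- if (fit$algorithm == "cnn") {
    extract_patches(cube, NULL, size = fit$spec$patch_size)
  } else {
    extract_spectra(cube, NULL)
  }
  pred <- predict(fit, ds$x)
  d <- dim(cube)
  structure(matrix(as.integer(pred), d[1], d[2]),
            model = fit$algorithm, class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map>", nrow(x), "x", ncol(x), "px from",
      attr(x, "model") %||% "?", "model\n")
  invisible(x)
}
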