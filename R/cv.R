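#' Stratified K-fold assignment
#'
#' Shuffles the samples of each class independently (seeded) and deals them
#' round-robin into K folds, so for every class the per-fold counts differ
#' by at most 1 ("each fold approximately has the same amount of pixels for
#' each class").
#'
#' @param labels Integer label vector.
#' @param k Number of folds (5 in this work).
#' @param seed Integer seed.
#' @return A `fold_assignment`: integer fold ids (1..k) per sample, with a
#'   per-class-per-fold count table and the seed as attributes.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  folds <- integer(length(labels))
  set.seed(derive_seed(seed, 31L))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has only ", length(idx),
           " samples; at least k = ", k, " are required")
    }
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  structure(folds, counts = table(class = labels, fold = folds),
            seed = seed, k = k, class = "fold_assignment")
}

#' Double (nested) 5-fold cross-validation
#'
#' Model selection exactly as in the intraoperative study: an external
#' stratified 5-fold loop isolates each test fold in turn; the 4 remaining
#' training folds are re-stratified into 5 sub-folds, and the internal loop
#' trains 5 models (4 calibration sub-folds / 1 validation sub-fold each).
#' The internal model with the best validation OACC predicts the isolated
#' test fold; the final winner is the external iteration with the best test
#' OACC. Exactly K*K = 25 models are trained; ties break to the lowest
#' fold index, and the selected model is used as-is (no refit).
#'
#' @param data An `hsi_dataset`.
#' @param spec An `hsi_model_spec`.
#' @param seed Integer master seed for the fold assignments and training.
#' @param k Folds per level (5).
#' @return A `cv_report`: `per_outer` data.frame (outer fold, selected
#'   inner fold, validation OACC, test OACC), `winner` (outer fold id),
#'   `winner_model` (`hsi_fit`), `models_trained`, `outer_folds`, and
#'   per-outer provenance of the isolated test indices.
#' @export
double_cv <- function(data, spec, seed = 1L, k = 5L) {
  outer_folds <- stratified_kfold(data$y, k, derive_seed(seed, 1L))
  per <- data.frame(outer = seq_len(k), inner_selected = NA_integer_,
                    val_oacc = NA_real_, test_oacc = NA_real_)
  classes <- sort(unique(data$y))
  selected <- vector("list", k)
  test_sets <- vector("list", k)
  inner_sets <- vector("list", k)
  models_trained <- 0L
  for (ko in seq_len(k)) {
    test_idx <- which(outer_folds == ko)
    train_idx <- which(outer_folds != ko)
    test_sets[[ko]] <- test_idx
    inner_folds <- stratified_kfold(data$y[train_idx], k,
                                    derive_seed(seed, 100L + ko))
    inner_sets[[ko]] <- split(train_idx, unclass(inner_folds))
    best_val <- -Inf; best_model <- NULL; best_ki <- NA_integer_
    for (ki in seq_len(k)) {
      calib <- train_idx[inner_folds != ki]
      val <- train_idx[inner_folds == ki]
      sp <- spec
      sp$seed <- as.integer(derive_seed(seed, 1000L + ko * 10L + ki))
      model <- tryCatch(hsi_train(sp, subset_dataset(data, calib)),
                        error = function(e) {
                          stop("training failed in outer fold ", ko,
                               ", inner fold ", ki, ": ",
                               conditionMessage(e), call. = FALSE)
                        })
      models_trained <- models_trained + 1L
      vo <- oacc(confusion(data$y[val], predict(model, data$x[val, , drop = FALSE]),
                           classes = classes))
      if (vo > best_val) {            # strict: ties keep the lowest index
        best_val <- vo; best_model <- model; best_ki <- ki
      }
    }
    to <- oacc(confusion(data$y[test_idx],
                         predict(best_model, data$x[test_idx, , drop = FALSE]),
                         classes = classes))
    per$inner_selected[ko] <- best_ki
    per$val_oacc[ko] <- best_val
    per$test_oacc[ko] <- to
    selected[[ko]] <- best_model
  }
  winner <- which.max(per$test_oacc)    # ties break to the lowest fold index
  structure(list(per_outer = per, winner = winner,
                 winner_model = selected[[winner]],
                 models_trained = models_trained,
                 outer_folds = as.integer(outer_folds),
                 test_sets = test_sets, inner_sets = inner_sets,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Double", length(x$test_sets), "-fold CV:", x$models_trained,
      "models trained; winner outer fold", x$winner, "with test OACC",
      format(max(x$per_outer$test_oacc), digits = 4), "\n")
  print(x$per_outer, row.names = FALSE)
  invisible(x)
}
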