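#' Intra-patient experiment (triple cross-validation)
#'
#' Every image contributes to both training and testing. Each image's
#' labeled pixels are stratified into 5 folds; for each fold-grouping
#' `g = 1..5` (the same g across all images), the union of the other 4
#' folds of every image (80% of the labeled pixels per image, within
#' rounding by the round-robin assignment) is the dataset for a double
#' 5-fold cross-validation, and the selected model is then scored on the
#' union of all held-out g folds (20%). The grouping with the best
#' held-out OACC wins. Finally, per-image metrics are reported both on the
#' held-out 20% folds and (optionally) on a full-image prediction of all
#' labeled pixels — the two readings are kept clearly distinct.
#'
#' @param images List of `list(cube = , gt = )` pairs (normalized cubes),
#'   optionally named; at least 2.
#' @param spec An `hsi_model_spec`.
#' @param seed Integer master seed.
#' @param predict_full Also predict every full image with the winning model
#'   and report metrics and classification maps from it.
#' @return An `experiment_report` with `experiment = "A"`, the winning
#'   grouping `best_g`, per-grouping test OACCs, per-image metric reports
#'   (`heldout` and, if requested, `full` + `map`), the winner `cv_report`,
#'   `models_trained`, and a mean/SD OACC summary.
#' @export
run_experiment_a <- function(images, spec, seed = 1L, predict_full = TRUE) {
  images <- check_images(images)
  n_img <- length(images)
  datasets <- lapply(seq_len(n_img), function(i) {
    build_dataset(images[[i]], spec, names(images)[i])
  })
  folds <- lapply(seq_len(n_img), function(i) {
    stratified_kfold(datasets[[i]]$y, 5L, derive_seed(seed, 200L + i))
  })
  k <- 5L
  models_trained <- 0L
  best <- list(oacc = -Inf, g = NA_integer_, cv = NULL)
  g_oacc <- numeric(k)
  for (g in seq_len(k)) {
    train_ds <- bind_datasets(lapply(seq_len(n_img), function(i) {
      subset_dataset(datasets[[i]], which(folds[[i]] != g))
    }))
    cv <- double_cv(train_ds, spec, seed = derive_seed(seed, 300L + g))
    models_trained <- models_trained + cv$models_trained
    held <- lapply(seq_len(n_img), function(i) {
      subset_dataset(datasets[[i]], which(folds[[i]] == g))
    })
    held_all <- bind_datasets(held)
    go <- oacc(confusion(held_all$y, predict(cv$winner_model, held_all$x)))
    g_oacc[g] <- go
    if (go > best$oacc) best <- list(oacc = go, g = g, cv = cv)
  }
  model <- best$cv$winner_model
  per_image <- lapply(seq_len(n_img), function(i) {
    held <- subset_dataset(datasets[[i]], which(folds[[i]] == best$g))
    rep_i <- list(heldout = metric_report(
      confusion(held$y, predict(model, held$x))))
    if (predict_full) {
      map <- predict_image(model, images[[i]]$cube)
      lab <- images[[i]]$gt > 0
      rep_i$full <- metric_report(confusion(images[[i]]$gt[lab], map[lab]))
      rep_i$map <- map
    }
    rep_i
  })
  names(per_image) <- names(images)
  oaccs <- vapply(per_image, function(r) r$heldout$OACC, 0)
  structure(list(experiment = "A", best_g = best$g, grouping_oacc = g_oacc,
                 cv = best$cv, per_image = per_image,
                 heldout_oacc = oaccs, summary = summarize_oacc(oaccs),
                 models_trained = models_trained, spec = spec, seed = seed),
            class = "experiment_report")
}

#' Inter-patient experiment (leave-one-image-out)
#'
#' The surgical deployment scenario: for each image in turn, all other
#' images' labeled pixels are pooled, a double 5-fold cross-validation
#' selects the model, and the held-out image — never seen in training — is
#' classified in full. Metrics are computed on its labeled pixels.
#'
#' @inheritParams run_experiment_a
#' @param predict_full Predict the entire held-out image (classification
#'   map); if `FALSE` only its labeled pixels are predicted.
#' @return An `experiment_report` with `experiment = "B"`, per-image metric
#'   reports and maps, per-image `cv_report`s, `models_trained` (n * 25),
#'   and a mean/SD OACC summary.
#' @export
run_experiment_b <- function(images, spec, seed = 1L, predict_full = TRUE) {
  images <- check_images(images)
  n_img <- length(images)
  datasets <- lapply(seq_len(n_img), function(i) {
    build_dataset(images[[i]], spec, names(images)[i])
  })
  models_trained <- 0L
  cvs <- vector("list", n_img)
  per_image <- lapply(seq_len(n_img), function(i) {
    pool <- bind_datasets(datasets[-i])
    cv <- double_cv(pool, spec, seed = derive_seed(seed, 400L + i))
    cvs[[i]] <<- cv
    models_trained <<- models_trained + cv$models_trained
    model <- cv$winner_model
    lab <- images[[i]]$gt > 0
    if (predict_full) {
      map <- predict_image(model, images[[i]]$cube)
      rep_i <- list(metrics = metric_report(
        confusion(images[[i]]$gt[lab], map[lab])), map = map)
    } else {
      pred <- predict(model, datasets[[i]]$x)
      rep_i <- list(metrics = metric_report(confusion(datasets[[i]]$y, pred)))
    }
    rep_i$trained_on <- unique(pool$provenance$image)
    rep_i
  })
  names(per_image) <- names(images)
  oaccs <- vapply(per_image, function(r) r$metrics$OACC, 0)
  structure(list(experiment = "B", per_image = per_image, cv = cvs,
                 oacc = oaccs, summary = summarize_oacc(oaccs),
                 models_trained = models_trained, spec = spec, seed = seed),
            class = "experiment_report")
}

check_images <- function(images) {
  stopifnot(is.list(images), length(images) >= 2L)
  if (is.null(names(images)) || any(names(images) == "")) {
    names(images) <- sprintf("img%02d", seq_along(images))
  }
  for (im in images) {
    stopifnot(inherits(im$cube, "hsi_cube"),
              all(dim(im$gt) == dim(im$cube)[1:2]))
  }
  images
}

build_dataset <- function(image, spec, id) {
  if (spec$algorithm == "cnn") {
    extract_patches(image$cube, image$gt, size = spec$patch_size,
                    image_id = id)
  } else {
    extract_spectra(image$cube, image$gt, image_id = id)
  }
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment", x$experiment, "(", x$spec$algorithm, "):",
      x$models_trained, "models trained\n")
  ov <- if (x$experiment == "A") x$heldout_oacc else x$oacc
  print(round(ov, 4))
  cat("mean OACC", format(x$summary$mean, digits = 4),
      "SD", format(x$summary$sd, digits = 4), "\n")
  invisible(x)
}

#' Per-image OACC table in the layout of per-patient result tables
#'
#' @param ... Named `experiment_report`s (names become columns, e.g. one
#'   per algorithm).
#' @return A data.frame with one row per image plus MEAN and SD rows.
#' @export
oacc_table <- function(...) {
  reps <- list(...)
  cols <- lapply(reps, function(r) {
    ov <- if (r$experiment == "A") r$heldout_oacc else r$oacc
    c(ov, MEAN = r$summary$mean, SD = r$summary$sd)
  })
  out <- data.frame(patient = names(cols[[1]]), cols,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
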