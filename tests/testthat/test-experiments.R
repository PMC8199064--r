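# Structural checks of the experiment runners use the fast spectra-based
# classifiers; classifier accuracy benchmarks live in test-acceptance.R.

fix_image_set <- function(n = 3, seed0 = 80, rows = 26, ...) {
  lib <- fix_library()
  setNames(lapply(seq_len(n), function(i) {
    fix_image(seed = seed0 + i, rows = rows, cols = rows, library = lib, ...)
  }), sprintf("scene%02d", seq_len(n)))
}

test_that("intra-patient runs keep the 80/20 per-image stratified split", {
  images <- fix_image_set(3)
  spec <- hsi_model_spec("svm", seed = 1)
  rep_a <- run_experiment_a(images, spec, seed = 2, predict_full = FALSE)
  expect_equal(rep_a$models_trained, 5L * 25L)
  expect_true(rep_a$best_g %in% 1:5)
  expect_equal(length(rep_a$grouping_oacc), 5L)   # one grouping per fold id
  expect_equal(length(rep_a$per_image), 3L)
  # training fraction: winner cv saw ~80% of every image's labeled pixels
  n_lab <- vapply(images, function(im) sum(im$gt > 0), 0)
  folds_sizes <- vapply(seq_along(images), function(i) {
    f <- stratified_kfold(
      extract_spectra(images[[i]]$cube, images[[i]]$gt)$y, 5,
      hsibrain:::derive_seed(2, 200 + i))
    sum(f != rep_a$best_g)
  }, 0)
  # per class the round-robin split puts 80% +- 1 sample in training
  for (i in seq_along(images)) {
    y <- extract_spectra(images[[i]]$cube, images[[i]]$gt)$y
    f <- stratified_kfold(y, 5, hsibrain:::derive_seed(2, 200 + i))
    for (k in sort(unique(y))) {
      in_train <- sum(y[f != rep_a$best_g] == k)
      expect_lte(abs(in_train - 0.8 * sum(y == k)), 1)
    }
  }
  # winner model trained on ~64% (80% of 80%) of the pooled training pixels
  expect_lt(abs(rep_a$cv$winner_model$fingerprint$n -
                  0.64 * sum(folds_sizes)), 10)
})

test_that("leave-one-image-out never trains on the held-out image", {
  images <- fix_image_set(3)
  spec <- hsi_model_spec("svm", seed = 5)
  rep_b <- run_experiment_b(images, spec, seed = 3, predict_full = FALSE)
  expect_equal(rep_b$models_trained, 3L * 25L)
  for (i in seq_along(images)) {
    expect_false(names(images)[i] %in% rep_b$per_image[[i]]$trained_on)
    expect_equal(length(rep_b$per_image[[i]]$trained_on), 2L)
  }
  expect_equal(length(rep_b$oacc), 3L)
  expect_equal(rep_b$summary$n, 3L)
})

test_that("identical phantoms give matching intra- and inter-patient OACC", {
  # scenes drawn from one library with the same conditions: experiment B's
  # out-of-image generalization should match experiment A's held-out folds
  images <- fix_image_set(3, seed0 = 90, rows = 30, separation = 0.3,
                          noise_sd = 0.01)
  spec <- hsi_model_spec("svm", seed = 7)
  rep_a <- run_experiment_a(images, spec, seed = 4, predict_full = FALSE)
  rep_b <- run_experiment_b(images, spec, seed = 4, predict_full = FALSE)
  expect_lt(abs(rep_a$summary$mean - rep_b$summary$mean), 0.02)
})

test_that("a shifted tumor signature depresses that scene's tumor recall", {
  # s3's tumor signature sits far closer to healthy than the signature the
  # other scenes were generated (and the model trained) with
  lib <- fix_library(separation = 0.3)
  lib_shift <- fix_library(separation = 0.03)  # same seed: same base curves
  images <- list(
    s1 = fix_image(seed = 95, rows = 30, cols = 30, library = lib,
                   noise_sd = 0.01),
    s2 = fix_image(seed = 96, rows = 30, cols = 30, library = lib,
                   noise_sd = 0.01),
    s3 = fix_image(seed = 97, rows = 30, cols = 30, noise_sd = 0.01,
                   library = lib_shift)
  )
  spec <- hsi_model_spec("svm", seed = 9)
  rep_b <- run_experiment_b(images, spec, seed = 5, predict_full = FALSE)
  sen_tumor <- vapply(rep_b$per_image, function(r) {
    r$metrics$per_class$SEN[r$metrics$per_class$class == "tumor"]
  }, 0)
  expect_lt(sen_tumor["s3"], min(sen_tumor["s1"], sen_tumor["s2"]))
})

test_that("experiment reports tabulate per-image OACC with mean and SD rows", {
  images <- fix_image_set(2, seed0 = 85, rows = 22)
  spec <- hsi_model_spec("svm", seed = 1)
  rep_b <- run_experiment_b(images, spec, seed = 1, predict_full = FALSE)
  tab <- oacc_table(SVM = rep_b)
  expect_equal(nrow(tab), 4L)          # 2 scenes + MEAN + SD
  expect_equal(tab$patient[3:4], c("MEAN", "SD"))
  expect_equal(tab$SVM[3], rep_b$summary$mean)
})

test_that("full-image prediction attaches maps and full-image metrics", {
  images <- fix_image_set(2, seed0 = 87, rows = 20)
  spec <- hsi_model_spec("svm", seed = 2)
  rep_a <- run_experiment_a(images, spec, seed = 6, predict_full = TRUE)
  for (r in rep_a$per_image) {
    expect_s3_class(r$map, "class_map")
    expect_equal(dim(r$map), c(20L, 20L))
    expect_true(!is.null(r$full$OACC) && !is.null(r$heldout$OACC))
  }
})
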