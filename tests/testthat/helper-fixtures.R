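# Shared fixtures, built in code. Kept deliberately small: scenes in the
# tens of pixels per side so the whole suite stays fast.

fix_library <- function(separation = 0.25, seed = 1L) {
  make_signature_library(seed = seed, separation = separation)
}

# A normalized cube + ground truth pair from a phantom scene (the region
# map doubles as the ground truth).
fix_image <- function(seed, rows = 36, cols = 36, separation = 0.25,
                      noise_sd = 0.01, illum_amplitude = 0.3,
                      fractions = c(0.32, 0.17, 0.035, 0.02, 0.17),
                      library = NULL) {
  lib <- library %||% fix_library(separation)
  sc <- make_phantom_scene(lib, rows, cols, class_fractions = fractions,
                           illum_amplitude = illum_amplitude,
                           noise_sd = noise_sd, seed = seed)
  norm <- rms_normalize(sc$cube)$cube
  list(cube = norm, gt = sc$region_map, scene = sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random confusion matrix with labels in 1..5
fix_random_cm <- function(n = 500, seed = 1L) {
  set.seed(seed)
  confusion(sample(1:5, n, replace = TRUE), sample(1:5, n, replace = TRUE))
}

# Brute-force one-vs-rest tally straight from label vectors, independent of
# the confusion-matrix path.
brute_counts <- function(y_true, y_pred, k) {
  tp <- sum(y_true == k & y_pred == k)
  fn <- sum(y_true == k & y_pred != k)
  fp <- sum(y_true != k & y_pred == k)
  tn <- sum(y_true != k & y_pred != k)
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}
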