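#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.625 -> 0.63` at 2 digits), unlike
#' [base::round()]'s round-half-even. Used wherever tabulated percentages are
#' reported to a fixed number of decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.625, 2) # 0.63
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small guard against values like 62.49999999 that are 62.5 analytically
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Deterministic per-stage seed derived from a master seed; kept < 2^31 - 1.
derive_seed <- function(master, stage) {
  ((as.numeric(master) %% 100003) * 7919 + as.numeric(stage) * 104729) %% 2147483647
}

#' Tissue classes used throughout the package
#'
#' Integer codes 1-5 for healthy tissue, tumor, venous blood, arterial blood
#' and dura mater; 0 denotes unlabeled pixels.
#'
#' @return Named integer vector of class codes.
#' @export
hsi_classes <- function() {
  c(healthy = 1L, tumor = 2L, venous = 3L, arterial = 4L, dura = 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
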