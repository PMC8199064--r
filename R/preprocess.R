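#' Hyperspectral cube container
#'
#' A rows x cols x bands numeric array with a processing-stage tag. Stages
#' produced by the pipeline are `"raw-cube"` (straight from demosaicking),
#' `"calibrated"` (white/dark reflectance calibration), `"corrected"`
#' (spectral crosstalk correction) and `"normalized"` (per-pixel RMS
#' normalization); the synthetic generator additionally uses `"scene"` for
#' true reflectance cubes.
#'
#' @param data 3D numeric array.
#' @param stage Stage tag string.
#' @param wavelengths Optional band-center wavelengths (nm).
#' @param layout Optional band-layout matrix recorded for provenance.
#' @return An `hsi_cube` (array with attributes).
#' @export
hsi_cube <- function(data, stage = "raw-cube", wavelengths = NULL,
                     layout = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  structure(data, stage = stage, wavelengths = wavelengths,
            band_layout = layout, class = c("hsi_cube", "array"))
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x)
  cat("<hsi_cube> ", d[1], "x", d[2], "px, ", d[3], " bands, stage: ",
      cube_stage(x), "\n", sep = "")
  invisible(x)
}

#' Stage tag of a cube
#' @param x An `hsi_cube`.
#' @return Stage string.
#' @export
cube_stage <- function(x) attr(x, "stage") %||% "unknown"

#' Default 5x5 mosaic band layout
#'
#' Band index at mosaic offset (i, j) (1-based within the block), row-major:
#' band `b` sits at row offset `(b-1) %/% 5` and column offset
#' `(b-1) %% 5`. The camera vendor's layout is not published, so the
#' convention is overridable everywhere a layout is consumed and is recorded
#' in cube metadata.
#'
#' @param period Mosaic period (5).
#' @return A period x period integer matrix of band indices.
#' @export
default_band_layout <- function(period = 5L) {
  matrix(seq_len(period^2), period, period, byrow = TRUE)
}

#' Convert a raw snapshot mosaic frame into a hyperspectral cube
#'
#' The sensor frame carries all 25 bands in repeating 5x5 mosaic blocks;
#' demosaicking rearranges it (no interpolation) into a cube of spatial
#' dims `(H/5, W/5)` and 25 bands. Exact inverse of [remosaic()].
#'
#' @param raw Numeric matrix (H x W), H and W divisible by the mosaic
#'   period.
#' @param layout Band-layout matrix, see [default_band_layout()].
#' @return An `hsi_cube` with stage `"raw-cube"`.
#' @export
demosaic <- function(raw, layout = default_band_layout()) {
  stopifnot(is.matrix(raw))
  p <- nrow(layout)
  H <- nrow(raw); W <- ncol(raw)
  if (H %% p != 0L || W %% p != 0L) {
    stop("raw frame dimensions (", H, " x ", W,
         ") are not divisible by the mosaic period ", p)
  }
  R <- H %/% p; C <- W %/% p
  a <- aperm(array(raw, c(p, R, p, C)), c(2, 4, 1, 3))  # (R, C, i, j)
  dim(a) <- c(R, C, p * p)                               # slice m = i + p(j-1)
  cube <- a[, , match(seq_len(p * p), as.vector(layout)), drop = FALSE]
  hsi_cube(cube, stage = "raw-cube", layout = layout)
}

#' Rebuild the raw mosaic frame from a cube (inverse of demosaic)
#'
#' @param cube An `hsi_cube` with `p^2` bands.
#' @param layout Band-layout matrix.
#' @return A numeric matrix of dims `(p*rows, p*cols)`.
#' @export
remosaic <- function(cube, layout = default_band_layout()) {
  p <- nrow(layout)
  d <- dim(cube)
  stopifnot(d[3] == p * p)
  a <- unclass(cube)[, , as.vector(layout), drop = FALSE]  # slice m holds offset (i,j)
  a <- aperm(array(a, c(d[1], d[2], p, p)), c(3, 1, 4, 2)) # (i, R, j, C)
  dim(a) <- c(p * d[1], p * d[2])
  a
}

#' White/dark reflectance calibration
#'
#' Converts a raw cube to reflectance band per band:
#' `Ic = (I - D) / (W - D)`, where `W` and `D` are the white and dark
#' reference cubes (demosaicked with the same layout). This removes the
#' illumination spectrum and sensor offset so captures taken under
#' different surgical lighting are comparable. Denominator entries below
#' `eps` are clamped to `eps` and counted in a warning.
#'
#' @param I,W,D `hsi_cube`s of identical shape (capture, white, dark).
#' @param eps Positive denominator clamp.
#' @return An `hsi_cube` with stage `"calibrated"` and attribute
#'   `n_clamped`.
#' @export
calibrate <- function(I, W, D, eps = 1e-6) {
  stopifnot(eps > 0)
  if (!identical(dim(I), dim(W)) || !identical(dim(I), dim(D))) {
    stop("capture, white and dark cubes must have identical dimensions")
  }
  den <- unclass(W) - unclass(D)
  n_clamped <- sum(den < eps)
  if (n_clamped > 0) {
    warning(n_clamped, " white-dark denominator entr",
            if (n_clamped == 1) "y" else "ies", " below eps = ", eps,
            " were clamped", call. = FALSE)
    den[den < eps] <- eps
  }
  out <- (unclass(I) - unclass(D)) / den
  structure(hsi_cube(out, stage = "calibrated",
                     wavelengths = attr(I, "wavelengths"),
                     layout = attr(I, "band_layout")),
            n_clamped = n_clamped)
}

#' Spectral crosstalk correction
#'
#' Right-multiplies each pixel spectrum (as a row vector) by the 25x25
#' spectral correction matrix supplied by the sensor calibration: each row
#' of the matrix is the set of virtual-band correction coefficients. Undoes
#' the leakage of neighboring band responses.
#'
#' @param Ic Calibrated `hsi_cube`.
#' @param scm Correction matrix (bands x bands), or a `crosstalk_model`
#'   whose `correction` element is used.
#' @return An `hsi_cube` with stage `"corrected"`.
#' @export
spectral_correct <- function(Ic, scm) {
  if (inherits(scm, "crosstalk_model")) scm <- scm$correction
  d <- dim(Ic)
  if (!is.matrix(scm) || nrow(scm) != ncol(scm) || nrow(scm) != d[3]) {
    stop("correction matrix must be square with dimension equal to the ",
         "band count (", d[3], ")")
  }
  P <- matrix(unclass(Ic), d[1] * d[2], d[3]) %*% scm
  hsi_cube(array(P, d), stage = "corrected",
           wavelengths = attr(Ic, "wavelengths"),
           layout = attr(Ic, "band_layout"))
}

#' Per-pixel RMS normalization
#'
#' Divides every pixel spectrum by its root-mean-square over bands,
#' `coef(r,c) = sqrt(sum_b x(r,c,b)^2 / B)`, preserving spectral shape
#' independently of brightness (the brain's curved surface puts pixels at
#' different heights, hence different collected intensities). All-zero
#' pixels are degenerate: they propagate as zeros and are flagged.
#'
#' @param Isc Spectrally corrected `hsi_cube` (any stage is accepted; the
#'   output stage is always `"normalized"`).
#' @return List with `cube` (normalized `hsi_cube`), `coef` (rows x cols
#'   matrix of normalizing coefficients, 0 where degenerate) and
#'   `degenerate` (logical matrix flagging all-zero pixels).
#' @export
rms_normalize <- function(Isc) {
  d <- dim(Isc)
  P <- matrix(unclass(Isc), d[1] * d[2], d[3])
  if (any(!is.finite(P))) stop("cube contains non-finite values")
  coef <- sqrt(rowMeans(P^2))
  degen <- coef == 0
  out <- P / ifelse(degen, 1, coef)
  list(cube = hsi_cube(array(out, d), stage = "normalized",
                       wavelengths = attr(Isc, "wavelengths"),
                       layout = attr(Isc, "band_layout")),
       coef = matrix(ifelse(degen, 0, coef), d[1], d[2]),
       degenerate = matrix(degen, d[1], d[2]))
}

#' Full pre-processing chain
#'
#' Convenience wrapper running demosaic, calibrate, spectral correction and
#' RMS normalization on raw capture/white/dark mosaic frames.
#'
#' @param raw,white,dark Raw mosaic frames (matrices).
#' @param scm Spectral correction matrix or `crosstalk_model`.
#' @param layout Band-layout matrix.
#' @param eps Calibration denominator clamp.
#' @return As [rms_normalize()].
#' @export
preprocess_capture <- function(raw, white, dark, scm,
                               layout = default_band_layout(), eps = 1e-6) {
  I <- demosaic(raw, layout)
  W <- demosaic(white, layout)
  D <- demosaic(dark, layout)
  rms_normalize(spectral_correct(calibrate(I, W, D, eps = eps), scm))
}
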