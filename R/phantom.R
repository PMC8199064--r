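#' Generate a phantom brain scene with known ground truth
#'
#' Creates a synthetic scene: a region map of connected class blobs with
#' (exactly) the requested pixel fractions, a smooth multiplicative
#' illumination field emulating the brightness variation over the brain's
#' curved surface, and a true reflectance cube in which every labeled pixel
#' carries its class signature scaled by the local illumination plus
#' additive Gaussian noise (clipped at zero). Blobs are produced by
#' thresholding per-class smoothed Gaussian random fields; classes claim
#' their pixel budget sequentially in class-id order, so earlier (lower-id)
#' classes win on overlap and the requested counts are met exactly.
#'
#' @param library A `signature_library`.
#' @param rows,cols Scene dimensions in cube pixels.
#' @param class_fractions Length-5 nonnegative vector (healthy, tumor,
#'   venous, arterial, dura) of image-pixel fractions; must sum to <= 1.
#'   Defaults mirror the strong class imbalance of intraoperative labeling
#'   (arterial rare, healthy/tumor abundant) with ~71% of pixels labeled.
#' @param illum_amplitude Illumination field amplitude, defined as
#'   max/min - 1 of the field. 0 gives flat illumination.
#' @param noise_sd Standard deviation of i.i.d. additive Gaussian noise in
#'   reflectance units.
#' @param seed Integer seed; the scene is reproducible in it.
#' @param background Reflectance assigned to unlabeled pixels (flat
#'   spectrum) before illumination and noise.
#' @param blob_scale Smoothing length of the per-class random fields as a
#'   fraction of the scene's short side. Controls region granularity: the
#'   default 0.2 gives a few large coherent regions per class, like
#'   hand-labeled tissue maps; smaller values fragment the classes.
#' @return Object of class `phantom_scene`: `region_map` (rows x cols
#'   integer matrix, 0 = unlabeled), `cube` (rows x cols x bands reflectance
#'   array), `illumination`, `noise_sd`, `seed`, `library`.
#' @export
make_phantom_scene <- function(library, rows, cols,
                               class_fractions = c(healthy = 0.32,
                                                   tumor = 0.17,
                                                   venous = 0.035,
                                                   arterial = 0.014,
                                                   dura = 0.17),
                               illum_amplitude = 0.3, noise_sd = 0.02,
                               seed = 1L, background = 0.15,
                               blob_scale = 0.2) {
  stopifnot(inherits(library, "signature_library"))
  if (length(class_fractions) != 5L || any(class_fractions < 0)) {
    stop("`class_fractions` must be 5 nonnegative values")
  }
  if (sum(class_fractions) > 1 + 1e-12) {
    stop("`class_fractions` must sum to at most 1 (got ",
         format(sum(class_fractions)), ")")
  }
  if (illum_amplitude < 0) stop("`illum_amplitude` must be >= 0")
  n_bands <- ncol(library$signatures)
  npix <- rows * cols

  set.seed(derive_seed(seed, 21L))
  region <- matrix(0L, rows, cols)
  unclaimed <- rep(TRUE, npix)
  sigma <- max(2, blob_scale * min(rows, cols))
  for (k in 1:5) {
    n_k <- round(class_fractions[k] * npix)
    if (n_k == 0) next
    f <- smooth_field(rows, cols, sigma)
    f[!unclaimed] <- -Inf
    take <- order(f, decreasing = TRUE)[seq_len(n_k)]
    region[take] <- k
    unclaimed[take] <- FALSE
  }

  illum <- illumination_field(rows, cols, illum_amplitude, seed)

  refl <- matrix(background, npix, n_bands)
  lab <- as.vector(region)
  for (k in 1:5) {
    sel <- lab == k
    if (any(sel)) {
      refl[sel, ] <- matrix(library$signatures[k, ], sum(sel), n_bands,
                            byrow = TRUE)
    }
  }
  refl <- refl * as.vector(illum)
  if (noise_sd > 0) {
    refl <- refl + matrix(stats::rnorm(npix * n_bands, sd = noise_sd),
                          npix, n_bands)
  }
  refl <- pmax(refl, 0)
  cube <- hsi_cube(array(refl, c(rows, cols, n_bands)), stage = "scene",
                   wavelengths = library$wavelengths)

  structure(list(region_map = region, cube = cube, illumination = illum,
                 noise_sd = noise_sd, seed = seed, library = library,
                 class_fractions = class_fractions),
            class = "phantom_scene")
}

# Smoothed Gaussian random field via FFT convolution on the torus.
smooth_field <- function(rows, cols, sigma) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  gr <- stats::dnorm(pmin(0:(rows - 1), rows - 0:(rows - 1)), sd = sigma)
  gc <- stats::dnorm(pmin(0:(cols - 1), cols - 0:(cols - 1)), sd = sigma)
  ker <- outer(gr, gc)
  ker <- ker / sum(ker)
  Re(stats::fft(stats::fft(z) * stats::fft(ker), inverse = TRUE)) / (rows * cols)
}

# Low-order polynomial illumination dome: 1 at the rim, 1 + amplitude at the
# (seeded) apex, so max/min - 1 == amplitude exactly.
illumination_field <- function(rows, cols, amplitude, seed) {
  set.seed(derive_seed(seed, 22L))
  r0 <- stats::runif(1, rows / 3, 2 * rows / 3)
  c0 <- stats::runif(1, cols / 3, 2 * cols / 3)
  d2 <- outer((seq_len(rows) - r0)^2, (seq_len(cols) - c0)^2, "+")
  g <- 1 - d2 / max(d2)
  rg <- range(g)
  if (rg[2] > rg[1]) g <- (g - rg[1]) / (rg[2] - rg[1])  # exactly [0, 1]
  1 + amplitude * g
}

#' @export
print.phantom_scene <- function(x, ...) {
  d <- dim(x$region_map)
  cat("Phantom scene", d[1], "x", d[2], "px,",
      sum(x$region_map > 0), "labeled pixels, noise sd", x$noise_sd, "\n")
  tab <- tabulate(x$region_map[x$region_map > 0], 5)
  names(tab) <- names(hsi_classes())
  print(tab)
  invisible(x)
}

#' Sensor crosstalk model and its spectral correction matrix
#'
#' The snapshot sensor's band response curves leak into neighboring bands.
#' This is modelled as a band-mixing matrix with exponentially decaying
#' off-diagonals (Toeplitz in the band distance), column-normalised so each
#' virtual band conserves energy; the matrix is diagonally dominant and its
#' row sums are ~1. The exported spectral correction matrix is its exact
#' inverse, so un-mixing is lossless.
#'
#' @param n_bands Number of bands (25).
#' @param leak Per-neighbor leakage factor in `[0, 1)`; 0 gives the identity
#'   (no crosstalk).
#' @return Object of class `crosstalk_model`: `mixing` (bands x bands),
#'   `correction` (its inverse, the SCM).
#' @export
crosstalk_model <- function(n_bands = 25L, leak = 0.15) {
  stopifnot(leak >= 0, leak < 1)
  M <- leak^abs(outer(seq_len(n_bands), seq_len(n_bands), "-"))
  M <- sweep(M, 2, colSums(M), "/")
  structure(list(mixing = M, correction = solve(M), leak = leak),
            class = "crosstalk_model")
}

#' Render a raw mosaic capture of a phantom scene
#'
#' Forward-simulates the acquisition that the pre-processing chain inverts:
#' per pixel, reflectance is mapped to radiance
#' (`radiance = reflectance * (white_level - dark_level) + dark_level`),
#' the 25-band radiance vector is mixed by the sensor crosstalk matrix, and
#' the mixed bands are laid out in repeating 5x5 mosaic blocks. A white
#' reference frame (unit reflectance) and dark reference frame (zero
#' reflectance) are rendered through the identical model.
#'
#' @param scene A `phantom_scene`.
#' @param crosstalk A `crosstalk_model` (or a bands x bands mixing matrix).
#' @param white_level,dark_level Radiance levels of the white and dark
#'   references; `white_level > dark_level >= 0` required.
#' @param layout Optional 5x5 band-layout matrix (see [demosaic()]).
#' @return List with elements `raw`, `white`, `dark`, each a
#'   `raw_mosaic_frame` (matrix of dims 5*rows x 5*cols).
#' @export
render_capture <- function(scene, crosstalk = crosstalk_model(),
                           white_level = 0.9, dark_level = 0.05,
                           layout = default_band_layout()) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (!(white_level > dark_level && dark_level >= 0)) {
    stop("`white_level` must exceed `dark_level` and `dark_level` must be >= 0")
  }
  M <- if (inherits(crosstalk, "crosstalk_model")) crosstalk$mixing else crosstalk
  d <- dim(scene$cube)
  P <- matrix(scene$cube, d[1] * d[2], d[3])

  mix <- function(refl_mat) {
    rad <- refl_mat * (white_level - dark_level) + dark_level
    rad %*% M
  }
  raw <- remosaic(hsi_cube(array(mix(P), d), stage = "scene"), layout = layout)
  white <- remosaic(hsi_cube(array(mix(matrix(1, d[1] * d[2], d[3])), d),
                             stage = "scene"), layout = layout)
  dark <- remosaic(hsi_cube(array(mix(matrix(0, d[1] * d[2], d[3])), d),
                            stage = "scene"), layout = layout)
  list(raw = raw, white = white, dark = dark)
}
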