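#' Reference spectral signatures for the five tissue classes
#'
#' Builds a library of 25-band mean reflectance signatures (655-975 nm) for
#' healthy tissue, tumor, venous blood, arterial blood and dura mater, with
#' the qualitative relations observed intraoperatively: healthy and tumor
#' nearly coincide over the measured spectrum, venous and arterial blood are
#' mutually similar but follow a different trend, and dura mater is the most
#' distinct class. The tumor signature is constructed as the healthy
#' signature plus a smooth perturbation orthogonal (as a vector) to it, so
#' that the spectral angle between healthy and tumor grows strictly
#' monotonically with `separation` (angle = atan(separation)).
#'
#' @param seed Integer seed; the library is bitwise-reproducible in it.
#' @param separation Nonnegative scalar controlling healthy-tumor divergence.
#'   0 makes tumor identical to healthy. Values up to ~0.5 keep all
#'   signatures inside (0, 1].
#' @param n_bands Number of spectral bands (25 for the snapshot camera).
#' @return An object of class `signature_library`: list with `signatures`
#'   (5 x bands matrix, rows named by class), `sd` (within-class standard
#'   deviations, same shape), `wavelengths`, `separation`, `seed`.
#' @export
#' @examples
#' lib <- make_signature_library(seed = 1, separation = 0.1)
#' matplot(lib$wavelengths, t(lib$signatures), type = "l")
make_signature_library <- function(seed = 1L, separation = 0.1, n_bands = 25L) {
  if (!is.numeric(separation) || length(separation) != 1L || is.na(separation) ||
      separation < 0) {
    stop("`separation` must be a single nonnegative number")
  }
  wl <- seq(655, 975, length.out = n_bands)
  u <- (wl - min(wl)) / diff(range(wl))   # 0..1 across the spectrum

  set.seed(derive_seed(seed, 11L))
  # small seeded smooth wiggle so different seeds give distinct libraries
  wiggle <- function(amp) {
    k <- stats::rnorm(3, sd = amp)
    k[1] * sin(2 * pi * u) + k[2] * cos(2 * pi * u) + k[3] * sin(4 * pi * u)
  }

  # base shapes: brain tissue rises gently into the NIR; blood is dark below
  # ~800 nm (hemoglobin absorption) then rises; dura is bright and flat-ish
  healthy  <- 0.28 + 0.30 * stats::plogis((wl - 730) / 55) + wiggle(0.006)
  venous   <- 0.10 + 0.42 * stats::plogis((wl - 815) / 38) + wiggle(0.006)
  arterial <- 0.13 + 0.44 * stats::plogis((wl - 795) / 42) + wiggle(0.006)
  # dura is bright with a falling NIR slope, making its spectral *shape*
  # (what the angle metric sees) the most distinct of the five classes
  dura     <- 0.90 - 0.50 * u + 0.10 * sin(2 * pi * u) + wiggle(0.006)

  # tumor = healthy + separation * p, with p orthogonal to healthy and
  # ||p|| = ||healthy||, so angle(healthy, tumor) = atan(separation)
  shape <- sin(2 * pi * u) * (0.5 + u)
  p <- shape - sum(shape * healthy) / sum(healthy^2) * healthy
  p <- p / sqrt(sum(p^2)) * sqrt(sum(healthy^2))
  tumor <- healthy + separation * p

  sig <- rbind(healthy = healthy, tumor = tumor, venous = venous,
               arterial = arterial, dura = dura)
  sig <- pmin(sig, 1)
  if (any(sig <= 0)) {
    stop("separation too large: signatures left (0, 1]")
  }

  a <- function(i, j) sam(sig[i, ], sig[j, ])
  if (!(a("healthy", "tumor") < a("healthy", "dura")) ||
      !(a("venous", "arterial") < a("venous", "healthy"))) {
    stop("signature library violates its class-similarity invariants ",
         "(separation too large?)")
  }

  sdm <- matrix(rep(c(0.010, 0.010, 0.025, 0.025, 0.030), n_bands),
                nrow = 5, dimnames = list(rownames(sig), NULL))
  structure(list(signatures = sig, sd = sdm, wavelengths = wl,
                 separation = separation, seed = seed),
            class = "signature_library")
}

#' Perturb a signature library (inter-patient variability)
#'
#' Adds a smooth seeded perturbation to the chosen class signatures. Used to
#' emulate patient-to-patient spectral variability in inter-patient
#' (leave-one-image-out) experiments.
#'
#' @param library A `signature_library`.
#' @param sd Amplitude of the smooth perturbation (reflectance units).
#' @param seed Integer seed.
#' @param classes Character vector of class names to perturb (default all).
#' @return A new `signature_library`.
#' @export
perturb_library <- function(library, sd = 0.01, seed = 1L,
                            classes = rownames(library$signatures)) {
  stopifnot(inherits(library, "signature_library"))
  u <- (library$wavelengths - min(library$wavelengths)) /
    diff(range(library$wavelengths))
  set.seed(derive_seed(seed, 13L))
  out <- library
  for (cl in classes) {
    k <- stats::rnorm(3, sd = sd)
    d <- k[1] * sin(2 * pi * u) + k[2] * cos(2 * pi * u) + k[3] * u
    out$signatures[cl, ] <- pmin(pmax(library$signatures[cl, ] + d, 1e-3), 1)
  }
  out
}

#' @export
print.signature_library <- function(x, ...) {
  cat("Signature library:", nrow(x$signatures), "classes,",
      ncol(x$signatures), "bands (",
      min(x$wavelengths), "-", max(x$wavelengths), "nm )\n")
  cat("  separation (healthy vs tumor):", x$separation,
      "-> spectral angle", format(atan(x$separation), digits = 4), "rad\n")
  invisible(x)
}
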