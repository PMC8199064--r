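#' Spectral angle between two spectra
#'
#' The spectral angle mapper (SAM) similarity:
#' `acos(<x, ref> / (||x|| * ||ref||))`, in radians in `[0, pi]`. Invariant
#' to positive rescaling of either argument and symmetric.
#'
#' @param x,ref Nonzero numeric vectors of equal length.
#' @return Angle in radians.
#' @export
#' @examples
#' sam(c(1, 1, 0), c(1, 0, 0)) # pi/4
sam <- function(x, ref) {
  if (length(x) != length(ref)) stop("spectra must have equal length")
  nx <- sqrt(sum(x^2)); nr <- sqrt(sum(ref^2))
  if (nx == 0 || nr == 0) stop("SAM is undefined for a zero spectrum")
  acos(pmin(pmax(sum(x * ref) / (nx * nr), -1), 1))
}

# Vectorized SAM of every cube pixel against one reference spectrum.
# Zero pixels get angle NA.
sam_map <- function(cube, ref) {
  d <- dim(cube)
  P <- matrix(unclass(cube), d[1] * d[2], d[3])
  nr <- sqrt(sum(ref^2))
  if (nr == 0) stop("SAM is undefined for a zero spectrum")
  np <- sqrt(rowSums(P^2))
  cosang <- as.vector(P %*% ref) / (np * nr)
  ang <- acos(pmin(pmax(cosang, -1), 1))
  ang[np == 0] <- NA_real_
  matrix(ang, d[1], d[2])
}

#' Create an empty ground-truth map
#'
#' @param rows,cols Spatial dimensions (must match the cube being labeled).
#' @return A `gt_map`: integer matrix of labels (0 = unlabeled, 1-5 =
#'   tissue classes) with a provenance attribute recording labeling actions.
#' @export
new_gt_map <- function(rows, cols) {
  structure(matrix(0L, rows, cols), provenance = list(), class = "gt_map")
}

#' @export
print.gt_map <- function(x, ...) {
  cat("<gt_map>", nrow(x), "x", ncol(x), "px,", sum(x > 0),
      "labeled pixels,", length(attr(x, "provenance")), "actions\n")
  invisible(x)
}

#' SAM-threshold labeling action
#'
#' Reproduces one action of the interactive ground-truth labeling tool: the
#' annotator picks a seed pixel and a tolerance; every pixel of the image
#' whose spectral angle to the seed pixel's spectrum is at most the
#' threshold receives the class. Thresholding is global (no connectivity
#' constraint) and the reference spectrum is the single seed pixel's
#' spectrum. The action is appended to the map's provenance so the map can
#' be replayed exactly.
#'
#' @param cube Normalized-stage `hsi_cube`.
#' @param seed_pixel Integer `(row, col)` of the reference pixel.
#' @param class_id Class to assign (1-5).
#' @param threshold SAM tolerance in radians (> 0).
#' @param gt A `gt_map` (created with [new_gt_map()] if missing).
#' @param overwrite If `TRUE` (interactive-tool semantics, the default),
#'   this action overwrites earlier labels; if `FALSE` only unlabeled
#'   pixels are touched. Recorded in provenance.
#' @return The updated `gt_map`.
#' @export
label_by_threshold <- function(cube, seed_pixel, class_id, threshold,
                               gt = NULL, overwrite = TRUE) {
  d <- dim(cube)
  if (cube_stage(cube) != "normalized") {
    stop("labeling requires a normalized-stage cube (got stage '",
         cube_stage(cube), "')")
  }
  if (is.null(gt)) gt <- new_gt_map(d[1], d[2])
  stopifnot(inherits(gt, "gt_map"), nrow(gt) == d[1], ncol(gt) == d[2])
  if (!(class_id %in% 1:5)) stop("`class_id` must be in 1..5")
  if (!(threshold > 0)) stop("`threshold` must be positive")
  r <- seed_pixel[1]; c <- seed_pixel[2]
  if (r < 1 || r > d[1] || c < 1 || c > d[2]) {
    stop("seed pixel (", r, ", ", c, ") is out of bounds for a ",
         d[1], " x ", d[2], " image")
  }
  ref <- unclass(cube)[r, c, ]
  ang <- sam_map(cube, ref)
  hit <- !is.na(ang) & ang <= threshold
  hit[r, c] <- TRUE   # the seed's self-angle is 0 analytically
  if (!overwrite) hit <- hit & gt == 0L
  prov <- attr(gt, "provenance")
  gt[hit] <- as.integer(class_id)
  prov[[length(prov) + 1L]] <- list(seed_pixel = c(r, c),
                                    class_id = as.integer(class_id),
                                    threshold = threshold,
                                    overwrite = overwrite)
  attr(gt, "provenance") <- prov
  gt
}

#' Replay a labeling provenance log
#'
#' Re-applies every recorded labeling action to an empty map; the result is
#' identical to the original ground-truth map.
#'
#' @param cube Normalized-stage `hsi_cube` the actions refer to.
#' @param provenance A provenance list (or a `gt_map` whose provenance is
#'   taken).
#' @return A reconstructed `gt_map`.
#' @export
replay_provenance <- function(cube, provenance) {
  if (inherits(provenance, "gt_map")) provenance <- attr(provenance, "provenance")
  gt <- new_gt_map(dim(cube)[1], dim(cube)[2])
  for (a in provenance) {
    gt <- label_by_threshold(cube, a$seed_pixel, a$class_id, a$threshold,
                             gt, overwrite = a$overwrite)
  }
  gt
}

#' Per-class labeled-pixel counts and percentages
#'
#' Tabulates labels 1-5 of a ground-truth map (or takes a ready-made count
#' vector, e.g. a row of a published dataset table) and reports counts plus
#' percentages of the labeled total, rounded half-up to 2 decimals. With no
#' labeled pixels the percentages are undefined and reported as `NA`.
#'
#' @param gt A `gt_map`, or a length-5 (named or positional) integer count
#'   vector in class order.
#' @return A data.frame with columns `class`, `count`, `percent`, plus a
#'   `total` attribute.
#' @export
gt_class_counts <- function(gt) {
  if (inherits(gt, "gt_map") || is.matrix(gt)) {
    counts <- tabulate(gt[gt > 0], nbins = 5L)
  } else {
    stopifnot(length(gt) == 5L, all(gt >= 0))
    counts <- as.integer(gt)
  }
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else
    rep(NA_real_, 5L)
  structure(data.frame(class = names(hsi_classes()), count = counts,
                       percent = pct),
            total = total)
}
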