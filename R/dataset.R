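#' Build a labeled spectra dataset from a cube and its ground truth
#'
#' One row of 25 normalized band values per labeled pixel; used by the SVM
#' and random-forest classifiers.
#'
#' @param cube Normalized-stage `hsi_cube`.
#' @param gt `gt_map` (or integer label matrix) of the same spatial dims;
#'   `NULL` takes every pixel (labels 0), as used for whole-image
#'   prediction.
#' @param image_id Identifier recorded per sample in the provenance.
#' @return An `hsi_dataset` with `kind = "spectra"`: `x` (N x bands
#'   matrix), `y` (integer labels), `provenance` (image, r, c per sample).
#' @export
extract_spectra <- function(cube, gt, image_id = "img") {
  d <- dim(cube)
  sel <- dataset_selection(gt, d)
  P <- matrix(unclass(cube), d[1] * d[2], d[3])
  new_dataset(x = P[sel$idx, , drop = FALSE], y = sel$y, kind = "spectra",
              provenance = sel$prov(image_id))
}

#' Extract overlapping patches for the 3D CNN
#'
#' One `size x size x bands` patch per labeled pixel, with the target pixel
#' at the center and the patch label equal to the center pixel's label.
#' Border patches are completed by mirror padding (reflection about the
#' edge pixel) of `(size-1)/2` pixels, so no edge label is dropped. The
#' patch is flattened in (row, col, band) order.
#'
#' @param cube Normalized-stage `hsi_cube`.
#' @param gt `gt_map` or label matrix; `NULL` takes every pixel.
#' @param size Odd patch side length (9 in this work).
#' @param image_id Identifier recorded per sample.
#' @return An `hsi_dataset` with `kind = "patches"`, `x` of dims
#'   N x (size^2 * bands) and a `patch_dim` field `c(size, size, bands)`.
#' @export
extract_patches <- function(cube, gt, size = 9L, image_id = "img") {
  if (size %% 2L == 0L) stop("patch `size` must be odd")
  d <- dim(cube)
  p <- (size - 1L) %/% 2L
  sel <- dataset_selection(gt, d)
  padded <- unclass(cube)[mirror_index(seq_len(d[1] + 2 * p) - p, d[1]),
                          mirror_index(seq_len(d[2] + 2 * p) - p, d[2]), ,
                          drop = FALSE]
  nfeat <- size * size * d[3]
  x <- matrix(0, length(sel$idx), nfeat)
  rr <- sel$r; cc <- sel$c
  for (i in seq_along(sel$idx)) {
    x[i, ] <- padded[rr[i]:(rr[i] + size - 1L),
                     cc[i]:(cc[i] + size - 1L), ]
  }
  ds <- new_dataset(x = x, y = sel$y, kind = "patches",
                    provenance = sel$prov(image_id))
  ds$patch_dim <- c(size, size, d[3])
  ds
}

# Mirror (reflect about the edge pixel) an out-of-range index into 1..n.
mirror_index <- function(i, n) {
  repeat {
    bad_lo <- i < 1L
    bad_hi <- i > n
    if (!any(bad_lo | bad_hi)) return(i)
    i[bad_lo] <- 2L - i[bad_lo]
    i[bad_hi] <- 2L * n - i[bad_hi]
  }
}

dataset_selection <- function(gt, d) {
  if (is.null(gt)) {
    idx <- seq_len(d[1] * d[2])
    y <- rep(0L, length(idx))
  } else {
    stopifnot(nrow(gt) == d[1], ncol(gt) == d[2])
    idx <- which(as.vector(gt) > 0L)
    y <- as.integer(gt[idx])
  }
  r <- ((idx - 1L) %% d[1]) + 1L
  c <- ((idx - 1L) %/% d[1]) + 1L
  list(idx = idx, y = y, r = r, c = c,
       prov = function(id) data.frame(image = id, r = r, c = c))
}

new_dataset <- function(x, y, kind, provenance) {
  key <- paste(provenance$image, provenance$r, provenance$c)
  if (anyDuplicated(key)) stop("duplicate (image, r, c) samples")
  structure(list(x = x, y = as.integer(y), kind = kind,
                 provenance = provenance),
            class = "hsi_dataset")
}

#' @export
print.hsi_dataset <- function(x, ...) {
  cat("<hsi_dataset>", nrow(x$x), x$kind, "samples,", ncol(x$x),
      "features;", length(unique(x$provenance$image)), "image(s)\n")
  print(table(x$y))
  invisible(x)
}

#' Subset a dataset by sample index
#' @param data An `hsi_dataset`.
#' @param idx Integer sample indices.
#' @return The subsetted `hsi_dataset`.
#' @export
subset_dataset <- function(data, idx) {
  out <- data
  out$x <- data$x[idx, , drop = FALSE]
  out$y <- data$y[idx]
  out$provenance <- data$provenance[idx, , drop = FALSE]
  out
}

#' Concatenate datasets of the same kind
#' @param ... `hsi_dataset` objects (or a single list of them).
#' @return The combined `hsi_dataset`.
#' @export
bind_datasets <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && !inherits(dss[[1]], "hsi_dataset")) dss <- dss[[1]]
  stopifnot(length(unique(vapply(dss, `[[`, "", "kind"))) == 1L)
  out <- dss[[1]]
  out$x <- do.call(rbind, lapply(dss, `[[`, "x"))
  out$y <- unlist(lapply(dss, `[[`, "y"), use.names = FALSE)
  out$provenance <- do.call(rbind, lapply(dss, `[[`, "provenance"))
  key <- paste(out$provenance$image, out$provenance$r, out$provenance$c)
  if (anyDuplicated(key)) stop("duplicate (image, r, c) samples after binding")
  out
}
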