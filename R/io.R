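#' Write a cube as ENVI (BSQ, float32)
#'
#' Writes `<path>.raw` (band-sequential little-endian float32) and
#' `<path>.hdr`, plus a JSON sidecar `<path>.json` recording the stage tag,
#' band layout and wavelengths so the processing provenance travels with
#' the file.
#'
#' @param cube An `hsi_cube`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  d <- dim(cube)
  hdr <- c("ENVI",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bsq",
           "byte order = 0")
  wl <- attr(cube, "wavelengths")
  if (!is.null(wl)) {
    hdr <- c(hdr, paste0("wavelength = { ",
                         paste(format(wl, trim = TRUE), collapse = " , "),
                         " }"))
  }
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  # BSQ: all of band 1 (row-major within band? ENVI is row-major per line),
  # i.e. for each band, lines of `samples` values
  for (b in seq_len(d[3])) {
    writeBin(as.vector(t(unclass(cube)[, , b])), con, size = 4,
             endian = "little")
  }
  sidecar <- list(stage = cube_stage(cube),
                  band_layout = attr(cube, "band_layout"),
                  wavelengths = wl)
  sidecar <- sidecar[!vapply(sidecar, is.null, TRUE)]
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ENVI cube written by [write_envi()]
#'
#' Supports BSQ float32 files with the minimal header fields; restores the
#' stage tag and wavelengths from the JSON sidecar when present.
#'
#' @param path Path without extension.
#' @return An `hsi_cube`.
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("ENVI header not found: ", hdr_path)
  hdr <- readLines(hdr_path)
  field <- function(name) {
    ln <- grep(paste0("^", name, " *="), hdr, value = TRUE)
    if (!length(ln)) stop("missing ENVI header field: ", name)
    as.integer(sub(".*= *", "", ln[1]))
  }
  samples <- field("samples"); lines <- field("lines"); bands <- field("bands")
  if (field("data type") != 4L) stop("only float32 (data type 4) is supported")
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = samples * lines * bands, size = 4,
                  endian = "little")
  cube <- array(0, c(lines, samples, bands))
  per_band <- samples * lines
  for (b in seq_len(bands)) {
    cube[, , b] <- t(matrix(vals[((b - 1) * per_band + 1):(b * per_band)],
                            samples, lines))
  }
  stage <- "raw-cube"; wl <- NULL; layout <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    stage <- sc$stage %||% stage
    wl <- sc$wavelengths
    bl <- sc$band_layout
    if (is.list(bl)) bl <- do.call(rbind, lapply(bl, unlist))
    if (length(bl)) layout <- matrix(as.integer(bl), nrow(bl))
  }
  hsi_cube(cube, stage = stage, wavelengths = wl, layout = layout)
}

#' Class color palette for classification maps
#'
#' The rendering convention of the intraoperative study: green healthy
#' tissue, red tumor, blue venous blood, cyan arterial blood, pink dura
#' mater; unlabeled background is black.
#'
#' @return Named character vector of hex colors for labels 0-5.
#' @export
hsi_palette <- function() {
  c(background = "#000000", healthy = "#00FF00", tumor = "#FF0000",
    venous = "#0000FF", arterial = "#00FFFF", dura = "#FF69B4")
}

#' Render a label map to a PNG file
#'
#' Writes an RGB PNG using exactly the palette colors (one color per
#' class); identical inputs give identical bytes. The rendering is lossless:
#' [read_map()] recovers the label grid exactly.
#'
#' @param map A `class_map`, `gt_map` or integer label matrix.
#' @param path Output PNG path.
#' @param palette Named colors for labels 0..(length-1), see
#'   [hsi_palette()].
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, palette = hsi_palette()) {
  labs <- as.integer(map)
  if (any(labs < 0L | labs >= length(palette))) {
    stop("map contains labels outside the palette (0..",
         length(palette) - 1L, ")")
  }
  rgb <- grDevices::col2rgb(palette) / 255
  img <- array(0, c(nrow(map), ncol(map), 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, labs + 1L], nrow(map))
  png::writePNG(img, path)
  invisible(path)
}

#' Read a label map back from a rendered PNG
#'
#' @param path PNG path written by [render_map()].
#' @param palette The palette used to render it.
#' @return Integer label matrix.
#' @export
read_map <- function(path, palette = hsi_palette()) {
  img <- png::readPNG(path)
  rgb <- round(grDevices::col2rgb(palette))
  key <- paste(rgb[1, ], rgb[2, ], rgb[3, ])
  obs <- paste(round(img[, , 1] * 255), round(img[, , 2] * 255),
               round(img[, , 3] * 255))
  m <- match(obs, key) - 1L
  if (anyNA(m)) stop("PNG contains colors outside the palette")
  matrix(m, dim(img)[1], dim(img)[2])
}

#' Write a ground-truth map as CSV plus provenance JSON
#'
#' CSV columns are `(r, c, label)` for labeled pixels; the labeling actions
#' go to `<path>.json` so the map can be replayed.
#'
#' @param gt A `gt_map`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_gt <- function(gt, path) {
  idx <- which(gt > 0L)
  df <- data.frame(r = ((idx - 1L) %% nrow(gt)) + 1L,
                   c = ((idx - 1L) %/% nrow(gt)) + 1L,
                   label = as.integer(gt[idx]))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(rows = nrow(gt), cols = ncol(gt),
                            provenance = attr(gt, "provenance")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth map from CSV (+ sidecar)
#'
#' @param path Path without extension.
#' @return A `gt_map`.
#' @export
read_gt <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".json"))  # keep provenance a list
  df <- utils::read.csv(paste0(path, ".csv"))
  gt <- new_gt_map(sc$rows, sc$cols)
  gt[cbind(df$r, df$c)] <- as.integer(df$label)
  attr(gt, "provenance") <- lapply(sc$provenance, function(a) {
    list(seed_pixel = unlist(a$seed_pixel), class_id = a$class_id,
         threshold = a$threshold, overwrite = a$overwrite)
  })
  gt
}

#' Serialize a phantom scene to a directory
#'
#' ENVI cube, PNG region map and a JSON sidecar with the generator
#' parameters and seed.
#'
#' @param scene A `phantom_scene`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_envi(scene$cube, file.path(dir, "cube"))
  render_map(scene$region_map, file.path(dir, "region_map.png"))
  params <- list(seed = scene$seed, noise_sd = scene$noise_sd,
                 class_fractions = as.list(scene$class_fractions),
                 separation = scene$library$separation,
                 library_seed = scene$library$seed,
                 rows = nrow(scene$region_map), cols = ncol(scene$region_map))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
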