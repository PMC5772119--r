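#' Write / read a calibrated single-channel TIFF
#'
#' Grey values are stored at the stated bit depth. The pixel-size
#' calibration is written to a small JSON sidecar (`<file>.json`) so it
#' travels with the image; [read_image()] restores it.
#'
#' @param path TIFF filename.
#' @param image Numeric matrix on the native grey scale.
#' @param bit_depth 8 or 16.
#' @param pixel_size Micrometres per pixel.
#' @export
write_image <- function(path, image, bit_depth = 8L, pixel_size = NULL) {
  image <- as_mat(image)
  tiff::writeTIFF(clip_grey(image, bit_depth) / max_grey(bit_depth), path,
                  bits.per.sample = as.integer(bit_depth))
  if (!is.null(pixel_size)) {
    jsonlite::write_json(list(pixel_size_um = pixel_size,
                              bit_depth = bit_depth),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_image
#' @return `read_image()`: a numeric matrix with attributes `pixel_size`
#'   (if a sidecar is present) and `bit_depth`.
#' @export
read_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(m, "pixel_size") <- meta$pixel_size_um
    attr(m, "bit_depth") <- meta$bit_depth
  }
  m
}

#' Load a tile grid from disk
#'
#' Reads either a `manifest.json` (as written by [generate_tile_grid()]) or
#' falls back to filenames matching `r{row}_c{col}.tif`.
#'
#' @param dir Directory of single-channel TIFF tiles.
#' @return A tibble with columns `row`, `col` and a list-column `image`.
#' @export
read_tile_grid <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    tb <- as_tibble(man[, c("row", "col", "filename")])
  } else {
    files <- list.files(dir, pattern = "^r\\d+_c\\d+\\.tif$")
    if (length(files) == 0) abort(paste("no tiles found in", dir))
    m <- regmatches(files, regexec("^r(\\d+)_c(\\d+)\\.tif$", files))
    tb <- tibble(row = as.integer(vapply(m, `[`, "", 2)),
                 col = as.integer(vapply(m, `[`, "", 3)),
                 filename = files)
  }
  tb$image <- lapply(file.path(dir, tb$filename), read_image)
  tb[order(tb$row, tb$col), c("row", "col", "image")]
}

#' Estimate the background grey level of a tile
#'
#' The slide background dominates a well-sampled tile, so its grey level is
#' the mode of the intensity histogram (values rounded to integer grey
#' levels; ties break to the lowest mode).
#'
#' @param image Numeric matrix.
#' @return The modal grey value (numeric scalar).
#' @export
estimate_background <- function(image) {
  v <- round(as.vector(as_mat(image)))
  if (length(v) == 0) abort("estimate_background: empty tile")
  tb <- table(v)
  as.numeric(names(tb)[which.max(tb)])   # names sorted ascending: lowest tie
}

#' Normalize tile brightness to a common background level
#'
#' Illumination fluctuations between acquisitions act as a multiplicative
#' gain, so each tile is scaled by `reference / background(tile)` and
#' clipped to the bit depth. With `reference = "median"` the target is the
#' median of all tile backgrounds.
#'
#' @param tiles A tibble with list-column `image` (see [read_tile_grid()]),
#'   or a plain list of matrices.
#' @param reference `"median"` or a numeric grey value.
#' @param bit_depth Bit depth used for clipping.
#' @return The input tiles with rescaled images and a `gain` column
#'   (attribute `gains` for list input).
#' @export
normalize_tiles <- function(tiles, reference = "median", bit_depth = 8L) {
  plain <- !is.data.frame(tiles)
  imgs <- if (plain) tiles else tiles$image
  if (length(imgs) < 1) abort("normalize_tiles: need at least one tile")
  bg <- vapply(imgs, estimate_background, numeric(1))
  if (any(bg == 0)) abort("normalize_tiles: background estimate of 0")
  ref <- if (identical(reference, "median")) median(bg) else as.numeric(reference)
  gains <- ref / bg
  scaled <- purrr::map2(imgs, gains,
                        function(im, g) clip_grey(as_mat(im) * g, bit_depth))
  if (plain) {
    attr(scaled, "gains") <- gains
    scaled
  } else {
    tiles$image <- scaled
    tiles$gain <- gains
    tiles
  }
}

#' Stitch a tile grid into a whole-slide mosaic
#'
#' Tiles are placed at their nominal stage offsets (step =
#' `round(tile_width * (1 - overlap_fraction))`); no feature registration is
#' attempted because the grid geometry comes from a motorized stage. In
#' overlap zones the tile placed later in meander order wins, so the result
#' does not depend on the order tiles are supplied in.
#'
#' @param tiles Tibble with columns `row`, `col` and list-column `image`
#'   (0-based grid positions).
#' @param rows,cols Grid shape.
#' @param overlap_fraction Overlap between adjacent tiles (0 <= f < 1).
#' @param pixel_size Micrometres per pixel, recorded on the mosaic.
#' @return A numeric matrix of the closed-form footprint
#'   `tile + (n - 1) * step` per axis, with attributes `pixel_size` and
#'   `provenance` (grid shape, overlap, and gains when present).
#' @export
stitch <- function(tiles, rows, cols, overlap_fraction, pixel_size = 0.78) {
  stopifnot(rows >= 1, cols >= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  if (nrow(tiles) != rows * cols) {
    abort(sprintf("stitch: expected %d tiles, got %d", rows * cols,
                  nrow(tiles)))
  }
  d <- dim(tiles$image[[1]])
  if (!all(vapply(tiles$image, function(im) identical(dim(as_mat(im)), d),
                  logical(1)))) {
    abort("stitch: tiles must share dimensions")
  }
  th <- d[1]; tw <- d[2]
  step_x <- round(tw * (1 - overlap_fraction))
  step_y <- round(th * (1 - overlap_fraction))
  out <- matrix(0, th + (rows - 1) * step_y, tw + (cols - 1) * step_x)
  ord <- meander_order(rows, cols)
  for (i in seq_len(nrow(ord))) {
    r <- ord$row[i]; cl <- ord$col[i]
    j <- which(tiles$row == r & tiles$col == cl)
    if (length(j) != 1) {
      abort(sprintf("stitch: missing tile for grid position (%d, %d)", r, cl))
    }
    out[r * step_y + seq_len(th), cl * step_x + seq_len(tw)] <-
      as_mat(tiles$image[[j]])
  }
  attr(out, "pixel_size") <- pixel_size
  attr(out, "provenance") <- list(rows = rows, cols = cols,
                                  overlap = overlap_fraction,
                                  gains = tiles[["gain"]])
  out
}
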