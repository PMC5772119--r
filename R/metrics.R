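#' Basic per-particle shape and intensity descriptors
#'
#' Computes area, intensity statistics and the moments-ellipse family of
#' shape descriptors for one particle mask. The fitted ellipse has the same
#' second central moments as the pixel set (with the 1/12 per-pixel
#' variance term, so 1-px-wide shapes stay non-degenerate), rescaled so its
#' area equals the mask area. The perimeter is a traced boundary chain with
#' sqrt(2) weighting for diagonal steps. Circularity (4*pi*A/P^2) is capped
#' at 1.
#'
#' @param mask Logical matrix, one particle.
#' @param image Numeric intensity matrix aligned with `mask`.
#' @param pixel_size Micrometres per pixel.
#' @return A one-row tibble: `n_px`, `area_um2`, `mean_intensity`,
#'   `sd_intensity`, `perimeter_um`, `major_um`, `minor_um`,
#'   `orientation_deg`, `circularity`, `roundness` (4A/(pi*major^2)),
#'   `elongation` (major/minor), `solidity` (area over convex-hull area,
#'   hull taken over pixel corners).
#' @export
basic_metrics <- function(mask, image, pixel_size = 0.78) {
  mask <- mask > 0
  if (!any(mask)) abort("basic_metrics: empty mask")
  coords <- which(mask, arr.ind = TRUE)
  n <- nrow(coords)
  vals <- as_mat(image)[mask]
  ell <- fit_ellipse(coords)
  P <- perimeter_px(mask)
  circ <- if (P > 0) min(1, 4 * pi * n / P^2) else 1
  tibble(n_px = n, area_um2 = n * pixel_size^2,
         mean_intensity = mean(vals),
         sd_intensity = if (n > 1) sd(vals) else 0,
         perimeter_um = P * pixel_size,
         major_um = 2 * ell$a * pixel_size,
         minor_um = 2 * ell$b * pixel_size,
         orientation_deg = ell$angle_deg,
         circularity = circ,
         roundness = 4 * n / (pi * (2 * ell$a)^2),
         elongation = ell$a / ell$b,
         solidity = n / hull_area(coords))
}

# same-second-moments ellipse (population moments + 1/12 pixel term),
# rescaled to the mask area; semi-axes in px
fit_ellipse <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  S <- crossprod(cc) / n + diag(1 / 12, 2)
  e <- eigen(S, symmetric = TRUE)
  a0 <- 2 * sqrt(e$values[1]); b0 <- 2 * sqrt(e$values[2])
  k <- sqrt(n / (pi * a0 * b0))
  v <- e$vectors[, 1]                       # (row, col) components
  ang <- atan2(-v[1], v[2]) * 180 / pi      # vs x-axis, y up
  list(a = k * a0, b = k * b0, angle_deg = ang %% 180,
       center = ctr)
}

# boundary chain length from the traced outer contour, with the standard
# corner-corrected Freeman-chain weights (Vossepoel-Smeulders): axial steps
# 0.980, diagonal steps 1.406, minus 0.091 per direction change — unbiased
# to ~0.5% on smooth shapes, where plain sqrt(2) weighting runs ~5% long
perimeter_px <- function(mask) {
  oc <- EBImage::ocontour(matrix(as.integer(mask > 0), nrow(mask),
                                 ncol(mask)))
  if (length(oc) == 0) return(0)
  ct <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  if (nrow(ct) < 2) return(0)
  d <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
  diag <- rowSums(abs(d)) == 2
  dirs <- atan2(d[, 2], d[, 1])
  corners <- sum(dirs != c(dirs[-1], dirs[1]))
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * corners
}

# convex hull area over pixel corners (each pixel a unit square)
hull_area <- function(coords) {
  off <- cbind(rep(c(-0.5, 0.5), each = 2), c(-0.5, 0.5, -0.5, 0.5))
  pts <- coords[rep(seq_len(nrow(coords)), each = 4), , drop = FALSE] +
    off[rep(1:4, nrow(coords)), ]
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
          hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
}

#' Maximum Feret diameter by rotation
#'
#' The particle's pixel coordinates are rotated in `step_deg` increments
#' over 0-178 degrees and the vertical pixel extent (max - min + 1) is
#' recorded at each angle; the maximum, converted to micrometres, is the
#' particle's longest axis. Only convex-hull vertices are rotated (the
#' extent of a point set is attained on its hull).
#'
#' @param mask Logical matrix.
#' @param step_deg Rotation increment in degrees (default 2).
#' @param pixel_size Micrometres per pixel.
#' @return Length in micrometres.
#' @export
feret_max <- function(mask, step_deg = 2, pixel_size = 0.78) {
  coords <- which(mask > 0, arr.ind = TRUE)
  if (nrow(coords) == 0) abort("feret_max: empty mask")
  pts <- coords
  if (nrow(pts) > 2) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- pts[, 1, drop = FALSE] %*% cos(th) + pts[, 2, drop = FALSE] %*% sin(th)
  ext <- apply(proj, 2, function(p) max(p) - min(p)) + 1
  max(ext) * pixel_size
}

#' Perimeter roughness
#'
#' The traced object perimeter divided by the perimeter of its fitted
#' ellipse (Ramanujan's second approximation). Protruding hyphae inflate
#' the numerator, so rough, hairy particles score well above 1.
#'
#' @inheritParams basic_metrics
#' @return Unitless ratio.
#' @export
roughness <- function(mask, pixel_size = 0.78) {
  mask <- mask > 0
  if (!any(mask)) abort("roughness: empty mask")
  ell <- fit_ellipse(which(mask, arr.ind = TRUE))
  perimeter_px(mask) / ellipse_perimeter(ell$a, ell$b)
}

# Ramanujan II approximation of an ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Morphology number
#'
#' A dimensionless composite of area, solidity, maximal diameter and
#' elongation: `Mn = 2 * sqrt(A / pi) * S / (feret * E)`. A perfect disk
#' scores 1; elongated or ragged particles tend towards 0.
#'
#' @param area_um2 Particle area (um^2).
#' @param solidity Area over convex-hull area.
#' @param feret_um Maximum Feret diameter (um).
#' @param elongation Major over minor fitted-ellipse axis.
#' @return Unitless Mn.
#' @export
morphology_number <- function(area_um2, solidity, feret_um, elongation) {
  if (any(feret_um == 0)) abort("morphology_number: feret_um of 0")
  2 * sqrt(area_um2 / pi) * solidity / (feret_um * elongation)
}

#' Box-counting fractal dimensions
#'
#' Box counting over dyadic box sizes `s in {2, 4, ..., side/4}` (side =
#' the bounding-box square side): `N(s)` = boxes containing any foreground;
#' the dimension is the least-squares slope of `log N` versus `log(1/s)`.
#' The box mass dimension `D_BM` uses the filled mask, the box surface
#' dimension `D_BS` its 1-px boundary, and the fractal quotient is
#' `FQ = D_BM / D_BS`. Masks with a bounding box under 16 px get `NA`
#' values and a flag rather than an error.
#'
#' @param mask Logical matrix.
#' @return A list: `dbm`, `dbs`, `fq`, `flag` (`NA` or
#'   `"fractal_undefined"`).
#' @export
fractal_dimensions <- function(mask) {
  mask <- mask > 0
  coords <- which(mask, arr.ind = TRUE)
  if (nrow(coords) == 0) abort("fractal_dimensions: empty mask")
  sub <- mask[min(coords[, 1]):max(coords[, 1]),
              min(coords[, 2]):max(coords[, 2]), drop = FALSE]
  side <- max(dim(sub))
  if (side < 16) {
    return(list(dbm = NA_real_, dbs = NA_real_, fq = NA_real_,
                flag = "fractal_undefined"))
  }
  dbm <- box_dimension(sub, side)
  dbs <- box_dimension(boundary_4(sub), side)
  list(dbm = dbm, dbs = dbs, fq = dbm / dbs, flag = NA_character_)
}

# least-squares box-counting dimension over dyadic sizes up to side/4
box_dimension <- function(mask, side = max(dim(mask))) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  sizes <- 2^seq(1, floor(log2(side / 4)))
  ns <- vapply(sizes, function(s) {
    length(unique(((idx[, 1] - 1) %/% s) * 2^26 + (idx[, 2] - 1) %/% s))
  }, numeric(1))
  unname(coef(lm(log(ns) ~ log(1 / sizes)))[2])
}

# 1-px boundary: foreground pixels with a 4-neighbour outside the mask
boundary_4 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(FALSE, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  core <- pad[2:(n + 1), 2:(m + 1), drop = FALSE]
  er <- core & pad[1:n, 2:(m + 1), drop = FALSE] &
    pad[3:(n + 2), 2:(m + 1), drop = FALSE] &
    pad[2:(n + 1), 1:m, drop = FALSE] &
    pad[2:(n + 1), 3:(m + 2), drop = FALSE]
  core & !er
}

#' Polar circularity
#'
#' Circularity from the radial distribution of all object pixels about the
#' unweighted centroid: with `r_bar` the mean pixel distance from the
#' centroid and `r_eq = sqrt(A / pi)` the equivalent-disk radius,
#' `C = min(1, 2 * r_eq / (3 * r_bar))`. A disk scores 1 (its mean radius
#' is 2R/3); mass far from the centroid lowers the score. Because every
#' pixel contributes — not just the perimeter — protruding hyphae barely
#' move it, unlike the conventional 4*pi*A/P^2 circularity.
#'
#' @inheritParams basic_metrics
#' @return Value in \[0, 1\].
#' @export
polar_circularity <- function(mask, pixel_size = 0.78) {
  coords <- which(mask > 0, arr.ind = TRUE)
  if (nrow(coords) == 0) abort("polar_circularity: empty mask")
  ctr <- colMeans(coords)
  r_bar <- mean(sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2))
  r_eq <- sqrt(nrow(coords) / pi)
  if (r_bar == 0) return(1)
  min(1, 2 * r_eq / (3 * r_bar))
}

#' Radial band intensity profile
#'
#' The mask is divided into `n_bands` donut-shaped bands that follow the
#' particle outline: the Euclidean distance-to-edge transform inside the
#' mask is normalized by its maximum, and band k (k = 1 outermost) collects
#' pixels with normalized depth in ((k-1)/n, k/n]. Every mask pixel falls
#' in exactly one band.
#'
#' @param mask Logical matrix.
#' @param image Numeric intensity matrix.
#' @param n_bands Number of bands (default 20).
#' @param pixel_size Micrometres per pixel.
#' @return A `band_profile` tibble: `band`, `n_px`, `mean_intensity`
#'   (`NaN` for empty bands), `mean_depth_um` (mean absolute depth from
#'   the particle edge).
#' @export
band_profile <- function(mask, image, n_bands = 20, pixel_size = 0.78) {
  mask <- mask > 0
  if (!any(mask)) abort("band_profile: empty mask")
  d <- as_mat(EBImage::distmap(matrix(as.numeric(mask), nrow(mask),
                                      ncol(mask))))
  din <- d[mask]
  vals <- as_mat(image)[mask]
  band_of <- pmax(1L, ceiling(din / max(din) * n_bands - 1e-9))
  counts <- as.integer(tabulate(band_of, nbins = n_bands))
  mi <- vapply(seq_len(n_bands), function(k) {
    if (counts[k] > 0) mean(vals[band_of == k]) else NaN
  }, numeric(1))
  md <- vapply(seq_len(n_bands), function(k) {
    if (counts[k] > 0) mean(din[band_of == k]) * pixel_size else NaN
  }, numeric(1))
  out <- tibble(band = seq_len(n_bands), n_px = counts,
                mean_intensity = mi, mean_depth_um = md)
  class(out) <- c("band_profile", class(out))
  attr(out, "pixel_size") <- pixel_size
  out
}

band_peak <- function(profile) {
  valid <- which(profile$n_px > 0)
  if (length(valid) == 0) abort("band profile has no nonempty bands")
  valid[which.max(profile$mean_intensity[valid])]  # ties: outermost band
}

#' Halo width: depth of the bright ring
#'
#' In phase contrast the dense region of a pellet starts at a bright ring;
#' the mean depth (um from the edge) of the maximum-intensity band measures
#' the width of the low-density hyphal exterior. Ties go to the outermost
#' such band (a conservative halo).
#'
#' @param profile A [band_profile()].
#' @return Halo width in micrometres.
#' @export
halo_width <- function(profile) {
  profile$mean_depth_um[band_peak(profile)]
}

#' Outer/inner density ratio
#'
#' Count-weighted mean intensity of the edge-side bands (1..peak) divided
#' by that of the interior bands (peak+1..20). Dense-core pellets (dark
#' interior) score above 1; open "mat" morphologies score lower. If the
#' peak falls in the innermost band the ratio is taken against that band
#' alone and flagged degenerate.
#'
#' @param profile A [band_profile()].
#' @return A list: `ratio`, `degenerate` (logical).
#' @export
density_ratio <- function(profile) {
  peak <- band_peak(profile)
  n_bands <- nrow(profile)
  degenerate <- peak == n_bands
  outer_b <- if (degenerate) seq_len(n_bands - 1) else seq_len(peak)
  inner_b <- if (degenerate) n_bands else (peak + 1):n_bands
  wmean <- function(b) {
    sel <- profile$n_px[b] > 0
    if (!any(sel)) return(NA_real_)
    sum(profile$mean_intensity[b][sel] * profile$n_px[b][sel]) /
      sum(profile$n_px[b][sel])
  }
  inner <- wmean(inner_b)
  if (is.na(inner) && !degenerate) {
    abort("density_ratio: no interior pixels inside the peak band")
  }
  list(ratio = wmean(outer_b) / inner, degenerate = degenerate)
}

#' Measure the full descriptor vector for every particle
#'
#' Applies every particle descriptor — basic shape and intensity metrics,
#' maximum Feret diameter (2 degree steps), roughness, morphology number,
#' box-counting fractal dimensions, polar circularity, the 20-band radial
#' profile with halo width and density ratio — to each labelled particle.
#' Per-particle failures (tiny masks, degenerate profiles) are recorded in
#' a `flags` column, never raised.
#'
#' @param particles A `particle_set` (from [segment()]) or an integer label
#'   matrix.
#' @param image Numeric intensity matrix aligned with the labels.
#' @param pixel_size Micrometres per pixel; defaults to the particle set's.
#' @return A tibble, one row per particle, stable column order with units
#'   in the names (`area_um2`, `feret_um`, `band_01`..`band_20`, ...).
#' @export
measure_all <- function(particles, image, pixel_size = NULL) {
  if (inherits(particles, "particle_set")) {
    labels <- particles$labels
    pixel_size <- pixel_size %||% particles$pixel_size
  } else {
    labels <- particles
    pixel_size <- pixel_size %||% 0.78
  }
  img <- as_mat(image)
  n_lab <- max(labels)
  empty <- measure_one(NULL, NULL, pixel_size, template = TRUE)
  if (n_lab == 0) return(empty[0, ])
  rows <- lapply(seq_len(n_lab), function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(labels), max(idx[, 1]) + 2)
    c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(labels), max(idx[, 2]) + 2)
    mask <- labels[r0:r1, c0:c1, drop = FALSE] == l
    sub <- img[r0:r1, c0:c1, drop = FALSE]
    dplyr::bind_cols(tibble(label = l),
                     measure_one(mask, sub, pixel_size))
  })
  dplyr::bind_rows(rows)
}

measure_one <- function(mask, image, pixel_size, template = FALSE) {
  bands <- paste0("band_", sprintf("%02d", 1:20))
  if (template) {
    out <- tibble(label = integer())
    for (nm in c("n_px", "area_um2", "mean_intensity", "sd_intensity",
                 "perimeter_um", "major_um", "minor_um", "orientation_deg",
                 "circularity", "roundness", "elongation", "solidity",
                 "feret_um", "roughness", "morphology_number", "dbm",
                 "dbs", "fq", "polar_circularity", "peak_band", "halo_um",
                 "density_ratio", bands)) {
      out[[nm]] <- numeric()
    }
    out$flags <- character()
    return(out)
  }
  flags <- character()
  bm <- basic_metrics(mask, image, pixel_size)
  if (bm$n_px < 5 || bm$perimeter_um == 0) flags <- c(flags, "degenerate")
  fer <- feret_max(mask, 2, pixel_size)
  rough <- perimeter_px(mask) /
    ellipse_perimeter(bm$major_um / 2 / pixel_size,
                      bm$minor_um / 2 / pixel_size)
  mn <- morphology_number(bm$area_um2, bm$solidity, fer, bm$elongation)
  fd <- fractal_dimensions(mask)
  if (!is.na(fd$flag)) flags <- c(flags, fd$flag)
  pc <- polar_circularity(mask, pixel_size)
  prof <- band_profile(mask, image, 20, pixel_size)
  peak <- band_peak(prof)
  halo <- halo_width(prof)
  dr <- tryCatch(density_ratio(prof),
                 error = function(e) list(ratio = NA_real_,
                                          degenerate = NA))
  if (isTRUE(dr$degenerate)) flags <- c(flags, "density_ratio_degenerate")
  bandvals <- as.list(prof$mean_intensity)
  names(bandvals) <- paste0("band_", sprintf("%02d", 1:20))
  dplyr::bind_cols(
    bm,
    tibble(feret_um = fer, roughness = rough, morphology_number = mn,
           dbm = fd$dbm, dbs = fd$dbs, fq = fd$fq,
           polar_circularity = pc, peak_band = as.numeric(peak),
           halo_um = halo, density_ratio = dr$ratio),
    as_tibble(bandvals),
    tibble(flags = if (length(flags)) paste(flags, collapse = ",")
           else NA_character_))
}

#' Write a particle metrics table to CSV
#'
#' @param metrics Tibble from [measure_all()].
#' @param path Output CSV path.
#' @export
write_metrics <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Plot a radial band profile
#'
#' @param object A [band_profile()].
#' @param ... Unused.
#' @return A ggplot: mean band intensity against mean depth from the edge.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.band_profile <- function(object, ...) {
  ggplot2::ggplot(object[object$n_px > 0, ],
                  ggplot2::aes(x = .data$mean_depth_um,
                               y = .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "depth from particle edge (µm)",
                  y = "mean grey value",
                  title = "Radial band intensity profile") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
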