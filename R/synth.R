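#' Describe a synthetic pellet
#'
#' A pellet is rendered with the radial intensity structure seen in
#' phase-contrast: dark protruding hyphae at the rim, a bright ring where the
#' dense region starts, and a darker interior. The ring sits at
#' `ring_depth_frac` of the body radius, measured inward from the edge.
#'
#' @param center Integer vector `c(row, col)`, pellet centre in pixels.
#' @param core_radius_um Radius of the pellet body in micrometres.
#' @param ring_depth_frac Position of the bright ring as a fraction of the
#'   body radius, measured from the edge (0–1).
#' @param core_intensity,ring_intensity,fringe_intensity Grey levels of the
#'   interior, the bright ring and the low-density outer fringe. The ring
#'   must be brighter than the core; the fringe darker than the slide
#'   background (hyphae image dark in phase contrast).
#' @param n_hyphae Number of protruding hyphae.
#' @param hypha_length_um Length of each hypha in micrometres.
#' @param hypha_thickness_px Hypha thickness in pixels.
#' @return A `pellet_spec` list, consumed by [synth_spec()].
#' @export
pellet_spec <- function(center, core_radius_um, ring_depth_frac = 0.2,
                        core_intensity = 60, ring_intensity = 120,
                        fringe_intensity = 40, n_hyphae = 12,
                        hypha_length_um = 25, hypha_thickness_px = 2) {
  stopifnot(length(center) == 2, core_radius_um > 0,
            ring_depth_frac >= 0, ring_depth_frac <= 1)
  if (ring_intensity <= core_intensity) {
    abort("pellet_spec: ring_intensity must exceed core_intensity")
  }
  structure(list(center = as.numeric(center),
                 core_radius_um = core_radius_um,
                 ring_depth_frac = ring_depth_frac,
                 core_intensity = core_intensity,
                 ring_intensity = ring_intensity,
                 fringe_intensity = fringe_intensity,
                 n_hyphae = as.integer(n_hyphae),
                 hypha_length_um = hypha_length_um,
                 hypha_thickness_px = hypha_thickness_px),
            class = "pellet_spec")
}

#' Describe a synthetic slide artifact
#'
#' Three contaminant kinds occur on real slides: air bubbles (huge bright-
#' haloed rings, diameter above 900 um), cotton-like fibers (dark elongated
#' strands, elongation at least 10) and cell debris (specks under 200 px).
#'
#' @param kind One of `"bubble"`, `"fiber"`, `"debris"`.
#' @param center `c(row, col)` centre in pixels.
#' @param diameter_um Bubble diameter (um); must exceed 900.
#' @param length_px,width_px Fiber dimensions (px); length/width >= 10.
#' @param area_px Debris area (px); must be below 200.
#' @param intensity Grey level of the artifact body.
#' @param angle Fiber orientation in radians.
#' @return An `artifact_spec` list, consumed by [synth_spec()].
#' @export
artifact_spec <- function(kind = c("bubble", "fiber", "debris"), center,
                          diameter_um = NULL, length_px = NULL,
                          width_px = NULL, area_px = NULL,
                          intensity = NULL, angle = 0) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2)
  if (kind == "bubble") {
    if (is.null(diameter_um) || diameter_um <= 900) {
      abort("artifact_spec: bubble diameter_um must exceed 900 um")
    }
    intensity <- intensity %||% 30
  } else if (kind == "fiber") {
    if (is.null(length_px) || is.null(width_px) ||
        length_px / width_px < 10) {
      abort("artifact_spec: fiber elongation (length/width) must be >= 10")
    }
    intensity <- intensity %||% 38
  } else {
    if (is.null(area_px) || area_px >= 200) {
      abort("artifact_spec: debris area_px must be below 200 px")
    }
    intensity <- intensity %||% 35
  }
  structure(list(kind = kind, center = as.numeric(center),
                 diameter_um = diameter_um, length_px = length_px,
                 width_px = width_px, area_px = area_px,
                 intensity = intensity, angle = angle),
            class = "artifact_spec")
}

#' Specify a synthetic phase-contrast slide
#'
#' @param width,height Canvas size in pixels.
#' @param pixel_size Calibration in micrometres per pixel (default 0.78,
#'   i.e. 780 nm, a x10 objective on the reference setup).
#' @param background Background grey level; must lie inside the default
#'   background class interval \[50, 90\].
#' @param noise_sd Standard deviation of additive Gaussian sensor noise, in
#'   grey levels.
#' @param pellets List of [pellet_spec()] objects.
#' @param artifacts List of [artifact_spec()] objects.
#' @param seed Integer; fully determines the rendered image and ground
#'   truth.
#' @param bit_depth Image bit depth (8 or 16).
#' @return A `synth_spec` list, consumed by [generate_image()].
#' @export
synth_spec <- function(width, height, pixel_size = 0.78, background = 70,
                       noise_sd = 2, pellets = list(), artifacts = list(),
                       seed = 1L, bit_depth = 8L) {
  stopifnot(is.na(width) || width >= 1, is.na(height) || height >= 1,
            pixel_size > 0, noise_sd >= 0, bit_depth %in% c(8L, 16L))
  if (background < 50 || background > 90) {
    abort("synth_spec: background grey level must lie in [50, 90]")
  }
  for (p in pellets) {
    if (!inherits(p, "pellet_spec")) abort("pellets must be pellet_spec objects")
    if (p$fringe_intensity >= background) {
      abort("pellet_spec: fringe_intensity must be darker than the background")
    }
    if (p$ring_intensity > max_grey(bit_depth)) {
      abort("pellet_spec: intensities must fit the image bit depth")
    }
  }
  for (a in artifacts) {
    if (!inherits(a, "artifact_spec")) abort("artifacts must be artifact_spec objects")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, background = background,
                 noise_sd = noise_sd, pellets = pellets,
                 artifacts = artifacts, seed = as.integer(seed),
                 bit_depth = as.integer(bit_depth)),
            class = "synth_spec")
}

# pixel offsets of a stamp disk of the given thickness
stamp_offsets <- function(thickness) {
  r <- thickness / 2
  k <- ceiling(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

# rasterize a polyline (n x 2 matrix of row/col) with a thickness stamp;
# returns unique integer pixel coordinates
rasterize_polyline <- function(pts, thickness) {
  segs <- lapply(seq_len(nrow(pts) - 1), function(i) {
    p0 <- pts[i, ]; p1 <- pts[i + 1, ]
    n <- max(2, ceiling(2 * sqrt(sum((p1 - p0)^2))))
    cbind(seq(p0[1], p1[1], length.out = n), seq(p0[2], p1[2], length.out = n))
  })
  pts_all <- do.call(rbind, c(list(pts[1, , drop = FALSE]), segs))
  off <- stamp_offsets(thickness)
  px <- cbind(rep(round(pts_all[, 1]), each = nrow(off)) + off$dr,
              rep(round(pts_all[, 2]), each = nrow(off)) + off$dc)
  unique(px)
}

# coordinates (row, col) and grey values for one pellet; uses the RNG for
# hypha jitter
render_pellet <- function(p, pixel_size) {
  R <- p$core_radius_um / pixel_size
  cr <- p$center[1]; cc <- p$center[2]
  k <- ceiling(R)
  rows <- (-k):k
  rho <- sqrt(outer(rows^2, rows^2, "+"))
  body <- which(rho <= R, arr.ind = TRUE)
  coords <- cbind(cr + rows[body[, 1]], cc + rows[body[, 2]])
  rv <- rho[body]
  ring_r <- R * (1 - p$ring_depth_frac)
  hw <- max(1.5, 0.08 * R)
  vals <- ifelse(abs(rv - ring_r) <= hw, p$ring_intensity,
                 ifelse(rv < ring_r - hw, p$core_intensity,
                        p$fringe_intensity))
  # hyphae: jagged radial random walks of fixed thickness
  L <- p$hypha_length_um / pixel_size
  if (p$n_hyphae > 0 && L >= 1) {
    n_steps <- max(2, ceiling(L / 2))
    for (i in seq_len(p$n_hyphae)) {
      theta <- 2 * pi * (i - 1) / p$n_hyphae + runif(1, -0.25, 0.25)
      dirs <- theta + cumsum(c(0, rnorm(n_steps - 1, 0, 0.12)))
      steps <- cbind(2 * sin(dirs), 2 * cos(dirs))
      start <- c(cr + (R - 1) * sin(theta), cc + (R - 1) * cos(theta))
      pts <- rbind(start, cbind(start[1] + cumsum(steps[, 1]),
                                start[2] + cumsum(steps[, 2])))
      coords <- rbind(coords, rasterize_polyline(pts, p$hypha_thickness_px))
      vals <- c(vals, rep(p$fringe_intensity,
                          nrow(coords) - length(vals)))
    }
  }
  dup <- duplicated(coords)
  list(coords = coords[!dup, , drop = FALSE], vals = vals[!dup])
}

render_artifact <- function(a, pixel_size) {
  cr <- a$center[1]; cc <- a$center[2]
  if (a$kind == "bubble") {
    rb <- a$diameter_um / 2 / pixel_size
    k <- ceiling(rb + 4)
    rows <- (-k):k
    rho <- sqrt(outer(rows^2, rows^2, "+"))
    rim <- rho >= rb - 6 & rho <= rb          # dark rim
    halo <- rho > rb & rho <= rb + 4          # bright outer halo
    sel <- which(rim | halo, arr.ind = TRUE)
    coords <- cbind(cr + rows[sel[, 1]], cc + rows[sel[, 2]])
    vals <- ifelse(rim[sel], a$intensity, 180)
    list(coords = coords, vals = vals)
  } else if (a$kind == "fiber") {
    L <- a$length_px
    n <- max(8, ceiling(L / 4))
    t <- seq(-L / 2, L / 2, length.out = n)
    amp <- 0.03 * L                            # slight bend
    perp <- a$angle + pi / 2
    bend <- amp * sin(pi * (t + L / 2) / L)
    pts <- cbind(cr + t * sin(a$angle) + bend * sin(perp),
                 cc + t * cos(a$angle) + bend * cos(perp))
    coords <- rasterize_polyline(pts, a$width_px)
    list(coords = coords, vals = rep(a$intensity, nrow(coords)))
  } else {
    r <- sqrt(a$area_px / pi)
    k <- ceiling(r)
    rows <- (-k):k
    rho <- sqrt(outer(rows^2, rows^2, "+"))
    sel <- which(rho <= r, arr.ind = TRUE)
    coords <- cbind(cr + rows[sel[, 1]], cc + rows[sel[, 2]])
    list(coords = coords, vals = rep(a$intensity, nrow(coords)))
  }
}

#' Render a synthetic slide image with pixel-exact ground truth
#'
#' Paints every pellet and artifact of `spec` onto a uniform background,
#' then adds clipped Gaussian sensor noise and rounds to integer grey
#' levels. The same seed always produces a bit-identical image.
#'
#' @param spec A [synth_spec()].
#' @return A `synth_slide` list: `image` (numeric matrix, native grey
#'   scale), `truth` (a list with `labels`, an integer matrix giving the
#'   generating object per painted pixel, and `objects`, a tibble of
#'   per-object kind and parameters), `pixel_size` and `bit_depth`.
#'   Object kinds are `"pellet"`, `"fragment"` (overall length under 150
#'   um) or `"artifact"`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$height; w <- spec$width
  ps <- spec$pixel_size
  img <- matrix(spec$background, h, w)
  labels <- matrix(0L, h, w)
  objs <- c(spec$pellets, spec$artifacts)
  rows <- vector("list", length(objs))
  withr::with_seed(spec$seed, {
    for (k in seq_along(objs)) {
      o <- objs[[k]]
      rend <- if (inherits(o, "pellet_spec")) render_pellet(o, ps)
              else render_artifact(o, ps)
      cr <- rend$coords
      if (nrow(cr) == 0 ||
          min(cr[, 1]) < 1 || max(cr[, 1]) > h ||
          min(cr[, 2]) < 1 || max(cr[, 2]) > w) {
        abort(sprintf("object %d extends outside the canvas", k))
      }
      idx <- cbind(cr[, 1], cr[, 2])
      img[idx] <- rend$vals
      labels[idx] <- k
      rows[[k]] <- summarise_object(o, k, nrow(cr), ps)
    }
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    }
  })
  img <- matrix(round(clip_grey(img, spec$bit_depth)), h, w)
  structure(list(image = img,
                 truth = list(labels = labels,
                              objects = dplyr::bind_rows(rows)),
                 pixel_size = ps, bit_depth = spec$bit_depth),
            class = "synth_slide")
}

summarise_object <- function(o, k, n_px, pixel_size) {
  if (inherits(o, "pellet_spec")) {
    extent_um <- 2 * (o$core_radius_um + o$hypha_length_um)
    tibble(object = k,
           kind = if (extent_um < 150) "fragment" else "pellet",
           center_row = o$center[1], center_col = o$center[2],
           core_radius_um = o$core_radius_um,
           ring_depth_frac = o$ring_depth_frac,
           hypha_length_um = o$hypha_length_um,
           artifact_kind = NA_character_, n_px = n_px)
  } else {
    tibble(object = k, kind = "artifact",
           center_row = o$center[1], center_col = o$center[2],
           core_radius_um = NA_real_, ring_depth_frac = NA_real_,
           hypha_length_um = NA_real_, artifact_kind = o$kind,
           n_px = n_px)
  }
}

#' Cut a synthetic master image into an overlapping tile grid
#'
#' Tiles are cropped from one master rendering so that adjacent tiles share
#' `overlap_fraction` of their width/height (offset step =
#' `round(tile * (1 - overlap))`), and are emitted in meander order: row 0
#' left to right, row 1 right to left, and so on — the acquisition order of
#' a motorized stage. If the spec does not fix a canvas size, the exact grid
#' footprint is used.
#'
#' @param spec A [synth_spec()]; its `width`/`height` must be at least the
#'   grid footprint (use `NA` to auto-size).
#' @param rows,cols Grid shape (>= 1).
#' @param overlap_fraction Fraction of tile size shared by adjacent tiles
#'   (0 <= f < 1).
#' @param tile_size Side length of the square tiles in pixels.
#' @param out_dir If non-NULL, tiles are written as single-channel TIFFs
#'   (`r{row}_c{col}.tif`) plus `manifest.json`, the master image, a 16-bit
#'   ground-truth label TIFF and a per-object CSV.
#' @return Invisibly, a list: `tiles` (matrices in meander order),
#'   `manifest` (tibble: filename, row, col, x_offset_px, y_offset_px),
#'   `master` (the `synth_slide`), and `dir`.
#' @export
generate_tile_grid <- function(spec, rows, cols, overlap_fraction,
                               tile_size = 256, out_dir = NULL) {
  stopifnot(rows >= 1, cols >= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  step <- round(tile_size * (1 - overlap_fraction))
  fw <- tile_size + (cols - 1) * step
  fh <- tile_size + (rows - 1) * step
  if (is.na(spec$width) || is.na(spec$height)) {
    spec$width <- as.integer(fw); spec$height <- as.integer(fh)
  }
  if (spec$width < fw || spec$height < fh) {
    abort(sprintf(
      "master image (%d x %d) smaller than required footprint (%d x %d)",
      spec$height, spec$width, fh, fw))
  }
  master <- generate_image(spec)
  manifest <- meander_order(rows, cols)
  manifest$x_offset_px <- manifest$col * step
  manifest$y_offset_px <- manifest$row * step
  manifest$filename <- sprintf("r%d_c%d.tif", manifest$row, manifest$col)
  tiles <- purrr::pmap(manifest, function(row, col, x_offset_px,
                                          y_offset_px, filename) {
    master$image[y_offset_px + seq_len(tile_size),
                 x_offset_px + seq_len(tile_size), drop = FALSE]
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      write_image(file.path(out_dir, manifest$filename[i]), tiles[[i]],
                  bit_depth = spec$bit_depth, pixel_size = spec$pixel_size)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = FALSE)
    write_image(file.path(out_dir, "master.tif"), master$image,
                bit_depth = spec$bit_depth, pixel_size = spec$pixel_size)
    write_image(file.path(out_dir, "truth_labels.tif"),
                master$truth$labels, bit_depth = 16L,
                pixel_size = spec$pixel_size)
    write.csv(master$truth$objects,
              file.path(out_dir, "truth_objects.csv"), row.names = FALSE)
  }
  invisible(list(tiles = tiles, manifest = as_tibble(manifest),
                 master = master, dir = out_dir))
}

#' Meander acquisition order of a tile grid
#'
#' The order a motorized stage visits grid positions: row 0 left to right,
#' row 1 right to left, alternating down to the last row.
#'
#' @param rows,cols Grid shape.
#' @return A tibble of 0-based `row`, `col` positions, one per tile, in
#'   acquisition order.
#' @export
meander_order <- function(rows, cols) {
  out <- do.call(rbind, lapply(seq_len(rows) - 1L, function(r) {
    cs <- if (r %% 2 == 0) seq_len(cols) - 1L else rev(seq_len(cols) - 1L)
    data.frame(row = r, col = cs)
  }))
  tibble::as_tibble(out)
}

#' Standard synthetic study slide
#'
#' Draws one slide under the package's reference study conditions: a
#' 2048 x 2048 px canvas at 0.78 um/px with background grey 70 and noise SD
#' 2, carrying 10 well-separated pellets (body radius 75–115 um, bright
#' ring at depth fraction ~0.2, protruding hyphae), 3 sub-200 px debris
#' specks, one air bubble (diameter 920–1000 um) and one dark fiber
#' (elongation well above 10). Placement uses rejection sampling so objects
#' never overlap; everything is a deterministic function of `seed`.
#'
#' @param seed Integer seed.
#' @param n_pellets,n_debris Object counts.
#' @param width,height Canvas size (px).
#' @return A [synth_spec()].
#' @export
standard_slide_spec <- function(seed, n_pellets = 10, n_debris = 3,
                                width = 2048, height = 2048) {
  ps <- 0.78
  withr::with_seed(seed, {
    # draw all object parameters first, then place everything largest
    # clearance first; a badly packing layout restarts from scratch
    bubble_d <- runif(1, 920, 1000)
    fiber_len <- runif(1, 300, 420)
    fiber_angle <- runif(1, 0, pi)
    pellet_par <- lapply(seq_len(n_pellets), function(i) {
      list(R_um = runif(1, 75, 110), L_um = runif(1, 15, 35),
           frac = runif(1, 0.15, 0.25), core = runif(1, 55, 68),
           ring = runif(1, 110, 140), fringe = runif(1, 35, 45),
           n_h = sample(8:16, 1))
    })
    debris_par <- lapply(seq_len(n_debris), function(i) {
      list(area = runif(1, 60, 150), intensity = sample(c(35, 140), 1))
    })
    bounds <- c(bubble_d / 2 / ps + 8, fiber_len / 2 + 8,
                vapply(pellet_par, function(p) (p$R_um + p$L_um) / ps + 4,
                       numeric(1)),
                vapply(debris_par, function(p) sqrt(p$area / pi) + 3,
                       numeric(1)))
    if (any(bounds + 4 >= height / 2) || any(bounds + 4 >= width / 2)) {
      abort("standard_slide_spec: canvas too small for the objects")
    }
    ord <- order(bounds, decreasing = TRUE)
    centers <- NULL
    for (restart in 1:50) {
      placed <- matrix(numeric(0), 0, 3)
      ok_all <- TRUE
      for (k in ord) {
        bound <- bounds[k]
        done <- FALSE
        for (try in 1:2000) {
          r <- runif(1, bound + 2, height - bound - 2)
          cl <- runif(1, bound + 2, width - bound - 2)
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - r)^2 + (placed[, 2] - cl)^2) >
                    placed[, 3] + bound + 10)) {
            placed <- rbind(placed, c(r, cl, bound))
            done <- TRUE
            break
          }
        }
        if (!done) { ok_all <- FALSE; break }
      }
      if (ok_all) {
        centers <- matrix(NA_real_, length(bounds), 2)
        centers[ord, ] <- round(placed[, 1:2])
        break
      }
    }
    if (is.null(centers)) {
      abort("standard_slide_spec: could not place all objects")
    }
    bubble <- artifact_spec("bubble", centers[1, ], diameter_um = bubble_d)
    fiber <- artifact_spec("fiber", centers[2, ], length_px = fiber_len,
                           width_px = 4, angle = fiber_angle)
    pellets <- lapply(seq_len(n_pellets), function(i) {
      p <- pellet_par[[i]]
      pellet_spec(centers[2 + i, ], core_radius_um = p$R_um,
                  ring_depth_frac = p$frac, core_intensity = p$core,
                  ring_intensity = p$ring, fringe_intensity = p$fringe,
                  n_hyphae = p$n_h, hypha_length_um = p$L_um,
                  hypha_thickness_px = 2)
    })
    debris <- lapply(seq_len(n_debris), function(i) {
      p <- debris_par[[i]]
      artifact_spec("debris", centers[2 + n_pellets + i, ],
                    area_px = p$area, intensity = p$intensity)
    })
    synth_spec(width, height, pixel_size = ps, background = 70,
               noise_sd = 2, pellets = pellets,
               artifacts = c(list(bubble, fiber), debris), seed = seed)
  })
}
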