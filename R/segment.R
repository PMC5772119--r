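#' Segmentation configuration
#'
#' Defaults follow the reference protocol for streptomycete slides at a x10
#' objective: grey values in \[50, 90\] are background (everything darker or
#' brighter is a candidate edge), a 5 px Gaussian blur precedes the
#' watershed, watershed cuts longer than 150 um are vetoed, and objects
#' under 200 px or over 6e5 um^2 (a diameter above ~900 um, i.e. air
#' bubbles) are discarded.
#'
#' @param background_low,background_high Inclusive background grey bounds.
#' @param sigma Gaussian blur SD in pixels, applied to the binary mask
#'   before watershedding.
#' @param max_interface_um A watershed separation is applied only if the
#'   interface between the two adjacent particles is shorter than this.
#' @param min_px Minimum object size in pixels (strict: smaller removed).
#' @param max_area_um2 Maximum object area (strict: larger removed).
#' @param pixel_size Micrometres per pixel.
#' @param watershed_tolerance Minimum height (on the 0-1 blurred mask)
#'   between two catchment basins for them to stay separate.
#' @return A `seg_config` list.
#' @export
seg_config <- function(background_low = 50, background_high = 90,
                       sigma = 5, max_interface_um = 150, min_px = 200,
                       max_area_um2 = 6e5, pixel_size = 0.78,
                       watershed_tolerance = 0.1) {
  stopifnot(background_low <= background_high, sigma > 0, min_px >= 1,
            max_area_um2 > min_px * pixel_size^2, pixel_size > 0)
  structure(list(background_low = background_low,
                 background_high = background_high, sigma = sigma,
                 max_interface_um = max_interface_um, min_px = min_px,
                 max_area_um2 = max_area_um2, pixel_size = pixel_size,
                 watershed_tolerance = watershed_tolerance),
            class = "seg_config")
}

#' Dual-sided foreground threshold
#'
#' Phase contrast renders hyphae dark and dense pellet edges bright, so
#' foreground is everything outside the background band: pixels strictly
#' below `low` or strictly above `high` (both bounds belong to the
#' background).
#'
#' @param image Numeric matrix of grey values.
#' @param low,high Background band, inclusive.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
threshold_foreground <- function(image, low = 50, high = 90) {
  stopifnot(low <= high)
  m <- as_mat(image)
  m < low | m > high
}

#' Fill enclosed holes in a binary mask
#'
#' Every background region not connected (4-connectivity) to the image
#' border becomes foreground, turning detected pellet edges into solid
#' objects.
#'
#' @param mask Logical matrix.
#' @return Logical matrix.
#' @export
fill_holes <- function(mask) {
  mask <- mask > 0
  bg <- EBImage::bwlabel(!mask)          # bwlabel is 4-connectivity
  bg <- matrix(as.integer(bg), nrow(mask), ncol(mask))
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | !(bg %in% c(0L, border))
}

# connected components; bwlabel gives 4-connectivity, diagonal-adjacent
# labels are merged by union-find for connectivity = 8
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask > 0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1) {
    n <- nrow(lab); m <- ncol(lab)
    a <- lab[-n, -m]; b <- lab[-1, -1]       # down-right diagonal
    p1 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
    a <- lab[-1, -m]; b <- lab[-n, -1]       # up-right diagonal
    p2 <- cbind(a[a > 0 & b > 0 & a != b], b[a > 0 & b > 0 & a != b])
    pairs <- unique(rbind(p1, p2))
    if (nrow(pairs) > 0) {
      map <- merge_labels(max(lab), pairs)
      lab <- matrix(map[lab + 1L], n, m)
    }
  }
  relabel_consecutive(lab)
}

# union-find: returns lookup vector of length n_labels + 1 (index 1 = label
# 0) mapping every label to its merged representative
merge_labels <- function(n_labels, pairs) {
  parent <- seq_len(n_labels)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n_labels), find, integer(1))
  c(0L, as.integer(roots))
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  map <- integer(max(u) + 1L)
  map[u + 1L] <- seq_along(u)
  matrix(map[lab + 1L], nrow(lab), ncol(lab))
}

#' Separate touching particles by blurred-mask watershed
#'
#' The filled mask is Gaussian-blurred and watershedded (basins grown from
#' the regional maxima of the blurred mask), which proposes cut lines
#' through thin bridges between adjacent particles. A cut is applied only
#' where the interface between the two particles is shorter than
#' `max_interface_um`; longer interfaces mean one irregularly shaped pellet,
#' and the two regions are re-merged. Each proposed cut is evaluated
#' independently.
#'
#' @param mask Filled binary mask.
#' @param sigma Blur SD (px).
#' @param max_interface_um Interface length veto (um).
#' @param pixel_size Micrometres per pixel.
#' @param tolerance Watershed tolerance on the 0-1 blurred mask.
#' @return Integer label matrix (0 = background, labels consecutive).
#' @export
separate_objects <- function(mask, sigma = 5, max_interface_um = 150,
                             pixel_size = 0.78, tolerance = 0.1) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  comp <- label_components(mask, connectivity = 8)
  lab <- split_components(comp, sigma, tolerance)
  n_lab <- max(lab)
  if (n_lab > 1) {
    iface <- interface_lengths(lab)
    if (nrow(iface) > 0) {
      long <- iface[iface$length_px * pixel_size >= max_interface_um, ,
                    drop = FALSE]
      if (nrow(long) > 0) {
        map <- merge_labels(n_lab, as.matrix(long[, c("a", "b")]))
        lab <- matrix(map[lab + 1L], nrow(lab), ncol(lab))
      }
    }
  }
  relabel_consecutive(lab)
}

# seeded watershed of the blurred mask, run per connected component on its
# cropped window: regional maxima are the plateau regions where the blurred
# mask exceeds 1 - tolerance (two basins whose saddle is shallower than
# `tolerance` share one plateau and stay merged); components holding
# several maxima are split by growing the maxima through the blurred
# landscape (EBImage::propagate), the rest pass through untouched
split_components <- function(comp, sigma, tolerance) {
  n_comp <- max(comp)
  if (n_comp == 0) return(comp)
  idx <- which(comp > 0, arr.ind = TRUE)
  cl <- comp[comp > 0]
  r0 <- tapply(idx[, 1], cl, min); r1 <- tapply(idx[, 1], cl, max)
  c0 <- tapply(idx[, 2], cl, min); c1 <- tapply(idx[, 2], cl, max)
  pad <- ceiling(4 * sigma)
  out <- comp
  next_lab <- n_comp
  for (ci in seq_len(n_comp)) {
    rr <- max(1, r0[ci] - pad):min(nrow(comp), r1[ci] + pad)
    cc <- max(1, c0[ci] - pad):min(ncol(comp), c1[ci] + pad)
    m_c <- comp[rr, cc, drop = FALSE] == ci
    b_c <- as_mat(EBImage::gblur(matrix(as.numeric(m_c), nrow(m_c),
                                        ncol(m_c)), sigma = sigma))
    s_c <- label_components(b_c > 1 - tolerance & m_c, connectivity = 8)
    if (max(s_c) >= 2) {
      w <- as_mat(EBImage::propagate(b_c, s_c, mask = m_c))
      w <- matrix(as.integer(round(w)), nrow(m_c), ncol(m_c))
      piece <- out[rr, cc, drop = FALSE]
      piece[m_c] <- next_lab + w[m_c]
      out[rr, cc] <- piece
      next_lab <- next_lab + max(w)
    }
  }
  relabel_consecutive(out)
}

# in-mask separation borders of a label map: labelled pixels with an
# 8-neighbour carrying a greater label (the same side convention as the
# Voronoi border, whose restriction to mask pixels this equals — a mask
# pixel's nearest label is its own); 8-adjacency guarantees the resulting
# components are disjoint
label_adjacency_border <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  padl <- matrix(0L, n + 2, m + 2)
  padl[2:(n + 1), 2:(m + 1)] <- lab
  border <- matrix(FALSE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- padl[(1:n) + 1 + dr, (1:m) + 1 + dc, drop = FALSE]
    border <- border | (lab > 0 & nb > lab)
  }
  border
}

# per adjacent label pair, the cut-line length in pixels: the larger of the
# two sides' counts of boundary pixels (4-adjacency)
interface_lengths <- function(lab) {
  n <- nrow(lab); m <- ncol(lab)
  idx <- matrix(seq_along(lab), n, m)
  collect <- function(a, b, ia, ib) {
    sel <- a > 0 & b > 0 & a != b
    data.frame(a = pmin(a[sel], b[sel]), b = pmax(a[sel], b[sel]),
               pa = ifelse(a[sel] < b[sel], ia[sel], ib[sel]),
               pb = ifelse(a[sel] < b[sel], ib[sel], ia[sel]))
  }
  adj <- rbind(
    collect(lab[, -m], lab[, -1], idx[, -m], idx[, -1]),
    collect(lab[-n, ], lab[-1, ], idx[-n, ], idx[-1, ]))
  if (nrow(adj) == 0) {
    return(data.frame(a = integer(), b = integer(), length_px = numeric()))
  }
  key <- paste(adj$a, adj$b)
  out <- lapply(split(adj, key), function(d) {
    data.frame(a = d$a[1], b = d$b[1],
               length_px = max(length(unique(d$pa)), length(unique(d$pb))))
  })
  do.call(rbind, unname(out))
}

#' Euclidean influence zones of a label map
#'
#' Every pixel of the image is assigned to the label whose pixels are
#' nearest in Euclidean distance (ties go to the lower label).
#' `voronoi_partition()` returns the 1-px border set between zones: pixels
#' with a 4-neighbour belonging to a higher zone.
#'
#' @param labels Integer label matrix with at least one positive label.
#' @return `voronoi_zones()`: integer zone matrix. `voronoi_partition()`:
#'   logical border mask with the zone matrix as attribute `zones`.
#' @export
voronoi_zones <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (length(labs) == 0) abort("voronoi_zones: no labels")
  best <- matrix(Inf, nrow(labels), ncol(labels))
  zone <- matrix(0L, nrow(labels), ncol(labels))
  for (l in labs) {                       # ascending: ties keep lower label
    d <- as_mat(EBImage::distmap(matrix(as.numeric(labels != l),
                                        nrow(labels), ncol(labels))))
    upd <- d < best
    best[upd] <- d[upd]
    zone[upd] <- l
  }
  zone
}

#' @rdname voronoi_zones
#' @export
voronoi_partition <- function(labels) {
  zone <- voronoi_zones(labels)
  n <- nrow(zone); m <- ncol(zone)
  border <- matrix(FALSE, n, m)
  border[, -m] <- border[, -m] | zone[, -1] > zone[, -m]
  border[, -1] <- border[, -1] | zone[, -m] > zone[, -1]
  border[-n, ] <- border[-n, ] | zone[-1, ] > zone[-n, ]
  border[-1, ] <- border[-1, ] | zone[-n, ] > zone[-1, ]
  attr(border, "zones") <- zone
  border
}

#' Remove zone borders from a mask
#'
#' Foreground pixels on the border set become background, which guarantees
#' that touching objects separate into disjoint connected components.
#'
#' @param mask Logical matrix.
#' @param border Logical border mask of the same dimensions.
#' @return Logical matrix.
#' @export
subtract_borders <- function(mask, border) {
  stopifnot(identical(dim(mask), dim(border)))
  mask > 0 & !(border > 0)
}

#' Remove too-small and too-large objects
#'
#' Objects smaller than `min_px` pixels (debris, precipitated salts) or
#' larger than `max_area_um2` (air bubbles; 6e5 um^2 corresponds to a
#' diameter above ~900 um) are dropped — both bounds strict. Survivors are
#' relabelled 1..n by descending area.
#'
#' @param labels Integer label matrix.
#' @param min_px Minimum pixel count (objects with fewer are removed).
#' @param max_area_um2 Maximum area in um^2 (objects above are removed).
#' @param pixel_size Micrometres per pixel.
#' @return Integer label matrix.
#' @export
size_filter <- function(labels, min_px = 200, max_area_um2 = 6e5,
                        pixel_size = 0.78) {
  n_lab <- max(labels)
  if (n_lab == 0) return(labels)
  counts <- tabulate(labels[labels > 0], nbins = n_lab)
  keep <- which(counts >= min_px & counts * pixel_size^2 <= max_area_um2)
  map <- integer(n_lab + 1L)
  map[keep + 1L] <- rank(-counts[keep], ties.method = "first")
  matrix(map[labels + 1L], nrow(labels), ncol(labels))
}

#' Segment a calibrated mosaic into candidate particles
#'
#' Runs the full chain: dual-sided threshold, hole filling, a bubble guard
#' that drops connected components already above the area cap (so a filled
#' air bubble cannot distort the watershed), blurred-mask watershed with
#' the interface veto, Voronoi border subtraction, 8-connectivity
#' relabelling, and the size filter.
#'
#' @param image Numeric grey-value matrix.
#' @param config A [seg_config()].
#' @return A `particle_set`: list with `labels` (final integer label map,
#'   largest particle first), `all_labels` (label map before the size
#'   filter, for manual rescue of false negatives), `records` (tibble of
#'   per-particle label, pixel count, area and bounding box), `pixel_size`
#'   and `config`.
#' @export
segment <- function(image, config = seg_config()) {
  ps <- config$pixel_size
  fg <- threshold_foreground(image, config$background_low,
                             config$background_high)
  filled <- fill_holes(fg)
  # bubble guard: drop pre-split components already over the area cap
  pre <- label_components(filled, connectivity = 8)
  if (max(pre) > 0) {
    counts <- tabulate(pre[pre > 0], nbins = max(pre))
    big <- which(counts * ps^2 > config$max_area_um2)
    if (length(big) > 0) filled <- filled & !(pre %in% big)
  }
  lab_ws <- separate_objects(filled, sigma = config$sigma,
                             max_interface_um = config$max_interface_um,
                             pixel_size = ps,
                             tolerance = config$watershed_tolerance)
  if (max(lab_ws) > 0) {
    filled <- subtract_borders(filled, label_adjacency_border(lab_ws))
  }
  all_labels <- label_components(filled, connectivity = 8)
  labels <- size_filter(all_labels, min_px = config$min_px,
                        max_area_um2 = config$max_area_um2,
                        pixel_size = ps)
  particle_set(labels, all_labels, ps, config)
}

particle_set <- function(labels, all_labels, pixel_size, config = NULL) {
  n_lab <- max(labels)
  records <- if (n_lab == 0) {
    tibble(label = integer(), n_px = integer(), area_um2 = numeric(),
           row_min = integer(), row_max = integer(), col_min = integer(),
           col_max = integer())
  } else {
    idx <- which(labels > 0, arr.ind = TRUE)
    l <- labels[labels > 0]
    dplyr::arrange(dplyr::summarise(
      dplyr::group_by(tibble(label = l, row = idx[, 1], col = idx[, 2]),
                      .data$label),
      n_px = dplyr::n(),
      area_um2 = dplyr::n() * pixel_size^2,
      row_min = min(.data$row), row_max = max(.data$row),
      col_min = min(.data$col), col_max = max(.data$col),
      .groups = "drop"), .data$label)
  }
  structure(list(labels = labels, all_labels = all_labels,
                 records = records, pixel_size = pixel_size,
                 config = config),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set: %d particles, %d x %d px, %.3g um/px>\n",
              max(x$labels), nrow(x$labels), ncol(x$labels), x$pixel_size))
  print(x$records, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-particle records of a particle set
#' @param x A `particle_set`.
#' @param ... Unused.
#' @return A tibble, one row per retained particle.
#' @export
tidy.particle_set <- function(x, ...) x$records

#' One-row summary of a particle set
#' @param x A `particle_set`.
#' @param ... Unused.
#' @return A tibble with particle counts and total covered area.
#' @export
glance.particle_set <- function(x, ...) {
  tibble(n_particles = max(x$labels),
         n_candidates = max(x$all_labels),
         total_area_um2 = sum(x$records$area_um2),
         pixel_size = x$pixel_size)
}

#' Write the label maps of a particle set
#'
#' Saves both the accepted label map and the pre-filter candidate map so
#' false negatives can be rescued manually.
#'
#' @param particles A `particle_set`.
#' @param path Output TIFF for the accepted labels (16-bit).
#' @param all_path Optional output TIFF for all candidate labels.
#' @export
write_labels <- function(particles, path, all_path = NULL) {
  write_image(path, particles$labels, bit_depth = 16L,
              pixel_size = particles$pixel_size)
  if (!is.null(all_path)) {
    write_image(all_path, particles$all_labels, bit_depth = 16L,
                pixel_size = particles$pixel_size)
  }
  invisible(path)
}
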