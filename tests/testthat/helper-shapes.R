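# Shared geometric fixtures, built in code.

# rasterized disk mask (pixel centers), radius r, padded canvas
mk_disk <- function(r, pad = 10) {
  side <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  outer(seq_len(side), seq_len(side),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# axis-aligned filled ellipse with semi-axes (a, b): rows, cols
mk_ellipse <- function(a, b, pad = 10) {
  h <- 2 * (a + pad) + 1; w <- 2 * (b + pad) + 1
  cy <- a + pad + 1; cx <- b + pad + 1
  outer(seq_len(h), seq_len(w),
        function(i, j) ((i - cy) / a)^2 + ((j - cx) / b)^2 <= 1)
}

# two r-radius disks with centres 2r + gap apart, joined by a bridge of the
# given width (px); gap < 0 fuses the disks directly
mk_dumbbell <- function(r, gap, bridge_w) {
  cx1 <- r + 12; cx2 <- cx1 + 2 * r + gap
  W <- cx2 + r + 12; H <- 2 * r + 40
  cy <- round(H / 2)
  m <- outer(seq_len(H), seq_len(W), function(i, j) {
    (i - cy)^2 + (j - cx1)^2 <= r^2 | (i - cy)^2 + (j - cx2)^2 <= r^2
  })
  if (bridge_w > 0) {
    half <- floor(bridge_w / 2)
    m[(cy - half):(cy - half + bridge_w - 1), cx1:cx2] <- TRUE
  }
  m
}

# quadratic Koch curve (5-segment generator, step 1/3): known box dimension
# log 5 / log 3
mk_koch <- function(iterations) {
  dirs <- 0L
  for (i in seq_len(iterations)) {
    dirs <- unlist(lapply(dirs, function(d) {
      c(d, (d + 1L) %% 4L, d, (d + 3L) %% 4L, d)
    }))
  }
  dx <- c(0L, 1L, 0L, -1L)[dirs + 1L]
  dy <- c(1L, 0L, -1L, 0L)[dirs + 1L]
  x <- cumsum(c(0L, dx)); y <- cumsum(c(0L, dy))
  m <- matrix(FALSE, max(y) - min(y) + 1, max(x) - min(x) + 1)
  m[cbind(y - min(y) + 1, x - min(x) + 1)] <- TRUE
  m
}

# random connected blob mask: a chain of overlapping random disks,
# deterministic in seed
mk_random_blob <- function(seed, side = 96, k = 4) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, side, side)
    ctr <- c(side / 2, side / 2)
    prev_r <- 0
    for (i in seq_len(k)) {
      r <- runif(1, 4, side / 8)
      if (i > 1) {
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0.2, 0.8) * (prev_r + r)
        ctr <- ctr + d * c(sin(ang), cos(ang))
      }
      ctr <- pmin(pmax(ctr, r + 2), side - r - 2)
      cy <- ctr[1]; cx <- ctr[2]
      m <- m | outer(seq_len(side), seq_len(side),
                     function(a, b) (a - cy)^2 + (b - cx)^2 <= r^2)
      prev_r <- r
    }
    m
  })
}

# independent maximum-Feret oracle: the sup over directions of the point
# extent equals the maximum pairwise distance between pixel centres
# (evaluated on the convex hull), plus the 1 px pixel-extent convention
feret_oracle_px <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) > 2) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  d <- as.matrix(dist(pts))
  max(d) + 1
}

# brute-force nearest-seed scan (ties to the lower label)
voronoi_oracle <- function(labels) {
  seeds <- which(labels > 0, arr.ind = TRUE)
  sl <- labels[labels > 0]
  ord <- order(sl)
  seeds <- seeds[ord, , drop = FALSE]; sl <- sl[ord]
  zone <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_len(nrow(labels))) {
    for (j in seq_len(ncol(labels))) {
      d2 <- (seeds[, 1] - i)^2 + (seeds[, 2] - j)^2
      zone[i, j] <- sl[which.min(d2)]   # first minimum = lowest label
    }
  }
  zone
}

# pellet test slide: one pellet with known ring geometry, no noise
mk_pellet_slide <- function(core_radius_um = 78, ring_depth_frac = 0.2,
                            hypha_length_um = 20, noise_sd = 0, seed = 3) {
  half <- ceiling((core_radius_um + hypha_length_um) / 0.78) + 6
  p <- pellet_spec(c(half + 1, half + 1), core_radius_um = core_radius_um,
                   ring_depth_frac = ring_depth_frac,
                   hypha_length_um = hypha_length_um)
  generate_image(synth_spec(2 * half + 2, 2 * half + 2, noise_sd = noise_sd,
                            pellets = list(p), seed = seed))
}
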