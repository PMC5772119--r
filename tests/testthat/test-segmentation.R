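test_that("thresholding keeps the background band on both bounds", {
  img <- matrix(c(49, 50, 70, 90, 91), 1, 5)
  expect_equal(as.vector(threshold_foreground(img)),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(threshold_foreground(matrix(70, 10, 10))))
})

test_that("thresholding a pellet image recovers the painted edge set", {
  g <- mk_pellet_slide(noise_sd = 0)
  fg <- threshold_foreground(g$image)
  painted_fg <- g$truth$labels > 0 & (g$image < 50 | g$image > 90)
  iou <- sum(fg & painted_fg) / sum(fg | painted_fg)
  expect_gte(iou, 0.9)
})

test_that("hole filling closes enclosed regions only", {
  ann <- mk_disk(20) & !mk_disk(10, pad = 20)
  filled <- fill_holes(ann)
  expect_equal(sum(filled), sum(mk_disk(20)))   # disk rasterization oracle
  solid <- mk_disk(8)
  expect_equal(fill_holes(solid), solid)
  cshape <- mk_disk(20) & !mk_disk(10, pad = 20)
  cshape[1:41, 21] <- FALSE                      # cut a channel to the top
  cshape[1:20, 20:22] <- FALSE
  expect_equal(fill_holes(cshape), cshape)
})

test_that("watershed splits thin necks and keeps wide interfaces whole", {
  disk <- mk_disk(30)
  expect_equal(max(separate_objects(disk)), 1)
  thin <- mk_dumbbell(30, 20, 5)     # 5 px cut = 3.9 um, far below 150 um
  lab <- separate_objects(thin)
  expect_equal(max(lab), 2)
  # each disk centre carries its own label
  expect_equal(sort(c(lab[50, 42], lab[50, 122])), c(1L, 2L))
  # a 200 px wide neck (156 um at 0.78 um/px) stays one object
  wide <- mk_dumbbell(150, -100, 200)
  expect_equal(max(separate_objects(wide)), 1)
})

test_that("the interface veto depends on physical cut length", {
  # identical geometry, two calibrations: a ~60 px neck is cut at
  # 0.78 um/px (~47 um) but vetoed at 3.2 um/px (~192 um)
  neck <- mk_dumbbell(100, 160, 60)
  fine <- separate_objects(neck, sigma = 25, pixel_size = 0.78)
  coarse <- separate_objects(neck, sigma = 25, pixel_size = 3.2)
  expect_equal(max(fine), 2)
  expect_equal(max(coarse), 1)
})

test_that("voronoi zones follow perpendicular bisectors with low-label ties", {
  lab <- matrix(0L, 3, 201)
  lab[2, 51] <- 1L; lab[2, 151] <- 2L
  border <- voronoi_partition(lab)
  zones <- attr(border, "zones")
  expect_true(all(zones[, 1:101] == 1))          # tie at col 101 -> label 1
  expect_true(all(zones[, 102:201] == 2))
  expect_equal(unique(which(border, arr.ind = TRUE)[, 2]), 101)
  # single label: no border
  one <- matrix(0L, 10, 10); one[5, 5] <- 1L
  expect_false(any(voronoi_partition(one)))
  # three collinear equidistant seeds: two parallel bisector borders
  tri <- matrix(0L, 3, 301)
  tri[2, c(51, 151, 251)] <- c(1L, 2L, 3L)
  b3 <- voronoi_partition(tri)
  expect_equal(sort(unique(which(b3, arr.ind = TRUE)[, 2])), c(101, 201))
})

test_that("voronoi zones match the brute-force nearest-seed scan", {
  for (seed in 1:5) {
    lab <- withr::with_seed(seed, {
      l <- matrix(0L, 48, 64)
      n <- sample(2:5, 1)
      pos <- cbind(sample(48, n), sample(64, n))
      l[pos] <- seq_len(n)
      l
    })
    expect_identical(voronoi_zones(lab), voronoi_oracle(lab),
                     label = paste("seed", seed))
  }
})

test_that("border subtraction separates and preserves elsewhere", {
  m <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(subtract_borders(m, none), m)
  expect_false(any(subtract_borders(m, matrix(TRUE, 10, 10))))
  thin <- mk_dumbbell(30, 20, 5)
  lab <- separate_objects(thin)
  cut <- subtract_borders(thin, pelletscan:::label_adjacency_border(lab))
  comp <- pelletscan:::label_components(cut, 8)
  expect_equal(max(comp), 2)
})

test_that("size filtering is strict on both bounds", {
  lab <- matrix(0L, 40, 60)
  lab[1:10, 1:20] <- 1L                  # 200 px: retained
  lab[20:30, 1:19] <- 2L                 # 209 px: retained
  lab[35:39, 1:39] <- 3L                 # 195 px: removed
  out <- size_filter(lab, min_px = 200, max_area_um2 = 6e5,
                     pixel_size = 0.78)
  expect_equal(sort(unique(out[out > 0])), c(1L, 2L))
  expect_equal(sum(out == 1), 209)       # relabelled by descending area
  # a disk of radius 450 um (~6.36e5 um^2) exceeds the cap
  disk <- mk_disk(round(450 / 0.78), pad = 2)
  lab2 <- matrix(0L, nrow(disk), ncol(disk)); lab2[disk] <- 1L
  expect_equal(max(size_filter(lab2, 200, 6e5, 0.78)), 0)
  empty <- matrix(0L, 5, 5)
  expect_equal(size_filter(empty, 200, 6e5, 0.78), empty)
})

test_that("label maps conserve pixel counts and respect monotonicity", {
  g <- mk_pellet_slide(noise_sd = 2)
  ps <- segment(g$image, seg_config())
  expect_equal(sum(ps$records$n_px), sum(ps$labels > 0))
  # raising min_px never increases the particle count
  counts <- vapply(c(50, 200, 5000, 50000), function(mp) {
    max(segment(g$image, seg_config(min_px = mp))$labels)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # widening the background band never increases foreground
  narrow <- sum(threshold_foreground(g$image, 60, 80))
  wide <- sum(threshold_foreground(g$image, 50, 90))
  expect_gte(narrow, wide)
})

test_that("segmentation recovers pellets and drops artifacts on a slide", {
  g <- generate_image(standard_slide_spec(21))
  ps <- segment(g$image, seg_config())
  tr <- g$truth
  pellets <- tr$objects$object[tr$objects$kind == "pellet"]
  ious <- vapply(pellets, function(k) {
    gt <- tr$labels == k
    cand <- setdiff(unique(ps$labels[gt]), 0)
    if (length(cand) == 0) return(0)
    max(vapply(cand, function(l) {
      sg <- ps$labels == l
      sum(gt & sg) / sum(gt | sg)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(ious >= 0.7))
  # bubble and sub-200 px debris never survive the size filters
  bubbles <- tr$objects$object[!is.na(tr$objects$artifact_kind) &
                                 tr$objects$artifact_kind %in%
                                 c("bubble", "debris")]
  for (k in bubbles) {
    expect_equal(setdiff(unique(ps$labels[tr$labels == k]), 0), integer(0))
  }
  # blank image: empty particle set
  blank <- segment(matrix(70, 64, 64), seg_config())
  expect_equal(max(blank$labels), 0)
  expect_equal(nrow(tidy(blank)), 0)
})
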