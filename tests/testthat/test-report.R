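test_that("the fragment split is strict at the cutoff and conserves counts", {
  m <- tibble::tibble(feret_um = c(100, 149, 150, 151))
  sp <- split_population(m, 150)
  expect_equal(sp$fragments$feret_um, c(100, 149))
  expect_equal(sp$pellets$feret_um, c(150, 151))
  expect_equal(nrow(sp$fragments) + nrow(sp$pellets), nrow(m))
  # raising the cutoff never decreases the fragment count
  n_frag <- vapply(c(100, 150, 200), function(ct) {
    nrow(split_population(m, ct)$fragments)
  }, numeric(1))
  expect_true(all(diff(n_frag) >= 0))
  e <- split_population(m[0, ], 150)
  expect_equal(nrow(e$fragments) + nrow(e$pellets), 0)
  allp <- split_population(tibble::tibble(feret_um = c(200, 300)), 150)
  expect_equal(nrow(allp$fragments), 0)
})

test_that("confidence ellipses follow the chi-square closed form", {
  withr::with_seed(42, {
    x <- rnorm(1e5); y <- rnorm(1e5)
  })
  ep <- confidence_ellipse(x, y, 0.95)
  expect_equal(ep$semi_axes[1], sqrt(qchisq(0.95, 2)),
               tolerance = 0.02 / 2.448)
  expect_equal(ep$semi_axes[2], sqrt(qchisq(0.95, 2)),
               tolerance = 0.02 / 2.448)
  # independent axes with variances 4 and 1: axis-aligned closed form
  withr::with_seed(7, {
    x2 <- 2 * rnorm(2e4); y2 <- rnorm(2e4)
  })
  # near-independent samples: the finite-sample cross-covariance perturbs
  # the eigenvalues at O(1/n)
  ep2 <- confidence_ellipse(x2, y2)
  expect_equal(ep2$semi_axes[1], sqrt(qchisq(0.95, 2) * var(x2)),
               tolerance = 1e-4)
  expect_equal(ep2$semi_axes[2], sqrt(qchisq(0.95, 2) * var(y2)),
               tolerance = 1e-4)
  expect_lt(min(ep2$angle_deg, 180 - ep2$angle_deg), 2)
  # exactly collinear data: degenerate minor axis at 45 degrees
  z <- c(1, 2, 3, 4)
  epz <- confidence_ellipse(z, z)
  expect_equal(epz$semi_axes[2], 0)
  expect_equal(epz$angle_deg, 45)
  expect_error(confidence_ellipse(1:2, 1:2), "3 points")
  expect_error(confidence_ellipse(rep(1, 5), rep(2, 5)), "identical")
})

test_that("confidence ellipses are translation- and scale-equivariant", {
  withr::with_seed(3, {
    x <- rnorm(500, sd = 2); y <- rnorm(500)
  })
  ep <- confidence_ellipse(x, y)
  shifted <- confidence_ellipse(x + 10, y - 4)
  expect_equal(unname(shifted$center), unname(ep$center) + c(10, -4))
  expect_equal(shifted$semi_axes, ep$semi_axes)
  scaled <- confidence_ellipse(3 * x, y)
  expect_equal(scaled$semi_axes[1], 3 * ep$semi_axes[1], tolerance = 0.01)
})

test_that("the Welch test matches its closed form and symmetries", {
  a <- c(1, 2, 3); b <- c(104, 105.5, 106)
  got <- compare_populations(a, b)
  va <- var(a) / 3; vb <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 2 + vb^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$statistic, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, p_hand, tolerance = 1e-10)
  expect_lt(got$p_value, 1e-3)
  swapped <- compare_populations(b, a)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  same <- compare_populations(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_populations(c(1, 1), c(1, 1)), "degenerate")
})

test_that("reports are written deterministically with matching counts", {
  withr::with_seed(10, {
    m <- pelletscan:::measure_one(NULL, NULL, 0.78, template = TRUE)
    n <- 30
    m <- tibble::as_tibble(lapply(m, function(col) rep(NA_real_, n)))
    m$label <- seq_len(n)
    m$feret_um <- c(runif(15, 40, 140), runif(15, 160, 400))
    m$polar_circularity <- runif(n, 0.3, 1)
    m$flags <- NA_character_
  })
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_report(m, dir1)
  write_report(m, dir2)
  frag <- utils::read.csv(file.path(dir1, "fragments.csv"))
  expect_equal(nrow(frag), 15)
  pell <- utils::read.csv(file.path(dir1, "pellets.csv"))
  expect_equal(nrow(pell), 15)
  for (f in c("summary.csv", "fragments.csv", "pellets.csv",
              "ellipses.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
  # empty input: header-only CSVs
  dir3 <- withr::local_tempdir()
  write_report(m[0, ], dir3)
  expect_equal(length(readLines(file.path(dir3, "fragments.csv"))), 1)
  p <- plot_morphology(m)
  expect_s3_class(p, "ggplot")
})
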