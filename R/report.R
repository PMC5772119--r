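#' Split a particle population into fragments and pellets
#'
#' Mycelial fragments are operationally the particles whose maximal length
#' (maximum Feret diameter) is strictly below the cutoff; everything else
#' is a pellet.
#'
#' @param metrics Tibble with a `feret_um` column.
#' @param cutoff_um Length cutoff in micrometres (default 150).
#' @return A list of two tibbles: `fragments` (`feret_um < cutoff_um`) and
#'   `pellets`.
#' @export
split_population <- function(metrics, cutoff_um = 150) {
  stopifnot("feret_um" %in% names(metrics))
  frag <- metrics$feret_um < cutoff_um
  list(fragments = metrics[frag, , drop = FALSE],
       pellets = metrics[!frag, , drop = FALSE])
}

#' Population summary by subpopulation
#'
#' @param metrics Metrics tibble.
#' @param cutoff_um Fragment/pellet split (um).
#' @param columns Metric columns to summarise (defaults to every numeric
#'   column except `label` and the band columns).
#' @return A tibble: subpopulation, metric, n, mean, sd.
#' @export
population_summary <- function(metrics, cutoff_um = 150, columns = NULL) {
  sp <- split_population(metrics, cutoff_um)
  columns <- columns %||% setdiff(
    names(metrics)[vapply(metrics, is.numeric, logical(1))],
    c("label", grep("^band_", names(metrics), value = TRUE)))
  one <- function(tb, who) {
    if (nrow(tb) == 0) {
      return(tibble(subpopulation = character(), metric = character(),
                    n = integer(), mean = numeric(), sd = numeric()))
    }
    dplyr::bind_rows(lapply(columns, function(cn) {
      v <- tb[[cn]]
      tibble(subpopulation = who, metric = cn, n = sum(!is.na(v)),
             mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
    }))
  }
  dplyr::bind_rows(one(sp$fragments, "fragment"), one(sp$pellets, "pellet"))
}

#' Bivariate confidence ellipse
#'
#' Eigen-decomposes the 2x2 sample covariance of `(x, y)`; semi-axis i is
#' `sqrt(q * lambda_i)` where `q` is the chi-square quantile with 2 degrees
#' of freedom at the requested level (5.991 at 0.95), and the orientation
#' is the principal eigenvector's angle. This is the standard error-ellipse
#' construction used to draw 95% confidence regions on
#' diameter-versus-circularity scatter plots.
#'
#' @param x,y Numeric vectors (at least 3 points, not all identical).
#' @param level Confidence level in (0, 1).
#' @return An `ellipse_params` list: `center` (means), `semi_axes`
#'   (major, minor), `angle_deg` (principal axis vs x), `level`.
#' @export
confidence_ellipse <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), level > 0, level < 1)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("confidence_ellipse: need at least 3 points")
  S <- cov(cbind(x, y))
  if (all(S == 0)) abort("confidence_ellipse: all points identical")
  e <- eigen(S, symmetric = TRUE)
  q <- qchisq(level, df = 2)
  v <- e$vectors[, 1]
  structure(list(center = c(x = mean(x), y = mean(y)),
                 semi_axes = sqrt(q * pmax(e$values, 0)),
                 angle_deg = (atan2(v[2], v[1]) * 180 / pi) %% 180,
                 level = level),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse_params: center (%.3g, %.3g), semi-axes %.3g / %.3g, %.0f deg, level %.2f>\n",
    x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$angle_deg, x$level))
  invisible(x)
}

#' @param x An `ellipse_params`.
#' @param ... Unused.
#' @export
tidy.ellipse_params <- function(x, ...) {
  tibble(center_x = x$center[1], center_y = x$center[2],
         semi_major = x$semi_axes[1], semi_minor = x$semi_axes[2],
         angle_deg = x$angle_deg, level = x$level)
}

# polygon path of an ellipse_params, for plotting
ellipse_path <- function(ep, n = 180) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- ep$angle_deg * pi / 180
  ex <- ep$semi_axes[1] * cos(t); ey <- ep$semi_axes[2] * sin(t)
  tibble(x = ep$center[1] + ex * cos(a) - ey * sin(a),
         y = ep$center[2] + ex * sin(a) + ey * cos(a))
}

#' Compare two particle populations (Welch t-test)
#'
#' Two-sided Welch (unequal-variance) two-sample t-test on, typically, the
#' maximum Feret diameters of two cultures.
#'
#' @param a,b Numeric vectors (each at least 2 values with finite
#'   variance).
#' @return A tibble: `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_populations <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2 || sd(a) == 0 && sd(b) == 0) {
    abort("compare_populations: need two non-degenerate samples")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Diameter versus polar-circularity scatter with confidence ellipses
#'
#' The standard population view: every particle as a point, fragments and
#' pellets coloured separately, with a confidence ellipse per
#' subpopulation (drawn only when it has at least 3 points).
#'
#' @param metrics Metrics tibble (needs `feret_um`, `polar_circularity`).
#' @param cutoff_um Fragment/pellet split (um).
#' @param level Ellipse confidence level.
#' @return A ggplot object.
#' @export
plot_morphology <- function(metrics, cutoff_um = 150, level = 0.95) {
  metrics$subpopulation <- ifelse(metrics$feret_um < cutoff_um,
                                  "fragment", "pellet")
  paths <- dplyr::bind_rows(lapply(split(metrics, metrics$subpopulation),
                                   function(d) {
    if (nrow(d) < 3) return(NULL)
    ep <- tryCatch(confidence_ellipse(d$feret_um, d$polar_circularity,
                                      level),
                   error = function(e) NULL)
    if (is.null(ep)) return(NULL)
    cbind(ellipse_path(ep), subpopulation = d$subpopulation[1])
  }))
  p <- ggplot2::ggplot(metrics,
                       ggplot2::aes(x = .data$feret_um,
                                    y = .data$polar_circularity,
                                    colour = .data$subpopulation)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "maximum Feret diameter (µm)",
                  y = "polar circularity",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::theme_minimal()
  if (nrow(paths) > 0) {
    p <- p + ggplot2::geom_path(data = paths,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$subpopulation),
                                inherit.aes = FALSE)
  }
  p
}

#' Write a population report
#'
#' Writes per-subpopulation summary statistics, the fragment and pellet
#' metric tables, confidence-ellipse parameters, a diameter-versus-polar-
#' circularity scatter plot, and a run log carrying a hash of the
#' configuration. Reruns on identical inputs produce byte-identical CSVs.
#'
#' @param metrics Metrics tibble.
#' @param out_dir Output directory (created if needed).
#' @param cutoff_um Fragment/pellet split (um).
#' @param level Ellipse confidence level.
#' @param config Optional configuration object recorded (hashed) in the
#'   run log.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(metrics, out_dir, cutoff_um = 150, level = 0.95,
                         config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste("cannot create", out_dir))
  sp <- split_population(metrics, cutoff_um)
  files <- file.path(out_dir, c("summary.csv", "fragments.csv",
                                "pellets.csv", "ellipses.csv",
                                "morphology.png", "run.json"))
  write.csv(population_summary(metrics, cutoff_um), files[1],
            row.names = FALSE)
  write.csv(sp$fragments, files[2], row.names = FALSE)
  write.csv(sp$pellets, files[3], row.names = FALSE)
  eps <- dplyr::bind_rows(lapply(c(fragment = "fragments",
                                   pellet = "pellets"), function(nm) {
    d <- sp[[nm]]
    if (nrow(d) < 3) return(NULL)
    ep <- tryCatch(confidence_ellipse(d$feret_um, d$polar_circularity,
                                      level),
                   error = function(e) NULL)
    if (is.null(ep)) return(NULL)
    tidy(ep)
  }), .id = "subpopulation")
  write.csv(eps, files[4], row.names = FALSE)
  ok_png <- tryCatch({
    p <- plot_morphology(metrics, cutoff_um, level)
    ggplot2::ggsave(files[5], p, width = 7, height = 5, dpi = 150)
    TRUE
  }, error = function(e) FALSE)
  log <- list(n_particles = nrow(metrics),
              n_fragments = nrow(sp$fragments),
              n_pellets = nrow(sp$pellets),
              cutoff_um = cutoff_um, level = level,
              config_hash = rlang::hash(config),
              plot_written = ok_png)
  jsonlite::write_json(log, files[6], auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}
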