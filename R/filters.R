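#' Declarative particle filter rules
#'
#' A `filter_rule` bounds one metric (inclusive on both sides); a
#' `filter_set` is a named, ordered list of rules combined with AND: a
#' particle is accepted only if it satisfies every rule. Rules referencing
#' a metric with a missing (`NA`) value fail for that particle.
#'
#' @param metric Name of a column of the metrics table
#'   (see [measure_all()]).
#' @param min,max Inclusive bounds; at least one must be finite.
#' @return `filter_rule()`: a one-row tibble; `filter_set()`: a
#'   `filter_set` object.
#' @export
filter_rule <- function(metric, min = -Inf, max = Inf) {
  stopifnot(is.character(metric), length(metric) == 1)
  if (is.infinite(min) && is.infinite(max)) {
    abort("filter_rule: at least one bound must be present")
  }
  if (min > max) abort("filter_rule: min must not exceed max")
  tibble(metric = metric, min = as.numeric(min), max = as.numeric(max))
}

#' @rdname filter_rule
#' @param name Filter set name.
#' @param rules List of [filter_rule()] rows (or a tibble of them).
#' @export
filter_set <- function(name, rules = list()) {
  rules <- if (is.data.frame(rules)) as_tibble(rules)
           else dplyr::bind_rows(rules)
  if (nrow(rules) == 0) {
    rules <- tibble(metric = character(), min = numeric(), max = numeric())
  }
  structure(list(name = name, rules = rules), class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set '%s': %d rules>\n", x$name, nrow(x$rules)))
  print(x$rules)
  invisible(x)
}

#' Rules of a filter set as a tibble
#' @param x A `filter_set`.
#' @param ... Unused.
#' @export
tidy.filter_set <- function(x, ...) x$rules

#' Partition particles into accepted and rejected
#'
#' @param metrics Tibble of particle metrics (one row per particle, e.g.
#'   from [measure_all()]).
#' @param fs A [filter_set()].
#' @return A list of two tibbles, `accepted` and `rejected`; `rejected`
#'   carries a `failed_rules` column naming every violated rule's metric.
#' @export
apply_filterset <- function(metrics, fs) {
  stopifnot(inherits(fs, "filter_set"))
  unknown <- setdiff(fs$rules$metric, names(metrics))
  if (length(unknown) > 0) {
    abort(paste("filter rule references unknown metric:",
                paste(unknown, collapse = ", ")))
  }
  n <- nrow(metrics)
  fails <- matrix(FALSE, n, nrow(fs$rules))
  for (i in seq_len(nrow(fs$rules))) {
    r <- fs$rules[i, ]
    v <- metrics[[r$metric]]
    ok <- !is.na(v) & v >= r$min & v <= r$max
    fails[, i] <- !ok
  }
  any_fail <- if (ncol(fails) > 0) rowSums(fails) > 0 else rep(FALSE, n)
  rejected <- metrics[any_fail, , drop = FALSE]
  rejected$failed_rules <- vapply(which(any_fail), function(j) {
    paste(fs$rules$metric[fails[j, ]], collapse = ",")
  }, character(1))
  list(accepted = metrics[!any_fail, , drop = FALSE], rejected = rejected)
}

#' Save / load a filter set as YAML
#'
#' The on-disk form is `{name, rules: [{metric, min, max}, ...]}`; missing
#' bounds round-trip as infinities. Loading validates the rule fields and
#' names the offending rule on failure.
#'
#' @param fs A [filter_set()].
#' @param path YAML file path.
#' @export
save_filterset <- function(fs, path) {
  stopifnot(inherits(fs, "filter_set"))
  rules <- lapply(seq_len(nrow(fs$rules)), function(i) {
    r <- as.list(fs$rules[i, ])
    if (is.infinite(r$min)) r$min <- NULL
    if (is.infinite(r$max)) r$max <- NULL
    r
  })
  yaml::write_yaml(list(name = fs$name, rules = rules), path)
  invisible(path)
}

#' @rdname save_filterset
#' @param metrics_names Optional character vector of valid metric names to
#'   validate against (defaults to the standard [measure_all()] columns).
#' @export
load_filterset <- function(path, metrics_names = NULL) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$name)) abort("filter file: missing 'name' field")
  metrics_names <- metrics_names %||%
    names(measure_one(NULL, NULL, 0.78, template = TRUE))
  rules <- lapply(seq_along(obj$rules), function(i) {
    r <- obj$rules[[i]]
    if (is.null(r$metric)) {
      abort(sprintf("filter file: rule %d has no 'metric' field", i))
    }
    if (!r$metric %in% metrics_names) {
      abort(sprintf("filter file: rule %d references unknown metric '%s'",
                    i, r$metric))
    }
    filter_rule(r$metric, r$min %||% -Inf, r$max %||% Inf)
  })
  filter_set(obj$name, rules)
}

#' Default particle filter for streptomycete slides
#'
#' Implements the two exclusions a streptomycete rule set needs: large
#' non-circular contaminants such as cotton fibers (elongation <= 6,
#' polar circularity >= 0.2) and objects deviating from normal pellet
#' density (intensity SD >= 3 grey levels rejects flat contaminants;
#' density ratio within \[0.2, 5\]). All bounds are user-replaceable; build
#' a custom [filter_set()] for other organisms.
#'
#' @return A [filter_set()] named `"streptomyces-default"`.
#' @export
default_streptomyces_filter <- function() {
  filter_set("streptomyces-default", list(
    filter_rule("elongation", max = 6),
    filter_rule("polar_circularity", min = 0.2),
    filter_rule("sd_intensity", min = 3),
    filter_rule("density_ratio", min = 0.2, max = 5)))
}
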