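#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The p-value is exact (full
#' enumeration of rank assignments) when the combined sample size is at
#' most 20 and there are no ties, and otherwise uses the normal
#' approximation with tie and continuity corrections. Computation is
#' delegated to `stats::wilcox.test` with the switch made explicit.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param label_a,label_b Group labels carried into the result.
#' @return List of class `mwu_result`: `group_a`, `group_b`, `n_a`,
#'   `n_b`, `U` (the U statistic for `x`), `p_two_sided`, `median_a`,
#'   `median_b`, `median_difference` (`median_a - median_b`, signed).
#' @export
mann_whitney_u <- function(x, y, label_a = "a", label_b = "b") {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y)) <= 20L && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  structure(list(group_a = label_a, group_b = label_b,
                 n_a = length(x), n_b = length(y),
                 U = unname(ht$statistic),
                 p_two_sided = min(1, ht$p.value),
                 median_a = stats::median(x), median_b = stats::median(y),
                 median_difference = stats::median(x) - stats::median(y),
                 exact = use_exact),
            class = "mwu_result")
}

#' Partition intron lengths into comparison groups
#'
#' Extracts the four length vectors contrasted downstream: canonical,
#' all non-canonical, the U2/U12-like subset and the non-U2/U12-like
#' subset. Junctions that are not classified (or excluded) appear in no
#' classified subset.
#'
#' @param catalog Classified junction catalog (the `catalog` element of
#'   [classify_junctions()]).
#' @return List of class `length_groups` with numeric vectors
#'   `canonical`, `non_canonical_all`, `u2u12_like`, `non_u2u12_like`.
#' @export
group_lengths <- function(catalog) {
  stopifnot("classification" %in% names(catalog))
  canon <- catalog$category == "canonical"
  nc <- catalog$category == "non_canonical"
  structure(list(
    canonical = catalog$intron_length[canon],
    non_canonical_all = catalog$intron_length[nc],
    u2u12_like =
      catalog$intron_length[catalog$classification == "u2u12_like"],
    non_u2u12_like =
      catalog$intron_length[catalog$classification == "non_u2u12_like"]
  ), class = "length_groups")
}

#' Pairwise intron-length contrasts
#'
#' Runs the four pre-specified contrasts: canonical vs all non-canonical,
#' canonical vs U2/U12-like, canonical vs non-U2/U12-like, and
#' U2/U12-like vs non-U2/U12-like. A contrast with an empty group is
#' skipped with a warning. Raw p-values are reported (four pre-specified
#' contrasts, no multiplicity correction).
#'
#' @param groups A `length_groups` (see [group_lengths()]).
#' @return Data.frame with one row per performed contrast: `group_a`,
#'   `group_b`, `n_a`, `n_b`, `U`, `p_two_sided`, `median_a`, `median_b`,
#'   `median_difference`.
#' @export
length_contrasts <- function(groups) {
  pairs <- list(c("canonical", "non_canonical_all"),
                c("canonical", "u2u12_like"),
                c("canonical", "non_u2u12_like"),
                c("u2u12_like", "non_u2u12_like"))
  rows <- lapply(pairs, function(p) {
    x <- groups[[p[1L]]]
    y <- groups[[p[2L]]]
    if (length(x) == 0L || length(y) == 0L) {
      warning("contrast ", p[1L], " vs ", p[2L],
              " skipped: empty group", call. = FALSE)
      return(NULL)
    }
    r <- mann_whitney_u(x, y, p[1L], p[2L])
    data.frame(group_a = r$group_a, group_b = r$group_b, n_a = r$n_a,
               n_b = r$n_b, U = r$U, p_two_sided = r$p_two_sided,
               median_a = r$median_a, median_b = r$median_b,
               median_difference = r$median_difference,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group_a = character(), group_b = character(),
                      n_a = integer(), n_b = integer(), U = numeric(),
                      p_two_sided = numeric(), median_a = numeric(),
                      median_b = numeric(), median_difference = numeric(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Empirical cumulative distribution function points
#'
#' Sorted unique values with cumulative proportions (duplicates collapse
#' into a single, taller step); the final proportion is exactly 1. With
#' `log10_transform` the x-axis value is log10 of the observation, so the
#' points plot directly on a log10 axis.
#'
#' @param values Numeric vector (strictly positive when
#'   `log10_transform = TRUE`).
#' @param log10_transform Transform the x-axis values (default `TRUE`).
#' @return Data.frame with `value` (possibly log10-transformed) and
#'   `cum_prop`.
#' @export
ecdf_points <- function(values, log10_transform = TRUE) {
  stopifnot(length(values) > 0L)
  if (log10_transform && any(values <= 0)) {
    stop("log10 transform requires strictly positive values")
  }
  x <- sort(unique(values))
  props <- stats::ecdf(values)(x)
  data.frame(value = if (log10_transform) log10(x) else x,
             cum_prop = props)
}

#' Boxplot summary with 1.5 x IQR outliers
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); outliers are observations strictly outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`; whiskers sit at the most extreme
#' non-outlier observations.
#'
#' @param values Non-empty numeric vector.
#' @return List of class `boxplot_summary`: `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7L))
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  structure(list(q1 = q[1L], median = q[2L], q3 = q[3L],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside]),
                 n = length(values)),
            class = "boxplot_summary")
}
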