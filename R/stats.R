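#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-tailed rank-sum comparison as used for every group comparison in the
#' analysis. The exact null distribution is used for small tie-free samples
#' (combined n <= 16); otherwise a tie-corrected normal approximation with
#' continuity correction. `"auto"` picks between the two accordingly.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List with `U` (the Mann-Whitney U for `x`), `p` (two-tailed),
#'   `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney requires non-empty samples")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 16) && !ties,
                  exact = TRUE,
                  normal_approx = FALSE)
  if (exact && ties)
    stop("exact mode is undefined in the presence of ties")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y),
       method = if (exact) "exact" else "normal_approx")
}

#' Bootstrap confidence interval of the median
#'
#' Percentile bootstrap. Deterministic for a given `seed` (the global RNG
#' state is restored afterwards). With fewer than two observations the median
#' is returned with a missing interval.
#'
#' @param x Numeric sample.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Optional integer seed pinning the resampling.
#' @return List with `median`, `lo`, `hi`, `level`, `n`.
#' @export
median_ci <- function(x, level = 0.95, n_boot = 2000, seed = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  med <- stats::median(x)
  if (n < 2)
    return(list(median = med, lo = NA_real_, hi = NA_real_, level = level,
                n = n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  res <- matrix(x[sample.int(n, n * n_boot, replace = TRUE)], nrow = n)
  meds <- apply(res, 2, stats::median)
  a <- (1 - level) / 2
  ci <- stats::quantile(meds, c(a, 1 - a), type = 7, names = FALSE)
  list(median = med, lo = ci[1], hi = ci[2], level = level, n = n)
}

#' Box-plot summary statistics
#'
#' First/third quartiles, median and the 5th/95th percentiles (whisker
#' convention), with linear-interpolation (type-7) quantiles.
#'
#' @param x Numeric sample (n >= 1).
#' @return Named vector `(q1, median, q3, p5, p95)`.
#' @export
box_summary <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75, 0.05, 0.95), type = 7,
                       names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3], p5 = q[4], p95 = q[5])
}

#' Per-gene rate-ratio test with BH adjustment
#'
#' A declared simple stand-in for dispersion-modelled differential testing:
#' for each gene, a two-sided exact binomial test of its condition-A count
#' against the library-proportion expectation given the combined count, with
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param counts_a,counts_b Named vectors of per-gene summed counts per
#'   condition.
#' @param total_a,total_b Library totals per condition (> 0).
#' @return data.frame `gene_id`, `p`, `adj_p`.
#' @export
per_gene_count_test <- function(counts_a, counts_b, total_a, total_b) {
  if (total_a <= 0 || total_b <= 0) stop("library totals must be > 0")
  stopifnot(length(counts_a) == length(counts_b))
  prob <- total_a / (total_a + total_b)
  p <- vapply(seq_along(counts_a), function(i) {
    n <- counts_a[i] + counts_b[i]
    if (n == 0) return(1)
    stats::binom.test(counts_a[i], n, p = prob)$p.value
  }, numeric(1))
  data.frame(gene_id = if (!is.null(names(counts_a))) names(counts_a)
             else as.character(seq_along(counts_a)),
             p = unname(p),
             adj_p = unname(stats::p.adjust(p, method = "BH")),
             stringsAsFactors = FALSE)
}
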