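#' Assumption-gated two-group comparison
#'
#' Tests normality of each group (Shapiro-Wilk) and homoscedasticity
#' across groups (Levene's test, median-centred); when all three pass at
#' `alpha`, a two-sided Student's t-test is used, otherwise a two-sided
#' Mann-Whitney U test. Significance is annotated at the 0.05 / 0.01 /
#' 0.001 star levels.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param alpha significance level used both for the assumption gate and
#'   the significance flag.
#' @return list of class `group_test`: `test_used` (`"student_t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `n`, assumption
#'   diagnostics (`shapiro_p`, `levene_p`), `alpha`, `significant`,
#'   `stars`.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3) stop("group 'a' has fewer than 3 values")
  if (length(b) < 3) stop("group 'b' has fewer than 3 values")
  sw <- function(x) {
    if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  }
  sh_a <- sw(a); sh_b <- sw(b)
  lev <- tryCatch({
    df <- data.frame(v = c(a, b),
                     g = factor(rep(c("a", "b"), c(length(a), length(b)))))
    car::leveneTest(v ~ g, data = df, center = stats::median)[["Pr(>F)"]][1]
  }, error = function(e) 0)
  parametric <- sh_a > alpha && sh_b > alpha && lev > alpha
  if (parametric) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    used <- "student_t"
  } else {
    tt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    used <- "mann_whitney"
  }
  p <- tt$p.value
  structure(list(test_used = used, statistic = unname(tt$statistic),
                 p_value = p, n = c(a = length(a), b = length(b)),
                 shapiro_p = c(a = sh_a, b = sh_b), levene_p = lev,
                 alpha = alpha, significant = p < alpha,
                 stars = star_label(p)),
            class = "group_test")
}

#' Star annotation for a p-value
#'
#' @param p p-value.
#' @return `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"` (p < 0.05) or
#'   `"ns"`.
#' @export
star_label <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g p=%.4g %s (n=%d vs %d)\n", x$test_used,
              x$statistic, x$p_value, x$stars, x$n[1], x$n[2]))
  cat(sprintf("  Shapiro-Wilk p: a=%.3g b=%.3g; Levene p=%.3g\n",
              x$shapiro_p[1], x$shapiro_p[2], x$levene_p))
  invisible(x)
}

#' Normalised frequency histogram
#'
#' Bins values at a fixed bin width and returns frequencies summing to 1.
#' Values outside `range` are clipped into the end bins, with a warning
#' stating how many were clipped.
#'
#' @param values numeric values (non-empty).
#' @param bin_width bin width (> 0); default 0.05 in normalised-ratio
#'   units.
#' @param range numeric length-2; defaults to the data range expanded to
#'   whole bins.
#' @return data frame with `bin_center` and `frequency`.
#' @export
normalized_histogram <- function(values, bin_width = 0.05, range = NULL) {
  if (length(values) == 0) stop("empty input")
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(range)) {
    range <- c(floor(min(values) / bin_width) * bin_width,
               ceiling(max(values) / bin_width) * bin_width)
    if (diff(range) == 0) range <- range + c(0, bin_width)
  }
  n_out <- sum(values < range[1] | values > range[2])
  if (n_out > 0) {
    warning(n_out, " value(s) outside range clipped into end bins")
    values <- pmin(pmax(values, range[1]), range[2])
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  data.frame(bin_center = centers, frequency = counts / sum(counts))
}

#' Boxplots of per-replicate normalised frequencies by bin
#'
#' Builds one normalised histogram per replicate on a common grid and
#' draws a boxplot of the replicate frequencies within each bin -- the
#' standard display for comparing ratio distributions across brains.
#'
#' @param replicates list of numeric vectors (one per brain).
#' @param bin_width,range passed to [normalized_histogram()].
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the matrix of frequencies (bins x replicates).
#' @export
histogram_boxplots <- function(replicates, bin_width = 0.05,
                               range = c(0, 3), ...) {
  freqs <- vapply(replicates, function(v) {
    normalized_histogram(v, bin_width, range)$frequency
  }, numeric(length(seq(range[1], range[2], by = bin_width)) - 1))
  centers <- normalized_histogram(replicates[[1]], bin_width,
                                  range)$bin_center
  graphics::boxplot(t(freqs), names = signif(centers, 3),
                    xlab = "normalised ratio", ylab = "frequency", ...)
  invisible(freqs)
}

#' Upper-tail hypergeometric enrichment test
#'
#' Exact probability of observing at least `k` successes in a sample of
#' size `n` drawn without replacement from a population of size `N`
#' containing `K` successes -- the standard over-representation test for
#' gene-set membership.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k successes in the sample.
#' @return p-value `P[X >= k]`.
#' @export
hypergeometric_enrichment <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(n, K)) stop("k must satisfy 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
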