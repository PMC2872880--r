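# Cohort comparison machinery: stratified bootstrap resampling of a
# control pool against a test set (sampling without replacement, matching
# stratum counts each draw), a Shapiro-Wilk normality gate on the null
# distribution (Z-score path when it passes, empirical P otherwise), and
# the auxiliary chi-squared / Kolmogorov-Smirnov tests.

#' Stratified bootstrap comparison of a test cohort against a control pool
#'
#' Draws `n_iter` samples from the control pool without replacement,
#' each matching the test set's stratum counts exactly (e.g. the same
#' number of synonymous and missense variants, or the same junction-
#' distance bin counts), computes the statistic per draw, and compares
#' the observed test statistic to that null distribution. When the null
#' passes a Shapiro-Wilk normality test (P > 0.05; applied to a capped
#' subsample of at most 5000 draws, since the test degenerates at large
#' n) a Z score and normal two-sided P are reported; otherwise the
#' empirical P is the result. The empirical P is
#' `(1 + #{null at least as extreme})/(1 + n_iter)` on the observed
#' tail, doubled for two-sidedness and capped at 1.
#'
#' @param test_values numeric (or logical, for `statistic =
#'   "proportion"`) feature values of the test set.
#' @param control_values feature values of the control pool.
#' @param test_strata,control_strata optional stratum labels (character/
#'   factor) aligned with the value vectors; control draws match the
#'   test stratum counts.
#' @param statistic `"mean"`, `"proportion"` (mean of logical) or
#'   `"sum"`.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer seed; the draw sequence is fully determined by it.
#' @param alpha significance level for [significance_gate()] annotation
#'   (default 0.01).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return object of class `bootstrap_result`.
#' @export
bootstrap_compare <- function(test_values, control_values,
                              test_strata = NULL, control_strata = NULL,
                              statistic = c("mean", "proportion", "sum"),
                              n_iter = 1000L, seed = 1L, alpha = 0.01,
                              alternative = c("two.sided", "greater", "less")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stat_fun <- switch(statistic, mean = mean,
                     proportion = function(x) mean(as.logical(x)),
                     sum = sum)
  if (is.null(test_strata)) test_strata <- rep("all", length(test_values))
  if (is.null(control_strata)) control_strata <- rep("all", length(control_values))
  stopifnot(length(test_strata) == length(test_values),
            length(control_strata) == length(control_values),
            n_iter >= 1L)
  need <- table(test_strata)
  idx_by_stratum <- split(seq_along(control_values), control_strata)
  for (s in names(need)) {
    avail <- length(idx_by_stratum[[s]])
    if (is.null(idx_by_stratum[[s]]) || avail < need[[s]])
      stop("stratum '", s, "': need ", need[[s]], " controls, have ",
           if (is.null(idx_by_stratum[[s]])) 0L else avail)
  }
  x <- stat_fun(test_values)
  null <- numeric(n_iter)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    draw <- unlist(lapply(names(need), function(s) {
      pool <- idx_by_stratum[[s]]
      pool[sample.int(length(pool), need[[s]])]
    }), use.names = FALSE)
    null[it] <- stat_fun(control_values[draw])
  }
  mu <- mean(null)
  sigma <- stats::sd(null)
  # normality gate on a deterministic, capped subsample
  sw_values <- if (n_iter > 5000L) null[seq(1L, n_iter, length.out = 5000L)]
    else null
  sw <- if (stats::sd(sw_values) > 0 && length(sw_values) >= 3L)
    tryCatch(stats::shapiro.test(sw_values)$p.value, error = function(e) 0)
  else 0
  normal_ok <- sw > 0.05 && sigma > 0
  z <- if (sigma > 0) (x - mu) / sigma else NA_real_
  p_normal <- if (!is.na(z)) switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z)) else NA_real_
  upper_tail <- sum(null >= x)
  lower_tail <- sum(null <= x)
  p_emp <- switch(alternative,
    two.sided = min(1, 2 * (1 + min(upper_tail, lower_tail)) / (1 + n_iter)),
    greater = (1 + upper_tail) / (1 + n_iter),
    less = (1 + lower_tail) / (1 + n_iter))
  p_used <- if (normal_ok) p_normal else p_emp
  structure(list(
    observed = x, null_mean = mu, null_sd = sigma, z = z,
    p_normal = p_normal, p_empirical = p_emp, p = p_used,
    normality_pass = normal_ok, shapiro_p = sw,
    iterations = n_iter, seed = seed, statistic = statistic,
    alternative = alternative,
    strata = as.list(need), alpha = alpha,
    significant = significance_gate(p_used, alpha),
    null = null),
    class = "bootstrap_result")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap %s: observed %.4g vs null %.4g (sd %.4g), %s, %s\n",
    x$statistic, x$observed, x$null_mean, x$null_sd,
    if (x$normality_pass) sprintf("Z = %.3f, P = %.3g", x$z, x$p)
    else sprintf("empirical P = %.3g (normality gate failed)", x$p),
    if (x$significant) paste0("significant at alpha=", x$alpha)
    else "not significant"))
  invisible(x)
}

#' Chi-squared test with Yates continuity correction on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `statistic` and `p_value`.
#' @export
chi2_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("2x2 table has a zero margin")
  t <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric vectors (each non-empty).
#' @return list with `D` and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  t <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  list(D = unname(t$statistic), p_value = t$p.value)
}

#' Significance gate at a stringent alpha
#'
#' Strict inequality: `p < alpha` is significant, `p == alpha` is not.
#'
#' @param p probability in `[0, 1]`.
#' @param alpha significance level (default 0.01).
#' @return logical flag.
#' @export
significance_gate <- function(p, alpha = 0.01) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must be in [0, 1]")
  p < alpha
}

#' Junction-distance stratum labels
#'
#' Default bins for matching control draws on minimum junction distance:
#' 4-10, 11-25, 26-50, >50 exonic bases.
#'
#' @param min_junction_distance integer vector.
#' @param breaks upper bounds of the first bins (default
#'   `c(10, 25, 50)`).
#' @return character vector of bin labels.
#' @export
junction_distance_bin <- function(min_junction_distance,
                                  breaks = c(10L, 25L, 50L)) {
  labs <- c(paste0("<=", breaks), paste0(">", breaks[length(breaks)]))
  idx <- findInterval(min_junction_distance, breaks + 1L) + 1L
  labs[idx]
}
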