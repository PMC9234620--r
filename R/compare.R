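#' Subsampling distribution of a statistic
#'
#' Sample-size correction by repeated random subsampling without
#' replacement: draw `n` individuals from a source group `iterations`
#' times, evaluate a statistic on each subsample, and return the full
#' distribution with its mean and standard error. Used to compare a large
#' group against a small one at matched sample size (e.g. the total number
#' of ROH segments found in 24 birds).
#'
#' @param ids character vector of sample ids of the source group.
#' @param n subsample size (`n <= length(ids)`).
#' @param stat_fn function taking a character vector of sample ids and
#'   returning a scalar.
#' @param iterations number of subsamples (default 1000).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class `subsample_result`: `values`, `mean`, `se`,
#'   `n_subsample`, `iterations`, `seed`.
#' @export
subsample_statistic <- function(ids, n, stat_fn, iterations = 1000L,
                                seed) {
  if (n > length(ids)) stop("subsample size ", n, " exceeds group size ",
                            length(ids))
  stopifnot(is.function(stat_fn), !missing(seed))
  set.seed(as.integer(seed))
  values <- vapply(seq_len(iterations), function(it)
    stat_fn(sample(ids, n)), numeric(1))
  structure(list(values = values, mean = mean(values),
                 se = stats::sd(values) / sqrt(iterations),
                 n_subsample = as.integer(n),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "subsample_result")
}

#' Wilcoxon rank-sum test (pinned conventions)
#'
#' Thin wrapper over `stats::wilcox.test` with the W statistic in R's
#' Mann-Whitney convention: W = (rank sum of `x`, midranks for ties)
#' - n_x(n_x+1)/2. Two-sided p-value by exact enumeration when both
#' samples are small and tie-free, otherwise by normal approximation with
#' tie and continuity correction. Degenerate input (all values identical
#' across both samples) returns W = n_x n_y / 2 and p = 1.
#'
#' @param x,y numeric vectors.
#' @return a list of class `fragdiv_test`: `test`, `statistic`, `p_value`,
#'   `convention`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    return(structure(list(test = "wilcoxon_rank_sum",
                          statistic = length(x) * length(y) / 2,
                          p_value = 1,
                          convention = "degenerate: all values tied"),
                     class = "fragdiv_test"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  structure(list(test = "wilcoxon_rank_sum",
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 convention = "W = Mann-Whitney U of first sample (R wilcox.test)"),
            class = "fragdiv_test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Thin wrapper over `stats::chisq.test`; the Yates continuity correction
#' follows the `yates` flag (default on, the R default). Replication
#' reports show both variants because published X^2 values may have been
#' computed either way.
#'
#' @param tab 2x2 matrix of counts.
#' @param yates apply the continuity correction.
#' @return a list of class `fragdiv_test`: `test`, `statistic`, `df`,
#'   `p_value`, `convention`.
#' @export
chi_square_2x2 <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in 2x2 table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  structure(list(test = "chi_square_2x2",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value,
                 convention = if (yates) "Yates-corrected" else "uncorrected"),
            class = "fragdiv_test")
}

#' @export
print.fragdiv_test <- function(x, ...) {
  cat(x$test, ": statistic =", signif(x$statistic, 6),
      if (!is.null(x$df)) paste0("df = ", x$df),
      ", p =", signif(x$p_value, 3), "\n  [", x$convention, "]\n")
  invisible(x)
}

#' Compare the variances of two allele-frequency-change vectors
#'
#' Two routes for the drift-signal comparison between populations: the
#' classical variance-ratio F-test and a locus-label permutation test on
#' the variance ratio (distribution-free, recommended for Delta-p vectors,
#' which are far from normal).
#'
#' @param dp_a,dp_b numeric vectors (per-locus frequency changes).
#' @param n_perm permutations for the permutation route.
#' @param seed seed for the permutation route.
#' @return a list: `var_a`, `var_b`, `ratio`, `f_test` p-value,
#'   `perm_test` p-value (two-sided).
#' @export
compare_delta_p_variance <- function(dp_a, dp_b, n_perm = 2000L, seed = 1L) {
  dp_a <- dp_a[is.finite(dp_a)]; dp_b <- dp_b[is.finite(dp_b)]
  va <- stats::var(dp_a); vb <- stats::var(dp_b)
  ft <- stats::var.test(dp_a, dp_b)
  set.seed(as.integer(seed))
  pool <- c(dp_a, dp_b); na <- length(dp_a)
  obs <- log(va / vb)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    log(stats::var(pool[idx]) / stats::var(pool[-idx]))
  }, numeric(1))
  list(var_a = va, var_b = vb, ratio = va / vb,
       f_test = ft$p.value,
       perm_test = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm))
}
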