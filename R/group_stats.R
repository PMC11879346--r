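# Group-level statistics: pooled-variance t-tests, cluster-based
# permutation comparison of TLI time courses, and brain-behavior
# correlations.

#' Pooled-variance independent-samples t-test
#'
#' @param x,y Numeric vectors for the two groups (e.g. control,
#'   dyslexia).
#' @param alternative `"greater"` (x > y), `"less"`, or `"two.sided"`.
#' @return List with `t`, `df` (n1 + n2 - 2), `p`, and Cohen's `d`
#'   (mean difference over the pooled SD, n-1 denominators).
#' @export
group_ttest <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 per group", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  list(t = t, df = df, p = p, d = (mean(x) - mean(y)) / sqrt(sp2))
}

# pointwise pooled t-statistics for all permutations at once;
# X: subjects x timepoints, idx: n_perm x n1 matrix of group-1 row indices
pointwise_t_perms <- function(X, idx) {
  n <- nrow(X); n1 <- ncol(idx); n2 <- n - n1
  S <- colSums(X); SS <- colSums(X^2)
  n_perm <- nrow(idx)
  I <- matrix(0, n_perm, n)
  I[cbind(rep(seq_len(n_perm), n1), as.vector(idx))] <- 1
  s1 <- I %*% X; ss1 <- I %*% X^2
  m1 <- s1 / n1
  m2 <- sweep(-s1, 2, S, "+") / n2
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  v2 <- (sweep(-ss1, 2, SS, "+") - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# maximal runs of >= min_len adjacent points with p < alpha and a common
# t sign; returns tibble(start, end, sum_t)
find_clusters <- function(t_series, df, alpha, min_len) {
  p <- 2 * stats::pt(-abs(t_series), df)
  lab <- ifelse(p < alpha, sign(t_series), 0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0 & r$lengths >= min_len
  tibble::tibble(
    start = starts[keep], end = ends[keep],
    sum_t = vapply(which(keep),
                   function(i) sum(t_series[starts[i]:ends[i]]), numeric(1)))
}

#' Cluster-based permutation test of group time courses
#'
#' Compares two groups of aligned time courses (e.g. sliding-window TLI
#' curves). Pointwise pooled t-tests are computed per timepoint; runs of
#' at least `min_len` adjacent points with pointwise p < `alpha` and a
#' common sign form clusters, whose statistic is the sum of t-values
#' within the run. The null distribution is the maximum absolute cluster
#' sum over `n_perm` random relabelings of subjects to groups (0 when a
#' permutation yields no cluster); each observed cluster's p-value is
#' `(1 + #\{null >= |sum_t|\}) / (n_perm + 1)`.
#'
#' @param timecourses Numeric matrix, subjects x timepoints.
#' @param groups Vector of two group labels, one per subject (first
#'   level = "x" side of the t contrast).
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Pointwise threshold (default 0.05).
#' @param min_len Minimum cluster length (default 2).
#' @param seed Integer seed for the permutations.
#' @param method `"sample"` (random relabelings, default) or
#'   `"exhaustive"` (all `choose(n, n1)` relabelings, exact for small
#'   groups; `n_perm` is ignored and the p-value denominator is the
#'   number of relabelings).
#' @return A `cluster_test` list: `clusters` (tibble start, end, sum_t,
#'   p), `t_series`, `p_series`, `null_distribution`, `n_perm`, `alpha`,
#'   `min_len`, `significant` (any cluster p <= 0.05).
#' @export
cluster_permutation <- function(timecourses, groups, n_perm = 1000,
                                alpha = 0.05, min_len = 2L, seed = 1L,
                                method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group", call. = FALSE)
  if (any(apply(timecourses, 2, stats::sd) == 0)) {
    stop("constant (degenerate) timepoint in the time courses", call. = FALSE)
  }
  n <- nrow(timecourses)
  df <- n - 2

  obs_t <- as.vector(pointwise_t_perms(
    timecourses, matrix(which(g == levels(g)[1]), nrow = 1)))
  obs_clusters <- find_clusters(obs_t, df, alpha, min_len)

  if (method == "exhaustive") {
    idx <- t(utils::combn(n, n1))
  } else {
    set.seed(seed)
    idx <- t(replicate(n_perm, sample.int(n, n1)))
  }
  Tm <- pointwise_t_perms(timecourses, idx)
  null <- vapply(seq_len(nrow(idx)), function(r) {
    cl <- find_clusters(Tm[r, ], df, alpha, min_len)
    if (nrow(cl)) max(abs(cl$sum_t)) else 0
  }, numeric(1))

  obs_clusters$p <- vapply(seq_len(nrow(obs_clusters)), function(i) {
    if (method == "exhaustive") {
      mean(null >= abs(obs_clusters$sum_t[i]) - 1e-12)
    } else {
      (1 + sum(null >= abs(obs_clusters$sum_t[i]))) / (n_perm + 1)
    }
  }, numeric(1))

  structure(list(clusters = obs_clusters, t_series = obs_t,
                 p_series = 2 * stats::pt(-abs(obs_t), df),
                 null_distribution = null, n_perm = nrow(idx), alpha = alpha,
                 min_len = min_len,
                 significant = nrow(obs_clusters) > 0 &&
                   any(obs_clusters$p <= 0.05)),
            class = "cluster_test")
}

#' Brain-behavior correlation
#'
#' Pearson correlation between a per-subject neural index (TLI) and a
#' behavioral score, with a one-sided test of r > 0 via
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param tli Numeric vector of per-subject TLI values.
#' @param score Numeric vector of (z-standardized) behavioral scores.
#' @return List with `r`, `t`, `df`, `p` (one-sided), `n`.
#' @export
brain_behavior_correlation <- function(tli, score) {
  ok <- is.finite(tli) & is.finite(score)
  tli <- tli[ok]; score <- score[ok]
  n <- length(tli)
  if (n < 4) stop("need at least 4 subjects with both measures", call. = FALSE)
  if (stats::sd(tli) == 0 || stats::sd(score) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  r <- stats::cor(tli, score)
  if (abs(r) == 1) {
    return(list(r = r, t = sign(r) * Inf, df = n - 2,
                p = if (r > 0) 0 else 1, n = n))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2,
       p = stats::pt(t, n - 2, lower.tail = FALSE), n = n)
}

#' z-standardize scores
#'
#' Centers and scales to mean 0, SD 1 (sample SD, n-1 denominator).
#'
#' @param scores Numeric vector (length >= 2, non-constant).
#' @return The z-scores.
#' @export
zstandardize <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(scores)
  if (s == 0) stop("zero standard deviation; cannot standardize", call. = FALSE)
  (scores - mean(scores)) / s
}
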