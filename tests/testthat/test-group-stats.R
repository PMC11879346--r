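test_that("pooled t-test matches the stats::t.test oracle", {
  x <- c(2.1, 1.9, 2.0, 2.2); y <- c(1.0, 0.9, 1.1, 1.0)
  res <- group_ttest(x, y, "two.sided")
  oracle <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p, oracle$p.value)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(res$d, (mean(x) - mean(y)) / sp)

  res1 <- group_ttest(x, y, "greater")
  expect_equal(res1$p, t.test(x, y, var.equal = TRUE,
                              alternative = "greater")$p.value)

  same <- group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1); expect_equal(same$d, 0)

  expect_error(group_ttest(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(group_ttest(1, c(1, 2)), "at least 2")
})

test_that("z-standardization centers and scales with the n-1 denominator", {
  expect_equal(zstandardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(14)
  z <- zstandardize(rnorm(20, 50, 9))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(zstandardize(rep(2, 5)), "zero standard deviation")
  expect_error(zstandardize(3), "at least 2")
})

test_that("brain-behavior correlation matches the one-sided cor.test oracle", {
  x <- c(0.2, 0.5, 0.9, 1.4, 1.7)
  res <- brain_behavior_correlation(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  set.seed(15)
  tli <- rnorm(12); score <- 0.5 * tli + rnorm(12)
  res2 <- brain_behavior_correlation(tli, score)
  oracle <- cor.test(tli, score, alternative = "greater")
  expect_equal(res2$r, unname(oracle$estimate))
  expect_equal(res2$p, oracle$p.value)

  expect_error(brain_behavior_correlation(tli, rep(1, 12)), "zero variance")
  expect_error(brain_behavior_correlation(1:3, 1:3), "at least 4")
})

test_that("cluster permutation matches exhaustive enumeration on a small instance", {
  set.seed(16)
  X <- matrix(rnorm(8 * 6), nrow = 8)
  X[1:4, 3:4] <- X[1:4, 3:4] + 2.5       # effect at timepoints 3-4
  groups <- rep(c("a", "b"), each = 4)

  res <- cluster_permutation(X, groups, alpha = 0.05, min_len = 2,
                             method = "exhaustive")
  expect_equal(res$n_perm, choose(8, 4))

  # independent brute-force oracle
  brute_max <- function(rows_a) {
    t_series <- vapply(1:6, function(j) {
      unname(t.test(X[rows_a, j], X[-rows_a, j],
                    var.equal = TRUE)$statistic)
    }, numeric(1))
    p <- 2 * pt(-abs(t_series), 6)
    lab <- ifelse(p < 0.05, sign(t_series), 0)
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ok <- r$values != 0 & r$lengths >= 2
    if (!any(ok)) return(0)
    max(abs(vapply(which(ok),
                   function(i) sum(t_series[starts[i]:ends[i]]), numeric(1))))
  }
  combos <- combn(8, 4)
  null_oracle <- apply(combos, 2, brute_max)
  expect_equal(sort(res$null_distribution), sort(null_oracle),
               tolerance = 1e-10)
  obs <- brute_max(1:4)
  expect_equal(max(abs(res$clusters$sum_t)), obs, tolerance = 1e-10)
  expect_equal(min(res$clusters$p), mean(null_oracle >= obs - 1e-12))
})

test_that("cluster rules: minimum length, sign handling, and label symmetry", {
  set.seed(17)
  n <- 16
  X <- matrix(rnorm(n * 10, sd = 0.3), nrow = n)
  X[1:8, 5] <- X[1:8, 5] + 5             # one isolated strong timepoint
  groups <- rep(c("a", "b"), each = 8)

  res2 <- cluster_permutation(X, groups, n_perm = 200, min_len = 2, seed = 2)
  expect_equal(nrow(res2$clusters), 0)   # run of length 1 is not a cluster

  res1 <- cluster_permutation(X, groups, n_perm = 200, min_len = 1, seed = 2)
  expect_true(any(res1$clusters$start == 5 & res1$clusters$end == 5))

  # swapping group labels flips t but preserves clusters and p-values
  Xe <- matrix(rnorm(n * 10, sd = 0.3), nrow = n)
  Xe[1:8, 4:7] <- Xe[1:8, 4:7] + 1.5
  ra <- cluster_permutation(Xe, groups, n_perm = 300, seed = 3)
  rb <- cluster_permutation(Xe, rev(groups), n_perm = 300, seed = 3)
  expect_equal(abs(ra$clusters$sum_t), abs(rb$clusters$sum_t))
  expect_equal(ra$clusters$p, rb$clusters$p)

  expect_error(cluster_permutation(matrix(1, 8, 5),
                                   rep(c("a", "b"), each = 4), seed = 1),
               "degenerate")
  expect_error(cluster_permutation(Xe, rep("a", n), seed = 1), "two groups")
})

test_that("an injected mid-course effect is localized by the cluster test", {
  set.seed(18)
  hits <- 0; overlaps <- 0
  for (r in 1:20) {
    X <- matrix(rnorm(20 * 30, sd = 1), nrow = 20)
    X[1:10, 10:20] <- X[1:10, 10:20] + 1.6
    res <- cluster_permutation(X, rep(c("a", "b"), each = 10),
                               n_perm = 200, seed = r)
    sig <- res$clusters[res$clusters$p <= 0.05, ]
    if (nrow(sig)) {
      hits <- hits + 1
      if (any(sig$start <= 20 & sig$end >= 10)) overlaps <- overlaps + 1
    }
  }
  expect_gt(hits, 10)
  expect_gte(overlaps / hits, 0.9)
})
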