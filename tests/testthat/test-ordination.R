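test_that("shape PCA reproduces an independent SVD decomposition", {
  set.seed(31)
  X <- matrix(rnorm(60), 10, 6)
  p <- shape_pca(X)
  # oracle: singular values of the centered matrix
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  expect_equal(p$eigenvalues, sv^2 / (nrow(X) - 1), tolerance = 1e-12)
  expect_equal(sum(p$proportion), 1, tolerance = 1e-12)
  # scores reconstruct the centered data exactly
  expect_equal(p$scores %*% t(p$loadings), sweep(X, 2, p$center),
               tolerance = 1e-10, ignore_attr = TRUE)
  # scores are uncorrelated with variances equal to the eigenvalues
  expect_equal(stats::cov(p$scores), diag(p$eigenvalues),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("collinear data load entirely on the first component", {
  t <- seq(-1, 1, length.out = 20)
  X <- cbind(t, 2 * t, -t)
  p <- shape_pca(X)
  expect_equal(p$proportion[1], 1, tolerance = 1e-12)
})

test_that("CVA recovers the closed-form Mahalanobis distance", {
  # two groups engineered so the pooled covariance is exactly the identity
  # and the mean difference is (2, 0): D = 2, D2 = 4
  base <- sqrt(3) / 2 * cbind(c(1, -1, 1, -1), c(1, -1, -1, 1))
  X <- rbind(base, sweep(base, 2, c(2, 0), "+"))
  grp <- rep(c("a", "b"), each = 4)
  cv <- cva(X, grp, var_retain = 1)
  expect_equal(unname(cv$D["a", "b"]), 2, tolerance = 1e-9)
  expect_equal(unname(cv$D2["a", "b"]), 4, tolerance = 1e-8)
})

test_that("identical group means give zero distance and eigenvalue", {
  set.seed(32)
  base <- matrix(rnorm(40), 10, 4)
  X <- rbind(base, base)
  cv <- cva(X, rep(c("a", "b"), each = 10), var_retain = 1)
  expect_lt(cv$D["a", "b"], 1e-8)
  expect_lt(cv$eigenvalues[1], 1e-12)
})

test_that("canonical-space distances equal the direct quadratic form", {
  set.seed(33)
  for (rep in 1:5) {
    g <- sample(3:5, 1)
    sim <- make_groups(12, setNames(lapply(1:g, function(i) rnorm(4, sd = 2)),
                                    paste0("g", 1:g)))
    cv <- cva(sim$X, sim$groups, var_retain = 1)
    # independent oracle: pooled covariance and quadratic form from scratch
    W <- matrix(0, 4, 4)
    M <- matrix(0, g, 4)
    for (i in 1:g) {
      Xi <- sim$X[sim$groups == levels(sim$groups)[i], ]
      M[i, ] <- colMeans(Xi)
      W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
    }
    W <- W / (nrow(sim$X) - g)
    for (i in 1:(g - 1)) for (j in (i + 1):g) {
      d <- M[i, ] - M[j, ]
      expect_equal(unname(cv$D[i, j]), sqrt(drop(t(d) %*% solve(W) %*% d)),
                   tolerance = 1e-8)
    }
    # pooled within-group variance along each canonical axis is 1
    expect_lte(sum(cv$eigenvalues > 1e-8), g - 1)
  }
})

test_that("Mahalanobis D is invariant to affine maps of the variables", {
  set.seed(34)
  sim <- make_groups(15, list(a = c(0, 0, 0), b = c(1.5, 0, -1), c = c(0, 2, 1)))
  A <- matrix(rnorm(9), 3) + diag(3)
  X2 <- sweep(sim$X %*% A, 2, c(3, -1, 7), "+")
  cv1 <- cva(sim$X, sim$groups, var_retain = 1)
  cv2 <- cva(X2, sim$groups, var_retain = 1)
  expect_equal(cv1$D, cv2$D, tolerance = 1e-8)
})

test_that("cumulative canonical variance tracks group separability", {
  set.seed(35)
  sim <- make_groups(20, list(a = c(0, 0), b = c(4, 0), c = c(0, 1)))
  cv <- cva(sim$X, sim$groups, var_retain = 1)
  expect_equal(cv$cumulative[length(cv$cumulative)], 1, tolerance = 1e-12)
  expect_equal(n_canonical_axes(cv, 0.8), 1)  # one dominant axis
})

test_that("permutation test saturates, reproduces, and obeys the add-one rule", {
  set.seed(36)
  sim <- make_groups(20, list(a = c(0, 0, 0), b = c(10, 0, 0)), sd = 1)
  p1 <- permutation_test(sim$X, sim$groups, c("a", "b"), n_perm = 199, seed = 99)
  expect_equal(p1$p_value, 1 / 200)
  p2 <- permutation_test(sim$X, sim$groups, c("a", "b"), n_perm = 199, seed = 99)
  expect_identical(p1$p_value, p2$p_value)
  p3 <- permutation_test(sim$X, sim$groups, c("a", "b"), n_perm = 199, seed = 7)
  expect_equal(p3$p_value, p1$p_value)  # saturated regardless of seed
  expect_error(permutation_test(sim$X, sim$groups, c("a", "x")), "pair")
  expect_error(permutation_test(sim$X, sim$groups, c("a", "b"), n_perm = 50),
               "at least 99")
})

test_that("pairwise permutation p-values populate the CVA result", {
  set.seed(37)
  sim <- make_groups(12, list(a = c(0, 0), b = c(6, 0), c = c(0, 6)))
  cv <- cva(sim$X, sim$groups, var_retain = 1, n_perm = 99, seed = 5)
  expect_equal(dim(cv$perm_pvalues), c(3, 3))
  expect_true(all(cv$perm_pvalues[upper.tri(cv$perm_pvalues)] == 1 / 100))
  expect_equal(cv$perm_pvalues, t(cv$perm_pvalues))
})

test_that("size-altitude correlation matches the hand Sigma-formula", {
  x <- c(2600, 2750, 2900, 3100, 3250)
  y <- c(410, 402, 399, 390, 381)
  # independent arithmetic from the definition
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- size_covariate_correlation(y, x)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n, 5)
  t_stat <- r_hand * sqrt(3) / sqrt(1 - r_hand^2)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_stat), df = 3),
               tolerance = 1e-12)

  expect_equal(size_covariate_correlation(-x, x)$r, -1, tolerance = 1e-12)
  expect_error(size_covariate_correlation(rep(1, 5), x), "zero variance")
})
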