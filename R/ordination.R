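# Resolve a tangent data matrix from a wing_gpa or plain matrix.
tangent_matrix <- function(x) {
  if (inherits(x, "wing_gpa")) return(x$tangent)
  if (is.matrix(x)) return(x)
  stop("expected a wing_gpa object or a numeric matrix")
}

# PCA pre-reduction shared by CVA, the discriminant model and the permutation
# test: project onto the leading principal components capturing `var_retain`
# of total variance, capped at n - g components and at the numerical rank.
# Guards against singular pooled within-group covariance when 2k exceeds the
# within-group degrees of freedom.
reduce_subspace <- function(X, n_groups, var_retain = 0.99) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  e <- eigen(stats::cov(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  m <- which(cumsum(ev) / sum(ev) >= var_retain - 1e-12)[1]
  m <- min(m, n - n_groups, rank)
  if (m < 1) stop("no usable dimensions after subspace reduction")
  basis <- e$vectors[, seq_len(m), drop = FALSE]
  list(center = ctr, basis = basis, m = m, Y = Xc %*% basis)
}

# Pooled within-group covariance (divisor n - g).
pooled_within_cov <- function(Y, groups) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  n <- nrow(Y)
  W <- matrix(0, ncol(Y), ncol(Y))
  for (lev in levels(groups)) {
    Yg <- Y[groups == lev, , drop = FALSE]
    Yg <- sweep(Yg, 2, colMeans(Yg))
    W <- W + crossprod(Yg)
  }
  W / (n - g)
}

group_means <- function(Y, groups) {
  groups <- droplevels(as.factor(groups))
  M <- matrix(0, nlevels(groups), ncol(Y),
              dimnames = list(levels(groups), colnames(Y)))
  for (lev in levels(groups))
    M[lev, ] <- colMeans(Y[groups == lev, , drop = FALSE])
  M
}

#' Principal component analysis of shape variables
#'
#' Spectral decomposition of the sample covariance matrix of the tangent
#' coordinates, used as the exploratory ordination of the whole sample. Sign
#' convention: each loading vector is flipped so its largest-magnitude
#' element is positive, making output deterministic across platforms.
#'
#' @param x a `wing_gpa` object or an `n x p` data matrix.
#' @return An object of class `wing_pca` with `eigenvalues` (descending,
#'   non-negative), `proportion` and `cumulative` variance fractions,
#'   `scores` (`n x p`), `loadings` (`p x p`) and `center`.
#' @export
shape_pca <- function(x) {
  X <- tangent_matrix(x)
  if (nrow(X) < 3) stop("PCA requires at least 3 specimens")
  ctr <- colMeans(X)
  e <- eigen(stats::cov(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(X, 2, ctr) %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(eigenvalues = ev, proportion = ev / sum(ev),
                 cumulative = cumsum(ev) / sum(ev),
                 scores = scores, loadings = V, center = ctr),
            class = "wing_pca")
}

#' @export
print.wing_pca <- function(x, ...) {
  npc <- min(5, length(x$eigenvalues))
  cat("Shape PCA:", nrow(x$scores), "specimens,", length(x$eigenvalues), "variables\n")
  tab <- rbind(eigenvalue = x$eigenvalues[1:npc],
               proportion = x$proportion[1:npc],
               cumulative = x$cumulative[1:npc])
  colnames(tab) <- paste0("PC", 1:npc)
  print(round(tab, 4))
  invisible(x)
}

#' Canonical variate analysis with pairwise Mahalanobis distances
#'
#' Ordination maximizing between-group relative to within-group shape
#' variance. The tangent data are first reduced to the leading principal
#' components capturing `var_retain` of total variance (capped at `n - g`) to
#' regularize the pooled within-group covariance `W`; canonical axes are the
#' eigenvectors of `W^-1 B` (computed via a symmetric Cholesky reformulation)
#' and scores are scaled so the pooled within-group variance along each axis
#' is 1. In that scaled space, Euclidean distance between group means equals
#' the Mahalanobis distance `D = sqrt((m_i - m_j)' W^-1 (m_i - m_j))`; both
#' routes are computed and cross-checked internally to 1e-8. Pairwise
#' permutation tests on `D` are run when `n_perm > 0`.
#'
#' @param x a `wing_gpa` object or data matrix.
#' @param groups factor of group labels, one per row/specimen.
#' @param var_retain fraction of total variance kept in the pre-reduction.
#' @param n_perm number of label permutations per group pair (0 = skip).
#' @param seed RNG seed for the permutation tests.
#' @return An object of class `wing_cva`: canonical `eigenvalues`, `scores`,
#'   `cumulative` variance explained per axis, group `means` (canonical
#'   space), `D` and `D2` (Mahalanobis distance matrices on the distance and
#'   squared scales; the distinction matters when comparing with published
#'   tables), `perm_pvalues`, `n_permutations`, `rng_seed`, and the
#'   reduction (`center`, `basis`, `axes`).
#' @export
cva <- function(x, groups, var_retain = 0.99, n_perm = 0, seed = NULL) {
  X <- tangent_matrix(x)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(X)) stop("groups must have one label per specimen")
  g <- nlevels(groups)
  n <- nrow(X)
  if (g < 2) stop("CVA requires at least 2 groups")
  if (any(table(groups) < 2)) stop("every group must have at least 2 specimens")
  if (n - g <= 1) stop("too few specimens for ", g, " groups")

  red <- reduce_subspace(X, g, var_retain)
  Y <- red$Y
  W <- pooled_within_cov(Y, groups)
  M <- group_means(Y, groups)
  ng <- as.vector(table(groups))
  gm <- colSums(M * ng) / n
  Mc <- sweep(M, 2, gm)
  B <- crossprod(Mc * sqrt(ng)) / (g - 1)

  R <- tryCatch(chol(W), error = function(e)
    stop("pooled within-group covariance is numerically singular; ",
         "lower var_retain"))
  Ri <- backsolve(R, diag(ncol(W)))
  S <- t(Ri) %*% B %*% Ri
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  axes <- Ri %*% e$vectors                     # A' W A = I
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  ev <- pmax(e$values, 0)
  scores <- sweep(Y, 2, gm) %*% axes
  colnames(scores) <- paste0("CV", seq_len(ncol(scores)))
  Mcan <- Mc %*% axes
  rownames(Mcan) <- levels(groups)

  # Mahalanobis distances: direct quadratic form, cross-checked against the
  # Euclidean distance between group means in the scaled canonical space.
  D <- matrix(0, g, g, dimnames = list(levels(groups), levels(groups)))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    d <- M[i, ] - M[j, ]
    D[i, j] <- D[j, i] <- sqrt(drop(crossprod(d, solve(W, d))))
  }
  Dcan <- as.matrix(stats::dist(Mcan))
  if (max(abs(D - Dcan)) > 1e-8)
    stop("internal inconsistency: canonical-space and direct Mahalanobis ",
         "distances disagree (", format(max(abs(D - Dcan))), ")")

  pv <- NULL
  if (n_perm > 0) {
    pv <- matrix(NA_real_, g, g, dimnames = dimnames(D))
    diag(pv) <- 1
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      pair_seed <- if (is.null(seed)) NULL else seed + i * 1000L + j
      pv[i, j] <- pv[j, i] <- permutation_test(
        X, groups, pair = levels(groups)[c(i, j)],
        n_perm = n_perm, seed = pair_seed, var_retain = var_retain)$p_value
    }
  }

  structure(list(eigenvalues = ev, scores = scores,
                 cumulative = if (sum(ev) > 0) cumsum(ev) / sum(ev) else ev,
                 groups = groups, means = Mcan, D = D, D2 = D^2,
                 perm_pvalues = pv, n_permutations = n_perm, rng_seed = seed,
                 var_retain = var_retain, center = red$center,
                 basis = red$basis, axes = axes, n = n),
            class = "wing_cva")
}

#' Number of canonical axes needed to reach a variance fraction
#'
#' @param x a `wing_cva` object.
#' @param threshold cumulative variance fraction, e.g. `0.8`.
#' @return Integer count of leading canonical axes.
#' @export
n_canonical_axes <- function(x, threshold = 0.8) {
  stopifnot(inherits(x, "wing_cva"))
  unname(which(x$cumulative >= threshold - 1e-12)[1])
}

#' @export
print.wing_cva <- function(x, ...) {
  g <- nlevels(x$groups)
  cat("Canonical variate analysis:", x$n, "specimens,", g, "groups\n")
  nz <- min(g - 1, length(x$eigenvalues))
  cat("  canonical eigenvalues:",
      paste(format(x$eigenvalues[1:nz], digits = 4), collapse = ", "), "\n")
  cat("  Mahalanobis distances D (D2 in $D2):\n")
  print(round(x$D, 3))
  if (!is.null(x$perm_pvalues)) {
    cat("  permutation p-values (", x$n_permutations, " permutations):\n", sep = "")
    print(signif(x$perm_pvalues, 3))
  }
  invisible(x)
}

#' Scatter plot of canonical scores with per-group probability ellipses
#'
#' Plots the first two canonical axes with, for each group, the normal-theory
#' ellipse containing the given probability mass (90% by default).
#'
#' @param x a `wing_cva` object.
#' @param axes which two canonical axes to draw.
#' @param ellipse_prob probability mass of the per-group ellipses.
#' @param col colors, one per group.
#' @param ... passed to [graphics::plot()].
#' @method plot wing_cva
#' @export
plot.wing_cva <- function(x, axes = c(1, 2), ellipse_prob = 0.9,
                          col = NULL, ...) {
  sc <- x$scores[, axes, drop = FALSE]
  grp <- x$groups
  if (is.null(col)) col <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
  graphics::plot(sc, col = col[as.integer(grp)], pch = 16, cex = 0.6,
                 xlab = paste0("CV", axes[1]), ylab = paste0("CV", axes[2]), ...)
  r <- sqrt(stats::qchisq(ellipse_prob, df = 2))
  th <- seq(0, 2 * pi, length.out = 120)
  for (i in seq_len(nlevels(grp))) {
    si <- sc[grp == levels(grp)[i], , drop = FALSE]
    if (nrow(si) < 3) next
    ctr <- colMeans(si)
    ch <- chol(stats::cov(si))
    ell <- sweep(r * cbind(cos(th), sin(th)) %*% ch, 2, ctr, "+")
    graphics::lines(ell, col = col[i])
  }
  graphics::legend("topright", legend = levels(grp), col = col, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Permutation test for the separation of two group mean shapes
#'
#' Tests the Mahalanobis distance between two group means against its
#' permutation distribution: group labels are shuffled between the two groups
#' only, and the distance (pooled within-group covariance and means refit per
#' permutation, in a fixed PCA subspace of the two groups' data) is
#' recomputed. The p-value uses the add-one convention
#' `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`, so it can never be 0.
#'
#' @param x a `wing_gpa` object or data matrix.
#' @param groups factor of group labels.
#' @param pair length-2 vector naming the two groups to compare.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed; same seed gives an identical p-value.
#' @param var_retain subspace reduction fraction, as in [cva()].
#' @return A list with `statistic` (observed D), `p_value`, `n_perm`, `pair`.
#' @export
permutation_test <- function(x, groups, pair, n_perm = 1000, seed = NULL,
                             var_retain = 0.99) {
  X <- tangent_matrix(x)
  groups <- as.character(groups)
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (length(pair) != 2 || !all(pair %in% groups))
    stop("pair must name two groups present in 'groups'")
  keep <- groups %in% pair
  Xp <- X[keep, , drop = FALSE]
  lab <- factor(groups[keep], levels = sort(pair))
  n1 <- sum(lab == levels(lab)[1]); n2 <- sum(lab == levels(lab)[2])
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")

  red <- reduce_subspace(Xp, 2, var_retain)
  Y <- red$Y
  stat <- function(idx1) {
    Y1 <- Y[idx1, , drop = FALSE]; Y2 <- Y[-idx1, , drop = FALSE]
    m1 <- colMeans(Y1); m2 <- colMeans(Y2)
    W <- (crossprod(sweep(Y1, 2, m1)) + crossprod(sweep(Y2, 2, m2))) /
      (nrow(Y) - 2)
    d <- m1 - m2
    sqrt(drop(crossprod(d, solve(W, d))))
  }
  idx1 <- which(lab == levels(lab)[1])
  observed <- stat(idx1)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(b) stat(sample(nrow(Y), n1)), numeric(1))
  p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_perm)
  list(statistic = observed, p_value = p, n_perm = n_perm, pair = sort(pair))
}

#' Correlation between centroid size and a covariate
#'
#' Pearson correlation (two-sided p-value from the t transform with n - 2
#' degrees of freedom) between per-specimen centroid sizes and a covariate
#' such as apiary altitude; the survey design expects a negative size
#' gradient with altitude.
#'
#' @param sizes numeric vector of centroid sizes (raw-coordinate scale).
#' @param covariate numeric vector, same length (e.g. altitude in m.a.s.l.).
#' @param names length-2 character vector naming the variables.
#' @return An object of class `wing_cor` with `r`, `n`, `p_value`,
#'   `variables`.
#' @export
size_covariate_correlation <- function(sizes, covariate,
                                       names = c("centroid_size", "altitude_masl")) {
  ok <- stats::complete.cases(sizes, covariate)
  sizes <- sizes[ok]; covariate <- covariate[ok]
  if (length(sizes) < 3) stop("need at least 3 paired observations")
  if (stats::sd(sizes) == 0 || stats::sd(covariate) == 0)
    stop("zero variance in ", if (stats::sd(sizes) == 0) names[1] else names[2])
  ct <- stats::cor.test(sizes, covariate, method = "pearson",
                        alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(sizes),
                 p_value = ct$p.value, variables = names),
            class = "wing_cor")
}

#' @export
print.wing_cor <- function(x, ...) {
  cat("Pearson correlation, ", x$variables[1], " ~ ", x$variables[2], ":\n",
      sep = "")
  cat("  r = ", format(x$r, digits = 3), ", n = ", x$n,
      ", two-sided p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
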