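# Shape vectors are flattened row-wise: (x1, y1, x2, y2, ...).
flatten_shape <- function(m) as.vector(t(m))
unflatten_shape <- function(v, k) matrix(v, nrow = k, ncol = 2, byrow = TRUE)

center_shape <- function(m) sweep(m, 2, colMeans(m))

#' Centroid size of a landmark configuration
#'
#' The standard size measure of geometric morphometrics: the square root of
#' the summed squared distances of the landmarks from their centroid. It is
#' invariant to translation and rotation and scales linearly under isotropic
#' scaling.
#'
#' @param x a `k x 2` coordinate matrix or a [wing_dataset] (in which case a
#'   vector of per-specimen sizes is returned, computed from the raw
#'   coordinates).
#' @return Positive numeric scalar (or vector for a dataset).
#' @export
centroid_size <- function(x) {
  if (inherits(x, "wing_dataset"))
    return(apply(x$coords, 3, centroid_size))
  if (!is.matrix(x) || ncol(x) != 2) stop("expected a k x 2 coordinate matrix")
  if (nrow(x) < 3) stop("at least 3 landmarks are required")
  cs <- sqrt(sum(center_shape(x)^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide")
  cs
}

# Center and scale to unit centroid size ("pre-shape").
preshape <- function(m) {
  m <- center_shape(m)
  cs <- sqrt(sum(m^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide")
  m / cs
}

# Optimal rotation (det +1, reflections disallowed) aligning X onto Y,
# both k x 2 and centered: R minimizing ||X R - Y||_F, from the SVD of X'Y.
optimal_rotation <- function(X, Y) {
  M <- crossprod(X, Y)
  s <- svd(M)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Ordinary Procrustes fit of one shape onto another
#'
#' Centers and scales both configurations to unit centroid size, then rotates
#' the target (rotation only; reflections are disallowed because all wings
#' are digitized on the same side) to minimize the summed squared landmark
#' distances to the reference. The minimized root-sum-of-squares is the
#' partial Procrustes distance between the two shapes.
#'
#' @param target,reference `k x 2` coordinate matrices with equal `k`.
#' @return A list with `aligned` (the fitted target, unit centroid size) and
#'   `residual` (the partial Procrustes distance).
#' @export
procrustes_fit <- function(target, reference) {
  if (nrow(target) != nrow(reference))
    stop("landmark count mismatch: ", nrow(target), " vs ", nrow(reference))
  X <- preshape(target)
  Y <- preshape(reference)
  R <- optimal_rotation(X, Y)
  aligned <- X %*% R
  list(aligned = aligned, residual = sqrt(sum((aligned - Y)^2)))
}

# Rotate the whole aligned set so the consensus sits on its principal axes.
# Eigenvector signs are fixed deterministically (largest-magnitude element of
# the first axis positive; second axis is its +90-degree perpendicular so the
# transform is a proper rotation), and the configuration is rotated by 180
# degrees if the first landmark's x would be negative.
principal_axis_rotation <- function(consensus) {
  C <- crossprod(consensus)           # consensus is centered
  e <- eigen(C, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  R <- cbind(v1, c(-v1[2], v1[1]))
  if ((consensus %*% R)[1, 1] < 0) R <- -R
  R
}

#' Generalized Procrustes alignment of a landmark dataset
#'
#' Iterative generalized Procrustes analysis: every configuration is centered
#' and scaled to unit centroid size, then repeatedly rotated to the current
#' consensus, which is re-estimated as the arithmetic mean (rescaled to unit
#' size) until it moves by less than `tol` in root-sum-of-squares. The final
#' alignment is rotated so the consensus lies on its principal axes, making
#' the output orientation deterministic. Aligned shapes are then orthogonally
#' projected into the tangent space at the consensus (see
#' [tangent_project()]), giving the shape variables used by all downstream
#' statistics. Centroid sizes are taken from the raw coordinates before unit
#' scaling, so they remain usable as a size variable.
#'
#' @param dataset a [wing_dataset] with at least 2 configurations.
#' @param tol convergence tolerance on the consensus displacement.
#' @param max_iter maximum number of GPA iterations; non-convergence yields a
#'   warning and the last iterate, not an error.
#' @return An object of class `wing_gpa`: `shapes` (`k x 2 x n` aligned
#'   coordinates), `consensus` (`k x 2`), `centroid_sizes`, `tangent`
#'   (`n x 2k` tangent-space coordinates), `ids`, `meta`, `iterations`,
#'   `converged`.
#' @export
gpa_align <- function(dataset, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(dataset, "wing_dataset"))
  if (dataset$n < 2) stop("GPA requires at least 2 configurations")
  k <- dataset$k; n <- dataset$n
  cs <- centroid_size(dataset)
  shapes <- array(apply(dataset$coords, 3, preshape), dim = c(k, 2, n))
  # Start from the mean pre-shape when orientations are already coherent
  # (makes GPA a fixpoint on aligned data); with arbitrary digitizing
  # orientations the mean collapses toward zero, so fall back to the first
  # specimen as the initial reference.
  m0 <- apply(shapes, c(1, 2), mean)
  consensus <- if (sqrt(sum(center_shape(m0)^2)) >= 0.2) preshape(m0) else
    shapes[, , 1]
  iterations <- 0L; converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (s in seq_len(n))
      shapes[, , s] <- shapes[, , s] %*% optimal_rotation(shapes[, , s], consensus)
    new_consensus <- preshape(apply(shapes, c(1, 2), mean))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations; returning last iterate")
  R <- principal_axis_rotation(consensus)
  consensus <- consensus %*% R
  for (s in seq_len(n)) shapes[, , s] <- shapes[, , s] %*% R
  dimnames(shapes) <- dimnames(dataset$coords)
  out <- structure(list(shapes = shapes, consensus = consensus,
                        centroid_sizes = stats::setNames(cs, dataset$ids),
                        tangent = NULL, ids = dataset$ids, meta = dataset$meta,
                        k = k, n = n, iterations = iterations,
                        converged = converged, tol = tol),
                   class = "wing_gpa")
  tangent_project(out)
}

#' Project aligned shapes into the tangent space at the consensus
#'
#' Flattens each aligned shape, subtracts its component along the (unit-norm)
#' flattened consensus, and stores the result as the specimen's tangent-space
#' coordinate vector of length `2k`. The consensus itself maps to the zero
#' vector, and every tangent vector is orthogonal to the consensus by
#' construction. For small shape variation these coordinates agree with the
#' raw Procrustes residuals to first order; multivariate statistics are valid
#' in this linearized space.
#'
#' @param x a `wing_gpa` object from [gpa_align()].
#' @return The same object with `tangent` filled (`n x 2k` matrix, columns
#'   named `LM<i>.x`/`LM<i>.y` with 1-based landmark numbering).
#' @export
tangent_project <- function(x) {
  stopifnot(inherits(x, "wing_gpa"))
  cvec <- flatten_shape(x$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  X <- t(apply(x$shapes, 3, flatten_shape))       # n x 2k
  tang <- X - (X %*% cvec) %*% t(cvec)
  colnames(tang) <- paste0("LM", rep(seq_len(x$k), each = 2), c(".x", ".y"))
  rownames(tang) <- x$ids
  x$tangent <- tang
  x
}

#' @export
print.wing_gpa <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat("  specimens:", x$n, "  landmarks:", x$k, "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  centroid size: mean", format(mean(x$centroid_sizes), digits = 5),
      " range", paste(format(range(x$centroid_sizes), digits = 5), collapse = " - "), "\n")
  invisible(x)
}

#' @method summary wing_gpa
#' @export
summary.wing_gpa <- function(object, ...) {
  rms <- sqrt(rowSums(object$tangent^2))
  cat("GPA of", object$n, "specimens,", object$k, "landmarks\n")
  cat("Procrustes distance to consensus (tangent norm):\n")
  print(summary(rms))
  invisible(list(tangent_norm = rms))
}

#' Plot aligned landmark scatter
#'
#' Scatter of all aligned landmark positions with the consensus overlaid
#' (filled points, 1-based landmark numbers).
#'
#' @param x a `wing_gpa` object.
#' @param ... passed to [graphics::plot()].
#' @method plot wing_gpa
#' @export
plot.wing_gpa <- function(x, ...) {
  pts <- do.call(rbind, lapply(seq_len(x$n), function(s) x$shapes[, , s]))
  graphics::plot(pts, col = grDevices::grey(0.6, alpha = 0.4), pch = 16, cex = 0.4,
                 asp = 1, xlab = "x", ylab = "y", ...)
  graphics::points(x$consensus, pch = 21, bg = "firebrick", cex = 1.1)
  graphics::text(x$consensus, labels = seq_len(x$k), pos = 3, cex = 0.7)
  invisible(x)
}

#' Export aligned data as a data frame
#'
#' One row per specimen: id, centroid size, and the `2k` tangent coordinates;
#' suitable for `write.csv` and external tools.
#'
#' @param x a `wing_gpa` object.
#' @param ... ignored.
#' @return A data frame.
#' @method as.data.frame wing_gpa
#' @export
as.data.frame.wing_gpa <- function(x, ...) {
  data.frame(specimen_id = x$ids, centroid_size = unname(x$centroid_sizes),
             x$tangent, check.names = FALSE, stringsAsFactors = FALSE)
}
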