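# Fixture builders and independent oracles used across the test files.

# Random non-degenerate landmark configuration.
rand_shape <- function(k) matrix(stats::rnorm(2 * k), k, 2)

# Random dataset of n independent Gaussian configurations.
rand_dataset <- function(n, k, ids = sprintf("s%03d", seq_len(n))) {
  wing_dataset(lapply(seq_len(n), function(i) rand_shape(k)), ids)
}

# Realistic morphometric dataset: moderate isotropic shape scatter around a
# random base shape, raw coordinates under random similarity transforms.
# GPA assumes this concentrated regime (a shape cloud spread over the whole
# pre-shape sphere has no well-defined mean shape).
concentrated_dataset <- function(n, k, sd = 0.03,
                                 ids = sprintf("s%03d", seq_len(n))) {
  base <- rand_shape(k)
  base <- sweep(base, 2, colMeans(base))
  base <- base / sqrt(sum(base^2))
  perturb_dataset(wing_dataset(lapply(seq_len(n), function(i)
    base + matrix(stats::rnorm(2 * k, sd = sd), k, 2)), ids))
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta),
                                 -sin(theta), cos(theta)), 2, 2)

# Apply a random similarity transform (rotation, translation, positive
# scaling) to every configuration of a dataset.
perturb_dataset <- function(ds) {
  coords <- ds$coords
  for (s in seq_len(ds$n)) {
    R <- rot2(stats::runif(1, 0, 2 * pi))
    sc <- stats::runif(1, 0.2, 5)
    tr <- stats::runif(2, -50, 50)
    coords[, , s] <- sweep(sc * coords[, , s] %*% R, 2, tr, "+")
  }
  wing_dataset(coords, ds$ids, ds$meta)
}

# Brute-force partial Procrustes distance: scan rotations of the centered,
# unit-size configurations on a fixed angular grid. Uses the closed-form
# residual ||X R(t) - Y||^2 = 2 - 2 (alpha cos t + beta sin t) so the scan
# stays exact and fast; independent of the SVD route under test.
brute_procrustes_residual <- function(target, reference, step_deg = 0.001) {
  ctr <- function(m) sweep(m, 2, colMeans(m))
  X <- ctr(target); X <- X / sqrt(sum(X^2))
  Y <- ctr(reference); Y <- Y / sqrt(sum(Y^2))
  M <- crossprod(X, Y)
  alpha <- M[1, 1] + M[2, 2]
  beta <- M[1, 2] - M[2, 1]
  th <- seq(0, 2 * pi, by = step_deg * pi / 180)
  sqrt(max(0, min(2 - 2 * (alpha * cos(th) + beta * sin(th)))))
}

# Independent UPGMA reference: clusters kept as explicit leaf sets, the
# distance between two clusters recomputed from scratch as the mean of the
# original leaf-to-leaf dissimilarities, minimum pair chosen with the same
# lexicographic tie rule. Returns the merged leaf sets and heights in merge
# order.
upgma_reference <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dij < best$d - 1e-15 ||
          (abs(dij - best$d) <= 1e-15 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = key)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- list(members = merged, height = best$d / 2)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# Leaf sets of the internal nodes of an upgma_tree, in merge order.
upgma_members <- function(tree) {
  members <- as.list(tree$labels)
  for (step in seq_len(tree$n - 1)) {
    ch <- tree$merge[step, ]
    members[[tree$n + step]] <- sort(c(members[[ch[1]]], members[[ch[2]]]))
  }
  members[(tree$n + 1):(2 * tree$n - 1)]
}

# Gaussian groups with a common covariance, stacked; returns list(X, groups).
make_groups <- function(n_per, means, sd = 1) {
  X <- do.call(rbind, lapply(seq_along(means), function(i)
    sweep(matrix(stats::rnorm(n_per * length(means[[i]]), sd = sd), n_per),
          2, means[[i]], "+")))
  list(X = X, groups = factor(rep(names(means), each = n_per)))
}
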