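#' Train a linear discriminant on reference groups
#'
#' Fits the linear discriminant used to identify specimens at the subspecies
#' level: for each reference group the score of a specimen `x` is
#' `m' W^-1 x - m' W^-1 m / 2 + log(prior)`, with `m` the group mean and `W`
#' the pooled within-group covariance, computed in the same PCA-reduced
#' subspace as [cva()] (fraction `var_retain` of total variance, capped at
#' `n - g`). Specimens with `NA` group labels are excluded from training, so
#' a jointly superimposed reference + query dataset can be passed directly.
#'
#' @param x a `wing_gpa` object or data matrix (reference and query specimens
#'   jointly superimposed; the subspace is estimated from the training rows).
#' @param groups group labels, one per specimen; `NA` rows are ignored.
#' @param priors `"equal"` (default; reference panels are balanced by design)
#'   or `"proportional"` to training group sizes.
#' @param var_retain subspace reduction fraction, as in [cva()].
#' @return An object of class `wing_dfa` storing the subspace (`center`,
#'   `basis`), group `means`, pooled covariance `W`, priors and, when fitted
#'   from a `wing_gpa`, the consensus shape used as a provenance check by
#'   [classify()].
#' @export
train_lda <- function(x, groups, priors = c("equal", "proportional"),
                      var_retain = 0.99) {
  priors <- match.arg(priors)
  X <- tangent_matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("groups must have one label per specimen")
  keep <- !is.na(groups)
  Xt <- X[keep, , drop = FALSE]
  lab <- factor(groups[keep], levels = sort(unique(groups[keep])))
  g <- nlevels(lab)
  if (g < 2) stop("at least 2 reference groups are required")
  if (any(table(lab) < 2)) stop("every reference group needs >= 2 specimens")

  red <- reduce_subspace(Xt, g, var_retain)
  Y <- red$Y
  W <- pooled_within_cov(Y, lab)
  M <- group_means(Y, lab)
  A <- tryCatch(t(solve(W, t(M))), error = function(e)
    stop("pooled within-group covariance is numerically singular; ",
         "lower var_retain"))                     # g x m, rows m_g' W^-1
  prior_p <- if (priors == "equal") rep(1 / g, g) else
    as.vector(table(lab)) / nrow(Y)
  const <- -0.5 * rowSums(A * M) + log(prior_p)

  structure(list(center = red$center, basis = red$basis, means = M,
                 W = W, coef = A, const = const, levels = levels(lab),
                 priors = priors, prior_p = stats::setNames(prior_p, levels(lab)),
                 var_retain = var_retain, p = ncol(X), n_train = nrow(Y),
                 consensus = if (inherits(x, "wing_gpa")) x$consensus else NULL),
            class = "wing_dfa")
}

#' @export
print.wing_dfa <- function(x, ...) {
  cat("Linear discriminant over", length(x$levels), "reference groups:",
      paste(x$levels, collapse = ", "), "\n")
  cat("  training specimens:", x$n_train, " subspace dims:", ncol(x$basis),
      " priors:", x$priors, "\n")
  invisible(x)
}

dfa_scores <- function(model, X) {
  if (ncol(X) != model$p)
    stop("query has ", ncol(X), " variables but the model was trained on ",
         model$p, " (joint superimposition required)")
  Y <- sweep(X, 2, model$center) %*% model$basis
  sc <- Y %*% t(model$coef)
  sc <- sweep(sc, 2, model$const, "+")
  colnames(sc) <- model$levels
  rownames(sc) <- rownames(X)
  sc
}

#' Classify specimens against reference groups
#'
#' Assigns each query specimen to the reference group with the highest
#' discriminant score (ties broken toward the lexicographically first group
#' name, with a warning). Queries must lie in the same tangent basis as the
#' training data: when both the model and the query carry a consensus shape
#' (fitted from `wing_gpa` objects), the two are compared and a mismatch is
#' an error, since mixing separate superimpositions silently invalidates the
#' discriminant.
#'
#' @param model a `wing_dfa` from [train_lda()].
#' @param newdata a `wing_gpa` object or `n x 2k` tangent matrix of queries.
#' @param truth optional vector of known group labels, enabling the confusion
#'   matrix and accuracy.
#' @return An object of class `wing_classification`: `assigned` (factor),
#'   `scores`, `posterior` (softmax-normalized weights), and when `truth` is
#'   given `confusion` (known x assigned counts) and `accuracy`.
#' @export
classify <- function(model, newdata, truth = NULL) {
  stopifnot(inherits(model, "wing_dfa"))
  if (inherits(newdata, "wing_gpa") && !is.null(model$consensus)) {
    if (!isTRUE(all.equal(dim(newdata$consensus), dim(model$consensus))) ||
        max(abs(newdata$consensus - model$consensus)) > 1e-9)
      stop("provenance mismatch: query superimposition differs from the ",
           "model's; reference and query must be superimposed jointly")
  }
  X <- tangent_matrix(newdata)
  sc <- dfa_scores(model, X)
  rmax <- apply(sc, 1, max)
  tied <- rowSums(sweep(sc, 1, rmax) > -1e-9 * pmax(1, abs(rmax))) > 1L
  if (any(tied))
    warning(sum(tied), " tied discriminant score(s); ",
            "assigned to the lexicographically first group")
  assigned <- factor(model$levels[max.col(sc, ties.method = "first")],
                     levels = model$levels)
  post <- exp(sweep(sc, 1, rmax))
  post <- post / rowSums(post)
  out <- list(assigned = assigned, scores = sc, posterior = post,
              levels = model$levels)
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = model$levels)
    out$confusion <- table(known = truth, assigned = assigned)
    out$accuracy <- mean(as.character(truth) == as.character(assigned),
                         na.rm = TRUE)
  }
  structure(out, class = "wing_classification")
}

#' @export
print.wing_classification <- function(x, ...) {
  cat("Classification of", length(x$assigned), "specimens\n")
  print(table(x$assigned))
  if (!is.null(x$confusion)) {
    cat("confusion matrix (known x assigned):\n")
    print(x$confusion)
    cat("accuracy:", format(x$accuracy, digits = 4), "\n")
  }
  invisible(x)
}

#' Resubstitution accuracy of the discriminant
#'
#' Trains on all labelled specimens and classifies the same specimens;
#' optimistic by construction, reported alongside [loocv_accuracy()].
#'
#' @inheritParams train_lda
#' @return Fraction of labelled specimens assigned to their own group.
#' @export
resubstitution_accuracy <- function(x, groups, priors = "equal",
                                    var_retain = 0.99) {
  X <- tangent_matrix(x)
  groups <- as.character(groups)
  keep <- !is.na(groups)
  model <- train_lda(X[keep, , drop = FALSE], groups[keep], priors, var_retain)
  res <- classify(model, X[keep, , drop = FALSE], truth = groups[keep])
  res$accuracy
}

#' Leave-one-out cross-validated accuracy
#'
#' For each labelled specimen the discriminant — including the PCA subspace
#' reduction — is refit on all other labelled specimens and the held-out
#' specimen is classified. The superimposition itself is not refit: removing
#' one specimen from a GPA changes the consensus negligibly, and refitting it
#' would leave the held-out specimen in a different basis. This is a known,
#' documented approximation.
#'
#' @inheritParams train_lda
#' @return Fraction of labelled specimens correctly classified out-of-sample.
#' @export
loocv_accuracy <- function(x, groups, priors = "equal", var_retain = 0.99) {
  X <- tangent_matrix(x)
  groups <- as.character(groups)
  keep <- !is.na(groups)
  X <- X[keep, , drop = FALSE]
  lab <- groups[keep]
  if (any(table(lab) < 3)) stop("every group needs >= 3 specimens for LOO")
  hits <- logical(nrow(X))
  for (i in seq_len(nrow(X))) {
    model <- train_lda(X[-i, , drop = FALSE], lab[-i], priors, var_retain)
    pred <- suppressWarnings(classify(model, X[i, , drop = FALSE]))
    hits[i] <- as.character(pred$assigned) == lab[i]
  }
  mean(hits)
}

#' Frequency table of assignments by population
#'
#' Percentage of each query population assigned to each reference group; one
#' row per population, rows summing to 100. This is the layout of the
#' published identification tables (populations x reference subspecies).
#'
#' @param assigned factor of assigned reference groups, one per specimen.
#' @param populations vector of query population labels (apiary, province,
#'   altitudinal floor, ...), same length.
#' @return A matrix of percentages (rows: populations; columns: reference
#'   groups), with an `n` attribute holding per-population counts.
#' @export
frequency_report <- function(assigned, populations) {
  if (length(assigned) != length(populations))
    stop("assigned and populations must have the same length")
  if (any(is.na(populations))) stop("missing population labels")
  tab <- table(population = populations, assigned = assigned)
  n <- rowSums(tab)
  pct <- sweep(unclass(tab), 1, n, "/") * 100
  attr(pct, "n") <- n
  pct
}

#' Africanized/European morphotype frequencies by altitudinal floor
#'
#' Collapses reference-group assignments into an Africanized vs European
#' dichotomy and tabulates percentages per altitudinal floor (columns summing
#' to 100). "Africanized" means assignment to the *A. m. scutellata*-like
#' reference or, when a hybrid reference class was trained, to that class.
#'
#' @param assigned factor of assigned reference groups.
#' @param floors vector of altitudinal-floor labels (see [altitude_floor()]).
#' @param africanized_groups reference group names counted as Africanized.
#' @return A 2-row matrix (`Africanized`, `European`) of percentages by
#'   floor, with per-floor counts in attribute `n`.
#' @export
africanization_table <- function(assigned, floors,
                                 africanized_groups = c("scutellata", "AB")) {
  if (length(assigned) != length(floors))
    stop("assigned and floors must have the same length")
  keep <- !is.na(floors)
  if (!any(keep)) stop("no specimens with an altitudinal floor")
  status <- ifelse(as.character(assigned)[keep] %in% africanized_groups,
                   "Africanized", "European")
  fl <- droplevels(as.factor(floors[keep]))
  tab <- table(morphotype = factor(status, levels = c("Africanized", "European")),
               floor = fl)
  n <- colSums(tab)
  pct <- sweep(unclass(tab), 2, n, "/") * 100
  attr(pct, "n") <- n
  pct
}
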