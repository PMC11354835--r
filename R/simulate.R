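# Seeded generators producing study-shaped landmark datasets (highland
# apiary survey: 15 apiaries x 5 colonies x 10 wings plus 4 balanced
# pure-subspecies reference groups) and mutated sequence sets, so every
# pipeline stage is testable without external data.

# Orthonormal basis of the non-shape directions at a unit-size, centered
# shape m (flattened): x-translation, y-translation, scale, rotation.
nuisance_basis <- function(m) {
  k <- nrow(m)
  tx <- rep(c(1, 0), k) / sqrt(k)
  ty <- rep(c(0, 1), k) / sqrt(k)
  sc <- flatten_shape(m)                       # unit norm already
  rot <- flatten_shape(cbind(-m[, 2], m[, 1])) # 90-degree spin direction
  rot <- rot / sqrt(sum(rot^2))
  cbind(tx, ty, sc, rot)
}

# Project a flattened perturbation into the shape-tangent space at m.
project_tangent_noise <- function(v, m) {
  B <- nuisance_basis(m)
  v - B %*% crossprod(B, v)
}

#' Generate reference mean shapes
#'
#' Builds a non-degenerate ring-like base wing outline (unit centroid size)
#' and adds to it, per group, a random tangent-space offset of norm
#' `separation` (offsets are drawn orthogonal to the translation, scale and
#' rotation directions, so `separation` is approximately the Procrustes
#' distance of each group mean from the base shape). `separation = 0` gives
#' identical means.
#'
#' @param k number of landmarks (19 in a honey bee forewing analysis).
#' @param separation tangent-space offset norm per group mean.
#' @param n_groups number of reference groups.
#' @param names group names; defaults to the four pure subspecies used as
#'   identification references.
#' @param seed RNG seed.
#' @return Named list of `k x 2` centered, unit-size mean shapes.
#' @export
make_reference_means <- function(k = 19, separation = 0.08, n_groups = 4,
                                 names = NULL, seed = NULL) {
  if (k < 3) stop("k must be >= 3")
  if (separation < 0) stop("separation must be >= 0")
  if (is.null(names))
    names <- if (n_groups == 4)
      c("carnica", "ligustica", "mellifera", "scutellata")
    else paste0("ref", seq_len(n_groups))
  if (!is.null(seed)) set.seed(seed)
  th <- 2 * pi * (seq_len(k) - 1) / k
  r <- 1 + 0.15 * cos(2 * th) + 0.1 * sin(3 * th)
  base <- preshape(cbind(r * cos(th), r * sin(th)))
  means <- lapply(seq_len(n_groups), function(i) {
    off <- project_tangent_noise(stats::rnorm(2 * k), base)
    nrm <- sqrt(sum(off^2))
    if (separation > 0 && nrm > 0) off <- off * separation / nrm else off <- off * 0
    preshape(unflatten_shape(flatten_shape(base) + off, k))
  })
  stats::setNames(means, names[seq_len(n_groups)])
}

# Draw n specimen shapes around a mixture of reference means, with isotropic
# Gaussian tangent noise, and emit raw image-like coordinates (random
# rotation/translation, scaled to the target centroid size).
sample_shapes_raw <- function(n, means, weights, sigma_w, cs, nuisance = TRUE) {
  k <- nrow(means[[1]])
  if (length(weights) != length(means)) stop("one mixing weight per reference mean")
  if (abs(sum(weights) - 1) > 1e-8) stop("mixing weights must sum to 1")
  mu_flat <- Reduce(`+`, Map(function(m, w) w * flatten_shape(m), means, weights))
  mu <- preshape(unflatten_shape(mu_flat, k))
  coords <- array(NA_real_, dim = c(k, 2, n))
  for (s in seq_len(n)) {
    noise <- if (sigma_w > 0)
      project_tangent_noise(stats::rnorm(2 * k, sd = sigma_w), mu) else 0
    shp <- preshape(unflatten_shape(flatten_shape(mu) + noise, k))
    if (nuisance) {
      a <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
      shp <- shp %*% R
      shift <- stats::runif(2, 100, 1000)
    } else shift <- c(0, 0)
    coords[, , s] <- sweep(cs[s] * shp, 2, shift, "+")
  }
  coords
}

# Centroid sizes following the linear altitude model
# CS = mean_cs + beta1 (alt - mean(alt)) + eps, with beta1 calibrated against
# the realized altitude spread so the population correlation equals rho.
sample_sizes <- function(altitudes, mean_cs, sd_cs, rho) {
  n <- length(altitudes)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)")
  sa <- stats::sd(altitudes)
  beta1 <- if (is.na(sa) || sa == 0) 0 else rho * sd_cs / sa
  eps_sd <- sd_cs * sqrt(1 - rho^2)
  cs <- mean_cs + beta1 * (altitudes - mean(altitudes)) +
    stats::rnorm(n, sd = eps_sd)
  pmax(cs, mean_cs * 0.1)
}

#' Sample one synthetic population of wing configurations
#'
#' Each specimen's mean shape is the mixture `sum(weights * means)`; isotropic
#' Gaussian tangent noise of SD `sigma_w` is added and the shape is emitted in
#' raw image-like units (random rotation and translation, scaled to a
#' centroid size drawn from a linear altitude model calibrated to the target
#' correlation `rho`), so the analysis pipeline must genuinely undo the
#' nuisance transforms.
#'
#' @param name population name (used as apiary id and specimen prefix).
#' @param n number of specimens.
#' @param means named list of reference mean shapes
#'   ([make_reference_means()]).
#' @param weights mixing weights over `means`, summing to 1.
#' @param sigma_w within-population tangent noise SD (shape units; unit-size
#'   shapes).
#' @param altitude_range length-2 range (m.a.s.l.) from which specimen
#'   altitudes are drawn uniformly; `NULL` for no altitude (reference
#'   groups).
#' @param mean_cs,sd_cs centroid-size model (raw image units).
#' @param rho target altitude-size Pearson correlation.
#' @param colonies number of colonies the specimens are split into.
#' @param group_label reference group label (`NA` for study populations).
#' @param nuisance apply random rotation/translation/scale (default `TRUE`).
#' @param seed RNG seed.
#' @return A [wing_dataset] with filled metadata.
#' @export
sample_population <- function(name, n, means, weights, sigma_w = 0.01,
                              altitude_range = NULL, mean_cs = 400,
                              sd_cs = 20, rho = -0.32, colonies = 1,
                              group_label = NA_character_, nuisance = TRUE,
                              seed = NULL) {
  if (n < 1) stop("n must be positive")
  if (sigma_w < 0) stop("sigma_w must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(altitude_range)) {
    alt <- stats::runif(n, altitude_range[1], altitude_range[2])
    cs <- sample_sizes(alt, mean_cs, sd_cs, rho)
  } else {
    alt <- rep(NA_real_, n)
    cs <- stats::rnorm(n, mean_cs, sd_cs)
  }
  coords <- sample_shapes_raw(n, means, weights, sigma_w, cs, nuisance)
  ids <- sprintf("%s_%03d", name, seq_len(n))
  colony_of <- rep(seq_len(colonies), each = ceiling(n / colonies))[seq_len(n)]
  meta <- data.frame(specimen_id = ids, apiary = name,
                     colony = paste0(name, "_c", colony_of),
                     altitude_masl = alt, group_label = group_label,
                     population = name, stringsAsFactors = FALSE)
  wing_dataset(coords, ids, meta)
}

#' Combine wing datasets
#'
#' @param ... `wing_dataset` objects with equal `k`.
#' @return A single [wing_dataset].
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "wing_dataset"))
    parts <- parts[[1]]
  ks <- vapply(parts, function(p) p$k, 1L)
  if (length(unique(ks)) != 1) stop("datasets differ in landmark count")
  coords <- array(unlist(lapply(parts, `[[`, "coords")),
                  dim = c(ks[1], 2, sum(vapply(parts, function(p) p$n, 1L))))
  metas <- lapply(parts, `[[`, "meta")
  meta <- if (all(!vapply(metas, is.null, TRUE))) do.call(rbind, metas) else NULL
  wing_dataset(coords, unlist(lapply(parts, `[[`, "ids")), meta)
}

#' Simulate a study-shaped highland survey dataset
#'
#' Emulates the statistical structure of the field survey: 15 apiary
#' populations of 5 colonies x 10 wings (750 study specimens) spanning
#' 2600-3274 m.a.s.l. with a negative altitude-centroid-size correlation
#' (default target rho = -0.32), plus 4 balanced pure-subspecies reference
#' groups of 50 wings each. Study populations are one dominant hybrid
#' morphotype: a shape mixture leaning `lambda` (default 0.8) toward the
#' *A. m. scutellata*-like reference mean, the remainder spread equally over
#' the three European means, so they overlap the scutellata reference as the
#' survey's wings do. Optionally a small stingless-bee-like `placebo`
#' population far from all references is added as a clustering outgroup.
#'
#' @param seed RNG seed (the whole dataset is reproducible from it).
#' @param k landmarks per wing.
#' @param n_apiaries,colonies_per_apiary,wings_per_colony survey design.
#' @param n_ref reference specimens per subspecies.
#' @param separation tangent-space separation of the reference means.
#' @param sigma_w within-group tangent noise SD.
#' @param lambda hybrid mixing weight toward the scutellata-like mean.
#' @param rho target altitude-size correlation.
#' @param altitude_range overall altitude span (m.a.s.l.).
#' @param mean_cs,sd_cs centroid-size model (raw image units).
#' @param placebo add a `placebo` outgroup population (n = 10)?
#' @param nuisance apply random rotation/translation/scale to raw output.
#' @return A [wing_dataset]; the generating parameters are recorded in
#'   `attr(, "config")`.
#' @export
simulate_study <- function(seed = NULL, k = 19, n_apiaries = 15,
                           colonies_per_apiary = 5, wings_per_colony = 10,
                           n_ref = 50, separation = 0.08, sigma_w = 0.01,
                           lambda = 0.8, rho = -0.32,
                           altitude_range = c(2600, 3274),
                           mean_cs = 400, sd_cs = 20, placebo = FALSE,
                           nuisance = TRUE) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  means <- make_reference_means(k, separation)
  refs <- lapply(names(means), function(nm) {
    w <- as.numeric(names(means) == nm)
    sample_population(nm, n_ref, means, w, sigma_w, altitude_range = NULL,
                      mean_cs = mean_cs, sd_cs = sd_cs,
                      group_label = nm, nuisance = nuisance)
  })

  n_per <- colonies_per_apiary * wings_per_colony
  apiary_alt <- seq(altitude_range[1], altitude_range[2],
                    length.out = n_apiaries)
  w_study <- ifelse(names(means) == "scutellata", lambda,
                    (1 - lambda) / (length(means) - 1))
  study <- lapply(seq_len(n_apiaries), function(i) {
    nm <- paste0("A", i)
    d <- sample_population(nm, n_per, means, w_study, sigma_w,
                           altitude_range = NULL, mean_cs = mean_cs,
                           sd_cs = sd_cs, colonies = colonies_per_apiary,
                           nuisance = nuisance)
    d$meta$altitude_masl <- round(apiary_alt[i])
    d
  })

  # study-wide size model so the overall altitude-size correlation hits rho
  sim <- bind_datasets(c(refs, study))
  is_study <- grepl("^A[0-9]+$", sim$meta$population)
  alt <- sim$meta$altitude_masl[is_study]
  cs_target <- sample_sizes(alt, mean_cs, sd_cs, rho)
  idx <- which(is_study)
  for (j in seq_along(idx)) {
    s <- idx[j]
    old_cs <- centroid_size(sim$coords[, , s])
    ctr <- colMeans(sim$coords[, , s])
    sim$coords[, , s] <- sweep(sweep(sim$coords[, , s], 2, ctr) *
                                 cs_target[j] / old_cs, 2, ctr, "+")
  }

  if (placebo) {
    pl_mean <- list(placebo = preshape(unflatten_shape(
      flatten_shape(means[[1]]) +
        project_tangent_noise(stats::rnorm(2 * k, sd = 1), means[[1]]) *
        (5 * max(separation, 0.02)), k)))
    pl <- sample_population("placebo", 10, pl_mean, 1, sigma_w,
                            altitude_range = NULL, mean_cs = mean_cs,
                            sd_cs = sd_cs, nuisance = nuisance)
    sim <- bind_datasets(list(sim, pl))
  }

  attr(sim, "config") <- list(seed = seed, k = k, n_apiaries = n_apiaries,
                              colonies_per_apiary = colonies_per_apiary,
                              wings_per_colony = wings_per_colony,
                              n_ref = n_ref, separation = separation,
                              sigma_w = sigma_w, lambda = lambda, rho = rho,
                              altitude_range = altitude_range,
                              mean_cs = mean_cs, sd_cs = sd_cs,
                              placebo = placebo, nuisance = nuisance)
  sim
}

#' Write a simulated dataset to disk
#'
#' Emits `wings.tps` (landmarks), `metadata.csv` (specimen metadata) and,
#' when the dataset carries a generator config, `config.yml` as a provenance
#' sidecar.
#'
#' @param x a [wing_dataset].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
save_simulation <- function(x, dir) {
  stopifnot(inherits(x, "wing_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tps <- file.path(dir, "wings.tps")
  csv <- file.path(dir, "metadata.csv")
  write_tps(x, tps)
  utils::write.csv(x$meta, csv, row.names = FALSE)
  paths <- c(tps, csv)
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    yml <- file.path(dir, "config.yml")
    yaml::write_yaml(cfg, yml)
    paths <- c(paths, yml)
  }
  invisible(paths)
}

#' Generate a synthetic haplotype reference panel
#'
#' Draws a random ancestral sequence and derives each haplotype by i.i.d.
#' substitutions at rate `divergence`, giving a panel of mutually divergent
#' references for exercising the assignment stage.
#'
#' @param n number of haplotypes.
#' @param length sequence length in bases (amplicons of the tRNALeu-COII
#'   region run roughly 400-740 bp).
#' @param divergence per-base substitution rate from the ancestor.
#' @param haplotypes,lineages names and lineage codes (defaults: bee-style
#'   A/C/M lineage labels).
#' @param seed RNG seed.
#' @return A [haplotype_panel] (synthetic; not real bee haplotypes).
#' @export
make_haplotype_panel <- function(n = 5, length = 500, divergence = 0.05,
                                 haplotypes = NULL, lineages = NULL,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(haplotypes))
    haplotypes <- c("A1", "A4", "A26", "C1", "M3", paste0("H", seq_len(max(0, n - 5))))[seq_len(n)]
  if (is.null(lineages))
    lineages <- substr(haplotypes, 1, 1)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    mut <- stats::runif(length) < divergence
    s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1), "")
    paste(s, collapse = "")
  }, "")
  haplotype_panel(stats::setNames(seqs, haplotypes), haplotypes, lineages)
}

#' Mutate panel sequences into synthetic queries
#'
#' Applies i.i.d. substitutions at the given per-base rate to each panel
#' sequence, `n_per` replicate queries per haplotype, keeping the true source
#' haplotype for recovery scoring.
#'
#' @param panel a [haplotype_panel] (or named character vector of sequences).
#' @param rate per-base substitution rate in `[0, 0.2]`.
#' @param n_per queries per source sequence.
#' @param seed RNG seed.
#' @return Data frame with columns `query_id`, `true_haplotype`, `seq`.
#' @export
mutate_sequences <- function(panel, rate, n_per = 1, seed = NULL) {
  if (rate < 0 || rate > 0.2) stop("rate must lie in [0, 0.2]")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(panel, "haplotype_panel")) {
    seqs <- stats::setNames(panel$seq, panel$haplotype)
  } else seqs <- panel
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (h in names(seqs)) {
    sv <- strsplit(seqs[[h]], "")[[1]]
    for (r in seq_len(n_per)) {
      s <- sv
      mut <- stats::runif(length(s)) < rate
      if (any(mut))
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1), "")
      rows[[length(rows) + 1]] <- data.frame(
        query_id = paste0(h, "_q", r), true_haplotype = h,
        seq = paste(s, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
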