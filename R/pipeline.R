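stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

write_output_csv <- function(x, path, hash, row_label = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# wingmorph config=", hash), con)
  if (is.matrix(x)) {
    x <- as.data.frame(x)
    if (!is.null(row_label)) x <- cbind(stats::setNames(
      data.frame(rownames(x), stringsAsFactors = FALSE), row_label), x)
  }
  utils::write.csv(x, con, row.names = FALSE)
  path
}

#' Run the full identification pipeline
#'
#' Chains the analysis end to end: read landmarks and metadata, generalized
#' Procrustes superimposition, exploratory PCA, CVA per grouping (all study
#' apiaries; altitudinal floors; pure-subspecies references vs study), the
#' centroid size ~ altitude correlation, discriminant classification of the
#' study specimens against the reference groups with resubstitution and
#' leave-one-out accuracy, frequency and Africanization tables, the pooled
#' Mahalanobis distance matrix over all populations, and a UPGMA tree written
#' as Newick. Reference specimens are the rows with a non-missing
#' `group_label`; rows with population `"placebo"` join the ordination and
#' the tree but are excluded from classification. All CSV outputs start with
#' a comment line carrying the config hash; given the same inputs and seed
#' the outputs are byte-identical.
#'
#' @param tps path to a TPS landmark file, or a [wing_dataset].
#' @param metadata path to the metadata CSV (or data frame); ignored when
#'   `tps` is a dataset that already carries metadata.
#' @param out_dir output directory; `NULL` to skip writing files.
#' @param var_retain subspace reduction fraction for CVA/DFA.
#' @param n_perm permutations for pairwise tests in the subspecies CVA
#'   (0 = skip).
#' @param seed RNG seed, recorded in the run log and used for permutations.
#' @param priors discriminant priors, `"equal"` or `"proportional"`.
#' @param scale_policy TPS scale handling, see [read_tps()].
#' @param loocv compute leave-one-out accuracy of the reference discriminant
#'   (the slowest step; `TRUE` by default).
#' @return Invisibly, a list with components `gpa`, `pca`, `cva_apiary`,
#'   `cva_floor`, `cva_subspecies`, `size_correlation`, `model`,
#'   `classification`, `accuracy` (resubstitution + LOO), `frequency`
#'   (per-apiary table), `floor_table`, `D` (population Mahalanobis matrix),
#'   `tree`, `newick`, `config`, `hash` and `files`.
#' @export
run_pipeline <- function(tps, metadata = NULL, out_dir = NULL,
                         var_retain = 0.99, n_perm = 0, seed = NULL,
                         priors = "equal", scale_policy = "apply",
                         loocv = TRUE) {
  config <- list(tps = if (is.character(tps)) tps else "<in-memory dataset>",
                 metadata = if (is.character(metadata)) metadata else NULL,
                 var_retain = var_retain, n_perm = n_perm, seed = seed,
                 priors = priors, scale_policy = scale_policy)
  hash <- config_hash(config)
  t0 <- Sys.time()
  log_lines <- c(paste0("wingmorph ", as.character(utils::packageVersion("wingmorph")),
                        " pipeline run"),
                 paste0("config hash: ", hash),
                 paste0("seed: ", if (is.null(seed)) "none" else seed))

  ds <- stage("read", {
    d <- if (inherits(tps, "wing_dataset")) tps else read_tps(tps, scale_policy)
    if (!is.null(metadata)) d <- attach_metadata(d, metadata)
    if (is.null(d$meta)) stop("specimen metadata are required")
    d
  })
  meta <- ds$meta
  if (is.null(meta$population))
    meta$population <- ifelse(is.na(meta$group_label), meta$apiary,
                              meta$group_label)
  is_ref <- !is.na(meta$group_label)
  is_placebo <- meta$population == "placebo"
  is_query <- !is_ref & !is_placebo

  gpa <- stage("gpa", gpa_align(ds))
  pca <- stage("pca", shape_pca(gpa$tangent[is_query, , drop = FALSE]))

  cva_apiary <- stage("cva_apiary", {
    grp <- meta$apiary[is_query]
    if (length(unique(grp)) >= 2)
      cva(gpa$tangent[is_query, , drop = FALSE], grp, var_retain) else NULL
  })

  floors <- stage("altitude", {
    if (is.null(meta$altitude_masl)) stop("metadata lack altitude_masl")
    altitude_floor(meta$altitude_masl)
  })
  cva_floor <- stage("cva_floor", {
    grp <- floors[is_query]
    if (nlevels(droplevels(grp[!is.na(grp)])) >= 2)
      cva(gpa$tangent[is_query & !is.na(floors), , drop = FALSE],
          droplevels(grp[!is.na(grp)]), var_retain) else NULL
  })
  size_cor <- stage("size_correlation", {
    ok <- is_query & !is.na(meta$altitude_masl)
    if (sum(ok) >= 3)
      size_covariate_correlation(gpa$centroid_sizes[ok],
                                 meta$altitude_masl[ok]) else NULL
  })

  cva_sub <- stage("cva_subspecies", {
    grp <- ifelse(is_ref, meta$group_label, "study")
    cva(gpa$tangent[!is_placebo, , drop = FALSE], grp[!is_placebo],
        var_retain, n_perm = n_perm, seed = seed)
  })

  model <- stage("train_dfa", {
    lab <- ifelse(is_ref, meta$group_label, NA)
    train_lda(gpa, lab, priors = priors, var_retain = var_retain)
  })
  cls_ref <- stage("classify_reference",
                   classify(model, gpa$tangent[is_ref, , drop = FALSE],
                            truth = meta$group_label[is_ref]))
  cls_query <- stage("classify_query",
                     classify(model, gpa$tangent[is_query, , drop = FALSE]))
  accuracy <- stage("accuracy", {
    lab <- ifelse(is_ref, meta$group_label, NA)
    list(resubstitution = cls_ref$accuracy,
         loocv = if (loocv) loocv_accuracy(gpa$tangent, lab, priors,
                                           var_retain) else NA_real_)
  })

  freq <- stage("frequency_tables", {
    combined <- rbind(
      frequency_report(cls_ref$assigned, meta$group_label[is_ref]),
      frequency_report(cls_query$assigned,
                       rep("AB", sum(is_query))))
    per_apiary <- frequency_report(cls_query$assigned, meta$apiary[is_query])
    list(combined = combined, per_apiary = per_apiary)
  })
  floor_table <- stage("floor_table", {
    fl <- floors[is_query]
    if (all(is.na(fl))) NULL else
      africanization_table(cls_query$assigned, fl,
                           africanized_groups = c("scutellata", "AB"))
  })

  tree_res <- stage("upgma", {
    grp <- meta$population
    cv_all <- cva(gpa$tangent, grp, var_retain)
    tr <- upgma(cv_all$D)
    list(D = cv_all$D, tree = tr, newick = to_newick(tr))
  })

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(out_dir, name)
    files <- c(
      write_output_csv(as.data.frame(gpa), out("aligned_tangent.csv"), hash),
      write_output_csv(cbind(specimen_id = rownames(pca$scores),
                             as.data.frame(pca$scores[, 1:min(10, ncol(pca$scores))])),
                       out("pca_scores.csv"), hash),
      write_output_csv(cva_sub$scores, out("cva_subspecies_scores.csv"), hash,
                       row_label = "specimen_id"),
      write_output_csv(cva_sub$D, out("mahalanobis_D_subspecies.csv"), hash,
                       row_label = "group"),
      write_output_csv(unclass(cls_ref$confusion),
                       out("confusion_reference.csv"), hash,
                       row_label = "known"),
      write_output_csv(freq$combined, out("frequency_table.csv"), hash,
                       row_label = "population"),
      write_output_csv(freq$per_apiary, out("frequency_by_apiary.csv"), hash,
                       row_label = "apiary"),
      write_output_csv(tree_res$D, out("mahalanobis_D_populations.csv"), hash,
                       row_label = "population"))
    if (!is.null(floor_table))
      files <- c(files, write_output_csv(floor_table, out("floor_table.csv"),
                                         hash, row_label = "morphotype"))
    writeLines(tree_res$newick, out("upgma.nwk"))
    files <- c(files, out("upgma.nwk"))
    log_lines <- c(log_lines,
                   paste0("specimens: ", ds$n, " (", sum(is_ref), " reference, ",
                          sum(is_query), " query, ", sum(is_placebo), " placebo)"),
                   paste0("gpa iterations: ", gpa$iterations),
                   paste0("elapsed: ",
                          format(difftime(Sys.time(), t0, units = "secs"))),
                   paste0("outputs: ", paste(basename(files), collapse = ", ")))
    writeLines(log_lines, out("run_log.txt"))
    files <- c(files, out("run_log.txt"))
  }

  invisible(list(gpa = gpa, pca = pca, cva_apiary = cva_apiary,
                 cva_floor = cva_floor, cva_subspecies = cva_sub,
                 size_correlation = size_cor, model = model,
                 classification = list(reference = cls_ref, query = cls_query),
                 accuracy = accuracy, frequency = freq,
                 floor_table = floor_table, D = tree_res$D,
                 tree = tree_res$tree, newick = tree_res$newick,
                 config = config, hash = hash, files = files))
}
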