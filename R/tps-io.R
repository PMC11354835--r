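#' Landmark dataset container
#'
#' A `wing_dataset` bundles the raw landmark configurations of a set of
#' specimens with their identifiers and a specimen metadata table. Coordinates
#' are stored exactly as digitized (image units, origin bottom-left as emitted
#' by tpsDig2); no axis flipping is performed, so all specimens are assumed to
#' be digitized on the same wing side.
#'
#' @param coords numeric array of dimension `k x 2 x n` (landmarks, x/y,
#'   specimens), or a list of `n` `k x 2` matrices.
#' @param ids character vector of `n` unique specimen identifiers.
#' @param meta optional data frame of specimen metadata with a `specimen_id`
#'   column (typical columns: `apiary`, `colony`, `altitude_masl`,
#'   `group_label`, `population`).
#' @return An object of class `wing_dataset` with elements `coords`, `ids`,
#'   `k`, `n` and `meta`.
#' @export
wing_dataset <- function(coords, ids, meta = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- unique(vapply(coords, nrow, 1L))
    if (length(k) != 1L)
      stop("all configurations must share the same landmark count k")
    coords <- array(unlist(coords), dim = c(k, 2L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("coords must be a k x 2 x n array")
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal the number of specimens")
  if (anyDuplicated(ids))
    stop("duplicate specimen ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (k < 3L) stop("at least 3 landmarks are required (k >= 3)")
  if (!all(is.finite(coords))) stop("all landmark coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y"), ids)
  if (!is.null(meta)) meta <- validate_meta(meta, ids)
  structure(list(coords = coords, ids = ids, k = k, n = n, meta = meta),
            class = "wing_dataset")
}

validate_meta <- function(meta, ids) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"specimen_id" %in% names(meta))
    stop("metadata must have a 'specimen_id' column")
  meta$specimen_id <- as.character(meta$specimen_id)
  missing <- setdiff(ids, meta$specimen_id)
  if (length(missing) > 0) {
    warning(length(missing), " specimen(s) missing from metadata table; ",
            "empty metadata attached (e.g. ", missing[1], ")")
    pad <- meta[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad$specimen_id <- missing
    meta <- rbind(meta, pad)
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  if ("altitude_masl" %in% names(meta)) {
    alt <- meta$altitude_masl
    if (any(!is.na(alt) & alt <= 0))
      stop("altitude_masl must be positive where present")
  }
  meta
}

#' @export
print.wing_dataset <- function(x, ...) {
  cat("wing_dataset:", x$n, "specimens,", x$k, "landmarks\n")
  if (!is.null(x$meta)) {
    grp <- x$meta$group_label
    if (!is.null(grp) && any(!is.na(grp)))
      cat("  reference groups:", paste(sort(unique(stats::na.omit(grp))), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a wing_dataset by specimen
#'
#' @param x a `wing_dataset`.
#' @param i index vector (integer, logical, or specimen ids).
#' @param ... ignored.
#' @export
`[.wing_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  wing_dataset(x$coords[, , i, drop = FALSE], x$ids[i],
               if (!is.null(x$meta)) x$meta[i, , drop = FALSE])
}

#' Read a TPS landmark file
#'
#' Parses the plain-text TPS dialect written by tpsDig2/tpsUtil: records start
#' with `LM=<k>`, followed by `k` lines of "x y" coordinates, then optional
#' `ID=`, `IMAGE=` and `SCALE=` keyword lines. Unknown keywords are skipped
#' with a warning. `ID=` provides the specimen id; when absent the `IMAGE=`
#' basename (extension stripped) is used.
#'
#' @param path TPS file path.
#' @param scale_policy `"apply"` (default) multiplies coordinates by the
#'   record's `SCALE=` factor so centroid sizes are comparable across images;
#'   `"ignore"` leaves coordinates in pixel units.
#' @return A [wing_dataset].
#' @export
read_tps <- function(path, scale_policy = c("apply", "ignore")) {
  scale_policy <- match.arg(scale_policy)
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  configs <- list(); ids <- character(); unknown <- character()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", ln, ignore.case = TRUE))
      stop("expected LM= header at line ", i, ", found: ", ln)
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 1L)
      stop("malformed LM= header at line ", i, ": ", ln)
    rec <- rec + 1L
    coords <- matrix(NA_real_, k, 2)
    for (j in seq_len(k)) {
      i <- i + 1L
      if (i > length(lines))
        stop("record ", rec, ": file ends before ", k, " coordinate lines")
      xy <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (length(xy) != 2L || any(is.na(xy)))
        stop("record ", rec, ": malformed coordinate at line ", i, ": ", lines[i])
      coords[j, ] <- xy
    }
    id <- NA_character_; image <- NA_character_; scl <- NA_real_
    i <- i + 1L
    while (i <= length(lines) && !grepl("^\\s*LM\\s*=", lines[i], ignore.case = TRUE)) {
      ln <- trimws(lines[i])
      if (ln == "") { i <- i + 1L; next }
      if (grepl("^ID\\s*=", ln, ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE\\s*=", ln, ignore.case = TRUE)) {
        image <- sub("^IMAGE\\s*=\\s*", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", ln, ignore.case = TRUE)) {
        scl <- suppressWarnings(as.numeric(sub("^SCALE\\s*=\\s*", "", ln, ignore.case = TRUE)))
      } else if (grepl("^[A-Za-z]+\\s*=", ln)) {
        unknown <- c(unknown, sub("\\s*=.*$", "", ln))
      } else {
        stop("record ", rec, ": unexpected line ", i, ": ", ln)
      }
      i <- i + 1L
    }
    if (is.na(id)) {
      if (!is.na(image)) {
        id <- sub("\\.[A-Za-z0-9]+$", "", basename(gsub("\\\\", "/", image)))
      } else {
        id <- paste0("specimen_", rec)
      }
    }
    if (!is.na(scl) && scale_policy == "apply") coords <- coords * scl
    configs[[rec]] <- coords
    ids[rec] <- id
  }
  if (rec == 0L) stop("no TPS records found in ", path)
  if (length(unknown) > 0)
    warning("ignored unknown TPS keyword(s): ", paste(unique(unknown), collapse = ", "))
  ks <- vapply(configs, nrow, 1L)
  if (length(unique(ks)) != 1L)
    stop("inconsistent landmark counts across records: ", paste(unique(ks), collapse = ", "))
  wing_dataset(configs, ids)
}

#' Write a wing_dataset to a TPS file
#'
#' Emits one record per specimen: `LM=`, the coordinate lines (6 significant
#' digits) and `ID=`. Output is re-readable by [read_tps()].
#'
#' @param x a [wing_dataset].
#' @param path output file path.
#' @export
write_tps <- function(x, path) {
  stopifnot(inherits(x, "wing_dataset"))
  if (x$n < 1L) stop("cannot write an empty dataset")
  out <- character()
  for (s in seq_len(x$n)) {
    m <- x$coords[, , s]
    out <- c(out, paste0("LM=", x$k),
             paste(format(signif(m[, 1], 6), digits = 6, trim = TRUE),
                   format(signif(m[, 2], 6), digits = 6, trim = TRUE)),
             paste0("ID=", x$ids[s]))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("failed to write TPS file ", path, ": ",
                                          conditionMessage(e)))
  invisible(ok)
}

#' Attach a specimen metadata table
#'
#' Joins a delimited metadata table (or data frame) to a dataset by
#' `specimen_id`. Specimens absent from the table receive empty metadata with
#' a warning. Expected columns: `specimen_id`, `apiary`, `colony`,
#' `altitude_masl`, `group_label`.
#'
#' @param x a [wing_dataset].
#' @param table a CSV file path or a data frame with a `specimen_id` column.
#' @return The dataset with `meta` filled.
#' @export
attach_metadata <- function(x, table) {
  stopifnot(inherits(x, "wing_dataset"))
  if (is.character(table)) {
    if (!file.exists(table)) stop("metadata file not found: ", table)
    table <- utils::read.csv(table, stringsAsFactors = FALSE, comment.char = "#")
  }
  if (!"specimen_id" %in% names(table))
    stop("metadata table must have a 'specimen_id' column")
  x$meta <- validate_meta(table, x$ids)
  x
}

#' Altitudinal floor of an altitude
#'
#' Assigns altitudes (m above sea level) to the survey's three closed
#' altitudinal bands: 2600-2800, 2801-3000 and 3001-3274 m.a.s.l. Altitudes
#' are rounded to the nearest integer before banding, so the bands tile
#' \[2600, 3274\] exactly. Out-of-range altitudes map to `NA` with a warning.
#'
#' @param altitude numeric vector of altitudes in m.a.s.l.
#' @return A factor with levels `"2600-2800"`, `"2801-3000"`, `"3001-3274"`.
#' @export
altitude_floor <- function(altitude) {
  a <- round(altitude)
  f <- rep(NA_character_, length(a))
  f[!is.na(a) & a >= 2600 & a <= 2800] <- "2600-2800"
  f[!is.na(a) & a >= 2801 & a <= 3000] <- "2801-3000"
  f[!is.na(a) & a >= 3001 & a <= 3274] <- "3001-3274"
  out_of_range <- !is.na(a) & is.na(f)
  if (any(out_of_range))
    warning(sum(out_of_range), " altitude(s) outside [2600, 3274] m.a.s.l.; no floor assigned")
  factor(f, levels = c("2600-2800", "2801-3000", "3001-3274"))
}
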