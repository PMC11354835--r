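# Mitochondrial companion to the wing morphometrics: percent identity of
# tRNALeu-COII amplicon sequences against a local reference haplotype panel,
# and best-hit haplotype/lineage assignment.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case DNA sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

check_dna <- function(s, what = "sequence") {
  s <- toupper(as.character(s))
  if (length(s) != 1 || is.na(s) || nchar(s) == 0) stop("empty ", what)
  if (grepl("[^ACGTUNRYSWKMBDHV]", s))
    stop(what, " contains non-IUPAC characters")
  s
}

# Needleman-Wunsch with linear gap penalty. Among score-optimal alignments
# the one maximizing matches, then aligned (diagonal) pairs, is selected by
# folding both counters into the DP score with dominance weights; this makes
# the reported identity well defined and symmetric in the two sequences
# (the tie-resolution weights assume score parameters of magnitude <= ~10,
# as with the default integer scoring). The score matrix is filled one
# a-base at a time; the within-row dependency of the gap move is resolved
# with a running-maximum reformulation (valid because the gap penalty is
# linear), so each step is a vectorized operation.
nw_align <- function(a, b, match = 1, mismatch = 0, gap = -1,
                     n_policy = c("mismatch", "literal")) {
  n_policy <- match.arg(n_policy)
  if (gap > 0) stop("gap penalty must be <= 0")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  ai <- utf8ToInt(a); bi <- utf8ToInt(b)
  eq <- outer(bi, ai, "==")                 # nb x na, one column per a-base
  if (n_policy == "mismatch") {
    eq[bv == "N", ] <- FALSE
    eq[, av == "N"] <- FALSE
  }
  # dominance weights: score >> matches >> diagonal pairs
  L <- na + nb + 1
  wM <- 4 * L
  wS <- 16 * L * L
  score_params <- c(match = match, mismatch = mismatch, gap = gap)
  subT <- wS * (mismatch + (match - mismatch) * eq) + wM * eq + 1
  gap <- wS * gap
  tol <- 1e-9 * wS

  # H stored transposed (column i+1 = DP row for a-prefix of length i) so the
  # inner loop touches contiguous memory.
  H <- matrix(0, nb + 1L, na + 1L)
  H[, 1L] <- gap * (0:nb)
  H[1L, ] <- gap * (0:na)
  jn <- seq_len(nb)
  gj <- gap * (0:nb)
  for (i in seq_len(na)) {
    prev <- H[, i]
    cand <- prev[jn] + subT[, i]            # diagonal move
    up <- prev[jn + 1L] + gap
    w <- up > cand
    cand[w] <- up[w]
    # left moves in closed form:
    # H[j] = max_{j' <= j} c[j'] + gap * (j - j'), with c[0] the row start
    H[, i + 1L] <- gj + cummax(c(gap * i, cand) - gj)
  }

  # traceback, tie preference diagonal > up > left
  i <- na; j <- nb
  al_a <- character(na + nb); al_b <- character(na + nb)
  matches <- 0L; diag_n <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L &&
        abs(H[j + 1L, i + 1L] - (H[j, i] + subT[j, i])) < tol) {
      al_a[cols] <- av[i]; al_b[cols] <- bv[j]
      if (eq[j, i]) matches <- matches + 1L
      diag_n <- diag_n + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(H[j + 1L, i + 1L] - (H[j + 1L, i] + gap)) < tol) {
      al_a[cols] <- av[i]; al_b[cols] <- "-"
      i <- i - 1L
    } else {
      al_a[cols] <- "-"; al_b[cols] <- bv[j]
      j <- j - 1L
    }
  }
  keep <- cols:1
  score <- matches * score_params[["match"]] +
    (diag_n - matches) * score_params[["mismatch"]] +
    (cols - diag_n) * score_params[["gap"]]
  list(score = score,
       aligned_a = paste(al_a[keep], collapse = ""),
       aligned_b = paste(al_b[keep], collapse = ""),
       matches = matches, columns = cols,
       identity = 100 * matches / cols)
}

#' Global-alignment percent identity of two DNA sequences
#'
#' Needleman-Wunsch global alignment with linear gap penalty (defaults:
#' match 1, mismatch 0, gap -1) and deterministic traceback (tie preference
#' diagonal > up > left; among score-optimal alignments the one maximizing
#' matches, then aligned pairs, is reported, which makes the identity value
#' well defined and symmetric in the two sequences). Identity is
#' `100 * matches / aligned columns`,
#' where gapped columns count in the denominator (global identity). `N`
#' matches nothing by default — it scores as a mismatch even against `N` —
#' a conservative convention switchable with `n_policy = "literal"`.
#'
#' @param a,b DNA sequences (character strings, IUPAC alphabet).
#' @param match,mismatch,gap alignment scores; `gap` must be <= 0.
#' @param n_policy `"mismatch"` (default) or `"literal"`.
#' @return Percent identity in `[0, 100]`.
#' @seealso [global_alignment()] for the full alignment.
#' @export
global_align_identity <- function(a, b, match = 1, mismatch = 0, gap = -1,
                                  n_policy = "mismatch") {
  global_alignment(a, b, match, mismatch, gap, n_policy)$identity
}

#' Global alignment of two DNA sequences
#'
#' @inheritParams global_align_identity
#' @return A list with `score`, `aligned_a`, `aligned_b`, `matches`,
#'   `columns` and `identity` (percent).
#' @export
global_alignment <- function(a, b, match = 1, mismatch = 0, gap = -1,
                             n_policy = "mismatch") {
  a <- check_dna(a, "sequence a"); b <- check_dna(b, "sequence b")
  nw_align(a, b, match, mismatch, gap, n_policy)
}

#' Build a haplotype reference panel
#'
#' @param seqs named character vector of panel sequences (names are sequence
#'   ids), or a FASTA path.
#' @param haplotype character vector of haplotype names, one per sequence.
#' @param lineage character vector of lineage codes (A / M / C), one per
#'   sequence.
#' @return A data frame of class `haplotype_panel` with columns `id`,
#'   `haplotype`, `lineage`, `seq`.
#' @export
haplotype_panel <- function(seqs, haplotype, lineage) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- read_fasta(seqs)
  if (length(haplotype) != length(seqs) || length(lineage) != length(seqs))
    stop("haplotype and lineage must have one entry per sequence")
  seqs <- vapply(seqs, check_dna, "", what = "panel sequence")
  out <- data.frame(id = if (is.null(names(seqs))) haplotype else names(seqs),
                    haplotype = as.character(haplotype),
                    lineage = as.character(lineage),
                    seq = unname(seqs), stringsAsFactors = FALSE)
  class(out) <- c("haplotype_panel", "data.frame")
  out
}

#' Read a haplotype panel from FASTA plus a metadata table
#'
#' The metadata CSV must have columns `id`, `haplotype`, `lineage`; rows are
#' matched to FASTA records by `id`.
#'
#' @param fasta FASTA path of panel sequences.
#' @param metadata CSV path or data frame.
#' @return A `haplotype_panel`.
#' @export
read_haplotype_panel <- function(fasta, metadata) {
  seqs <- read_fasta(fasta)
  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  need <- c("id", "haplotype", "lineage")
  if (!all(need %in% names(metadata)))
    stop("panel metadata needs columns: ", paste(need, collapse = ", "))
  miss <- setdiff(names(seqs), metadata$id)
  if (length(miss) > 0)
    stop("panel sequences missing from metadata: ", paste(miss, collapse = ", "))
  m <- metadata[match(names(seqs), metadata$id), ]
  haplotype_panel(seqs, m$haplotype, m$lineage)
}

#' Assign a query sequence to its best-matching haplotype
#'
#' Computes global-alignment percent identity of the query against every
#' panel sequence and reports the best hit, its lineage, the runner-up and
#' the identity margin. Exact identity ties are broken toward the
#' lexicographically first haplotype name; a margin below
#' `ambiguity_margin` percentage points triggers an ambiguity warning.
#'
#' @param query a DNA sequence string, optionally named (the name becomes
#'   `query_id`).
#' @param panel a [haplotype_panel].
#' @param ambiguity_margin margin (percentage points) below which the
#'   assignment is flagged ambiguous.
#' @param ... passed to [global_align_identity()].
#' @return One-row data frame: `query_id`, `best_haplotype`, `lineage`,
#'   `identity_pct`, `runner_up`, `runner_up_identity`, `margin`.
#' @export
assign_haplotype <- function(query, panel, ambiguity_margin = 0.5, ...) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (nrow(panel) < 1) stop("empty haplotype panel")
  qid <- if (!is.null(names(query))) names(query)[1] else "query"
  q <- check_dna(query, "query sequence")
  ident <- vapply(panel$seq, function(s) global_align_identity(q, s, ...),
                  numeric(1))
  ord <- order(-ident, panel$haplotype)
  best <- ord[1]
  runner <- if (nrow(panel) >= 2) ord[2] else NA_integer_
  margin <- if (is.na(runner)) NA_real_ else ident[best] - ident[runner]
  if (!is.na(margin) && margin < ambiguity_margin)
    warning("ambiguous assignment for ", qid, ": margin ",
            format(margin, digits = 3), " < ", ambiguity_margin,
            " percentage points")
  data.frame(query_id = qid,
             best_haplotype = panel$haplotype[best],
             lineage = panel$lineage[best],
             identity_pct = unname(ident[best]),
             runner_up = if (is.na(runner)) NA_character_ else panel$haplotype[runner],
             runner_up_identity = if (is.na(runner)) NA_real_ else unname(ident[runner]),
             margin = margin, stringsAsFactors = FALSE)
}

#' Assign many query sequences to haplotypes
#'
#' @param queries named character vector of query sequences, or a FASTA path.
#' @param panel a [haplotype_panel].
#' @param ... passed to [assign_haplotype()].
#' @return Data frame with one row per query (see [assign_haplotype()]).
#' @export
assign_haplotypes <- function(queries, panel, ...) {
  if (is.character(queries) && length(queries) == 1 && file.exists(queries))
    queries <- read_fasta(queries)
  if (is.null(names(queries)))
    names(queries) <- paste0("query_", seq_along(queries))
  out <- do.call(rbind, lapply(names(queries), function(id)
    assign_haplotype(stats::setNames(queries[id], id), panel, ...)))
  rownames(out) <- NULL
  out
}
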