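test_that("percent identity follows the gap-inclusive global convention", {
  # self-identity on the forward amplification primer
  expect_equal(global_align_identity("GGCAGAATAAGTGCATTG", "GGCAGAATAAGTGCATTG"), 100)
  # one substitution over four columns
  expect_equal(global_align_identity("ACGT", "ACGA"), 75)
  # a deletion costs a gapped column in the denominator
  expect_equal(global_align_identity("ACGT", "ACT"), 75)
  al <- global_alignment("ACGT", "ACT")
  expect_equal(al$columns, 4)
  expect_equal(al$matches, 3)
  expect_equal(al$score, 3 - 1)
  expect_error(global_alignment("", "ACGT"), "empty")
  expect_error(global_alignment("AXGT", "ACGT"), "non-IUPAC")
})

test_that("N matches nothing by default but can be literal", {
  expect_equal(global_align_identity("ANA", "ANA"), 100 * 2 / 3)
  expect_equal(global_align_identity("ANA", "ANA", n_policy = "literal"), 100)
  expect_equal(global_align_identity("AAA", "ANA"), 100 * 2 / 3)
})

test_that("identity is symmetric and equals 100 on self", {
  set.seed(61)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
    expect_equal(global_align_identity(a, b), global_align_identity(b, a))
    expect_equal(global_align_identity(a, a), 100)
  }
})

test_that("alignment scores match the Biostrings dynamic-programming oracle", {
  set.seed(62)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  for (rep in 1:8) {
    la <- sample(30:80, 1); lb <- sample(30:80, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    expect_equal(global_alignment(a, b)$score, Biostrings::score(ref))
  }
})

test_that("best-hit assignment recovers mutated panel members", {
  panel <- make_haplotype_panel(5, 300, divergence = 0.06, seed = 63)
  expect_s3_class(panel, "haplotype_panel")
  # query identical to a panel member
  q <- setNames(panel$seq[3], "q1")
  res <- assign_haplotype(q, panel)
  expect_equal(res$best_haplotype, panel$haplotype[3])
  expect_equal(res$identity_pct, 100)
  expect_equal(res$lineage, panel$lineage[3])
  expect_gte(res$identity_pct, res$runner_up_identity)
  # 3% mutated copies come back with identity near 97
  qs <- mutate_sequences(panel, rate = 0.03, n_per = 4, seed = 64)
  out <- assign_haplotypes(setNames(qs$seq, qs$query_id), panel)
  expect_equal(out$best_haplotype, qs$true_haplotype)
  expect_equal(mean(out$identity_pct), 97, tolerance = 0.02)
})

test_that("ties go to the lexicographically first haplotype with a warning", {
  panel <- haplotype_panel(c(h2 = "AAAATTTT", h1 = "TTTTAAAA"),
                           haplotype = c("B9", "A9"), lineage = c("C", "A"))
  expect_warning(assign_haplotype(c(q = "AAAAAAAA"), panel), "ambiguous")
  res <- suppressWarnings(assign_haplotype(c(q = "AAAAAAAA"), panel))
  expect_equal(res$best_haplotype, "A9")
  expect_equal(res$margin, 0)
})

test_that("assignment is invariant to panel order away from ties", {
  panel <- make_haplotype_panel(4, 200, divergence = 0.08, seed = 65)
  qs <- mutate_sequences(panel, rate = 0.02, n_per = 1, seed = 66)
  shuffled <- panel[c(3, 1, 4, 2), ]
  class(shuffled) <- class(panel)
  a1 <- assign_haplotypes(setNames(qs$seq, qs$query_id), panel)
  a2 <- assign_haplotypes(setNames(qs$seq, qs$query_id), shuffled)
  expect_equal(a1$best_haplotype, a2$best_haplotype)
  expect_equal(a1$identity_pct, a2$identity_pct)
})

test_that("FASTA and panel files round-trip", {
  panel <- make_haplotype_panel(3, 120, seed = 67)
  fa <- withr::local_tempfile(fileext = ".fasta")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_fasta(setNames(panel$seq, panel$id), fa)
  utils::write.csv(panel[, c("id", "haplotype", "lineage")], meta,
                   row.names = FALSE)
  back <- read_haplotype_panel(fa, meta)
  expect_equal(back$seq, panel$seq)
  expect_equal(back$haplotype, panel$haplotype)
  expect_equal(back$lineage, panel$lineage)
})
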