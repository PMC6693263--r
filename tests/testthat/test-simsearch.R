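nt <- scoring_scheme("nucleotide")
aa <- scoring_scheme("protein")

test_that("identity and no-similarity base cases score as expected", {
  h <- local_align("ACGT", "ACGT", nt)
  expect_equal(h$score, 8)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$query_cov_pct, 100)

  h0 <- local_align("AAAA", "CCCC", nt)
  expect_equal(h0$score, 0)
  expect_equal(h0$aligned_query, "")
  expect_equal(h0$identity_pct, 0)
  expect_equal(h0$query_cov_pct, 0)

  expect_error(local_align("ACGT", "MKPW", nt), "scoring scheme")
})

test_that("a deletion pair matches the affine oracle and degaps correctly", {
  a <- "ACGTACGT"; b <- "ACGACGT"
  h <- local_align(a, b, nt)
  expect_equal(h$score, sw_affine_oracle(a, b, nt$matrix, nt$gap_open, nt$gap_extend))
  expect_equal(gsub("-", "", h$aligned_query),
               substr(a, h$q_start + 1, h$q_end))
  expect_equal(gsub("-", "", h$aligned_subject),
               substr(b, h$s_start + 1, h$s_end))
})

test_that("enumeration of every alignment validates the linear-gap DP oracle", {
  set.seed(5)
  S <- nt$matrix
  for (i in 1:25) {
    a <- rand_dna_str(sample(2:5, 1)); b <- rand_dna_str(sample(2:5, 1))
    expect_equal(sw_linear_oracle(a, b, S, 2), enum_local_score(a, b, S, 2))
  }
})

test_that("engine equals the linear-gap oracle when gap_open == gap_extend", {
  set.seed(13)
  sch <- scoring_scheme("nucleotide", gap_open = 2, gap_extend = 2)
  for (i in 1:80) {
    a <- rand_dna_str(sample(4:12, 1)); b <- rand_dna_str(sample(4:12, 1))
    expect_equal(local_align(a, b, sch)$score,
                 sw_linear_oracle(a, b, sch$matrix, 2))
  }
})

test_that("engine equals the plain-R Gotoh oracle in affine mode", {
  set.seed(17)
  for (i in 1:40) {
    a <- rand_dna_str(sample(5:20, 1)); b <- rand_dna_str(sample(5:20, 1))
    expect_equal(local_align(a, b, nt)$score,
                 sw_affine_oracle(a, b, nt$matrix, nt$gap_open, nt$gap_extend))
  }
  for (i in 1:15) {
    a <- rand_prot_str(sample(5:15, 1)); b <- rand_prot_str(sample(5:15, 1))
    expect_equal(local_align(a, b, aa)$score,
                 sw_affine_oracle(a, b, aa$matrix, aa$gap_open, aa$gap_extend))
  }
})

test_that("score is symmetric and substrings align at 100% identity", {
  set.seed(23)
  for (i in 1:20) {
    a <- rand_dna_str(sample(4:15, 1)); b <- rand_dna_str(sample(4:15, 1))
    expect_equal(local_align(a, b, nt)$score, local_align(b, a, nt)$score)
  }
  for (i in 1:10) {
    b <- rand_dna_str(30)
    st <- sample(1:20, 1)
    a <- substr(b, st, st + 9)
    h <- local_align(a, b, nt)
    expect_equal(h$identity_pct, 100)
    expect_equal(h$query_cov_pct, 100)
  }
})

test_that("independent pairwise aligner cross-checks the engine score", {
  # Biostrings charges a length-L gap open + L*ext, so shift the opening
  # penalty to express the same affine cost
  set.seed(31)
  mat <- nt$matrix[1:4, 1:4]
  for (i in 1:15) {
    a <- rand_dna_str(sample(10:40, 1)); b <- rand_dna_str(sample(10:40, 1))
    ours <- local_align(a, b, nt)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = nt$gap_open - nt$gap_extend,
      gapExtension = nt$gap_extend, scoreOnly = TRUE)
    expect_equal(ours, max(0, ref))
  }
})

test_that("E-values follow the Karlin-Altschul closed forms", {
  h <- local_align("ACGT", "ACGT", nt)
  # score 0 -> evalue = m * n * K
  h0 <- h; h0$score <- 0
  h0 <- add_evalue(h0, 50, 1000, nt)
  expect_equal(h0$evalue, 50 * 1000 * nt$K, tolerance = 1e-12)
  # doubling n doubles the E-value at fixed score
  e1 <- add_evalue(h, 50, 1000, nt)$evalue
  e2 <- add_evalue(h, 50, 2000, nt)$evalue
  expect_equal(e2 / e1, 2, tolerance = 1e-12)
  # closed-form re-computation with protein gapped defaults
  hp <- h; hp$score <- 100
  hp <- add_evalue(hp, 100, 1e5, aa)
  bit <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(hp$bit_score, bit, tolerance = 1e-12)
  expect_equal(hp$evalue, 100 * 1e5 * 2^(-bit), tolerance = 1e-12)
  # monotone: higher score -> lower evalue; larger n -> higher evalue
  hs <- h; hs$score <- h$score + 5
  expect_lt(add_evalue(hs, 50, 1000, nt)$evalue, e1)
  expect_gt(add_evalue(h, 50, 5000, nt)$evalue, e1)
})

test_that("database search filters, sorts and tie-breaks deterministically", {
  db <- data.frame(id = c("s_b", "s_a", "s_c"),
                   seq = c("ACGTACGTACGTACGT", "ACGTACGTACGTACGT",
                           "TTTTTTTTGGGGCCCC"),
                   stringsAsFactors = FALSE)
  q <- "ACGTACGTACGTACGT"
  # identical subject is the single best hit; lexicographic tie-break
  hits <- search_db(q, db, nt, max_evalue = 10, max_hits = 2, exhaustive = TRUE)
  expect_equal(hits$sseqid[1:2], c("s_a", "s_b"))
  hits1 <- search_db(q, db, nt, max_evalue = 10, max_hits = 1, exhaustive = TRUE)
  expect_equal(nrow(hits1), 1L)

  # random query vs unrelated db at a strict threshold -> empty,
  # matching exhaustive alignment over the db
  set.seed(3)
  rq <- rand_prot_str(40)
  pdb <- data.frame(id = c("d1", "d2"),
                    seq = vapply(1:2, function(i) rand_prot_str(60), ""),
                    stringsAsFactors = FALSE)
  hits <- search_db(rq, pdb, aa, max_evalue = 1e-5, max_hits = 5,
                    exhaustive = TRUE)
  expect_equal(nrow(hits), 0L)
  n_db <- sum(nchar(pdb$seq))
  for (i in 1:2) {
    h <- add_evalue(local_align(rq, pdb$seq[i], aa), nchar(rq), n_db, aa)
    expect_gt(h$evalue, 1e-5)
  }

  # search with no E-value cap returns every positive-score subject
  all_hits <- search_db(q, db, nt, max_evalue = Inf, max_hits = Inf,
                        exhaustive = TRUE)
  pos <- vapply(db$seq, function(s) local_align(q, s, nt)$score > 0, TRUE)
  expect_equal(sort(all_hits$sseqid), sort(db$id[pos]))
})

test_that("outfmt-6 files round-trip ids, identities and E-values", {
  db <- data.frame(id = "s1", seq = paste(rep("ACGTAGGCCT", 10), collapse = ""),
                   stringsAsFactors = FALSE)
  hits <- search_db(db$seq, db, nt, max_evalue = Inf, max_hits = 1,
                    exhaustive = TRUE, query_id = "q1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tabular(hits, f)
  row <- strsplit(readLines(f), "\t")[[1]]
  expect_length(row, 12L)
  expect_equal(row[3], "100.000")
  expect_equal(as.integer(row[7]), 1L)   # 1-based inclusive coordinates
  expect_equal(as.integer(row[8]), 100L)
  back <- read_tabular(f)
  expect_equal(back$qseqid, hits$qseqid)
  expect_equal(back$sseqid, hits$sseqid)
  expect_equal(back$pident, round(hits$pident, 3))
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-2)

  # empty hit list -> empty file, read back as zero rows
  write_tabular(hits[0, ], f)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(read_tabular(f)), 0L)
})
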