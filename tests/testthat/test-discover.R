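leader1 <- "MKTLLLTLVVVTIVCLDLGYT"

make_candidate <- function(id, peptide, coverage = 50) {
  row <- data.frame(id = id, seq = NA_character_, coverage = coverage,
                    peptide = peptide, stringsAsFactors = FALSE)
  row$prediction <- list(suppressWarnings(predict_signal(peptide)))
  row
}

test_that("high-expression selection applies the 0.5% rule to unidentified only", {
  tx <- make_transcripts(c("u_hi", "u_lo", "t_hi"), rep("ATGAAATAA", 3),
                         c(1L, 1L, 1L))
  tx$coverage <- c(60, 40, 500)  # total 600: fractions 10%, 6.7%, 83%
  tx$label <- c("unidentified", "unidentified", "toxin:alpha-KTx")
  sel <- select_high_expressed_unidentified(tx, fraction = 0.08)
  expect_equal(sel$id, "u_hi")
  # 0.4% excluded, 0.6% included at the default threshold
  tx$coverage <- c(6, 4, 990)
  sel <- select_high_expressed_unidentified(tx, fraction = 0.005)
  expect_equal(sel$id, "u_hi")
})

test_that("ORF choice prefers signal score, then span, then finder order", {
  # a leader ORF plus a longer leaderless ORF downstream
  lead_pep <- paste0(leader1, strrep("A", 10))
  long_pep <- paste0("M", strrep("D", 60))
  seq <- paste0(
    "CCTCC",
    paste0("ATG", substr(make_cds(lead_pep), 4, 1e6)), "TAA",
    "CCTCC",
    paste0("ATG", substr(make_cds(long_pep), 4, 1e6)), "TAA")
  pick <- pick_orf_with_best_signal(seq)
  expect_equal(pick$orf$peptide, lead_pep)
  expect_gt(pick$prediction$score, 0.7)

  # equal scores: longer span wins
  seqs_equal <- paste0("ATGGATGATTAA", strrep("C", 6),
                       "ATGGATGATGACGATGACTAA")
  orfs <- find_orfs(seqs_equal, min_nt = 12)
  pick2 <- pick_orf_with_best_signal(seqs_equal, min_nt = 12)
  expect_equal(pick2$orf$span, max(orfs$span))

  expect_null(pick_orf_with_best_signal("CCCCCCCCCCCC"))
})

test_that("clustering links compatible scaffolds with similar leaders", {
  mat_a <- "SSCAAAAAACDDDDCCKK"        # C-6-C-4-C-C
  mat_b <- "TTCAAAGAACDDEDCCRK"        # same scaffold, different gaps content
  pep1 <- paste0(leader1, mat_a)
  pep2 <- paste0(leader1, mat_b)
  cands <- rbind(make_candidate("x1", pep1), make_candidate("x2", pep2))
  cl <- cluster_candidates(cands)
  expect_length(cl, 1L)
  expect_equal(sort(cl[[1]]$members$id), c("x1", "x2"))

  # 3 vs 8 cysteines never link
  pep3 <- paste0(leader1, "SSCAACAACDD")
  pep8 <- paste0(leader1, "CCAACCAACCAACC")
  cl2 <- cluster_candidates(rbind(make_candidate("a", pep3),
                                  make_candidate("b", pep8)))
  expect_length(cl2, 2L)

  # a single candidate is a singlet
  cl3 <- cluster_candidates(make_candidate("solo", pep1))
  expect_length(cl3, 1L)
  expect_equal(nrow(cl3[[1]]$members), 1L)

  # direct pairwise computation backs the linkage decision
  sA <- cysteine_pattern(mat_a)$spacing
  sB <- cysteine_pattern(mat_b)$spacing
  expect_equal(sA, sB)
})

test_that("expansion filters hits on signal and the strict coverage bound", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 11, n_housekeeping = 2, n_toxin_per_family = c("alpha-NaTx" = 1),
    n_novel_families = 1, novel_family_size = 3, n_noise = 0))
  nov <- sim$telson[grepl("^nov", sim$telson$id), ]
  nov$coverage <- compute_coverage(nov$read_count, nov$length)
  seedrow <- nov[1, ]
  pick <- pick_orf_with_best_signal(seedrow$seq)
  seed_cand <- data.frame(id = seedrow$id, seq = seedrow$seq,
                          coverage = seedrow$coverage,
                          peptide = pick$orf$peptide, stringsAsFactors = FALSE)
  seed_cand$prediction <- list(pick$prediction)
  clusters <- cluster_candidates(seed_cand)

  pooled <- nov[2:3, ]
  pooled$coverage <- c(40, 3)  # second homolog sits below the > 5 bound
  out <- expand_clusters(clusters, pooled)
  expect_equal(sort(out[[1]]$members$id), sort(c(seedrow$id, nov$id[2])))

  # a hit whose best ORF has no signal peptide is discarded
  noise <- make_transcripts("junk", strrep("ATGGATGATGACGATGAC", 6), 1L)
  noise$coverage <- 50
  out2 <- expand_clusters(clusters, noise)
  expect_equal(out2[[1]]$members$id, seedrow$id)

  # the seed itself is never removed and counts never shrink
  expect_true(all(vapply(out, function(cl)
    cl$seed_member %in% cl$members$id, TRUE)))
})

test_that("center-star MSA merges gaps and always degaps to its inputs", {
  msa <- center_star_msa(c("MKCW", "MKCW"))
  expect_equal(as.character(msa), c("MKCW", "MKCW"))

  msa2 <- center_star_msa(c("MKC", "MKAC"))
  expect_equal(nchar(msa2[1]), nchar(msa2[2]))
  expect_equal(gsub("-", "", msa2[1]), "MKC")
  expect_equal(gsub("-", "", msa2[2]), "MKAC")
  expect_equal(sum(strsplit(msa2[1], "")[[1]] == "-") +
                 sum(strsplit(msa2[2], "")[[1]] == "-"), 1L)

  set.seed(19)
  for (i in 1:10) {
    peps <- vapply(1:sample(2:5, 1), function(j)
      paste0("M", rand_prot_str(sample(4:20, 1))), "")
    msa <- center_star_msa(peps)
    expect_equal(length(unique(nchar(msa))), 1L)
    expect_equal(as.character(gsub("-", "", msa)), peps)
  }

  expect_error(center_star_msa("MK"), "at least two")
})

test_that("center choice maximizes summed pairwise scores on small triples", {
  aa <- scoring_scheme("protein")
  aa$gap_open <- 10; aa$gap_extend <- 1
  set.seed(29)
  for (i in 1:8) {
    peps <- vapply(1:3, function(j) rand_prot_str(sample(3:6, 1)), "")
    msa <- center_star_msa(peps)
    cen <- attr(msa, "center")
    sums <- vapply(1:3, function(ci) sum(vapply(setdiff(1:3, ci), function(cj)
      local_align(peps[ci], peps[cj], aa, mode = "global")$score, 0)), 0)
    expect_equal(sums[cen], max(sums))
  }
})

test_that("conserved-residue banding reflects column agreement", {
  expect_equal(conserved_residue_band(c("MKCW", "MKCW", "MKCW")), "high")
  expect_equal(conserved_residue_band("MKCW"), "high")  # singlet convention
  set.seed(37)
  rnd <- vapply(1:6, function(i) rand_prot_str(30), "")
  expect_equal(conserved_residue_band(center_star_msa(rnd)), "low")
  # f = 0.3 lands in the some band
  msa <- c(paste0(strrep("A", 3), strrep("W", 7)),
           paste0(strrep("A", 3), rand_prot_str(7)))
  f <- mean(vapply(1:10, function(j)
    substr(msa[1], j, j) == substr(msa[2], j, j), TRUE))
  if (f >= 0.25 && f < 0.5)
    expect_equal(conserved_residue_band(msa), "some")
})

test_that("hit descriptions map onto the best-hit categories", {
  expect_equal(hit_category("Potassium channel toxin alpha-KTx 4.5"),
               "named_toxin_family_member")
  expect_equal(hit_category("Hypothetical secreted protein"),
               "hypothetical_or_uncharacterized")
  expect_equal(hit_category("Venom toxin meuTx23"),
               "named_toxin_or_venom_peptide")
  expect_equal(hit_category("venom peptide HtC4Tx1"),
               "named_toxin_or_venom_peptide")
  expect_equal(hit_category("Orphan peptide AbOp-11"),
               "hypothetical_or_uncharacterized")
  expect_equal(hit_category(NA_character_), "no_hit")
  expect_equal(hit_category("SH3 domain-containing protein"), "no_hit")
})

test_that("the novelty rules resolve the published feature combinations", {
  expect_equal(classify_features("high", TRUE, "hypothetical_or_uncharacterized"),
               "novel_putative_toxin_family")
  expect_equal(classify_features("high", FALSE, "hypothetical_or_uncharacterized",
                                 "Orphan peptide"),
               "novel_putative_secreted_protein")
  expect_equal(classify_features("some", TRUE, "named_toxin_family_member"),
               "new_toxins_in_existing_family")
  # venom-peptide hit with a conserved C pattern and non-high signal
  expect_equal(classify_features("low", TRUE, "named_toxin_or_venom_peptide",
                                 "venom peptide HtC4Tx1"),
               "novel_putative_toxin_family")
  # the same features in a singlet give the singlet category
  expect_equal(classify_features("low", TRUE, "no_hit", is_singlet = TRUE),
               "novel_putative_toxin")
  expect_equal(classify_features("high", FALSE, "hypothetical_or_uncharacterized",
                                 "Putative antimicrobial peptide"),
               "novel_putative_amp")
  expect_error(classify_features("high", TRUE, "whatever"))
})

test_that("the discovery screen recovers planted novel families end to end", {
  sim <- simulate_transcriptomes(sim_config(seed = 2))
  ann <- run_pipeline(sim$telson, sim$chela, sim$refdb)
  scr <- discover_novel_toxins(ann, known = sim$known)
  truth_nov <- sim$truth[grepl("^novel:", sim$truth$true_class), ]
  fams <- split(truth_nov$id, truth_nov$true_class)
  # each planted family ends up together inside exactly one cluster
  # (expansion at the permissive E <= 1 may legitimately add lower-scoring
  # pooled transcripts around them, as cluster expansion is meant to)
  for (fam_ids in fams) {
    holding <- vapply(scr$clusters, function(cl)
      all(fam_ids %in% cl$members$id), TRUE)
    expect_equal(sum(holding), 1L)
  }
  # categories partition the clusters
  expect_true(all(nzchar(scr$summary$category)))
  expect_equal(nrow(scr$summary), length(scr$clusters))
  # outputs serialize
  dir <- withr::local_tempdir()
  write_novelty_screen(scr, dir)
  expect_true(file.exists(file.path(dir, "clusters.tsv")))
})

test_that("the shipped worked-example rows classify as published", {
  feats <- classify_feature_table(cluster_feature_rows())
  expect_equal(nrow(feats), 24L)
  expect_equal(sum(feats$category == "novel_putative_toxin_family"), 6L)
  expect_gte(sum(feats$category == feats$published_category), 20L)
})
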