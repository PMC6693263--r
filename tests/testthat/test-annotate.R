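test_that("coverage follows read_len * count / length", {
  expect_equal(compute_coverage(10, 300), 5.0)
  expect_equal(compute_coverage(0, 300), 0.0)
  expect_equal(compute_coverage(7, 150), 7.0)
  expect_equal(compute_coverage(c(10, 0), c(300, 100)), c(5, 0))
  expect_error(compute_coverage(1, 0), ">= 1")
  expect_error(compute_coverage(-1, 10), "non-negative")
})

# fixture: two unrelated 200-mers; the second gets a chela counterpart with
# exactly 2 mismatches per 100 nt (98% identity over the full length)
make_orthologue_fixture <- function() {
  set.seed(21)
  seq_a <- rand_dna_str(200)
  seq_b <- rand_dna_str(200)
  ch <- strsplit(seq_b, "")[[1]]
  for (p in c(40, 80, 120, 160))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  list(seq_a = seq_a, seq_b = seq_b, seq_b98 = paste(ch, collapse = ""))
}

test_that("orthologue subtraction applies all three thresholds", {
  fx <- make_orthologue_fixture()
  telson <- make_transcripts(c("t_exact", "t_98", "t_alone"),
                             c(fx$seq_a, fx$seq_b, rand_dna_str(180)),
                             c(100L, 100L, 100L))
  telson$coverage <- compute_coverage(telson$read_count, telson$length)
  chela <- make_transcripts(c("c_exact", "c_98"),
                            c(fx$seq_a, fx$seq_b98), c(50L, 50L), "chela")
  cfg <- pipeline_config(exhaustive_search = TRUE)
  out <- remove_chela_orthologues(telson, chela, cfg)
  # byte-identical transcript: identity 100 >= 99, coverage 100 >= 95 -> removed
  expect_true("t_exact" %in% out$removed$id)
  # 98% identity over full length fails the 99% bar -> kept
  expect_true("t_98" %in% out$kept$id)
  m98 <- out$map[out$map$telson_id == "t_98", ]
  expect_equal(m98$pident, 98, tolerance = 1e-9)
  expect_false(m98$passed)
  # no chela alignment above score 0 -> kept
  expect_true("t_alone" %in% out$kept$id)

  # empty chela: nothing removed
  none <- remove_chela_orthologues(telson, chela[0, ], cfg)
  expect_equal(nrow(none$removed), 0L)
  expect_equal(nrow(none$map), 0L)
})

test_that("annotation takes the best qualifying hit's label or unidentified", {
  db <- make_tiny_refdb()
  peptides <- data.frame(
    id = c("a", "b", "c"),
    peptide = c(db$records$seq[db$records$id == "tx1"],   # exact toxin
                db$records$seq[db$records$id == "ot1"],   # exact other_toxin
                strrep("GN", 25)),                        # matches nothing
    stringsAsFactors = FALSE)
  out <- annotate_against_db(peptides, db, pipeline_config(exhaustive_search = TRUE))
  expect_equal(out$label, c("toxin:alpha-KTx", "other_toxin", "unidentified"))
  expect_equal(out$best_hit[1], "tx1")
  # exhaustive confirmation that nothing qualifies for the unidentified one
  aa <- scoring_scheme("protein")
  n_db <- sum(nchar(db$records$seq))
  for (s in db$records$seq) {
    h <- local_align(peptides$peptide[3], s, aa)
    if (h$score > 0)
      expect_gt(add_evalue(h, nchar(peptides$peptide[3]), n_db, aa)$evalue, 1e-5)
  }
  expect_error(annotate_against_db(peptides, list(records = NULL)), "empty")
})

test_that("the coverage cutoff removes strictly-below-cutoff transcripts", {
  tx <- make_transcripts(c("a", "b", "c"), rep("ATGAAATAA", 3), c(1L, 1L, 1L))
  tx$coverage <- c(4.99, 5.0, 100)
  out <- apply_coverage_cutoff(tx, 5)
  expect_equal(out$kept$id, c("b", "c"))
  expect_equal(out$dropped$id, "a")
  expect_equal(nrow(apply_coverage_cutoff(tx, 1000)$kept), 0L)
  expect_equal(nrow(apply_coverage_cutoff(tx, 0)$kept), 3L)
})

test_that("orthologue-flagged survivors are relabeled physiological", {
  tx <- make_transcripts(c("a", "b", "c"), rep("ATGAAATAA", 3), c(1L, 1L, 1L))
  tx$label <- c("toxin:CaTx", "other_toxin", "unidentified")
  map <- data.frame(telson_id = c("a", "c"), chela_id = c("x", "y"),
                    evalue = 0, pident = 100, qcovpct = 100,
                    passed = c(TRUE, FALSE), stringsAsFactors = FALSE)
  out <- finalize_labels(tx, map)
  expect_equal(out$label, c("physiological", "other_toxin", "unidentified"))
  expect_equal(out$venom, c(FALSE, TRUE, FALSE))
})

test_that("signal validation is advisory and limited to highly expressed toxins", {
  leader_pep <- paste0("MKTLLLTLVVVTIVCLDLGYT", strrep("A", 30))
  tx <- make_transcripts(c("hi_tox", "lo_tox", "hi_untox"),
                         rep("ATGAAATAA", 3), c(1L, 1L, 1L))
  tx$coverage <- c(80, 0.1, 100)
  tx$label <- c("toxin:alpha-KTx", "toxin:alpha-KTx", "unidentified")
  tx$peptide <- c(leader_pep, leader_pep, strrep("GN", 20))
  out <- validate_toxin_signals(tx, fraction = 0.005)
  expect_equal(out$id, "hi_tox")
  expect_true(out$validated)
  expect_equal(tx$label[1], "toxin:alpha-KTx")  # labels untouched

  # highly expressed toxin without a leader: reported, not relabeled
  tx$peptide[1] <- paste0("M", strrep("D", 40))
  out2 <- validate_toxin_signals(tx, fraction = 0.005)
  expect_false(out2$validated)
})

test_that("the full pipeline keeps its label partition and coverage ledger", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 3, n_housekeeping = 6, n_toxin_per_family = c("alpha-NaTx" = 3),
    n_novel_families = 1, novel_family_size = 2, n_noise = 4))
  ann <- run_pipeline(sim$telson, sim$chela, sim$refdb)
  tx <- ann$transcripts
  known <- c("physiological", "other_toxin", "unidentified")
  expect_true(all(tx$label %in% known | grepl("^toxin:", tx$label)))
  expect_equal(sum(ann$report$coverage_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(ann$report$counts), nrow(tx))
  # attrition ledger reconciles at every step
  expect_equal(ann$attrition$input, nrow(sim$telson))
  expect_equal(ann$attrition$after_orthologue_removal,
               ann$attrition$input - nrow(ann$removed_orthologues))
  expect_equal(ann$attrition$after_coverage_cutoff,
               ann$attrition$after_orf_prediction - nrow(ann$dropped_low_coverage))
  expect_equal(nrow(tx), ann$attrition$after_coverage_cutoff)
})

test_that("telson identical to chela leaves an empty venom set", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 5, n_housekeeping = 5, n_toxin_per_family = c("alpha-KTx" = 2),
    n_novel_families = 0, novel_family_size = 0, n_noise = 0))
  same <- sim$telson
  chela_same <- same
  chela_same$tissue <- "chela"
  ann <- run_pipeline(same, chela_same, sim$refdb)
  expect_equal(nrow(ann$transcripts), 0L)
  expect_equal(sum(ann$transcripts$venom), 0L)
})

test_that("an empty chela disables subtraction so labels come from the database", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 5, n_housekeeping = 5, n_toxin_per_family = c("alpha-KTx" = 2),
    n_novel_families = 0, novel_family_size = 0, n_noise = 0))
  ann <- run_pipeline(sim$telson, sim$chela[0, ], sim$refdb)
  expect_equal(nrow(ann$orthologue_map), 0L)
  lab <- ann$transcripts$label[grepl("^tox", ann$transcripts$id)]
  expect_true(all(lab == "toxin:alpha-KTx"))
  # housekeeping transcripts now annotate as physiological via the database
  hk <- ann$transcripts$label[grepl("^hk", ann$transcripts$id)]
  expect_true(all(hk == "physiological"))
})

test_that("annotating before or after the cutoff gives the same venom set", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 7, n_housekeeping = 5, n_toxin_per_family = c("alpha-NaTx" = 3),
    n_novel_families = 1, novel_family_size = 2, n_noise = 3))
  cfg <- pipeline_config()
  ann <- run_pipeline(sim$telson, sim$chela, sim$refdb, cfg)
  venom_iv_then_v <- sort(ann$transcripts$id[ann$transcripts$venom])
  # reverse order: cutoff first, then annotate the survivors only
  telson <- sim$telson
  telson$coverage <- compute_coverage(telson$read_count, telson$length)
  kept <- remove_chela_orthologues(telson, sim$chela, cfg)$kept
  kept <- apply_coverage_cutoff(kept, cfg$coverage_cutoff)$kept
  orfs <- lapply(seq_len(nrow(kept)), function(i)
    longest_orf(find_orfs(kept$seq[i], id = kept$id[i])))
  has <- !vapply(orfs, is.null, TRUE)
  kept <- kept[has, ]
  kept$peptide <- vapply(orfs[has], function(o) o$peptide, "")
  ann2 <- annotate_against_db(kept[, c("id", "peptide")], sim$refdb, cfg)
  venom_v_then_iv <- sort(ann2$id[grepl("^toxin:", ann2$label) |
                                    ann2$label == "other_toxin"])
  expect_equal(venom_iv_then_v, venom_v_then_iv)
})

test_that("pipeline outputs serialize to the documented report files", {
  sim <- simulate_transcriptomes(sim_config(
    seed = 3, n_housekeeping = 4, n_toxin_per_family = c("alpha-KTx" = 2),
    n_novel_families = 0, novel_family_size = 0, n_noise = 2))
  ann <- run_pipeline(sim$telson, sim$chela, sim$refdb)
  dir <- withr::local_tempdir()
  write_annotation(ann, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "transcripts.tsv", "composition.tsv", "attrition.json",
    "orthologue_hits.outfmt6", "annotation_hits.outfmt6")))))
  tab <- read.delim(file.path(dir, "transcripts.tsv"))
  expect_equal(nrow(tab), nrow(ann$transcripts))
  att <- jsonlite::read_json(file.path(dir, "attrition.json"))
  expect_equal(att$input, nrow(sim$telson))
})
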