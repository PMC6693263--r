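# Deterministic generator of paired telson/chela transcriptomes, reference
# databases, family representatives and known-protein sets, with a
# machine-readable ground-truth manifest. Emulates the statistical
# structure the annotation pipeline assumes: housekeeping transcripts
# shared between tissues, family-similar toxin transcripts carrying
# secretion leaders and cysteine scaffolds, novel toxin families with no
# counterpart in any database, and unstructured noise.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

# codons per amino acid (standard code), for uniform synonymous
# back-translation
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Default pool of planted secretion-leader peptides
#'
#' Classical tripartite leaders (charged n-region, strongly hydrophobic
#' h-region, small residues around the cleavage site) that the built-in
#' signal-peptide heuristic detects with a high band.
#'
#' @export
default_leader_pool <- function() {
  c("MKTLLLTLVVVTIVCLDLGYT",
    "MKRLVLVLLLVSLSLAIEGFA",
    "MKSLILLALLGVCLLSVLGSA",
    "MNKLVILSLLLLLISQLSEAG",
    "MKVFSAVLLLTLFVCSIEAGA")
}

#' Default pool of cysteine-scaffold spacing templates
#'
#' Spacing strings in the [cysteine_pattern()] notation; entries differ in
#' cysteine count so distinct scaffolds never fall in one clustering class.
#'
#' @export
default_scaffold_pool <- function() {
  c("C-6-C-4-C-C",
    "C-2-C-9-C-3-C-1-C-C",
    "C-4-C-6-C-3-C",
    "C-1-C-7-C-2-C-5-C-4-C-C-C")
}

#' Simulation configuration
#'
#' The defaults describe a small paired telson/chela experiment: 20
#' housekeeping transcripts copied into both tissues, two toxin families
#' of five members each, two novel families of three members whose
#' expression is forced above the 0.5\% discovery threshold, and 10 noise
#' transcripts. Read counts follow a log-normal depth model.
#'
#' @param seed integer; fixing it makes the generated files byte-identical.
#' @param n_housekeeping housekeeping transcripts (both tissues).
#' @param n_toxin_per_family named integer vector, members per toxin family.
#' @param n_novel_families,novel_family_size planted novel toxin families.
#' @param n_noise unstructured noise transcripts.
#' @param mutation_rate_orthologue per-base mutation rate applied to the
#'   chela copy of each housekeeping transcript (0 = exact copies).
#' @param mutation_rate_toxin per-residue mutation rate between a toxin
#'   transcript and its family reference record (kept well under 15\%).
#' @param read_meanlog,read_sdlog log-normal read-depth model.
#' @param force_high_expression force novel-family read counts above the
#'   relative-expression threshold (disable to exercise the exclusion
#'   branch).
#' @param high_expression_fraction the threshold used when forcing.
#' @param leader_pool,scaffold_pool planted leader peptides and cysteine
#'   spacing templates.
#' @param n_other_toxin venom-tissue records with no family representative
#'   similarity (labeled `other_toxin` at build time).
#' @param verify check planted similarities with the package's own search
#'   engine before returning.
#' @export
sim_config <- function(seed = 1L, n_housekeeping = 20L,
                       n_toxin_per_family = c("alpha-NaTx" = 5L,
                                              "alpha-KTx" = 5L),
                       n_novel_families = 2L, novel_family_size = 3L,
                       n_noise = 10L, mutation_rate_orthologue = 0,
                       mutation_rate_toxin = 0.06,
                       read_meanlog = 4, read_sdlog = 1,
                       force_high_expression = TRUE,
                       high_expression_fraction = 0.005,
                       leader_pool = default_leader_pool(),
                       scaffold_pool = default_scaffold_pool(),
                       n_other_toxin = 4L, verify = TRUE) {
  fields <- mget(names(formals()))
  stopifnot(n_housekeeping >= 0, all(n_toxin_per_family >= 0),
            n_novel_families >= 0, novel_family_size >= 0, n_noise >= 0,
            mutation_rate_orthologue >= 0, mutation_rate_orthologue < 1)
  n_leaders_needed <- length(n_toxin_per_family) + n_novel_families
  if (n_leaders_needed > length(leader_pool))
    stop("leader pool has ", length(leader_pool), " entries but ",
         n_leaders_needed, " families need one")
  if (n_novel_families > length(scaffold_pool))
    stop("scaffold pool too small for ", n_novel_families, " novel families")
  structure(fields, class = "sim_config")
}

rand_peptide <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# uniform synonymous back-translation; appends a random stop codon
back_translate <- function(peptide, ct = codon_table()) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    cs <- ct[[a]]
    cs[sample.int(length(cs), 1L)]
  }, "")
  paste(c(codons, ct[["*"]][sample.int(3L, 1L)]), collapse = "")
}

# point mutations that never touch protected positions nor introduce new
# cysteines, so a planted scaffold survives mutation exactly
mutate_peptide <- function(peptide, rate, protect = integer(0)) {
  aas <- strsplit(peptide, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(aas)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) aas[i] <- sample(setdiff(AA20, c(aas[i], "C")), 1L)
  paste(aas, collapse = "")
}

mutate_dna <- function(seq, rate) {
  nts <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(nts)) < rate)
  for (i in hit) nts[i] <- sample(setdiff(c("A", "C", "G", "T"), nts[i]), 1L)
  paste(nts, collapse = "")
}

# random 5' UTR free of ATG (in any frame), so the planted ORF stays the
# longest one
rand_utr <- function(n) {
  repeat {
    u <- rand_dna(n)
    if (!grepl("ATG", u, fixed = TRUE)) return(u)
  }
}

# build a transcript around a planted peptide; resample the codons/UTRs
# until the planted ORF really is the transcript's longest, so spurious
# (e.g. reverse-strand open-ended) ORFs never shadow it
build_transcript <- function(pep, ct, utr5 = 5:20, utr3 = 10:40,
                             min_nt = 75L, max_tries = 50L) {
  for (try in seq_len(max_tries)) {
    seq <- paste0(rand_utr(sample(utr5, 1L)), back_translate(pep, ct),
                  rand_dna(sample(utr3, 1L)))
    top <- longest_orf(find_orfs(seq, min_nt = min_nt))
    if (!is.null(top) && top$peptide == pep) return(seq)
  }
  stop("could not embed the planted ORF as the longest one")
}

# realize a cysteine-spacing template as a mature peptide with random
# non-cysteine residues in the gaps and short non-cysteine flanks
realize_scaffold <- function(spacing, flank5 = 5L, flank3 = 8L) {
  gaps <- spacing_gaps(spacing)
  aa_nc <- setdiff(AA20, "C")
  body <- "C"
  for (g in gaps)
    body <- paste0(body, paste(sample(aa_nc, g, replace = TRUE), collapse = ""),
                   "C")
  paste0(paste(sample(aa_nc, flank5, replace = TRUE), collapse = ""),
         body,
         paste(sample(aa_nc, flank3, replace = TRUE), collapse = ""))
}

draw_counts <- function(n, meanlog, sdlog, min_count = 1L) {
  pmax(min_count, as.integer(round(rlnorm(n, meanlog, sdlog))))
}

#' Generate paired synthetic transcriptomes with ground truth
#'
#' Housekeeping transcripts are copied into both tissues (mutated in the
#' chela copy at `mutation_rate_orthologue`); toxin transcripts appear only
#' in the telson and consist of a planted leader plus a family-template
#' mature peptide back-translated with random synonymous codons; novel
#' families share a leader and cysteine scaffold within the family but have
#' no counterpart in the reference or known sets; noise transcripts are
#' random. Novel-family read counts are forced above the high-expression
#' threshold unless disabled. With `verify = TRUE` the generator checks,
#' using the package's own search engine, that planted toxins hit their
#' family's reference record at E <= 1e-5 and that novel members have no
#' reference hit at that threshold.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, telson/chela FASTA +
#'   count sidecars, the reference and representative FASTAs, the known
#'   FASTA and a JSON ground-truth manifest are written there.
#' @return list with `telson`, `chela` (transcript data frames), `refdb`
#'   (a `reference_db`), `representatives`, `known`, `truth` (the manifest
#'   data frame) and, when written, `paths`.
#' @export
simulate_transcriptomes <- function(cfg = sim_config(), out_dir = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  ct <- codon_table()

  telson <- list(); chela <- list(); truth <- list()
  general <- list(); venom <- list(); reps <- list(); known <- list()

  add_truth <- function(id, class, leader = NA_character_,
                        scaffold = NA_character_, read_count = NA_integer_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = id, true_class = class, leader = leader, scaffold = scaffold,
      read_count = read_count, stringsAsFactors = FALSE)
  }

  # --- housekeeping: shared between tissues, backed by general proteins ---
  for (i in seq_len(cfg$n_housekeeping)) {
    pep <- paste0("M", rand_peptide(sample(150:280, 1L)))
    seq <- build_transcript(pep, ct)
    id <- sprintf("hk%03d", i)
    rc_t <- draw_counts(1L, cfg$read_meanlog, cfg$read_sdlog)
    rc_c <- draw_counts(1L, cfg$read_meanlog, cfg$read_sdlog)
    cseq <- if (cfg$mutation_rate_orthologue > 0)
      mutate_dna(seq, cfg$mutation_rate_orthologue) else seq
    telson[[id]] <- list(seq = seq, rc = rc_t)
    chela[[id]] <- list(seq = cseq, rc = rc_c)
    general[[length(general) + 1L]] <- data.frame(
      id = sprintf("P_hk%03d", i), seq = pep, stringsAsFactors = FALSE)
    add_truth(id, "housekeeping", read_count = rc_t)
  }
  # a few extra general proteins with no transcript counterpart
  for (i in seq_len(5L))
    general[[length(general) + 1L]] <- data.frame(
      id = sprintf("P_gen%02d", i), seq = paste0("M", rand_peptide(120L)),
      stringsAsFactors = FALSE)

  # --- toxin families -----------------------------------------------------
  families <- names(cfg$n_toxin_per_family)
  fam_leader <- setNames(cfg$leader_pool[seq_along(families)], families)
  tx_i <- 0L
  for (f in families) {
    # toxin families take scaffolds after the ones reserved for novel
    # families, so planted novel scaffolds stay absent from every database
    sc_idx <- 1L + (cfg$n_novel_families + match(f, families) - 1L) %%
      length(cfg$scaffold_pool)
    ref_mature <- realize_scaffold(cfg$scaffold_pool[sc_idx])
    ref_precursor <- paste0(fam_leader[[f]], ref_mature)
    rid <- sprintf("P_tox_%s_ref", gsub("[^A-Za-z0-9]", "", f))
    venom[[length(venom) + 1L]] <- data.frame(id = rid, seq = ref_precursor,
                                              stringsAsFactors = FALSE)
    reps[[length(reps) + 1L]] <- data.frame(
      id = sprintf("rep_%s", gsub("[^A-Za-z0-9]", "", f)), family = f,
      seq = ref_mature, stringsAsFactors = FALSE)
    known[[length(known) + 1L]] <- data.frame(
      id = sprintf("K_%s", gsub("[^A-Za-z0-9]", "", f)), seq = ref_precursor,
      desc = paste(f, "toxin"), stringsAsFactors = FALSE)
    cpos <- cysteine_pattern(ref_mature)$positions + 1L
    for (m in seq_len(cfg$n_toxin_per_family[[f]])) {
      tx_i <- tx_i + 1L
      mature <- mutate_peptide(ref_mature, cfg$mutation_rate_toxin,
                               protect = cpos)
      pep <- paste0(fam_leader[[f]], mature)
      seq <- build_transcript(pep, ct, utr5 = 5:15, utr3 = 10:30)
      id <- sprintf("tox%03d", tx_i)
      rc <- draw_counts(1L, cfg$read_meanlog + 1.5, cfg$read_sdlog, 30L)
      telson[[id]] <- list(seq = seq, rc = rc)
      add_truth(id, paste0("toxin:", f), leader = fam_leader[[f]],
                read_count = rc)
    }
  }
  # venom-tissue records with no representative similarity -> other_toxin
  for (i in seq_len(cfg$n_other_toxin))
    venom[[length(venom) + 1L]] <- data.frame(
      id = sprintf("P_oth%02d", i),
      seq = paste0("M", paste(sample(setdiff(AA20, "C"), 60L, replace = TRUE),
                              collapse = "")),
      stringsAsFactors = FALSE)

  # --- novel families: planted leader + scaffold, absent from databases ---
  nv_i <- 0L
  novel_ids <- list()
  for (nf in seq_len(cfg$n_novel_families)) {
    leader <- cfg$leader_pool[length(families) + nf]
    scaffold <- cfg$scaffold_pool[nf]
    ref_mature <- realize_scaffold(scaffold)
    cpos <- cysteine_pattern(ref_mature)$positions + 1L
    ids <- character(0)
    for (m in seq_len(cfg$novel_family_size)) {
      nv_i <- nv_i + 1L
      mature <- mutate_peptide(ref_mature, 0.05, protect = cpos)
      pep <- paste0(leader, mature)
      seq <- build_transcript(pep, ct, utr5 = 5:15, utr3 = 10:30)
      id <- sprintf("nov%03d", nv_i)
      telson[[id]] <- list(seq = seq, rc = 1L)  # forced below
      ids <- c(ids, id)
      add_truth(id, sprintf("novel:%d", nf), leader = leader,
                scaffold = scaffold, read_count = NA_integer_)
    }
    novel_ids[[nf]] <- ids
  }

  # --- noise --------------------------------------------------------------
  for (i in seq_len(cfg$n_noise)) {
    id <- sprintf("noise%03d", i)
    rc <- draw_counts(1L, cfg$read_meanlog - 2, cfg$read_sdlog)
    telson[[id]] <- list(seq = rand_dna(sample(200:500, 1L)), rc = rc)
    add_truth(id, "noise", read_count = rc)
  }

  to_df <- function(lst, tissue) {
    if (!length(lst))
      return(data.frame(id = character(0), seq = character(0),
                        length = integer(0), read_count = integer(0),
                        tissue = character(0), coverage = numeric(0),
                        label = character(0), stringsAsFactors = FALSE))
    data.frame(id = names(lst),
               seq = vapply(lst, `[[`, "", "seq"),
               length = nchar(vapply(lst, `[[`, "", "seq")),
               read_count = vapply(lst, function(x) as.integer(x$rc), 1L),
               tissue = tissue, coverage = NA_real_, label = "unprocessed",
               row.names = NULL, stringsAsFactors = FALSE)
  }
  telson_df <- to_df(telson, "telson")
  chela_df <- to_df(chela, "chela")

  # force novel-family expression above the discovery threshold
  all_novel <- unlist(novel_ids)
  if (length(all_novel) && cfg$force_high_expression) {
    is_nov <- telson_df$id %in% all_novel
    base_cov <- sum(150 * telson_df$read_count[!is_nov] /
                      telson_df$length[!is_nov])
    target <- 1.6 * cfg$high_expression_fraction  # comfortable margin
    k <- sum(is_nov)
    per_cov <- target * base_cov / (1 - k * target)
    telson_df$read_count[is_nov] <-
      as.integer(ceiling(per_cov * telson_df$length[is_nov] / 150))
  }
  truth_df <- do.call(rbind, truth)
  truth_df$read_count <- telson_df$read_count[match(truth_df$id, telson_df$id)]

  # --- reference database, representatives, known set ---------------------
  general_df <- do.call(rbind, general)
  venom_df <- do.call(rbind, venom)
  reps_df <- do.call(rbind, reps)
  known_df <- if (length(known)) do.call(rbind, known) else
    data.frame(id = character(0), seq = character(0), desc = character(0),
               stringsAsFactors = FALSE)
  labeled <- label_by_representatives(venom_df, reps_df)
  refdb <- merge_reference_db(general_df, labeled, representatives = reps_df)

  if (cfg$verify) verify_planted(telson_df, truth_df, refdb)

  out <- list(telson = telson_df, chela = chela_df, refdb = refdb,
              representatives = reps_df, known = known_df, truth = truth_df,
              cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(out_dir, ...)
    write_transcripts(telson_df, p("telson.fasta"), p("telson_counts.tsv"))
    write_transcripts(chela_df, p("chela.fasta"), p("chela_counts.tsv"))
    src <- rbind(data.frame(id = general_df$id, seq = general_df$seq,
                            source = "general", stringsAsFactors = FALSE),
                 data.frame(id = venom_df$id, seq = venom_df$seq,
                            source = "venom_tissue", stringsAsFactors = FALSE))
    write_proteins(src, p("reference.fasta"))
    reps_out <- reps_df
    write_proteins(reps_out, p("representatives.fasta"))
    write_proteins(known_df, p("known.fasta"))
    jsonlite::write_json(truth_df, p("ground_truth.json"), dataframe = "rows")
    out$paths <- list(telson = p("telson.fasta"),
                      telson_counts = p("telson_counts.tsv"),
                      chela = p("chela.fasta"),
                      chela_counts = p("chela_counts.tsv"),
                      reference = p("reference.fasta"),
                      representatives = p("representatives.fasta"),
                      known = p("known.fasta"),
                      truth = p("ground_truth.json"))
  }
  out
}

# generator self-check: planted toxins must hit their family's reference
# record at E <= 1e-5 under the package's own engine; novel members must not
# hit anything at that threshold
verify_planted <- function(telson_df, truth_df, refdb,
                           scheme = scoring_scheme("protein")) {
  for (i in seq_len(nrow(truth_df))) {
    cls <- truth_df$true_class[i]
    if (!grepl("^toxin:|^novel:", cls)) next
    row <- telson_df[telson_df$id == truth_df$id[i], ]
    orf <- longest_orf(find_orfs(row$seq, id = row$id))
    if (is.null(orf)) stop("planted transcript ", row$id, " lost its ORF")
    h <- search_db(orf$peptide, refdb$records, scheme, max_evalue = 1e-5,
                   max_hits = 1L, query_id = row$id)
    if (grepl("^toxin:", cls)) {
      if (nrow(h) == 0L ||
          refdb$records$label[refdb$records$id == h$sseqid[1]] != cls)
        stop("planted toxin ", row$id, " does not recover label ", cls)
    } else if (nrow(h) > 0L) {
      stop("planted novel transcript ", row$id,
           " unexpectedly hits the reference database")
    }
  }
  invisible(TRUE)
}
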