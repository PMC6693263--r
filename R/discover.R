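# Novel-toxin discovery over "unidentified" transcripts: high-expression
# selection, choice of the ORF with the best signal peptide, clustering on
# signal-peptide/cysteine-scaffold features, cluster expansion against the
# pooled telson transcriptomes, center-star MSA, identification against a
# known-protein set, and the rule-based novelty classifier.

#' Discovery configuration
#'
#' @param fraction relative-expression threshold for "highly expressed"
#'   unidentified transcripts (default 0.5\%).
#' @param leader_identity_min minimum global percent identity between two
#'   candidates' signal-peptide regions for them to link (default 60).
#' @param scaffold_gap_tol two cysteine scaffolds fall in the same class
#'   when every inter-cysteine gap differs by at most this many residues
#'   (default 2).
#' @param expansion_max_evalue E-value threshold for cluster expansion
#'   (default 1).
#' @param expansion_min_coverage expansion hits need coverage strictly
#'   above this (default 5; note the pipeline's own cutoff keeps coverage
#'   exactly 5 — the discrepancy mirrors the two rules' different wording
#'   and is deliberate).
#' @param conserved_high,conserved_some band cutoffs on the fraction of
#'   conserved alignment columns.
#' @param conserved_col_identity a column counts as conserved when at least
#'   this fraction of members agree (default 0.8).
#' @param msa_gap_open,msa_gap_extend gap costs for the cluster MSA.
#' @param known_max_evalue E-value threshold for identification against the
#'   known-protein set.
#' @param family_synonyms keywords marking a hit description as a named
#'   toxin-family member.
#' @param signal_cutoffs banding cutoffs from [signal_cutoffs()].
#' @export
discover_config <- function(fraction = 0.005,
                            leader_identity_min = 60,
                            scaffold_gap_tol = 2L,
                            expansion_max_evalue = 1,
                            expansion_min_coverage = 5,
                            conserved_high = 0.5, conserved_some = 0.25,
                            conserved_col_identity = 0.8,
                            msa_gap_open = 10, msa_gap_extend = 1,
                            known_max_evalue = 1e-5,
                            family_synonyms = default_family_synonyms(),
                            signal_cutoffs = venomscan::signal_cutoffs()) {
  structure(as.list(environment()), class = "discover_config")
}

#' Default toxin-family synonym keywords
#'
#' Substrings (matched case-insensitively) of hit descriptions that name a
#' recognized scorpion toxin family.
#'
#' @export
default_family_synonyms <- function() {
  c("NaTx", "KTx", "sodium channel toxin", "potassium channel toxin",
    "chloride channel toxin", "chlorotoxin", "calcium channel toxin",
    "CaTx", "Kunitz", "theraphotoxin", "bradykinin", "BmKa",
    "phospholipase", "PLA2", "buthitoxin")
}

#' Select highly expressed unidentified transcripts
#'
#' Unidentified transcripts whose coverage is at least `fraction` of the
#' summed coverage of all surviving transcripts.
#'
#' @param transcripts annotated transcript data frame (pipeline output).
#' @param fraction relative-expression threshold (default 0.005).
#' @export
select_high_expressed_unidentified <- function(transcripts, fraction = 0.005) {
  total <- sum(transcripts$coverage)
  stopifnot(total > 0)
  sel <- transcripts$label == "unidentified" &
    transcripts$coverage / total >= fraction
  transcripts[sel, , drop = FALSE]
}

#' Pick the ORF with the best signal peptide
#'
#' Among all ORFs of a transcript, selects by signal score (descending),
#' then nucleotide span (descending), then the ORF finder's tie order.
#'
#' @param transcript one-row transcript data frame or nucleotide string.
#' @param min_nt minimum ORF span.
#' @param predictor signal predictor function.
#' @param cutoffs banding cutoffs.
#' @return list with `orf` (one-row data frame) and `prediction`, or `NULL`
#'   when the transcript has no qualifying ORF.
#' @export
pick_orf_with_best_signal <- function(transcript, min_nt = 75L,
                                      predictor = predict_signal,
                                      cutoffs = signal_cutoffs()) {
  orfs <- find_orfs(transcript, min_nt = min_nt)
  if (nrow(orfs) == 0L) return(NULL)
  preds <- lapply(orfs$peptide, function(p) suppressWarnings(predictor(p, cutoffs)))
  scores <- vapply(preds, function(p) p$score, 0)
  best <- order(-scores, -orfs$span, seq_len(nrow(orfs)))[1]
  list(orf = orfs[best, , drop = FALSE], prediction = preds[[best]])
}

# leader region of a peptide: up to the predicted cleavage site, else the
# first 20 residues
leader_region <- function(peptide, prediction) {
  end <- if (!is.null(prediction) && !is.na(prediction$cleavage_pos))
    prediction$cleavage_pos else min(20L, nchar(peptide))
  substr(peptide, 1L, end)
}

# mature region used for the cysteine scaffold
mature_region <- function(peptide, prediction) {
  if (!is.null(prediction) && !is.na(prediction$cleavage_pos) &&
      prediction$cleavage_pos < nchar(peptide))
    substr(peptide, prediction$cleavage_pos + 1L, nchar(peptide))
  else peptide
}

# global percent identity of two leader peptides
leader_identity <- function(a, b, scheme) {
  hit <- local_align(a, b, scheme, mode = "global")
  hit$identity_pct
}

#' Cluster novel-toxin candidates by scaffold and leader
#'
#' Single-linkage grouping: two candidates link iff their cysteine spacing
#' strings fall in the same class (equal cysteine count, every gap within
#' `scaffold_gap_tol` residues) and the global identity of their
#' signal-peptide regions is at least `leader_identity_min` percent.
#' Ungrouped candidates become singlets.
#'
#' @param candidates data frame with columns `id`, `peptide`, and list
#'   column `prediction` of `signal_prediction` objects (as produced by
#'   [discover_novel_toxins()] internally), plus `coverage`.
#' @param dcfg a [discover_config()].
#' @param scheme protein [scoring_scheme()].
#' @return list of `novelty_cluster` objects (fields `id`, `members`,
#'   `seed_member`).
#' @export
cluster_candidates <- function(candidates, dcfg = discover_config(),
                               scheme = scoring_scheme("protein")) {
  n <- nrow(candidates)
  if (n == 0L) return(list())
  scaffolds <- vapply(seq_len(n), function(i)
    cysteine_pattern(mature_region(candidates$peptide[i],
                                   candidates$prediction[[i]]))$spacing, "")
  leaders <- vapply(seq_len(n), function(i)
    leader_region(candidates$peptide[i], candidates$prediction[[i]]), "")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (!compatible_scaffolds(scaffolds[i], scaffolds[j], dcfg$scaffold_gap_tol))
      next
    if (leader_identity(leaders[i], leaders[j], scheme) <
        dcfg$leader_identity_min) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), roots)
  # deterministic order: by first member's appearance
  groups <- groups[order(vapply(groups, min, 1L))]
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    # seed = highest-coverage member (the originating high-expressed one)
    seed <- idx[order(-candidates$coverage[idx], candidates$id[idx])][1]
    members <- candidates[idx, , drop = FALSE]
    out[[g]] <- structure(list(
      id = sprintf("cluster_%02d", g),
      members = members,
      seed_member = candidates$id[seed],
      scaffold = scaffolds[idx[1]]), class = "novelty_cluster")
  }
  out
}

#' Expand clusters against the pooled telson transcriptomes
#'
#' Each seed transcript is searched (nucleotide mode) against the pooled
#' telson set at `E <= expansion_max_evalue`. Hits are translated through
#' their best-signal ORF and kept only when a signal peptide is present and
#' coverage is strictly above `expansion_min_coverage`; a hit qualifying
#' for several clusters joins the one where its E-value to the seed is
#' best. The seed is never removed, so member counts only grow.
#'
#' @param clusters list of `novelty_cluster` objects.
#' @param pooled data frame of pooled telson transcripts with coverage
#'   computed.
#' @param dcfg a [discover_config()].
#' @param nt_scheme nucleotide [scoring_scheme()].
#' @param min_orf_nt minimum ORF span for translating hits.
#' @export
expand_clusters <- function(clusters, pooled, dcfg = discover_config(),
                            nt_scheme = scoring_scheme("nucleotide"),
                            min_orf_nt = 75L) {
  if (!length(clusters) || nrow(pooled) == 0L) return(clusters)
  seed_seqs <- lapply(clusters, function(cl)
    cl$members[cl$members$id == cl$seed_member, , drop = FALSE])
  all_members <- unlist(lapply(clusters, function(cl) cl$members$id))
  assigned <- list()  # hit id -> (cluster index, evalue)
  for (ci in seq_along(clusters)) {
    seed <- seed_seqs[[ci]]
    if (!"seq" %in% names(seed) || nrow(seed) == 0L) next
    subj <- pooled[!pooled$id %in% all_members, , drop = FALSE]
    if (nrow(subj) == 0L) next
    # pooled sets are small here, so the seed search runs exhaustively:
    # the permissive E <= 1 threshold is exactly where a k-mer prefilter
    # would drop borderline homologs
    hits <- search_db(seed$seq[1], subj, nt_scheme,
                      max_evalue = dcfg$expansion_max_evalue,
                      max_hits = Inf, exhaustive = TRUE,
                      query_id = seed$id[1])
    for (k in seq_len(nrow(hits))) {
      hid <- hits$sseqid[k]
      prev <- assigned[[hid]]
      if (is.null(prev) || hits$evalue[k] < prev$evalue)
        assigned[[hid]] <- list(cluster = ci, evalue = hits$evalue[k])
    }
  }
  for (hid in names(assigned)) {
    ci <- assigned[[hid]]$cluster
    row <- pooled[pooled$id == hid, , drop = FALSE]
    if (row$coverage <= dcfg$expansion_min_coverage) next
    pick <- pick_orf_with_best_signal(row$seq, min_nt = min_orf_nt,
                                      cutoffs = dcfg$signal_cutoffs)
    if (is.null(pick) || !pick$prediction$present) next
    add <- data.frame(id = row$id, seq = row$seq, coverage = row$coverage,
                      peptide = pick$orf$peptide, stringsAsFactors = FALSE)
    add$prediction <- list(pick$prediction)
    keep <- intersect(names(clusters[[ci]]$members), names(add))
    clusters[[ci]]$members <- rbind(clusters[[ci]]$members[, keep, drop = FALSE],
                                    add[, keep, drop = FALSE])
  }
  clusters
}

#' Center-star multiple sequence alignment
#'
#' The center is the peptide maximizing its summed pairwise global
#' alignment scores; every other peptide is aligned to the center pairwise
#' and gaps are merged under the once-a-gap-always-a-gap rule. Removing gap
#' characters from any row reproduces its input peptide.
#'
#' @param peptides at least two amino-acid strings.
#' @param gap_open,gap_extend affine gap costs (defaults 10/1).
#' @param scheme protein [scoring_scheme()]; gap costs above override it.
#' @return character vector of aligned rows (equal width), in input order,
#'   with the center index as attribute `"center"`.
#' @export
center_star_msa <- function(peptides, gap_open = 10, gap_extend = 1,
                            scheme = scoring_scheme("protein")) {
  k <- length(peptides)
  if (k < 2L) stop("center-star MSA needs at least two peptides")
  scheme$gap_open <- gap_open
  scheme$gap_extend <- gap_extend
  scores <- matrix(0, k, k)
  for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    s <- local_align(peptides[i], peptides[j], scheme, mode = "global")$score
    scores[i, j] <- scores[j, i] <- s
  }
  center <- which.max(rowSums(scores))
  master <- strsplit(peptides[center], "", fixed = TRUE)[[1]]
  rows <- list()
  rows[[center]] <- master
  for (i in seq_len(k)) {
    if (i == center) next
    hit <- local_align(peptides[center], peptides[i], scheme, mode = "global")
    ac <- strsplit(hit$aligned_query, "", fixed = TRUE)[[1]]
    ai <- strsplit(hit$aligned_subject, "", fixed = TRUE)[[1]]
    # merge the new pairwise alignment into the master columns
    p <- 1L; q <- 1L
    new_master <- character(0); new_row <- character(0)
    grow_old <- integer(0)  # master columns kept/inserted, 0 = inserted gap
    while (p <= length(master) || q <= length(ac)) {
      if (p <= length(master) && master[p] == "-") {
        # existing gap column from earlier merges
        new_master <- c(new_master, "-"); new_row <- c(new_row, "-")
        grow_old <- c(grow_old, p); p <- p + 1L
      } else if (q <= length(ac) && ac[q] == "-") {
        # new gap opened in the center by this pair
        new_master <- c(new_master, "-"); new_row <- c(new_row, ai[q])
        grow_old <- c(grow_old, 0L); q <- q + 1L
      } else {
        new_master <- c(new_master, master[p]); new_row <- c(new_row, ai[q])
        grow_old <- c(grow_old, p); p <- p + 1L; q <- q + 1L
      }
    }
    # propagate newly inserted gap columns into previously aligned rows
    for (r in seq_along(rows)) {
      if (is.null(rows[[r]]) || r == i) next
      old <- rows[[r]]
      rows[[r]] <- ifelse(grow_old == 0L, "-", old[pmax(grow_old, 1L)])
    }
    master <- new_master
    rows[[i]] <- new_row
  }
  out <- vapply(rows, paste, "", collapse = "")
  attr(out, "center") <- center
  out
}

#' Conserved-residue band of a cluster alignment
#'
#' `f` is the fraction of gap-free alignment columns in which at least
#' `col_identity` of the members share one residue; `high` when
#' `f >= high`, `some` when `some <= f < high`, else `low`. Singlets are
#' banded `high` by the self-comparison convention.
#'
#' @param msa aligned rows from [center_star_msa()], or a single peptide.
#' @param high,some band cutoffs on `f`.
#' @param col_identity per-column agreement threshold.
#' @export
conserved_residue_band <- function(msa, high = 0.5, some = 0.25,
                                   col_identity = 0.8) {
  stopifnot(length(msa) >= 1L)
  if (length(msa) == 1L) return("high")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  nongap <- colSums(m == "-") == 0L
  if (!any(nongap)) return("low")
  f <- mean(apply(m[, nongap, drop = FALSE], 2L, function(col)
    max(table(col)) / length(col) >= col_identity))
  if (f >= high) "high" else if (f >= some) "some" else "low"
}

#' Categorize the best hit of a cluster against known proteins
#'
#' Every member peptide is searched against the known-protein set; the best
#' hit's description is mapped onto a category by keyword rules: a
#' configured family synonym makes it `named_toxin_family_member`;
#' "toxin" or "venom peptide" makes it `named_toxin_or_venom_peptide`;
#' "hypothetical", "uncharacterized", "orphan" or "putative" makes it
#' `hypothetical_or_uncharacterized`; anything else (including an empty
#' known set) is `no_hit`.
#'
#' @param cluster a `novelty_cluster`.
#' @param known data frame of known proteins (`id`, `seq`, `desc`); may
#'   have zero rows.
#' @param dcfg a [discover_config()].
#' @param scheme protein [scoring_scheme()].
#' @return list with `category`, `desc` and `evalue` of the best hit.
#' @export
identify_cluster <- function(cluster, known, dcfg = discover_config(),
                             scheme = scoring_scheme("protein")) {
  if (is.null(known) || nrow(known) == 0L)
    return(list(category = "no_hit", desc = NA_character_, evalue = NA_real_))
  best <- NULL
  for (pep in cluster$members$peptide) {
    h <- search_db(pep, known, scheme, max_evalue = dcfg$known_max_evalue,
                   max_hits = 1L)
    if (nrow(h) && (is.null(best) || h$evalue[1] < best$evalue[1]))
      best <- h[1, ]
  }
  if (is.null(best))
    return(list(category = "no_hit", desc = NA_character_, evalue = NA_real_))
  desc <- known$desc[known$id == best$sseqid[1]]
  if (!length(desc) || is.na(desc)) desc <- best$sseqid[1]
  list(category = hit_category(desc, dcfg$family_synonyms), desc = desc,
       evalue = best$evalue[1])
}

#' Map a hit description to a best-hit category
#'
#' @param desc hit description (or `NA` for no hit).
#' @param family_synonyms keywords naming recognized toxin families.
#' @export
hit_category <- function(desc, family_synonyms = default_family_synonyms()) {
  if (is.na(desc) || !nzchar(desc)) return("no_hit")
  d <- tolower(desc)
  if (any(vapply(tolower(family_synonyms), grepl, TRUE, x = d, fixed = TRUE)))
    return("named_toxin_family_member")
  if (grepl("toxin", d) || grepl("venom peptide", d))
    return("named_toxin_or_venom_peptide")
  if (grepl("hypothetical|uncharacterized|orphan|putative", d))
    return("hypothetical_or_uncharacterized")
  "no_hit"
}

#' Rule-based novelty classification of a cluster
#'
#' Rules applied in order:
#' \enumerate{
#'   \item best hit is a named toxin-family member: new toxins in that
#'     existing family;
#'   \item a conserved C pattern, and the best hit is hypothetical /
#'     uncharacterized, absent, or a named toxin or venom peptide whose
#'     signal band is not high: a novel putative toxin family (a novel
#'     putative toxin for singlets);
#'   \item the best-hit description mentions "antimicrobial": a novel
#'     putative AMP;
#'   \item otherwise (no conserved C pattern but a signal peptide):
#'     a novel putative secreted protein.
#' }
#'
#' @param signal_band `high`/`some`/`low`.
#' @param has_conserved_c_pattern logical.
#' @param best_hit_category one of the [hit_category()] values.
#' @param best_hit_desc description of the best hit (for the AMP keyword);
#'   may be `NA`.
#' @param is_singlet logical.
#' @return one of `new_toxins_in_existing_family`,
#'   `novel_putative_toxin_family`, `novel_putative_toxin`,
#'   `novel_putative_amp`, `novel_putative_secreted_protein`.
#' @export
classify_features <- function(signal_band, has_conserved_c_pattern,
                              best_hit_category, best_hit_desc = NA_character_,
                              is_singlet = FALSE) {
  stopifnot(signal_band %in% c("high", "some", "low"),
            is.logical(has_conserved_c_pattern),
            best_hit_category %in% c("named_toxin_family_member",
                                     "named_toxin_or_venom_peptide",
                                     "hypothetical_or_uncharacterized",
                                     "no_hit"))
  if (best_hit_category == "named_toxin_family_member")
    return("new_toxins_in_existing_family")
  if (has_conserved_c_pattern &&
      (best_hit_category %in% c("hypothetical_or_uncharacterized", "no_hit") ||
       (best_hit_category == "named_toxin_or_venom_peptide" &&
        signal_band != "high")))
    return(if (is_singlet) "novel_putative_toxin" else
      "novel_putative_toxin_family")
  if (!is.na(best_hit_desc) && grepl("antimicrobial", tolower(best_hit_desc)))
    return("novel_putative_amp")
  "novel_putative_secreted_protein"
}

#' Classify a feature-complete cluster
#'
#' @param cluster a `novelty_cluster` whose `features` are set.
#' @export
classify_cluster <- function(cluster) {
  f <- cluster$features
  if (is.null(f)) stop("cluster features are incomplete")
  classify_features(f$signal_band, f$has_conserved_c_pattern,
                    f$best_hit_category, f$best_hit_desc,
                    is_singlet = nrow(cluster$members) == 1L)
}

#' Run the full novel-toxin discovery procedure
#'
#' Selects highly expressed unidentified transcripts, picks each one's
#' best-signal ORF, keeps those with a signal peptide, clusters them by
#' scaffold and leader, expands the clusters against the pooled telson
#' transcriptomes, aligns each cluster, identifies it against the
#' known-protein set and applies the novelty classifier.
#'
#' @param annotation a `venom_annotation` (or its transcript data frame).
#' @param pooled pooled telson transcripts (coverage computed); defaults to
#'   the annotation's own transcript set.
#' @param known known-protein data frame (`id`, `seq`, `desc`); may be
#'   empty or `NULL`.
#' @param dcfg a [discover_config()].
#' @param cfg the [pipeline_config()] used for schemes and ORF length.
#' @return object of class `novelty_screen`: the cluster list (each with
#'   `features`, `msa`, `category`) and a summary data frame.
#' @export
discover_novel_toxins <- function(annotation, pooled = NULL, known = NULL,
                                  dcfg = discover_config(),
                                  cfg = pipeline_config()) {
  tx <- if (inherits(annotation, "venom_annotation"))
    annotation$transcripts else annotation
  if (is.null(pooled)) pooled <- tx
  high <- select_high_expressed_unidentified(tx, dcfg$fraction)
  cands <- list()
  for (i in seq_len(nrow(high))) {
    pick <- pick_orf_with_best_signal(high$seq[i], min_nt = cfg$min_orf_nt,
                                      cutoffs = dcfg$signal_cutoffs)
    if (is.null(pick) || !pick$prediction$present) next
    row <- data.frame(id = high$id[i], seq = high$seq[i],
                      coverage = high$coverage[i],
                      peptide = pick$orf$peptide, stringsAsFactors = FALSE)
    row$prediction <- list(pick$prediction)
    cands[[length(cands) + 1L]] <- row
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else
    data.frame(id = character(0), seq = character(0), coverage = numeric(0),
               peptide = character(0), stringsAsFactors = FALSE)
  clusters <- cluster_candidates(candidates, dcfg, cfg$aa_scheme)
  # transcripts the pipeline already assigned to a toxin family (or "other
  # toxin") are annotated output, not expansion material: novelty clusters
  # grow only from the unannotated remainder of the pool
  expansion_pool <- pooled
  if (!is.null(expansion_pool$label)) {
    claimed <- grepl("^toxin:", expansion_pool$label) |
      expansion_pool$label == "other_toxin"
    expansion_pool <- expansion_pool[!claimed, , drop = FALSE]
  }
  clusters <- expand_clusters(clusters, expansion_pool, dcfg, cfg$nt_scheme,
                              cfg$min_orf_nt)
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    peps <- cl$members$peptide
    cl$msa <- if (length(peps) >= 2L)
      center_star_msa(peps, dcfg$msa_gap_open, dcfg$msa_gap_extend,
                      cfg$aa_scheme)
    else peps
    seed_i <- match(cl$seed_member, cl$members$id)
    seed_pred <- cl$members$prediction[[seed_i]]
    scaffolds <- vapply(seq_len(nrow(cl$members)), function(i)
      cysteine_pattern(mature_region(cl$members$peptide[i],
                                     cl$members$prediction[[i]]))$spacing, "")
    has_c <- if (nrow(cl$members) == 1L) {
      cysteine_pattern(mature_region(peps[1], seed_pred))$bridged
    } else {
      all(vapply(scaffolds, identical, TRUE, scaffolds[1])) &&
        cysteine_pattern(mature_region(peps[1], cl$members$prediction[[1]]))$bridged
    }
    ident <- identify_cluster(cl, known, dcfg, cfg$aa_scheme)
    cl$features <- list(
      signal_band = seed_pred$band,
      has_conserved_c_pattern = has_c,
      conserved_residue_band = conserved_residue_band(
        cl$msa, dcfg$conserved_high, dcfg$conserved_some,
        dcfg$conserved_col_identity),
      best_hit_category = ident$category,
      best_hit_desc = ident$desc,
      best_hit_evalue = ident$evalue)
    cl$category <- classify_cluster(cl)
    clusters[[ci]] <- cl
  }
  summary <- do.call(rbind, c(lapply(clusters, function(cl) data.frame(
    cluster = cl$id, n_members = nrow(cl$members),
    seed = cl$seed_member,
    signal_band = cl$features$signal_band,
    c_pattern = cl$features$has_conserved_c_pattern,
    conserved_residues = cl$features$conserved_residue_band,
    best_hit = ifelse(is.na(cl$features$best_hit_desc), "No Hit",
                      cl$features$best_hit_desc),
    category = cl$category, stringsAsFactors = FALSE)),
    list(data.frame(cluster = character(0), n_members = integer(0),
                    seed = character(0), signal_band = character(0),
                    c_pattern = logical(0), conserved_residues = character(0),
                    best_hit = character(0), category = character(0),
                    stringsAsFactors = FALSE))))
  structure(list(clusters = clusters, summary = summary,
                 n_high_expressed = nrow(high),
                 n_with_signal = nrow(candidates)),
            class = "novelty_screen")
}

#' @export
print.novelty_screen <- function(x, ...) {
  singlets <- sum(x$summary$n_members == 1L)
  cat("novelty_screen:", x$n_high_expressed, "highly expressed unidentified,",
      x$n_with_signal, "with a signal peptide,",
      nrow(x$summary) - singlets, "clusters and", singlets, "singlets\n")
  if (nrow(x$summary)) print(table(x$summary$category))
  invisible(x)
}

#' Write discovery outputs
#'
#' Cluster table (TSV) and one aligned FASTA per cluster.
#'
#' @param x a `novelty_screen`.
#' @param dir output directory.
#' @export
write_novelty_screen <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$summary, file.path(dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (cl in x$clusters) {
    aln <- Biostrings::AAStringSet(setNames(as.character(cl$msa),
                                            cl$members$id))
    Biostrings::writeXStringSet(aln, file.path(dir, paste0(cl$id, ".afa")),
                                width = 60L)
  }
  invisible(dir)
}
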