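# The seven-step telson annotation pipeline: (i) coverage normalization,
# (ii) chela-orthologue subtraction, (iii) ORF prediction, (iv) similarity
# annotation against the labeled reference database, (v) coverage cutoff,
# (vi) orthologue-based relabeling, (vii) signal-peptide validation of
# highly expressed toxins — plus the composition report.

#' Pipeline configuration
#'
#' Defaults follow the study conditions the pipeline was designed for:
#' average read length 150 nt for the coverage formula; orthologue
#' subtraction at E <= 1e-50, identity >= 99\% and query coverage >= 95\%;
#' annotation at E <= 1e-5 with a single best subject; removal of
#' transcripts with coverage lower than 5 (a coverage of exactly 5
#' survives); and a 0.5\% relative-expression threshold for "highly
#' expressed" transcripts.
#'
#' @param avg_read_len average read length used in the coverage formula.
#' @param orthologue_max_evalue,orthologue_min_identity_pct,orthologue_min_query_cov_pct
#'   three thresholds a telson transcript's best chela hit must all satisfy
#'   for the transcript to be removed as an orthologue.
#' @param annotation_max_evalue E-value threshold for database annotation.
#' @param coverage_cutoff transcripts with coverage strictly below this are
#'   removed.
#' @param high_expression_fraction relative-expression threshold defining
#'   "highly expressed" (fraction of total coverage).
#' @param min_orf_nt minimum ORF span for step (iii).
#' @param orthologue_relabel `"strict"` (step (vi) relabels exactly the
#'   transcripts whose chela hit passed all three removal thresholds) or
#'   `"loose"` (surviving transcripts are re-tested with query coverage
#'   recomputed over their best ORF span).
#' @param exhaustive_search disable the k-mer search prefilter.
#' @param nt_scheme,aa_scheme scoring schemes for the two search stages.
#' @param signal_cutoffs banding cutoffs for signal-peptide validation.
#' @param seed integer seed recorded with the run.
#' @export
pipeline_config <- function(avg_read_len = 150L,
                            orthologue_max_evalue = 1e-50,
                            orthologue_min_identity_pct = 99,
                            orthologue_min_query_cov_pct = 95,
                            annotation_max_evalue = 1e-5,
                            coverage_cutoff = 5,
                            high_expression_fraction = 0.005,
                            min_orf_nt = 75L,
                            orthologue_relabel = c("strict", "loose"),
                            exhaustive_search = FALSE,
                            nt_scheme = scoring_scheme("nucleotide"),
                            aa_scheme = scoring_scheme("protein"),
                            signal_cutoffs = venomscan::signal_cutoffs(),
                            seed = 1L) {
  stopifnot(avg_read_len > 0, orthologue_max_evalue > 0,
            orthologue_min_identity_pct > 0, orthologue_min_query_cov_pct > 0,
            annotation_max_evalue > 0, coverage_cutoff >= 0,
            high_expression_fraction > 0, high_expression_fraction < 1)
  structure(list(
    avg_read_len = avg_read_len,
    orthologue_max_evalue = orthologue_max_evalue,
    orthologue_min_identity_pct = orthologue_min_identity_pct,
    orthologue_min_query_cov_pct = orthologue_min_query_cov_pct,
    annotation_max_evalue = annotation_max_evalue,
    coverage_cutoff = coverage_cutoff,
    high_expression_fraction = high_expression_fraction,
    min_orf_nt = min_orf_nt,
    orthologue_relabel = match.arg(orthologue_relabel),
    exhaustive_search = exhaustive_search,
    nt_scheme = nt_scheme, aa_scheme = aa_scheme,
    signal_cutoffs = signal_cutoffs, seed = seed),
    class = "pipeline_config")
}

#' Normalized transcript coverage
#'
#' `coverage = avg_read_len * read_count / transcript_length`, which
#' normalizes the raw read count by transcript size so transcripts are
#' comparable. Vectorized.
#'
#' @param read_count non-negative read count(s).
#' @param transcript_length transcript length(s) in nucleotides, >= 1.
#' @param avg_read_len average read length (default 150).
#' @export
compute_coverage <- function(read_count, transcript_length, avg_read_len = 150L) {
  if (any(transcript_length < 1)) stop("transcript_length must be >= 1")
  if (any(read_count < 0)) stop("read_count must be non-negative")
  avg_read_len * read_count / transcript_length
}

#' Remove telson transcripts with a chela orthologue
#'
#' Each telson transcript is searched against the chela transcriptome
#' (nucleotide mode, best hit only). It is removed iff its best chela hit
#' satisfies all three thresholds (E-value, percent identity, percent query
#' coverage). The orthologue map records every best hit, with a `passed`
#' flag, for the step-(vi) relabeling.
#'
#' @param telson,chela transcript data frames (telson coverage computed).
#' @param cfg a [pipeline_config()].
#' @return list with `kept`, `removed`, `map` (data frame: telson_id,
#'   chela_id, evalue, pident, qcovpct, passed) and the raw `hits` table.
#' @export
remove_chela_orthologues <- function(telson, chela, cfg = pipeline_config()) {
  if (nrow(chela) == 0L) {
    map <- data.frame(telson_id = character(0), chela_id = character(0),
                      evalue = numeric(0), pident = numeric(0),
                      qcovpct = numeric(0), passed = logical(0),
                      stringsAsFactors = FALSE)
    return(list(kept = telson, removed = telson[0, ], map = map,
                hits = empty_hit_table()))
  }
  hits_list <- vector("list", nrow(telson))
  for (i in seq_len(nrow(telson)))
    hits_list[[i]] <- search_db(telson[i, ], chela, cfg$nt_scheme,
                                max_evalue = Inf, max_hits = 1L,
                                exhaustive = cfg$exhaustive_search)
  hits <- do.call(rbind, c(hits_list, list(empty_hit_table())))
  map <- data.frame(telson_id = hits$qseqid, chela_id = hits$sseqid,
                    evalue = hits$evalue, pident = hits$pident,
                    qcovpct = hits$qcovpct,
                    passed = hits$evalue <= cfg$orthologue_max_evalue &
                      hits$pident >= cfg$orthologue_min_identity_pct &
                      hits$qcovpct >= cfg$orthologue_min_query_cov_pct,
                    stringsAsFactors = FALSE)
  removed_ids <- map$telson_id[map$passed]
  list(kept = telson[!telson$id %in% removed_ids, , drop = FALSE],
       removed = telson[telson$id %in% removed_ids, , drop = FALSE],
       map = map, hits = hits)
}

#' Annotate ORF peptides against the reference database
#'
#' Each peptide is searched against the database records (protein mode,
#' best hit only, E-value threshold from the config); the transcript takes
#' the label of its best qualifying hit, or `unidentified` when there is
#' none.
#'
#' @param peptides data frame with `id` and `peptide` columns.
#' @param db a `reference_db`.
#' @param cfg a [pipeline_config()].
#' @return `peptides` with `label`, `best_hit` and `evalue` columns, plus
#'   the hits table as attribute `"hits"`.
#' @export
annotate_against_db <- function(peptides, db, cfg = pipeline_config()) {
  if (is.null(db$records) || nrow(db$records) == 0L)
    stop("reference database is empty")
  labels <- rep("unidentified", nrow(peptides))
  best_hit <- rep(NA_character_, nrow(peptides))
  evalue <- rep(NA_real_, nrow(peptides))
  hits_list <- vector("list", nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    h <- search_db(peptides$peptide[i], db$records, cfg$aa_scheme,
                   max_evalue = cfg$annotation_max_evalue, max_hits = 1L,
                   exhaustive = cfg$exhaustive_search,
                   query_id = peptides$id[i])
    hits_list[[i]] <- h
    if (nrow(h)) {
      labels[i] <- db$records$label[db$records$id == h$sseqid[1]]
      best_hit[i] <- h$sseqid[1]
      evalue[i] <- h$evalue[1]
    }
  }
  peptides$label <- labels
  peptides$best_hit <- best_hit
  peptides$evalue <- evalue
  attr(peptides, "hits") <- do.call(rbind, c(hits_list, list(empty_hit_table())))
  peptides
}

#' Apply the coverage cutoff
#'
#' Transcripts with coverage strictly lower than the cutoff are removed
#' (coverage equal to the cutoff survives).
#'
#' @param transcripts transcript data frame with coverage computed.
#' @param cutoff coverage cutoff (default 5).
#' @return list with `kept` and `dropped`.
#' @export
apply_coverage_cutoff <- function(transcripts, cutoff = 5) {
  stopifnot(!anyNA(transcripts$coverage))
  keep <- transcripts$coverage >= cutoff
  list(kept = transcripts[keep, , drop = FALSE],
       dropped = transcripts[!keep, , drop = FALSE])
}

#' Relabel surviving chela orthologues as physiological
#'
#' Any surviving transcript flagged in the orthologue map is relabeled
#' `physiological` regardless of its database label. Transcripts labeled
#' with a toxin family or as `other_toxin` constitute the venom set.
#'
#' @param transcripts annotated transcript data frame.
#' @param orthologue_map map from [remove_chela_orthologues()].
#' @return `transcripts` with labels finalized and a logical `venom` column.
#' @export
finalize_labels <- function(transcripts, orthologue_map) {
  flagged <- orthologue_map$telson_id[orthologue_map$passed]
  transcripts$label[transcripts$id %in% flagged] <- "physiological"
  transcripts$venom <- grepl("^toxin:", transcripts$label) |
    transcripts$label == "other_toxin"
  transcripts
}

#' Signal-peptide validation of highly expressed toxins
#'
#' For every toxin-labeled transcript whose coverage fraction is at least
#' `fraction`, a signal peptide is predicted on its ORF peptide as advisory
#' validation of the annotation; labels are never changed.
#'
#' @param transcripts annotated transcripts with `peptide` and coverage.
#' @param fraction high-expression threshold (fraction of total coverage).
#' @param predictor function mapping a peptide to a `signal_prediction`.
#' @return data frame: id, label, coverage_fraction, signal score, band,
#'   validated flag.
#' @export
validate_toxin_signals <- function(transcripts, fraction = 0.005,
                                   predictor = predict_signal) {
  total <- sum(transcripts$coverage)
  toxin <- grepl("^toxin:", transcripts$label) |
    transcripts$label == "other_toxin"
  sel <- which(toxin & transcripts$coverage / total >= fraction)
  rows <- lapply(sel, function(i) {
    p <- suppressWarnings(predictor(transcripts$peptide[i]))
    data.frame(id = transcripts$id[i], label = transcripts$label[i],
               coverage_fraction = transcripts$coverage[i] / total,
               signal_score = p$score, signal_band = p$band,
               validated = p$present, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(
    id = character(0), label = character(0), coverage_fraction = numeric(0),
    signal_score = numeric(0), signal_band = character(0),
    validated = logical(0), stringsAsFactors = FALSE))))
}

#' Composition report of an annotated transcriptome
#'
#' Per-label transcript counts plus per-label (and per toxin family)
#' coverage sums and fractions of the total coverage. Fractions sum to 1.
#'
#' @param transcripts annotated transcript data frame.
#' @export
composition_report <- function(transcripts) {
  counts <- table(transcripts$label)
  cov_by_label <- tapply(transcripts$coverage, transcripts$label, sum)
  total_cov <- sum(transcripts$coverage)
  fam_rows <- grepl("^toxin:", transcripts$label)
  fam_cov <- if (any(fam_rows))
    tapply(transcripts$coverage[fam_rows],
           sub("^toxin:", "", transcripts$label[fam_rows]), sum)
  else numeric(0)
  structure(list(
    n_transcripts = nrow(transcripts),
    counts = counts,
    coverage = cov_by_label,
    coverage_fraction = cov_by_label / total_cov,
    family_coverage = fam_cov,
    family_coverage_fraction = fam_cov / total_cov,
    total_coverage = total_cov), class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("Composition of", x$n_transcripts, "annotated transcripts\n")
  for (l in names(x$counts))
    cat(sprintf("  %-28s %5d transcripts  %6.2f%% of expression\n", l,
                x$counts[[l]], 100 * x$coverage_fraction[[l]]))
  invisible(x)
}

#' Run the full annotation pipeline
#'
#' Executes the seven steps in order — coverage (i), orthologue subtraction
#' (ii), ORF prediction (iii, transcripts without a qualifying ORF are
#' dropped), database annotation (iv), coverage cutoff (v), orthologue
#' relabeling (vi), signal validation of highly expressed toxins (vii) —
#' logging the attrition at every step.
#'
#' @param telson,chela transcript data frames ([read_transcripts()]) or
#'   FASTA paths.
#' @param db a `reference_db`.
#' @param cfg a [pipeline_config()].
#' @param telson_counts,chela_counts count sidecar paths when FASTA paths
#'   are given.
#' @return object of class `venom_annotation`: final `transcripts` (with
#'   `label`, `venom`, `peptide`, `best_hit`, `evalue`), the
#'   `composition_report`, `attrition` log, `orthologue_map`, the two hit
#'   tables, the `validation` table and the config.
#' @export
run_pipeline <- function(telson, chela, db, cfg = pipeline_config(),
                         telson_counts = NULL, chela_counts = NULL) {
  if (is.character(telson))
    telson <- read_transcripts(telson, "telson", telson_counts)
  if (is.character(chela))
    chela <- read_transcripts(chela, "chela", chela_counts)
  attrition <- list(input = nrow(telson))

  # (i) coverage normalization
  telson$coverage <- compute_coverage(telson$read_count, telson$length,
                                      cfg$avg_read_len)

  # (ii) chela-orthologue subtraction
  orth <- remove_chela_orthologues(telson, chela, cfg)
  cur <- orth$kept
  attrition$after_orthologue_removal <- nrow(cur)

  # (iii) ORF prediction; transcripts without a qualifying ORF are dropped
  orfs <- lapply(seq_len(nrow(cur)), function(i)
    longest_orf(find_orfs(cur$seq[i], min_nt = cfg$min_orf_nt, id = cur$id[i])))
  has_orf <- !vapply(orfs, is.null, TRUE)
  cur <- cur[has_orf, , drop = FALSE]
  cur$peptide <- vapply(orfs[has_orf], function(o) o$peptide, "")
  cur$orf_span <- vapply(orfs[has_orf], function(o) o$span, 0L)
  attrition$after_orf_prediction <- nrow(cur)

  # (iv) annotation against the labeled database
  ann <- annotate_against_db(cur[, c("id", "peptide")], db, cfg)
  cur$label <- ann$label
  cur$best_hit <- ann$best_hit
  cur$evalue <- ann$evalue
  db_hits <- attr(ann, "hits")

  # (v) coverage cutoff
  cut <- apply_coverage_cutoff(cur, cfg$coverage_cutoff)
  cur <- cut$kept
  attrition$after_coverage_cutoff <- nrow(cur)

  # (vi) orthologue relabeling
  map <- orth$map
  if (cfg$orthologue_relabel == "loose" && nrow(map)) {
    # re-test survivors with query coverage over their best ORF span
    idx <- match(map$telson_id, cur$id)
    span <- cur$orf_span[idx]
    aln_nt <- map$qcovpct / 100 * telson$length[match(map$telson_id, telson$id)]
    orf_cov <- ifelse(is.na(span), NA_real_, pmin(100, 100 * aln_nt / span))
    map$passed <- map$passed | (!is.na(orf_cov) &
      map$evalue <= cfg$orthologue_max_evalue &
      map$pident >= cfg$orthologue_min_identity_pct &
      orf_cov >= cfg$orthologue_min_query_cov_pct)
  }
  cur <- finalize_labels(cur, map)

  # (vii) signal-peptide validation of highly expressed toxins
  validation <- validate_toxin_signals(cur, cfg$high_expression_fraction)

  structure(list(
    transcripts = cur,
    report = composition_report(cur),
    attrition = attrition,
    orthologue_map = map,
    orthologue_hits = orth$hits,
    db_hits = db_hits,
    validation = validation,
    removed_orthologues = orth$removed,
    dropped_low_coverage = cut$dropped,
    cfg = cfg), class = "venom_annotation")
}

#' @export
print.venom_annotation <- function(x, ...) {
  cat("venom_annotation:", x$attrition$input, "telson transcripts in,",
      nrow(x$transcripts), "annotated\n")
  cat("  attrition:",
      paste(names(x$attrition), unlist(x$attrition), sep = "=", collapse = ", "),
      "\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.venom_annotation <- function(object, ...) {
  print(object)
  cat("venom set:", sum(object$transcripts$venom), "transcripts;",
      nrow(object$validation), "highly expressed toxins validated (",
      sum(object$validation$validated), "with a signal peptide )\n")
  invisible(object)
}

#' Write pipeline outputs to a directory
#'
#' Labeled transcript table (TSV), composition report (TSV), attrition log
#' (JSON) and the outfmt-6 hit tables for both search stages.
#'
#' @param x a `venom_annotation`.
#' @param dir output directory.
#' @export
write_annotation <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- x$transcripts
  sig <- x$validation$signal_score[match(tx$id, x$validation$id)]
  out <- data.frame(id = tx$id, length = tx$length,
                    read_count = tx$read_count,
                    coverage = tx$coverage, label = tx$label,
                    best_hit = tx$best_hit, evalue = tx$evalue,
                    signal_score = sig, stringsAsFactors = FALSE)
  write.table(out, file.path(dir, "transcripts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rep <- data.frame(label = names(x$report$counts),
                    n = as.integer(x$report$counts),
                    coverage_fraction =
                      as.numeric(x$report$coverage_fraction[names(x$report$counts)]),
                    stringsAsFactors = FALSE)
  write.table(rep, file.path(dir, "composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x$attrition, file.path(dir, "attrition.json"),
                       auto_unbox = TRUE)
  write_tabular(x$orthologue_hits, file.path(dir, "orthologue_hits.outfmt6"))
  write_tabular(x$db_hits, file.path(dir, "annotation_hits.outfmt6"))
  invisible(dir)
}
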