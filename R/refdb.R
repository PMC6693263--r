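# Construction of the annotated reference protein database: label venom-
# tissue proteins by similarity to toxin-family representatives, then merge
# with the general protein set so every record is physiological, a named
# toxin family, or "other toxin".

#' Read a protein FASTA with key=value header tokens
#'
#' Recognized tokens: `source=general|venom_tissue`, `family=<name>`,
#' `label=<label>`, `desc=...` is not needed — everything after the id that
#' is not a token is kept as the description.
#'
#' @param path protein FASTA.
#' @return data frame with columns `id`, `seq`, `desc` and any token columns
#'   present (`source`, `family`, `label`).
#' @export
read_proteins <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) stop("duplicate protein id: ", ids[duplicated(ids)][1])
  rest <- sub("^\\S+\\s*", "", names(aa))
  out <- data.frame(id = ids, seq = unname(as.character(aa)),
                    stringsAsFactors = FALSE)
  for (tok in c("source", "family", "label")) {
    m <- regmatches(rest, regexpr(sprintf("%s=\\S+", tok), rest))
    if (length(m)) {
      val <- rep(NA_character_, length(ids))
      has <- grepl(sprintf("%s=", tok), rest)
      val[has] <- sub(sprintf("^%s=", tok), "", m)
      out[[tok]] <- val
    }
  }
  out$desc <- trimws(gsub("\\S+=\\S+", "", rest))
  out
}

#' Write proteins to FASTA with key=value header tokens
#'
#' @param proteins data frame with `id`, `seq` and optional `source`,
#'   `family`, `label`, `desc` columns.
#' @param path output path.
#' @export
write_proteins <- function(proteins, path) {
  hdr <- proteins$id
  for (tok in c("source", "family", "label"))
    if (!is.null(proteins[[tok]])) {
      has <- !is.na(proteins[[tok]])
      hdr[has] <- paste0(hdr[has], " ", tok, "=", proteins[[tok]][has])
    }
  if (!is.null(proteins$desc)) {
    has <- !is.na(proteins$desc) & nzchar(proteins$desc)
    hdr[has] <- paste(hdr[has], proteins$desc[has])
  }
  x <- Biostrings::AAStringSet(setNames(proteins$seq, hdr))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Label venom-tissue proteins by their best toxin-family representative
#'
#' Each record is searched against all family representatives; the best hit
#' (ascending E-value, then descending bit score, then ascending family
#' name) with `evalue <= max_evalue` assigns the label `toxin:<family>`.
#' Records with no qualifying hit are labeled `other_toxin`.
#'
#' @param venom_set data frame of venom-tissue proteins (`id`, `seq`).
#' @param representatives data frame with `family` and `seq` columns
#'   (one to four representatives per family).
#' @param max_evalue qualifying E-value threshold (default 0.1).
#' @param scheme protein [scoring_scheme()].
#' @return `venom_set` with a `label` column filled in.
#' @export
label_by_representatives <- function(venom_set, representatives,
                                     max_evalue = 1e-1,
                                     scheme = scoring_scheme("protein")) {
  if (is.null(representatives) || nrow(representatives) == 0L)
    stop("at least one family representative is required")
  n_db <- sum(nchar(representatives$seq))
  labels <- character(nrow(venom_set))
  for (i in seq_len(nrow(venom_set))) {
    best <- NULL
    for (j in seq_len(nrow(representatives))) {
      hit <- local_align(venom_set$seq[i], representatives$seq[j], scheme)
      if (hit$score <= 0) next
      hit <- add_evalue(hit, nchar(venom_set$seq[i]), n_db, scheme)
      if (hit$evalue > max_evalue) next
      fam <- representatives$family[j]
      if (is.null(best) ||
          hit$evalue < best$evalue ||
          (hit$evalue == best$evalue && hit$bit_score > best$bit) ||
          (hit$evalue == best$evalue && hit$bit_score == best$bit &&
           fam < best$family))
        best <- list(evalue = hit$evalue, bit = hit$bit_score, family = fam)
    }
    labels[i] <- if (is.null(best)) "other_toxin" else paste0("toxin:", best$family)
  }
  venom_set$label <- labels
  venom_set
}

#' Merge the general and labeled venom protein sets into a reference database
#'
#' Records present in both sets take the venom-set label; general-only
#' records become `physiological`. Conflicting sequences under one id are an
#' error. The build log records attrition counts per label.
#'
#' @param general_set data frame of general proteins (`id`, `seq`).
#' @param labeled_venom_set output of [label_by_representatives()].
#' @param representatives representatives kept with the database.
#' @return object of class `reference_db` with `records` (every record
#'   labeled), `representatives` and `build_log`.
#' @export
merge_reference_db <- function(general_set, labeled_venom_set,
                               representatives = NULL) {
  stopifnot(!is.null(labeled_venom_set$label))
  shared <- intersect(general_set$id, labeled_venom_set$id)
  for (id in shared) {
    if (general_set$seq[general_set$id == id] !=
        labeled_venom_set$seq[labeled_venom_set$id == id])
      stop("conflicting sequences for protein id ", id)
  }
  gen_only <- general_set[!general_set$id %in% shared, c("id", "seq")]
  if (nrow(gen_only)) gen_only$label <- "physiological"
  ven <- labeled_venom_set[, c("id", "seq", "label")]
  records <- rbind(gen_only[, c("id", "seq", "label")], ven)
  records <- records[order(records$id), , drop = FALSE]
  rownames(records) <- NULL
  fam <- grepl("^toxin:", records$label)
  build_log <- c(
    n_general = nrow(general_set), n_venom = nrow(labeled_venom_set),
    n_records = nrow(records),
    physiological = sum(records$label == "physiological"),
    family_labeled = sum(fam),
    other_toxin = sum(records$label == "other_toxin"))
  per_family <- table(sub("^toxin:", "", records$label[fam]))
  structure(list(records = records, representatives = representatives,
                 build_log = build_log, per_family = per_family),
            class = "reference_db")
}

#' Build a reference database from FASTA inputs
#'
#' Convenience wrapper: reads a reference FASTA whose headers carry
#' `source=general|venom_tissue` tokens and a representatives FASTA with
#' `family=<name>` tokens, labels the venom-tissue subset by similarity and
#' merges.
#'
#' @param reference_path protein FASTA with `source=` tokens.
#' @param representatives_path protein FASTA with `family=` tokens.
#' @param max_evalue representative-match threshold (default 0.1).
#' @param scheme protein [scoring_scheme()].
#' @export
build_reference_db <- function(reference_path, representatives_path,
                               max_evalue = 1e-1,
                               scheme = scoring_scheme("protein")) {
  prot <- read_proteins(reference_path)
  if (is.null(prot$source)) stop("reference FASTA lacks source= header tokens")
  reps <- read_proteins(representatives_path)
  if (is.null(reps$family)) stop("representatives FASTA lacks family= tokens")
  venom <- prot[prot$source == "venom_tissue", , drop = FALSE]
  general <- prot[prot$source == "general", , drop = FALSE]
  venom <- label_by_representatives(venom, reps, max_evalue, scheme)
  merge_reference_db(general, venom, representatives = reps)
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Annotated reference database:", x$build_log[["n_records"]], "records\n")
  cat("  physiological:", x$build_log[["physiological"]],
      " family-labeled:", x$build_log[["family_labeled"]],
      " other toxin:", x$build_log[["other_toxin"]], "\n")
  if (length(x$per_family)) {
    cat("  families:\n")
    for (f in names(x$per_family)) cat("    ", f, ":", x$per_family[[f]], "\n")
  }
  invisible(x)
}

#' Serialize a reference database as FASTA plus a label table
#'
#' @param db a `reference_db`.
#' @param dir output directory (created if needed).
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteins(db$records, file.path(dir, "reference.fasta"))
  write.table(db$records[, c("id", "label")], file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(db$representatives))
    write_proteins(db$representatives, file.path(dir, "representatives.fasta"))
  invisible(dir)
}

#' Read a serialized reference database
#'
#' @param dir directory written by [write_reference_db()].
#' @export
read_reference_db <- function(dir) {
  records <- read_proteins(file.path(dir, "reference.fasta"))
  labels <- read.delim(file.path(dir, "labels.tsv"), stringsAsFactors = FALSE)
  records$label <- labels$label[match(records$id, labels$id)]
  reps_path <- file.path(dir, "representatives.fasta")
  reps <- if (file.exists(reps_path)) read_proteins(reps_path) else NULL
  fam <- grepl("^toxin:", records$label)
  build_log <- c(n_general = NA, n_venom = NA, n_records = nrow(records),
                 physiological = sum(records$label == "physiological"),
                 family_labeled = sum(fam),
                 other_toxin = sum(records$label == "other_toxin"))
  structure(list(records = records[, c("id", "seq", "label")],
                 representatives = reps, build_log = build_log,
                 per_family = table(sub("^toxin:", "", records$label[fam]))),
            class = "reference_db")
}
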