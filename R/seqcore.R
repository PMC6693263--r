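# Sequence records, FASTA I/O, translation, six-frame ORF finding and
# cysteine-scaffold extraction.

FRAME_ORDER <- c(1L, 2L, 3L, -1L, -2L, -3L)

TRANSCRIPT_LABELS <- c("unprocessed", "physiological", "other_toxin", "unidentified")

#' Read an assembled transcriptome from FASTA
#'
#' One record per transcript. Read counts come from a two-column
#' tab-separated sidecar (`transcript_id<TAB>read_count`, header optional)
#' when `counts` is given, otherwise from a `count=<int>` token in the FASTA
#' header. Sequences must be over the alphabet A, C, G, T, N.
#'
#' @param path FASTA file of assembled transcripts.
#' @param tissue `"telson"` (venom gland) or `"chela"` (control).
#' @param counts optional path to the read-count sidecar.
#' @return A data frame with one row per transcript and columns `id`, `seq`,
#'   `length`, `read_count`, `tissue`, `coverage` (`NA` until
#'   [compute_coverage()] runs) and `label` (starts `"unprocessed"`).
#' @export
read_transcripts <- function(path, tissue = c("telson", "chela"), counts = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(file.exists(path))
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      length = integer(0), read_count = integer(0),
                      tissue = character(0), coverage = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  ids <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(ids))
    stop("duplicate transcript id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(dna))
  names(seqs) <- NULL
  bad <- regexpr("[^ACGTN]", seqs)
  if (length(bad) && any(bad > 0)) {
    w <- which(bad > 0)[1]
    stop("non-ACGTN character '", substr(seqs[w], bad[w], bad[w]),
         "' at position ", bad[w], " in transcript ", ids[w])
  }
  if (!is.null(counts)) {
    tab <- read_count_table(counts)
    missing <- setdiff(ids, names(tab))
    if (length(missing))
      stop("transcript id missing from counts table: ", missing[1])
    rc <- unname(tab[ids])
  } else {
    tok <- regmatches(names(dna), regexpr("count=[0-9]+", names(dna)))
    if (length(dna) && length(tok) != length(dna))
      stop("no counts table given and some headers lack a count=<int> token")
    rc <- as.integer(sub("count=", "", tok))
  }
  if (any(rc < 0)) stop("read counts must be non-negative")
  data.frame(id = ids, seq = seqs, length = nchar(seqs),
             read_count = as.integer(rc), tissue = tissue,
             coverage = NA_real_, label = "unprocessed",
             stringsAsFactors = FALSE)
}

read_count_table <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(integer(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("counts table must have two tab-separated columns")
  first <- parts[[1]]
  if (is.na(suppressWarnings(as.integer(first[2])))) parts <- parts[-1]  # header row
  ids <- vapply(parts, `[[`, "", 1L)
  cnt <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(cnt)) stop("non-integer read count in counts table")
  if (anyDuplicated(ids)) stop("duplicate id in counts table: ", ids[duplicated(ids)][1])
  setNames(cnt, ids)
}

#' Write transcripts to FASTA (wrapped at 60 columns) plus a counts sidecar
#'
#' @param transcripts data frame from [read_transcripts()].
#' @param path output FASTA path.
#' @param counts_path optional path for the two-column read-count sidecar.
#' @export
write_transcripts <- function(transcripts, path, counts_path = NULL) {
  x <- Biostrings::DNAStringSet(setNames(transcripts$seq, transcripts$id))
  Biostrings::writeXStringSet(x, path, width = 60L)
  if (!is.null(counts_path))
    write.table(transcripts[, c("id", "read_count")], counts_path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("transcript_id", "read_count"))
  invisible(path)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a nucleotide sequence in one of six frames
#'
#' Standard genetic code; codons containing `N` translate to `X`; stop codons
#' translate to `*`. Negative frames translate the reverse complement.
#' Returns the empty string when fewer than 3 nucleotides remain after the
#' frame offset.
#'
#' @param seq nucleotide string over A, C, G, T, N.
#' @param frame integer in `{1, 2, 3, -1, -2, -3}`.
#' @export
translate_frame <- function(seq, frame = 1L) {
  stopifnot(frame %in% FRAME_ORDER)
  if (frame < 0) seq <- reverse_complement(seq)
  off <- abs(frame) - 1L
  s <- substr(seq, off + 1L, nchar(seq))
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Every ATG paired with its next in-frame stop codon is reported, provided
#' the nucleotide span (stop codon included) is at least `min_nt`. ORFs that
#' reach the end of the transcript without a stop are kept and flagged
#' `open_ended`. Coordinates are 0-based half-open on the forward strand.
#' Results are sorted by descending span, then frame order
#' +1, +2, +3, -1, -2, -3, then ascending start.
#'
#' @param seq nucleotide string (or a one-row transcript data frame).
#' @param min_nt minimum nucleotide span, at least 6 and divisible by 3.
#' @param policy start-codon policy; only `"atg_only"` is supported.
#' @param id transcript id recorded in the result.
#' @return data frame with columns `transcript_id`, `frame`, `nt_start`,
#'   `nt_end`, `span`, `peptide`, `open_ended`.
#' @export
find_orfs <- function(seq, min_nt = 75L, policy = "atg_only", id = NA_character_) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    id <- seq$id
    seq <- seq$seq
  }
  policy <- match.arg(policy, "atg_only")
  stopifnot(min_nt >= 6L, min_nt %% 3L == 0L)
  L <- nchar(seq)
  out <- list()
  for (frame in FRAME_ORDER) {
    pep <- translate_frame(seq, frame)
    if (!nzchar(pep)) next
    npep <- nchar(pep)
    chars <- strsplit(pep, "", fixed = TRUE)[[1]]
    ms <- which(chars == "M")
    if (!length(ms)) next
    stars <- which(chars == "*")
    off <- abs(frame) - 1L
    for (i in ms) {
      j <- stars[stars >= i]
      j <- if (length(j)) j[1] else NA_integer_
      if (!is.na(j)) {
        span <- (j - i + 1L) * 3L
        peptide <- substr(pep, i, j - 1L)
        open_ended <- FALSE
        end_codon <- j
      } else {
        span <- (npep - i + 1L) * 3L
        peptide <- substr(pep, i, npep)
        open_ended <- TRUE
        end_codon <- npep
      }
      if (span < min_nt) next
      sf <- off + 3L * (i - 1L)        # 0-based start on the frame strand
      ef <- off + 3L * end_codon       # 0-based half-open end (incl. stop)
      if (frame > 0) { nt_start <- sf; nt_end <- ef }
      else { nt_start <- L - ef; nt_end <- L - sf }
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = id, frame = frame, nt_start = nt_start,
        nt_end = nt_end, span = span, peptide = peptide,
        open_ended = open_ended, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      nt_start = integer(0), nt_end = integer(0),
                      span = integer(0), peptide = character(0),
                      open_ended = logical(0), stringsAsFactors = FALSE))
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(-orfs$span, match(orfs$frame, FRAME_ORDER), orfs$nt_start), ,
               drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Longest ORF under the documented tie-breaks
#'
#' First element of the [find_orfs()] ordering (descending span, frame order,
#' leftmost start), or `NULL` for an empty set.
#'
#' @param orfs data frame from [find_orfs()].
#' @export
longest_orf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  orfs[1L, , drop = FALSE]
}

#' Cysteine scaffold of a peptide
#'
#' Returns the 0-based positions of cysteine residues, their count, an
#' inter-cysteine spacing string such as `"C-4-C-7-C"`, and whether the
#' peptide can form a disulfide bridge (at least two cysteines).
#'
#' @param peptide non-empty amino-acid string.
#' @export
cysteine_pattern <- function(peptide) {
  stopifnot(is.character(peptide), nzchar(peptide))
  pos1 <- which(strsplit(peptide, "", fixed = TRUE)[[1]] == "C")
  count <- length(pos1)
  spacing <- if (count == 0L) "" else {
    gaps <- diff(pos1) - 1L
    parts <- character(2L * count - 1L)
    parts[seq(1L, by = 2L, length.out = count)] <- "C"
    if (count > 1L) parts[seq(2L, by = 2L, length.out = count - 1L)] <- gaps
    paste(parts, collapse = "-")
  }
  structure(list(positions = pos1 - 1L, count = count, spacing = spacing,
                 bridged = count >= 2L),
            class = "cysteine_pattern")
}

#' Inter-cysteine gap lengths encoded in a spacing string
#'
#' @param spacing a spacing string from [cysteine_pattern()].
#' @return integer vector of gaps (length 0 for 0 or 1 cysteine).
#' @export
spacing_gaps <- function(spacing) {
  if (!nzchar(spacing)) return(integer(0))
  parts <- strsplit(spacing, "-", fixed = TRUE)[[1]]
  as.integer(parts[parts != "C"])
}

# TRUE when two scaffolds fall in the same class: equal cysteine count and
# every corresponding gap differing by at most `tol` residues.
compatible_scaffolds <- function(sp_a, sp_b, tol = 2L) {
  ga <- spacing_gaps(sp_a); gb <- spacing_gaps(sp_b)
  ca <- if (nzchar(sp_a)) sum(strsplit(sp_a, "-")[[1]] == "C") else 0L
  cb <- if (nzchar(sp_b)) sum(strsplit(sp_b, "-")[[1]] == "C") else 0L
  if (ca != cb) return(FALSE)
  if (!length(ga)) return(TRUE)
  all(abs(ga - gb) <= tol)
}
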