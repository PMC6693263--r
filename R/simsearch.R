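# Self-contained local-alignment search engine: affine-gap Smith-Waterman
# with Karlin-Altschul E-values, percent identity and percent query
# coverage, plus a BLAST outfmt-6 compatible tabular writer/reader.

#' Scoring scheme for pairwise alignment and E-value statistics
#'
#' Nucleotide mode uses a match/mismatch matrix (defaults +2/-3) and protein
#' mode a substitution matrix (default BLOSUM62, with `X` scoring 0 against
#' everything). A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#' `lambda` and `K` are the Karlin-Altschul parameters used for bit scores
#' and E-values; the defaults are published gapped values for each scheme
#' (BLOSUM62 gapped: lambda 0.267, K 0.041; +2/-3 gapped: lambda 0.625,
#' K 0.41). E-values are calibrated for this engine's own thresholds; exact
#' parity with other search tools is not a goal.
#'
#' @param kind `"nucleotide"` or `"protein"`.
#' @param match,mismatch nucleotide match/mismatch scores.
#' @param matrix protein substitution matrix name (only `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (defaults 5/2
#'   nucleotide, 11/1 protein).
#' @param lambda,K Karlin-Altschul parameters.
#' @export
scoring_scheme <- function(kind = c("nucleotide", "protein"),
                           match = 2, mismatch = -3, matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  kind <- match.arg(kind)
  if (kind == "nucleotide") {
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
    if (is.null(lambda)) lambda <- 0.625
    if (is.null(K)) K <- 0.41
    ab <- c("A", "C", "G", "T", "N")
    S <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
    diag(S) <- match
    S["N", ] <- 0; S[, "N"] <- 0
  } else {
    matrix <- match.arg(matrix, "BLOSUM62")
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    S <- e$BLOSUM62
    # ambiguous residues never reward a match
    S["X", ] <- 0; S[, "X"] <- 0
  }
  stopifnot(gap_open >= gap_extend, gap_extend >= 1, lambda > 0, K > 0)
  structure(list(kind = kind, matrix = S, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

validate_alphabet <- function(seq, scheme, what = "sequence") {
  ok <- paste(rownames(scheme$matrix), collapse = "")
  bad <- regexpr(sprintf("[^%s]", ok), seq)
  if (bad > 0)
    stop("character '", substr(seq, bad, bad), "' at position ", bad,
         " of ", what, " does not match a ", scheme$kind, " scoring scheme")
  invisible(TRUE)
}

#' Optimal local (or global) pairwise alignment
#'
#' Smith-Waterman under affine gaps; one optimal alignment is returned, with
#' traceback ties resolved by preferring diagonal, then up, then left. A pair
#' with no positive-scoring cell yields score 0 and an empty alignment.
#'
#' @param a,b sequences (a is the query).
#' @param scheme a [scoring_scheme()].
#' @param query_id,subject_id ids recorded on the hit.
#' @param mode `"local"` or `"global"`.
#' @return An object of class `alignment_hit`: raw `score`, `bit_score` and
#'   `evalue` (`NA` until [add_evalue()]), `identity_pct` (identical columns /
#'   alignment columns), `query_cov_pct` (aligned query span / query length),
#'   0-based half-open spans and the gapped aligned strings.
#' @export
local_align <- function(a, b, scheme = scoring_scheme("nucleotide"),
                        query_id = NA_character_, subject_id = NA_character_,
                        mode = c("local", "global")) {
  mode <- match.arg(mode)
  stopifnot(nzchar(a), nzchar(b))
  validate_alphabet(a, scheme, "query")
  validate_alphabet(b, scheme, "subject")
  r <- .align_pair_cpp(a, b, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend, mode == "local")
  qa <- strsplit(r$aligned_a, "", fixed = TRUE)[[1]]
  sa <- strsplit(r$aligned_b, "", fixed = TRUE)[[1]]
  cols <- length(qa)
  ident <- sum(qa == sa & qa != "-")
  gaps <- qa == "-" | sa == "-"
  gap_opens <- sum(diff(c(FALSE, gaps)) == 1L)
  structure(list(
    query_id = query_id, subject_id = subject_id,
    score = r$score, bit_score = NA_real_, evalue = NA_real_,
    identity_pct = if (cols) 100 * ident / cols else 0,
    query_cov_pct = 100 * (r$a_end - r$a_start) / nchar(a),
    q_start = r$a_start, q_end = r$a_end,
    s_start = r$b_start, s_end = r$b_end,
    aligned_query = r$aligned_a, aligned_subject = r$aligned_b,
    n_ident = ident, n_cols = cols,
    n_mismatch = sum(qa != sa & !gaps), n_gap_open = gap_opens,
    query_len = nchar(a)), class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("alignment_hit %s vs %s: score %g, identity %.1f%%, qcov %.1f%%",
              x$query_id, x$subject_id, x$score, x$identity_pct,
              x$query_cov_pct))
  if (!is.na(x$evalue)) cat(sprintf(", E = %.3g", x$evalue))
  cat("\n")
  invisible(x)
}

#' Karlin-Altschul bit score and E-value
#'
#' `bit_score = (lambda * score - ln K) / ln 2`;
#' `evalue = m * n * 2^(-bit_score)` for query length `m` and total database
#' residue count `n`. Both are stored on the hit.
#'
#' @param hit an `alignment_hit`.
#' @param m query length.
#' @param n total database residues.
#' @param scheme the [scoring_scheme()] used for the alignment.
#' @export
add_evalue <- function(hit, m, n, scheme) {
  stopifnot(m >= 1, n >= 1)
  hit$bit_score <- (scheme$lambda * hit$score - log(scheme$K)) / log(2)
  hit$evalue <- m * n * 2^(-hit$bit_score)
  hit
}

# exact shared-k-mer test used by the seeded prefilter; sequences shorter
# than k are never filtered out
shares_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)
  ka <- substring(a, 1:(nchar(a) - k + 1L), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1L), k:nchar(b))
  any(ka %in% kb)
}

#' Search a query against a sequence database
#'
#' Aligns the query to each database record, attaches E-values (with `n` the
#' total residue count of the database), keeps hits with positive score and
#' `evalue <= max_evalue`, sorts by ascending E-value, then descending bit
#' score, then ascending subject id, and truncates to `max_hits`. An exact
#' k-mer prefilter (k = 11 nucleotide, k = 4 protein) skips subjects sharing
#' no seed with the query; `exhaustive = TRUE` disables it.
#'
#' @param query query sequence (character) or a one-row data frame with
#'   `id` and `seq` columns.
#' @param db data frame with `id` and `seq` columns.
#' @param scheme a [scoring_scheme()].
#' @param max_evalue E-value threshold.
#' @param max_hits maximum number of hits returned.
#' @param exhaustive disable the k-mer prefilter.
#' @param query_id id recorded on hits when `query` is a bare string.
#' @return data frame of class `hit_table`, one row per hit.
#' @export
search_db <- function(query, db, scheme = scoring_scheme("nucleotide"),
                      max_evalue = 10, max_hits = 1L, exhaustive = FALSE,
                      query_id = "query") {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1L)
    query_id <- query$id
    query <- query$seq
  }
  stopifnot(is.data.frame(db), nrow(db) >= 1L)
  n_db <- sum(nchar(db$seq))
  m <- nchar(query)
  k <- if (scheme$kind == "nucleotide") 11L else 4L
  rows <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    if (!exhaustive && !shares_kmer(query, db$seq[i], k)) next
    hit <- local_align(query, db$seq[i], scheme,
                       query_id = query_id, subject_id = db$id[i])
    if (hit$score <= 0) next
    hit <- add_evalue(hit, m, n_db, scheme)
    if (hit$evalue > max_evalue) next
    rows[[i]] <- hit_row(hit)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else empty_hit_table()
  out <- out[order(out$evalue, -out$bitscore, out$sseqid), , drop = FALSE]
  out <- head(out, max_hits)
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

hit_row <- function(hit) {
  data.frame(qseqid = hit$query_id, sseqid = hit$subject_id,
             pident = hit$identity_pct, length = hit$n_cols,
             mismatch = hit$n_mismatch, gapopen = hit$n_gap_open,
             qstart = hit$q_start, qend = hit$q_end,
             sstart = hit$s_start, send = hit$s_end,
             evalue = hit$evalue, bitscore = hit$bit_score,
             score = hit$score, qcovpct = hit$query_cov_pct,
             aligned_query = hit$aligned_query,
             aligned_subject = hit$aligned_subject,
             stringsAsFactors = FALSE)
}

empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), score = numeric(0), qcovpct = numeric(0),
             aligned_query = character(0), aligned_subject = character(0),
             stringsAsFactors = FALSE)
}

#' Write hits in BLAST tabular (outfmt 6) format
#'
#' Twelve tab-separated columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore) with 1-based
#' inclusive printed coordinates.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @export
write_tabular <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     hits$qseqid, hits$sseqid, hits$pident, hits$length,
                     hits$mismatch, hits$gapopen,
                     hits$qstart + 1L, hits$qend,
                     hits$sstart + 1L, hits$send,
                     formatC(hits$evalue, format = "g", digits = 3),
                     hits$bitscore)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) file
#'
#' Inverse of [write_tabular()]; internal coordinates are converted back to
#' 0-based half-open.
#'
#' @param path outfmt-6 file.
#' @export
read_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0)
    return(setNames(empty_hit_table()[, cols], cols))
  x <- read.delim(path, header = FALSE, col.names = cols,
                  stringsAsFactors = FALSE)
  x$qstart <- x$qstart - 1L
  x$sstart <- x$sstart - 1L
  x
}
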