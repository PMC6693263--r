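# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations, structured differently from the
# package's aligner and ORF finder, so agreement is meaningful.

rand_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                  collapse = "")

rand_prot_str <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                          n, replace = TRUE), collapse = "")

# --- exhaustive enumeration of every global alignment (linear gaps) -------
# Recursion without memoisation: literally every alignment is visited.
enum_global_score <- function(a, b, S, gap) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(0)
    best <- -Inf
    if (i <= nchar(a) && j <= nchar(b))
      best <- max(best, S[substr(a, i, i), substr(b, j, j)] + rec(i + 1, j + 1))
    if (i <= nchar(a)) best <- max(best, -gap + rec(i + 1, j))
    if (j <= nchar(b)) best <- max(best, -gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# best local score = best global score over all substring pairs (or 0)
enum_local_score <- function(a, b, S, gap) {
  best <- 0
  for (i in seq_len(nchar(a))) for (j in i:nchar(a))
    for (k in seq_len(nchar(b))) for (l in k:nchar(b)) {
      s <- enum_global_score(substr(a, i, j), substr(b, k, l), S, gap)
      if (s > best) best <- s
    }
  best
}

# --- quadratic-time linear-gap local DP (plain R) --------------------------
sw_linear_oracle <- function(a, b, S, gap) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  H <- matrix(0, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n)
    H[i + 1, j + 1] <- max(0, H[i, j] + S[ca[i], cb[j]],
                           H[i, j + 1] - gap, H[i + 1, j] - gap)
  max(H)
}

# --- quadratic-time affine local DP (plain R Gotoh), score only -----------
sw_affine_oracle <- function(a, b, S, open, ext) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + S[ca[i], cb[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(H)
}

# --- brute-force ORF scan --------------------------------------------------
# Works on codon strings directly (never via the package's translator) and
# enumerates every (frame, ATG, next in-frame stop) triple.
orf_oracle <- function(seq, min_nt = 75L) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  revcomp <- chartr("ACGTN", "TGCAN",
                    paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
  rows <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    s <- if (frame > 0) seq else revcomp
    off <- abs(frame) - 1L
    ncod <- (nchar(s) - off) %/% 3L
    if (ncod < 1L) next
    cod <- substring(s, off + 1L + 3L * (0:(ncod - 1L)),
                     off + 3L * (1:ncod))
    starts <- which(cod == "ATG")
    stop_idx <- which(cod %in% stops)
    for (st in starts) {
      nx <- stop_idx[stop_idx >= st]
      if (length(nx)) {
        end <- nx[1]; open_ended <- FALSE
      } else {
        end <- ncod; open_ended <- TRUE
      }
      span <- (end - st + 1L) * 3L
      if (span < min_nt) next
      sf <- off + 3L * (st - 1L)
      ef <- off + 3L * end
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frame,
        nt_start = if (frame > 0) sf else L - ef,
        nt_end = if (frame > 0) ef else L - sf,
        span = span, open_ended = open_ended)
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), span = integer(0),
                      open_ended = logical(0)))
  out <- do.call(rbind, rows)
  out[order(out$frame, out$nt_start), , drop = FALSE]
}

# small shared fixture builders ---------------------------------------------

make_transcripts <- function(ids, seqs, read_counts, tissue = "telson") {
  data.frame(id = ids, seq = seqs, length = nchar(seqs),
             read_count = as.integer(read_counts), tissue = tissue,
             coverage = NA_real_, label = "unprocessed",
             stringsAsFactors = FALSE)
}

# a tiny labeled reference database built in code
make_tiny_refdb <- function() {
  general <- data.frame(id = c("p1", "p2"),
                        seq = c("MDEKRQSTNNLVEEGHRLMDEKRQSTNNLVEEGHRL",
                                "MHHEEDDSSTTQQNNAAGGMHHEEDDSSTTQQNNAA"),
                        stringsAsFactors = FALSE)
  venom <- data.frame(
    id = c("tx1", "ot1"),
    seq = c("MKCIPCFTTDPNMAKKCRDCCGGNGKCFGPQCLCNR",
            "MGLAWLFLVAVLEFSLVAEGGYLLDKYTGLKLDRLA"),
    label = c("toxin:alpha-KTx", "other_toxin"), stringsAsFactors = FALSE)
  merge_reference_db(general, venom)
}

# deterministic back-translation for fixtures: first codon of each residue
make_cds <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(pep, "")[[1]],
               function(a) sort(names(gc)[gc == a])[1], ""), collapse = "")
}
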