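# Signal-peptide prediction. The built-in backend is a transparent
# von-Heijne-style heuristic over the three classical regions of a
# secretion leader (charged n-region, hydrophobic h-region, small-residue
# c-region); an adapter reads predictions produced by an external predictor
# into the same type, so downstream behavior is backend-independent.

# Kyte-Doolittle hydropathy
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0, U = 0, B = -3.5, Z = -3.5, `*` = 0)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T", "V")

#' Signal-peptide banding cutoffs
#'
#' `high` when `score >= high`, `some` when `some <= score < high`, `low`
#' otherwise. A peptide counts as having a signal peptide (`present`) when
#' `score >= presence`.
#'
#' @param high,some band cutoffs.
#' @param presence presence cutoff.
#' @export
signal_cutoffs <- function(high = 0.75, some = 0.45, presence = 0.45) {
  stopifnot(high > some, some > 0, presence > 0)
  list(high = high, some = some, presence = presence)
}

#' Predict an N-terminal signal peptide
#'
#' Heuristic score in \[0, 1\] combining three components with weights
#' 0.2 / 0.5 / 0.3:
#' \itemize{
#'   \item n-region charge: at least one K or R in residues 2-6;
#'   \item h-region hydrophobicity: the best 8-residue window within
#'     residues 3-20 must reach mean Kyte-Doolittle 1.6 (graded above
#'     that, saturating at 3.0);
#'   \item c-region: small residues (A, G, S, C, T, V) at the -3 and -1
#'     positions of a candidate cleavage site within residues 15-35.
#' }
#' The cleavage position is the first qualifying candidate site, and is
#' `NA` when the h-region component fails. Peptides shorter than 15
#' residues score 0. A peptide counts as `present` only when the h-region
#' component fires and the score reaches the presence cutoff: without a
#' hydrophobic core there is no signal peptide, however favorable the
#' flanking regions.
#'
#' @param peptide amino-acid string; should start with M (a warning is
#'   issued otherwise, and the peptide is still scored).
#' @param cutoffs banding cutoffs from [signal_cutoffs()].
#' @return object of class `signal_prediction` with `score`,
#'   `cleavage_pos` (1-based residue after which cleavage occurs, or `NA`),
#'   `band` (`high`/`some`/`low`) and `present`.
#' @export
predict_signal <- function(peptide, cutoffs = signal_cutoffs()) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  if (substr(peptide, 1L, 1L) != "M")
    warning("peptide does not start with M; scored anyway")
  len <- nchar(peptide)
  if (len < 15L)
    return(structure(list(score = 0, cleavage_pos = NA_integer_,
                          band = "low", present = FALSE),
                     class = "signal_prediction"))
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  kd <- unname(KD_SCALE[chars])
  kd[is.na(kd)] <- 0

  # (a) n-region charge
  a <- as.numeric(any(chars[2:min(6L, len)] %in% c("K", "R")))

  # (b) h-region: best 8-residue window inside residues 3..20
  win_starts <- 3:13
  win_starts <- win_starts[win_starts + 7L <= min(20L, len)]
  best_mean <- if (length(win_starts)) {
    max(vapply(win_starts, function(w) mean(kd[w:(w + 7L)]), 0))
  } else -Inf
  b <- if (best_mean < 1.6) 0 else min(1, best_mean / 3.0)

  # (c) c-region: small residues at -3/-1 of a cleavage candidate in 15..35
  cands <- 15:min(35L, len - 1L)
  ok <- cands[chars[cands] %in% SMALL_RESIDUES &
              chars[cands - 2L] %in% SMALL_RESIDUES]
  cc <- as.numeric(length(ok) > 0L)
  cleavage <- if (b > 0 && length(ok)) ok[1] else NA_integer_

  score <- 0.2 * a + 0.5 * b + 0.3 * cc
  # a peptide without a hydrophobic core is not a signal peptide, whatever
  # its flanking regions look like
  structure(list(score = score, cleavage_pos = cleavage,
                 band = band_of(score, cutoffs),
                 present = b > 0 && score >= cutoffs$presence),
            class = "signal_prediction")
}

#' @export
print.signal_prediction <- function(x, ...) {
  cat(sprintf("signal_prediction: score %.2f (%s), cleavage after residue %s\n",
              x$score, x$band,
              if (is.na(x$cleavage_pos)) "-" else x$cleavage_pos))
  invisible(x)
}

#' Qualitative band of a signal-peptide score
#'
#' @param score real in \[0, 1\].
#' @param cutoffs banding cutoffs from [signal_cutoffs()].
#' @return `"high"`, `"some"` or `"low"`.
#' @export
band_of <- function(score, cutoffs = signal_cutoffs()) {
  if (is.na(score) || score < 0 || score > 1)
    stop("signal score must lie in [0, 1]")
  if (score >= cutoffs$high) "high"
  else if (score >= cutoffs$some) "some"
  else "low"
}

#' Import external signal-peptide predictions
#'
#' Adapter for an external predictor's output: a tab-separated file
#' `id<TAB>score<TAB>cleavage_pos` (header optional, cleavage_pos may be NA)
#' is parsed into `signal_prediction` objects, so the pipeline behaves
#' identically whichever backend produced the scores.
#'
#' @param path tab-separated predictions file.
#' @param cutoffs banding cutoffs from [signal_cutoffs()].
#' @return named list of `signal_prediction` objects.
#' @export
read_signal_predictions <- function(path, cutoffs = signal_cutoffs()) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (is.na(suppressWarnings(as.numeric(parts[[1]][2])))) parts <- parts[-1]
  out <- list()
  for (p in parts) {
    score <- as.numeric(p[2])
    cleav <- suppressWarnings(as.integer(p[3]))
    out[[p[1]]] <- structure(
      list(score = score, cleavage_pos = cleav,
           band = band_of(score, cutoffs),
           present = score >= cutoffs$presence),
      class = "signal_prediction")
  }
  out
}
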