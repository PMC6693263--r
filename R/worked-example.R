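# Worked example: feature annotations for the 24 candidate clusters and
# singlets reported in a six-species scorpion venom-gland survey, shipped
# as a plain-text table so the novelty classifier can be exercised on real
# published feature rows.

#' Published cluster feature rows
#'
#' Feature annotations (best-hit description, signal-peptide band,
#' conserved-C-pattern flag, conserved-residue band) for 24 candidate
#' clusters and singlets from a six-species scorpion venom-gland survey,
#' together with the category each was given. `"N.A."` cells in the
#' original table are transcribed as `low` bands; the C-pattern flag
#' follows the table's own footnote marker for a conserved cysteine
#' pattern, which is authoritative where it contradicts the cell text.
#'
#' @param path the TSV to load; defaults to the copy shipped with the
#'   package.
#' @return data frame with columns `name`, `best_hit_desc`, `signal_band`,
#'   `c_pattern`, `conserved_band`, `published_category` and `is_singlet`.
#' @export
cluster_feature_rows <- function(path = system.file(
  "extdata", "scorpion_cluster_features.tsv", package = "venomscan")) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$c_pattern <- as.logical(x$c_pattern)
  x$is_singlet <- grepl("^Singlet", x$name)
  x
}

#' Classify a table of cluster feature rows
#'
#' Applies [classify_features()] to each row of a feature table such as
#' [cluster_feature_rows()].
#'
#' @param features data frame with `signal_band`, `c_pattern`,
#'   `best_hit_desc` and `is_singlet` columns.
#' @param family_synonyms keywords naming recognized toxin families.
#' @return `features` with a `category` column appended.
#' @export
classify_feature_table <- function(features,
                                   family_synonyms = default_family_synonyms()) {
  features$category <- vapply(seq_len(nrow(features)), function(i) {
    desc <- features$best_hit_desc[i]
    if (identical(desc, "No Hit")) desc <- NA_character_
    classify_features(
      signal_band = features$signal_band[i],
      has_conserved_c_pattern = features$c_pattern[i],
      best_hit_category = hit_category(desc, family_synonyms),
      best_hit_desc = desc,
      is_singlet = isTRUE(features$is_singlet[i]))
  }, "")
  features
}
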