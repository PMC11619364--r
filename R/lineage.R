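#' The taxonomic rank ladder, most specific first
#'
#' All concordance and host-range logic walks this fixed seven-rank ladder.
#' `species` is the lowest (most specific) rank and sits at index 1;
#' `superkingdom` is the highest.
#'
#' @return A character vector:
#'   `c("species", "genus", "family", "order", "class", "phylum", "superkingdom")`.
#' @export
#' @examples
#' rank_ladder()
rank_ladder <- function() {
  c("species", "genus", "family", "order", "class", "phylum", "superkingdom")
}

#' Normalize a species name to its binomial
#'
#' Host species names in sequence databases frequently embed the strain
#' designation ("Escherichia coli K-12 MG1655"). For species-level comparison
#' only the first two whitespace-separated tokens are kept; single-token names
#' pass through unchanged. The function is idempotent and vectorized.
#'
#' @param x Character vector of raw species names. `NA` values propagate.
#' @return Character vector of normalized binomials.
#' @export
#' @examples
#' normalize_species_name("Escherichia coli K-12 MG1655")
#' normalize_species_name(c("uncultured bacterium", "Bacillus"))
normalize_species_name <- function(x) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of species names.")
  }
  if (any(!is.na(x) & !nzchar(trimws(x)))) {
    abort("Malformed taxonomy row: empty species name.")
  }
  x <- stringr::str_squish(x)
  tokens <- stringr::str_split(x, stringr::fixed(" "))
  vapply(tokens, function(tk) {
    if (length(tk) == 1L && is.na(tk[1L])) return(NA_character_)
    paste(head(tk, 2L), collapse = " ")
  }, character(1))
}

#' Flag species names whose normalized binomial is low-confidence
#'
#' Single-token names (no epithet) and "Candidatus" names (whose first two
#' tokens are "Candidatus" plus the genus, not a true binomial) are flagged so
#' that downstream species-level comparisons can be audited.
#'
#' @param x Character vector of raw species names.
#' @return Logical vector, `TRUE` where the normalized name is low-confidence.
#' @export
species_name_low_confidence <- function(x) {
  x <- stringr::str_squish(x)
  n_tokens <- stringr::str_count(x, stringr::fixed(" ")) + 1L
  single <- !is.na(x) & n_tokens == 1L
  cand <- !is.na(x) & stringr::str_detect(x, stringr::regex("^candidatus\\b",
                                                            ignore_case = TRUE))
  single | cand
}

#' Detect "uncultured" reported hosts
#'
#' Plasmids deposited with an uncultured reported host (e.g. "uncultured
#' bacterium") can never be concordant at any rank; they are flagged rather
#' than dropped so non-concordant predictions can be broken down by this flag.
#'
#' @param species Character vector of species names.
#' @return Logical vector.
#' @export
is_uncultured_host <- function(species) {
  !is.na(species) &
    stringr::str_detect(species, stringr::regex("uncultured", ignore_case = TRUE))
}

lineage_cols <- function() rev(rank_ladder())  # superkingdom ... species

#' Read a taxonomic lineage table
#'
#' A lineage table is a TSV with an `accession` column, the seven canonical
#' rank columns (`superkingdom` ... `species`) and an optional `strain`
#' column. Lines starting with `#` are ignored. Extra rank columns (suborder,
#' etc.) are dropped; missing canonical columns are added as `NA`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `accession`, `superkingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`, `strain`.
#' @export
read_lineages <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"accession" %in% names(df)) {
    abort(paste0("Lineage table ", path, " lacks an `accession` column."))
  }
  for (cl in c(lineage_cols(), "strain")) {
    if (!cl %in% names(df)) df[[cl]] <- NA_character_
  }
  as_tibble(df)[, c("accession", lineage_cols(), "strain")]
}

#' Write a taxonomic lineage table
#'
#' @param lineages Tibble as returned by [read_lineages()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  readr::write_tsv(lineages[, c("accession", lineage_cols(), "strain")], path)
  invisible(path)
}

#' Check a lineage table for rank inconsistencies
#'
#' In a well-formed taxonomy, two records that agree at a rank must also agree
#' at every rank above it: a genus belongs to exactly one family, a family to
#' one order, and so on. Dirty taxonomies (one child taxon under two parents)
#' are reported rather than silently used, because they can fabricate or mask
#' concordance.
#'
#' @param lineages A lineage tibble (see [read_lineages()]).
#' @return A tibble of violations with columns `rank`, `taxon`,
#'   `parent_rank`, `parents` (comma-separated). Zero rows means clean.
#' @export
validate_lineages <- function(lineages) {
  ladder <- rank_ladder()
  out <- purrr::map_dfr(seq_len(length(ladder) - 1L), function(i) {
    child <- ladder[i]
    parent <- ladder[i + 1L]
    pairs <- lineages %>%
      filter(!is.na(.data[[child]]), !is.na(.data[[parent]])) %>%
      distinct(.data[[child]], .data[[parent]])
    bad <- pairs %>%
      group_by(.data[[child]]) %>%
      filter(n() > 1L) %>%
      summarise(parents = paste(sort(.data[[parent]]), collapse = ","),
                .groups = "drop")
    if (nrow(bad) == 0L) return(tibble())
    tibble(rank = child, taxon = bad[[child]],
           parent_rank = parent, parents = bad$parents)
  })
  if (nrow(out) > 0L) {
    warn(sprintf("Lineage table has %d rank inconsistency(ies).", nrow(out)))
  }
  out
}
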