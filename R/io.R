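#' Read plasmid sequences from FASTA
#'
#' The accession is the first whitespace-separated token of each header.
#' Sequences are uppercased.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A tibble with columns `accession`, `sequence`.
#' @export
read_plasmid_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(
    accession = stringr::str_split_i(names(ss), "\\s+", 1L),
    sequence = unname(toupper(as.character(ss)))
  )
}

#' Write plasmid sequences to FASTA
#'
#' @param plasmids Tibble with columns `accession`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plasmid_fasta <- function(plasmids, path) {
  ss <- Biostrings::DNAStringSet(setNames(plasmids$sequence, plasmids$accession))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read spacers from FASTA with `spacerID|sourceAccession` headers
#'
#' @param path Path to a spacer FASTA file whose headers are
#'   `spacer_id|source_accession`.
#' @return A tibble with columns `spacer_id`, `sequence`, `source_accession`.
#' @export
read_spacer_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- stringr::str_split_i(names(ss), "\\s+", 1L)
  parts <- stringr::str_split_fixed(hdr, stringr::fixed("|"), 2L)
  if (any(!nzchar(parts[, 2L]))) {
    abort("Spacer FASTA headers must be of the form `spacerID|sourceAccession`.")
  }
  tibble(
    spacer_id = parts[, 1L],
    sequence = unname(toupper(as.character(ss))),
    source_accession = parts[, 2L]
  )
}

#' Read / write a spacer table
#'
#' The TSV carries `spacer_id`, `sequence`, `source_accession`.
#'
#' @param path Path to a TSV file.
#' @return `read_spacers_tsv()`: a tibble; `write_spacers_tsv()`: `path`,
#'   invisibly.
#' @export
read_spacers_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character())) %>%
    mutate(sequence = toupper(.data$sequence))
}

#' @rdname read_spacers_tsv
#' @param spacers Tibble with columns `spacer_id`, `sequence`,
#'   `source_accession`.
#' @export
write_spacers_tsv <- function(spacers, path) {
  readr::write_tsv(spacers[, c("spacer_id", "sequence", "source_accession")], path)
  invisible(path)
}

hit_cols <- function() {
  c("plasmid_accession", "spacer_id", "spacer_source_accession",
    "start0", "end0", "strand", "match_length", "mismatches",
    "identity", "evalue")
}

#' Read / write a spacer-hit table
#'
#' Hit tables use 0-based half-open coordinates on the plasmid forward strand
#' and a fixed column order so that outputs diff cleanly.
#'
#' @param path Path to a TSV file.
#' @return `read_hits_tsv()`: a tibble of hits; `write_hits_tsv()`: `path`,
#'   invisibly.
#' @export
read_hits_tsv <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      start0 = readr::col_integer(), end0 = readr::col_integer(),
      match_length = readr::col_integer(), mismatches = readr::col_integer(),
      identity = readr::col_double(), evalue = readr::col_double(),
      .default = readr::col_character()
    )
  )
}

#' @rdname read_hits_tsv
#' @param hits Tibble of hits as produced by [scan_plasmids()].
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(hits[, hit_cols()], path)
  invisible(path)
}

feature_cols <- function() {
  c("accession", "feature_type", "start1", "end1", "strand",
    "feature_id", "product", "go_function")
}

#' Read a plasmid feature table
#'
#' Flat TSV of per-plasmid feature annotations with 1-based inclusive
#' coordinates (`start1`, `end1`), as in GenBank feature tables. Internally
#' hits are compared against these features after conversion to 0-based
#' half-open (`start0 = start1 - 1`, `end0 = end1`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `accession`, `feature_type`, `start1`,
#'   `end1`, `strand`, `feature_id`, `product`, `go_function`.
#' @export
read_features_tsv <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      start1 = readr::col_integer(), end1 = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  for (cl in feature_cols()) if (!cl %in% names(df)) df[[cl]] <- NA_character_
  as_tibble(df)[, feature_cols()]
}

#' @rdname read_features_tsv
#' @param features Feature tibble.
#' @export
write_features_tsv <- function(features, path) {
  readr::write_tsv(features[, feature_cols()], path)
  invisible(path)
}

#' Read plasmid features from GFF3
#'
#' GFF3 coordinates are 1-based inclusive, matching the flat TSV dialect.
#' The feature id is taken from the `ID` attribute and the product from the
#' `product` attribute when present.
#'
#' @param path Path to a GFF3 file.
#' @return A feature tibble (see [read_features_tsv()]).
#' @export
read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Reading GFF3 requires the rtracklayer package.")
  }
  g <- rtracklayer::readGFF(path)
  tibble(
    accession = as.character(g$seqid),
    feature_type = as.character(g$type),
    start1 = as.integer(g$start),
    end1 = as.integer(g$end),
    strand = as.character(g$strand),
    feature_id = if ("ID" %in% names(g)) as.character(g$ID) else NA_character_,
    product = if ("product" %in% names(g)) as.character(g$product) else NA_character_,
    go_function = if ("Ontology_term" %in% names(g)) {
      vapply(g$Ontology_term, function(x) paste(x, collapse = ","), character(1))
    } else NA_character_
  )
}

#' Read a two-column label table (MOB status or PTU membership)
#'
#' @param path Path to a TSV with columns `accession` and either `mob`
#'   (values `MOB+` / `MOB-`) or `ptu`.
#' @return A tibble.
#' @export
read_mob_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  bad <- setdiff(unique(df$mob), c("MOB+", "MOB-"))
  if (length(bad) > 0L) {
    abort(paste0("Unknown MOB label(s): ", paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname read_mob_tsv
#' @export
read_ptu_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
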