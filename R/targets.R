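target_categories <- function() {
  c("FUNCTION_UNKNOWN", "TRANSPOSON_ASSOCIATED", "PLASMID_BACKBONE",
    "POTENTIAL_BACKBONE", "GENERAL_FUNCTIONAL")
}

#' Default product-name lexicon for target categorization
#'
#' Keyword (regular-expression) lists mapping feature product names to the
#' five target categories: function-unknown names (hypothetical proteins,
#' DUFs, `nan` placeholders), transposon-associated genes (transposases,
#' IS-element integrases), plasmid backbone genes (conjugation, replication
#' control, partitioning, toxin-antitoxin addiction systems), potential
#' backbone genes (general DNA-modifying, methylation and
#' restriction/anti-restriction functions), and general functional genes
#' (everything else). Patterns are matched case-insensitively in priority
#' order `FUNCTION_UNKNOWN`, `TRANSPOSON_ASSOCIATED`, `PLASMID_BACKBONE`,
#' `POTENTIAL_BACKBONE`, `GENERAL_FUNCTIONAL`; putting transposons before
#' backbone keeps "transposase" from being misfiled however plasmid-like the
#' rest of the product string looks.
#'
#' The lexicon is configuration, not code: edit a copy or load your own with
#' [read_lexicon()].
#'
#' @return A named list of regular-expression vectors, in priority order.
#' @export
default_lexicon <- function() {
  list(
    FUNCTION_UNKNOWN = c(
      "hypothetical protein", "\\bDUF\\d*", "domain of unknown function",
      "^nan$", "uncharacteri[sz]ed", "unknown function"
    ),
    TRANSPOSON_ASSOCIATED = c(
      "transposase", "transposon", "integrase", "insertion sequence",
      "\\bIS\\d+", "resolvase"
    ),
    PLASMID_BACKBONE = c(
      "conjuga", "\\btra[A-Z]\\b", "\\btrb[A-Z]\\b", "type IV secretion",
      "relaxase", "mobili[sz]ation", "\\bmob[A-Z]\\b",
      "replication initiat", "replication control", "replication protein",
      "\\brep[A-Z]\\b", "copy number", "\\bcop[A-Z]\\b", "plasmid replication",
      "partition", "\\bpar[A-Z]\\b", "plasmid stabili[sz]ation",
      "toxin-antitoxin", "antitoxin", "\\btoxin\\b", "addiction",
      "post-?segregational killing"
    ),
    POTENTIAL_BACKBONE = c(
      "methyltransferase", "methylation", "methylase",
      "restriction", "anti-restriction", "endonuclease", "exonuclease",
      "\\bnuclease\\b", "helicase", "topoisomerase", "primase",
      "recombinase", "DNA[- ]binding", "single-strand(ed)? DNA",
      "\\bssb\\b", "DNA repair", "DNA process"
    ),
    GENERAL_FUNCTIONAL = c(
      "ATPase", "ribosom", "phage", "metabol", "dehydrogenase", "kinase",
      "transport", "permease", "reductase", "synthase", "synthetase",
      "transferase", "regulator", "membrane protein"
    )
  )
}

#' Read / write a categorization lexicon
#'
#' The on-disk form is a TSV with columns `category`, `pattern`; category
#' priority follows first appearance.
#'
#' @param path Path to a lexicon TSV.
#' @return `read_lexicon()`: a named list of pattern vectors;
#'   `write_lexicon()`: `path`, invisibly.
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  bad <- setdiff(unique(df$category), target_categories())
  if (length(bad) > 0L) {
    abort(paste0("Unknown lexicon category(ies): ", paste(bad, collapse = ", ")))
  }
  split(df$pattern, factor(df$category, levels = unique(df$category)))
}

#' @rdname read_lexicon
#' @param lexicon A named list of pattern vectors.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- tibble(category = rep(names(lexicon), lengths(lexicon)),
               pattern = unlist(lexicon, use.names = FALSE))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Categorize feature product names
#'
#' Assigns each product name to exactly one of the five target categories by
#' first match in lexicon priority order. Empty or missing names are
#' `FUNCTION_UNKNOWN`. Names matching no pattern fall back to
#' `GENERAL_FUNCTIONAL` and are flagged as lexicon misses so the fallback is
#' auditable.
#'
#' @param name Character vector of product names.
#' @param lexicon A lexicon (named list of regex vectors), by default
#'   [default_lexicon()].
#' @return A character vector of categories with a logical attribute
#'   `lexicon_miss` of the same length.
#' @export
#' @examples
#' categorize_feature(c("hypothetical protein", "IS6 family transposase",
#'                      "conjugal transfer protein TraG"))
categorize_feature <- function(name, lexicon = default_lexicon()) {
  out <- rep(NA_character_, length(name))
  miss <- rep(FALSE, length(name))
  blank <- is.na(name) | !nzchar(trimws(name))
  out[blank] <- "FUNCTION_UNKNOWN"
  for (cat in names(lexicon)) {
    rx <- paste0("(", paste(lexicon[[cat]], collapse = ")|("), ")")
    hit <- is.na(out) & stringr::str_detect(name, stringr::regex(rx, ignore_case = TRUE))
    out[hit] <- cat
  }
  unmatched <- is.na(out)
  out[unmatched] <- "GENERAL_FUNCTIONAL"
  miss[unmatched] <- TRUE
  attr(out, "lexicon_miss") <- miss
  out
}

#' Locate hits within annotated features
#'
#' A hit is annotated with the feature whose interval fully contains it
#' ("within", not mere overlap); a hit straddling a feature boundary is
#' unannotated. When several features contain a hit, the shortest (most
#' specific) wins; ties resolve to the lowest start.
#'
#' @param hits A hit tibble.
#' @param features A feature tibble (1-based inclusive coordinates; see
#'   [read_features_tsv()]).
#' @param rule Either `"within"` (default, full containment) or
#'   `"any"` (any overlap).
#' @return The hits with appended columns `feature_type`, `feature_id`,
#'   `product`, `go_function` (`NA` for unannotated hits).
#' @export
annotate_hits <- function(hits, features, rule = c("within", "any")) {
  rule <- match.arg(rule)
  feats <- features %>%
    mutate(start0 = .data$start1 - 1L, end0 = .data$end1,
           .feature_row = row_number())
  ann_cols <- c("feature_type", "feature_id", "product", "go_function")
  if (nrow(hits) == 0L) {
    out <- hits
    for (cl in ann_cols) out[[cl]] <- character()
    return(out)
  }
  per_plasmid <- hits %>%
    mutate(.hit_row = row_number()) %>%
    group_by(.data$plasmid_accession) %>%
    dplyr::group_map(function(h, key) {
      f <- feats %>% filter(.data$accession == key$plasmid_accession[1L])
      if (nrow(f) == 0L) return(tibble(.hit_row = h$.hit_row))
      hr <- IRanges::IRanges(start = h$start0 + 1L, end = h$end0)
      fr <- IRanges::IRanges(start = f$start0 + 1L, end = f$end0)
      ov <- IRanges::findOverlaps(hr, fr, type = if (rule == "within") "within" else "any")
      if (length(ov) == 0L) return(tibble(.hit_row = h$.hit_row))
      cand <- tibble(
        .hit_row = h$.hit_row[S4Vectors::queryHits(ov)],
        .feature_row = f$.feature_row[S4Vectors::subjectHits(ov)],
        .width = f$end0[S4Vectors::subjectHits(ov)] - f$start0[S4Vectors::subjectHits(ov)],
        .start = f$start0[S4Vectors::subjectHits(ov)]
      ) %>%
        arrange(.data$.hit_row, .data$.width, .data$.start) %>%
        distinct(.data$.hit_row, .keep_all = TRUE)
      tibble(.hit_row = h$.hit_row) %>%
        left_join(cand, by = ".hit_row")
    }) %>%
    bind_rows()
  if (!".feature_row" %in% names(per_plasmid)) {
    per_plasmid$.feature_row <- NA_integer_
  }
  hits %>%
    mutate(.hit_row = row_number()) %>%
    left_join(per_plasmid, by = ".hit_row") %>%
    left_join(feats[, c(".feature_row", ann_cols)], by = ".feature_row") %>%
    select(-dplyr::any_of(c(".hit_row", ".feature_row", ".width", ".start")))
}

#' Feature-ID frequencies among annotated hits
#'
#' @param annotated_hits Output of [annotate_hits()].
#' @param top_n Optionally keep only the `top_n` most frequent feature IDs
#'   (`Inf` keeps all).
#' @return A tibble `feature_id`, `n`, `rel_freq` sorted by descending
#'   count (ties by feature id); relative frequencies sum to 1 over all
#'   annotated hits before any `top_n` cut.
#' @export
feature_frequencies <- function(annotated_hits, top_n = Inf) {
  ann <- annotated_hits %>% filter(!is.na(.data$feature_id))
  if (nrow(ann) == 0L) {
    return(tibble(feature_id = character(), n = integer(), rel_freq = double()))
  }
  out <- ann %>%
    count(.data$feature_id, name = "n") %>%
    mutate(rel_freq = .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n), .data$feature_id)
  if (is.finite(top_n)) out <- head(out, top_n)
  out
}

#' Categorize annotated hits
#'
#' @param annotated_hits Output of [annotate_hits()].
#' @param lexicon A categorization lexicon.
#' @return `annotated_hits` with `category` and `lexicon_miss` columns
#'   (`NA` category for unannotated hits). Features of type `repeat` with a
#'   missing ID are `nan` placeholders and categorize as
#'   `FUNCTION_UNKNOWN`.
#' @export
categorize_hits <- function(annotated_hits, lexicon = default_lexicon()) {
  ann <- !is.na(annotated_hits$feature_id) | !is.na(annotated_hits$feature_type)
  nm <- annotated_hits$product
  nm[!is.na(annotated_hits$feature_type) &
       annotated_hits$feature_type == "repeat" &
       (is.na(nm) | nm == "nan")] <- "nan"
  cats <- categorize_feature(nm, lexicon)
  out <- annotated_hits
  out$category <- ifelse(ann, as.character(cats), NA_character_)
  out$lexicon_miss <- ifelse(ann, attr(cats, "lexicon_miss"), NA)
  out
}

#' Category summary of targeted features
#'
#' Two breakdowns of the annotated CRISPR targets: (a) across all five
#' categories including unknown-function targets, and (b) across the four
#' known-function categories only (the usual reporting denominator), whose
#' percentages sum to 100 up to rounding.
#'
#' @param categorized_hits Output of [categorize_hits()].
#' @return A tibble of class `category_summary` with columns `category`,
#'   `n`, `pct_all`, `pct_known` (1 decimal; `NA` for `FUNCTION_UNKNOWN`
#'   in the known-function column). If every annotated target is unknown, a
#'   warning is raised and `pct_known` is all `NA`.
#' @export
category_summary <- function(categorized_hits) {
  ann <- categorized_hits %>% filter(!is.na(.data$category))
  tab <- table(factor(ann$category, levels = target_categories()))
  n <- as.integer(tab)
  known <- target_categories() != "FUNCTION_UNKNOWN"
  n_known <- sum(n[known])
  if (nrow(ann) > 0L && n_known == 0L) {
    warn("All annotated targets have unknown function; known-function percentages are undefined.")
  }
  out <- tibble(
    category = target_categories(),
    n = n,
    pct_all = if (nrow(ann) > 0L) round(100 * n / nrow(ann), 1) else rep(NA_real_, 5L),
    pct_known = ifelse(known & n_known > 0L, round(100 * n / n_known, 1), NA_real_)
  )
  class(out) <- c("category_summary", class(out))
  out
}

#' Hits falling within mobile-element features
#'
#' Flags hits contained in a feature of type `mobile_element` (annotated IS
#' elements) regardless of which feature annotated them, and reports the
#' distinct plasmids they come from. Spacer matches inside IS elements are
#' the main suspected source of spurious host assignments.
#'
#' @param hits A hit tibble.
#' @param features A feature tibble.
#' @return The flagged hits; the distinct plasmid accessions are in
#'   `attr(x, "plasmid_accessions")`.
#' @export
flag_mobile_element_hits <- function(hits, features) {
  me <- features %>% filter(.data$feature_type == "mobile_element")
  if (nrow(me) == 0L || nrow(hits) == 0L) {
    out <- hits[0, , drop = FALSE]
    attr(out, "plasmid_accessions") <- character()
    return(out)
  }
  flagged <- annotate_hits(hits, me) %>% filter(!is.na(.data$feature_type))
  out <- flagged[, names(hits), drop = FALSE]
  attr(out, "plasmid_accessions") <- sort(unique(flagged$plasmid_accession))
  out
}
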