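#' Attach predicted-host lineages to hits
#'
#' Joins each hit to the lineage of the strain its spacer came from; that
#' strain is the predicted host the hit nominates.
#'
#' @param hits A hit tibble (after [remove_self_hits()]).
#' @param lineages Lineage tibble keyed by `accession` (see
#'   [read_lineages()]) covering the spacer source strains.
#' @return The hits with a `host_accession` column plus the seven rank
#'   columns and `strain` of the predicted host. Hits whose source strain has
#'   no lineage row are dropped with a warning.
#' @export
add_predicted_lineages <- function(hits, lineages) {
  joined <- hits %>%
    mutate(host_accession = .data$spacer_source_accession) %>%
    left_join(lineages, by = c(host_accession = "accession"))
  missing <- is.na(joined$superkingdom) & is.na(joined$species)
  if (any(missing)) {
    warn(sprintf("Dropping %d hit(s) whose source strain has no lineage.",
                 sum(missing)))
    joined <- joined[!missing, , drop = FALSE]
  }
  joined
}

#' Per-plasmid predicted host sets
#'
#' Reduces hits to the unique (plasmid, host accession) pairs that define the
#' predicted host set of each matched plasmid.
#'
#' @param hits_with_lineages Output of [add_predicted_lineages()].
#' @return A tibble with one row per (plasmid, predicted host) pair:
#'   `plasmid_accession`, `host_accession`, the rank columns and `strain`.
#' @export
predict_hosts <- function(hits_with_lineages) {
  hits_with_lineages %>%
    distinct(.data$plasmid_accession, .data$host_accession,
             .keep_all = TRUE) %>%
    select(dplyr::all_of(c("plasmid_accession", "host_accession",
                           lineage_cols(), "strain")))
}

#' Best-match concordance rank for one plasmid
#'
#' Returns the most specific (lowest) rank at which the reported host lineage
#' agrees with at least one predicted host lineage, walking the ladder from
#' species to superkingdom. Species are compared as normalized binomials.
#' A missing rank value never matches anything, including another missing
#' value.
#'
#' @param reported A one-row tibble (or named list) with the rank columns of
#'   the reported host.
#' @param predicted A tibble of predicted host lineages (rank columns).
#' @return A single rank name, or `NA_character_` if the lineages disagree
#'   even at superkingdom.
#' @export
best_match_rank <- function(reported, predicted) {
  if (is.null(nrow(predicted)) || nrow(predicted) == 0L) {
    abort("`predicted` must be non-empty (unmatched plasmids have no rank).")
  }
  for (r in rank_ladder()) {
    rep_val <- as.character(reported[[r]])[1L]
    pred_val <- predicted[[r]]
    if (r == "species") {
      rep_val <- if (!is.na(rep_val)) normalize_species_name(rep_val) else rep_val
      pred_val <- ifelse(is.na(pred_val), NA_character_,
                         normalize_species_name(pred_val))
    }
    if (!is.na(rep_val) && any(!is.na(pred_val) & pred_val == rep_val)) {
      return(r)
    }
  }
  NA_character_
}

#' Concordance of predictions with the reported hosts
#'
#' Computes, for every matched plasmid, the lowest taxonomic rank at which
#' its reported host agrees with any predicted host, and flags plasmids whose
#' reported host is "uncultured" (those can never be concordant and may be
#' read as novel predictions rather than mismatches).
#'
#' @param predictions Output of [predict_hosts()].
#' @param reported_lineages Lineage tibble keyed by plasmid `accession`
#'   giving each plasmid's reported host lineage.
#' @return A tibble with columns `plasmid_accession`, `best_match_rank`
#'   (`NA` = no agreement at any rank) and `uncultured` (logical).
#' @export
concordance <- function(predictions, reported_lineages) {
  ladder <- rank_ladder()
  joined <- predictions %>%
    left_join(reported_lineages, by = c(plasmid_accession = "accession"),
              suffix = c("", ".reported"))
  # per-rank agreement, vectorized over all (plasmid, host) pairs
  agree <- purrr::map(ladder, function(r) {
    pred_val <- joined[[r]]
    rep_val <- joined[[paste0(r, ".reported")]]
    if (r == "species") {
      pred_val <- ifelse(is.na(pred_val), NA, normalize_species_name(pred_val))
      rep_val <- ifelse(is.na(rep_val), NA, normalize_species_name(rep_val))
    }
    !is.na(pred_val) & !is.na(rep_val) & pred_val == rep_val
  })
  names(agree) <- ladder
  joined$.best <- NA_integer_
  for (i in rev(seq_along(ladder))) {
    joined$.best[agree[[ladder[i]]]] <- i
  }
  joined %>%
    group_by(.data$plasmid_accession) %>%
    summarise(
      best_match_rank = if (all(is.na(.data$.best))) NA_character_ else
        rank_ladder()[min(.data$.best, na.rm = TRUE)],
      uncultured = any(is_uncultured_host(.data$species.reported)),
      .groups = "drop"
    )
}

#' Per-rank concordance counts and percentages
#'
#' For each rank, counts the plasmids whose best-match rank is at or below
#' it (cumulative up the ladder) and expresses the count as a percentage of
#' matched plasmids and, when `n_total` is given, of all plasmids in the
#' database. Percentages are rounded to one decimal. A final `none` row
#' counts plasmids with no agreement at any rank.
#'
#' @param conc Output of [concordance()], one row per matched plasmid.
#' @param n_total Total number of plasmids in the database (defaults to the
#'   number of matched plasmids); must be `>= nrow(conc)`.
#' @return A tibble of class `concordance_table` with columns `rank`, `n`
#'   (per-rank count), `n_cumulative`, `pct_matched`, `pct_total`. The
#'   uncultured share among non-concordant plasmids is in
#'   `attr(x, "none_uncultured")`.
#' @export
concordance_table <- function(conc, n_total = NULL) {
  n_matched <- nrow(conc)
  n_total <- n_total %||% n_matched
  if (n_total < n_matched) {
    abort("`n_total` must be at least the number of matched plasmids.")
  }
  ladder <- rank_ladder()
  rk <- factor(conc$best_match_rank, levels = ladder)
  per_rank <- as.integer(table(rk))
  n_none <- sum(is.na(rk))
  cum <- cumsum(per_rank)
  out <- tibble(
    rank = c(ladder, "none"),
    n = c(per_rank, n_none),
    n_cumulative = c(cum, n_none),
    pct_matched = round(100 * c(cum, n_none) / n_matched, 1),
    pct_total = round(100 * c(cum, n_none) / n_total, 1)
  )
  n_unc <- sum(is.na(rk) & conc$uncultured)
  attr(out, "none_uncultured") <- tibble(
    n_none = n_none, n_uncultured = n_unc,
    pct_uncultured = if (n_none > 0L) round(100 * n_unc / n_none, 1) else NA_real_
  )
  class(out) <- c("concordance_table", class(out))
  out
}

#' Consolidate predicted hosts to species per plasmid
#'
#' Unique (plasmid, host accession) pairs are collapsed by normalized species
#' binomial, so different isolates/strains of one species count once.
#'
#' @param predictions Output of [predict_hosts()].
#' @return A tibble with one row per plasmid: `plasmid_accession`,
#'   `n_species`, and `species` (a list-column of the distinct normalized
#'   binomials).
#' @export
consolidate_species <- function(predictions) {
  predictions %>%
    distinct(.data$plasmid_accession, .data$host_accession, .keep_all = TRUE) %>%
    mutate(species_norm = ifelse(is.na(.data$species), NA_character_,
                                 normalize_species_name(.data$species))) %>%
    distinct(.data$plasmid_accession, .data$species_norm) %>%
    group_by(.data$plasmid_accession) %>%
    summarise(n_species = dplyr::n(),
              species = list(sort(.data$species_norm)), .groups = "drop")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summary of consolidated species counts
#'
#' @param consolidated Output of [consolidate_species()].
#' @return A one-row tibble: `mean` (2 decimals), `sd` (population standard
#'   deviation, 2 decimals), `max`, and `max_accessions` (comma-separated
#'   plasmids attaining the maximum).
#' @export
species_per_plasmid_summary <- function(consolidated) {
  x <- consolidated$n_species
  tibble(
    mean = round(mean(x), 2),
    sd = round(pop_sd(x), 2),
    max = max(x),
    max_accessions = paste(
      sort(consolidated$plasmid_accession[x == max(x)]), collapse = ","
    )
  )
}

#' Distribution of hits per matched plasmid
#'
#' Quartiles use linear interpolation between closest ranks (R's default
#' quantile type 7); the standard deviation is the population convention.
#'
#' @param hits A non-empty hit tibble.
#' @return A one-row tibble: `mean`, `sd`, `p25`, `p50`, `p75`, `max`,
#'   `max_accession`.
#' @export
hits_per_plasmid_summary <- function(hits) {
  if (nrow(hits) == 0L) abort("`hits` must be non-empty.")
  counts <- hits %>% count(.data$plasmid_accession)
  q <- quantile(counts$n, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    mean = mean(counts$n), sd = pop_sd(counts$n),
    p25 = q[1], p50 = q[2], p75 = q[3],
    max = max(counts$n),
    max_accession = counts$plasmid_accession[which.max(counts$n)]
  )
}
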