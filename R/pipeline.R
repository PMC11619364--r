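#' Run the full host-prediction pipeline
#'
#' Chains every stage: spacer indexing, both-strand scanning with E-value
#' filtering, self-hit removal, predicted-host lineage assignment, species
#' consolidation, concordance with reported hosts, host-range grading,
#' MOB-stratified grade distribution, target annotation/categorization (when
#' features are given) and bipartite network construction with pruning.
#'
#' @param plasmids Tibble `accession`, `sequence` (see
#'   [read_plasmid_fasta()]).
#' @param spacers Tibble `spacer_id`, `sequence`, `source_accession`.
#' @param lineages Lineage tibble covering spacer source strains and plasmid
#'   reported hosts (see [read_lineages()]).
#' @param mob,ptu,features Optional label, PTU and feature tables.
#' @param params A [match_params()] object.
#' @param lexicon Categorization lexicon (default [default_lexicon()]).
#' @param min_plasmids Family-pruning threshold for the network (default 10).
#' @return An object of class `host_prediction`: a list with elements
#'   `hits`, `predictions`, `consolidated`, `concordance`,
#'   `concordance_table`, `grades`, `grade_distribution`, `network`,
#'   `network_pruned`, and (with features) `categorized_hits`,
#'   `category_summary`, plus a `counts` tibble reconciling records kept and
#'   dropped at each stage. Explore with [tidy()], [glance()], `print()` and
#'   [autoplot()].
#' @export
run_host_prediction <- function(plasmids, spacers, lineages,
                                mob = NULL, ptu = NULL, features = NULL,
                                params = match_params(),
                                lexicon = default_lexicon(),
                                min_plasmids = 10L) {
  index <- build_spacer_index(spacers)
  hits_all <- scan_plasmids(plasmids, index, params)
  hits <- remove_self_hits(hits_all)
  n_self <- attr(hits, "n_self_removed")

  hwl <- add_predicted_lineages(hits, lineages)
  predictions <- predict_hosts(hwl)
  consolidated <- consolidate_species(predictions)
  conc <- concordance(predictions, lineages)
  conc_tab <- concordance_table(conc, n_total = nrow(plasmids))
  grades <- assign_grades(predictions)
  grade_dist <- grade_distribution(grades, mob = mob)

  net <- build_family_network(predictions)
  net_pruned <- prune_isolated_families(net, min_plasmids = min_plasmids)

  out <- list(
    hits = hits, predictions = predictions, consolidated = consolidated,
    concordance = conc, concordance_table = conc_tab,
    grades = grades, grade_distribution = grade_dist,
    network = net, network_pruned = net_pruned,
    params = params,
    counts = tibble(
      n_plasmids = nrow(plasmids), n_spacers_input = nrow(spacers),
      n_spacers_indexed = attr(index, "load_report")$n_indexed,
      n_hits_raw = nrow(hits_all), n_self_removed = n_self,
      n_hits = nrow(hits),
      n_matched_plasmids = n_distinct(hits$plasmid_accession),
      n_uncultured_reported = sum(conc$uncultured)
    )
  )
  if (!is.null(ptu)) {
    ptu_pred <- collapse_to_ptu(predictions, ptu)
    out$ptu_network <- build_family_network(ptu_pred, unit_col = "ptu",
                                            unit_class = "PTU")
  }
  if (!is.null(features)) {
    cat_hits <- categorize_hits(annotate_hits(hits, features), lexicon)
    out$categorized_hits <- cat_hits
    out$category_summary <- category_summary(cat_hits)
    out$mobile_element_hits <- flag_mobile_element_hits(hits, features)
  }
  structure(out, class = "host_prediction")
}

#' @export
print.host_prediction <- function(x, ...) {
  cnt <- x$counts
  cat("<host_prediction>\n")
  cat(sprintf("  %d / %d plasmids matched (%.1f%%), %d hits (%d self-hits removed)\n",
              cnt$n_matched_plasmids, cnt$n_plasmids,
              100 * cnt$n_matched_plasmids / cnt$n_plasmids,
              cnt$n_hits, cnt$n_self_removed))
  fam <- x$concordance_table
  cat(sprintf("  concordance: species %.1f%%, family %.1f%%, phylum %.1f%% of matched\n",
              fam$pct_matched[fam$rank == "species"],
              fam$pct_matched[fam$rank == "family"],
              fam$pct_matched[fam$rank == "phylum"]))
  mg <- attr(x$grade_distribution, "mean_grade")
  cat(sprintf("  mean host-range grade: %.2f\n",
              mg$mean_grade[mg$group == "all"]))
  invisible(x)
}

#' Per-plasmid tidy summary of a host prediction
#'
#' @param x A `host_prediction` object.
#' @param ... Unused.
#' @return A tibble with one row per matched plasmid: `plasmid_accession`,
#'   `n_hits`, `n_species`, `species` (comma-separated normalized
#'   binomials), `best_match_rank`, `uncultured`, `grade`.
#' @method tidy host_prediction
#' @export
tidy.host_prediction <- function(x, ...) {
  x$hits %>%
    count(.data$plasmid_accession, name = "n_hits") %>%
    left_join(x$consolidated %>%
                mutate(species = purrr::map_chr(.data$species, paste,
                                                collapse = ",")),
              by = "plasmid_accession") %>%
    left_join(x$concordance, by = "plasmid_accession") %>%
    left_join(x$grades %>% select("plasmid_accession", "grade"),
              by = "plasmid_accession")
}

#' One-row summary of a host prediction
#'
#' @param x A `host_prediction` object.
#' @param ... Unused.
#' @return A one-row tibble: plasmid/hit counts, percentage matched, mean
#'   hits and species per matched plasmid, species/family/phylum
#'   concordance percentages and the mean host-range grade.
#' @method glance host_prediction
#' @export
glance.host_prediction <- function(x, ...) {
  cnt <- x$counts
  ct <- x$concordance_table
  mg <- attr(x$grade_distribution, "mean_grade")
  hs <- hits_per_plasmid_summary(x$hits)
  ss <- species_per_plasmid_summary(x$consolidated)
  tibble(
    n_plasmids = cnt$n_plasmids,
    n_matched = cnt$n_matched_plasmids,
    pct_matched = round(100 * cnt$n_matched_plasmids / cnt$n_plasmids, 1),
    n_hits = cnt$n_hits,
    n_self_removed = cnt$n_self_removed,
    mean_hits = round(hs$mean, 2),
    mean_species = ss$mean,
    pct_species = ct$pct_matched[ct$rank == "species"],
    pct_family = ct$pct_matched[ct$rank == "family"],
    pct_phylum = ct$pct_matched[ct$rank == "phylum"],
    mean_grade = mg$mean_grade[mg$group == "all"]
  )
}
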