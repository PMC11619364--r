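grade_levels <- function() c("I", "II", "III", "IV", "V", "VI")

#' Host-range grade of one predicted host set
#'
#' Grades follow the six-grade scale of Redondo-Salvo et al.: the grade is
#' set by the highest taxonomic rank at which the predicted hosts differ.
#' Hosts differing only at species level (or a single host, or several hits
#' from the exact same species) give grade I; spanning two or more genera
#' gives II, families III, orders IV, classes V, and phyla VI.
#'
#' A plasmid whose host set needs a rank that is missing from a lineage
#' cannot be graded honestly and returns `NA` with a reason (guessing would
#' silently inflate broad grades).
#'
#' @param predicted A tibble of predicted host lineages (rank columns), one
#'   row per host; must be non-empty.
#' @return A length-1 character grade (`"I"`..`"VI"`), or `NA_character_`
#'   with attribute `reason` when grading is impossible.
#' @export
#' @examples
#' assign_grade(tibble::tibble(
#'   superkingdom = "Bacteria", phylum = "Pseudomonadota",
#'   class = "Gammaproteobacteria", order = "Enterobacterales",
#'   family = "Enterobacteriaceae", genus = "Escherichia",
#'   species = "Escherichia coli"
#' ))
assign_grade <- function(predicted) {
  if (is.null(nrow(predicted)) || nrow(predicted) == 0L) {
    abort("`predicted` must be non-empty.")
  }
  sp <- ifelse(is.na(predicted$species), NA_character_,
               normalize_species_name(predicted$species))
  if (nrow(predicted) == 1L ||
      (!anyNA(sp) && n_distinct(sp) == 1L)) {
    return("I")
  }
  deciding <- c("genus", "family", "order", "class", "phylum")
  for (r in deciding) {
    if (anyNA(predicted[[r]])) {
      out <- NA_character_
      attr(out, "reason") <- paste0("missing ", r)
      return(out)
    }
  }
  if (n_distinct(predicted$phylum) >= 2L) return("VI")
  if (n_distinct(predicted$class) >= 2L) return("V")
  if (n_distinct(predicted$order) >= 2L) return("IV")
  if (n_distinct(predicted$family) >= 2L) return("III")
  if (n_distinct(predicted$genus) >= 2L) return("II")
  "I"
}

#' Host-range grades for all matched plasmids
#'
#' @param predictions Output of [predict_hosts()].
#' @return A tibble with columns `plasmid_accession`, `grade` (ordered
#'   factor `I < ... < VI`, `NA` when ungradable), `grade_num` (1-6) and
#'   `excluded_reason`.
#' @export
assign_grades <- function(predictions) {
  predictions %>%
    tidyr::nest(.by = "plasmid_accession", .key = "hosts") %>%
    mutate(
      .g = purrr::map(.data$hosts, assign_grade),
      grade = factor(purrr::map_chr(.data$.g, 1L),
                     levels = grade_levels(), ordered = TRUE),
      grade_num = as.integer(.data$grade),
      excluded_reason = purrr::map_chr(
        .data$.g, function(g) attr(g, "reason") %||% NA_character_
      )
    ) %>%
    select("plasmid_accession", "grade", "grade_num", "excluded_reason")
}

#' Grade distribution, overall and by plasmid mobility
#'
#' Counts and percentages of each host-range grade among graded plasmids,
#' overall and (when MOB labels are supplied) within MOB+ and MOB- plasmids,
#' plus the mean numeric grade per group.
#'
#' @param grades Output of [assign_grades()]; ungradable plasmids are
#'   excluded with a message.
#' @param mob Optional tibble with columns `accession`, `mob`
#'   (`"MOB+"`/`"MOB-"`). Plasmids without a label are counted only in the
#'   overall group.
#' @return A tibble of class `grade_distribution` with columns `group`,
#'   `grade`, `n`, `pct` (1 decimal). Mean grades per group (2 decimals) are
#'   in `attr(x, "mean_grade")`.
#' @export
grade_distribution <- function(grades, mob = NULL) {
  graded <- grades %>% filter(!is.na(.data$grade))
  n_excl <- nrow(grades) - nrow(graded)
  if (n_excl > 0L) {
    inform(sprintf("Excluding %d ungradable plasmid(s) from the distribution.",
                   n_excl))
  }
  groups <- list(all = graded)
  if (!is.null(mob)) {
    labelled <- graded %>%
      left_join(mob, by = c(plasmid_accession = "accession")) %>%
      filter(!is.na(.data$mob))
    groups <- c(groups, split(labelled, labelled$mob))
  }
  out <- purrr::imap_dfr(groups, function(df, nm) {
    tab <- table(factor(df$grade, levels = grade_levels()))
    tibble(group = nm, grade = factor(grade_levels(), levels = grade_levels(),
                                      ordered = TRUE),
           n = as.integer(tab),
           pct = round(100 * as.integer(tab) / nrow(df), 1))
  })
  attr(out, "mean_grade") <- purrr::imap_dfr(groups, function(df, nm) {
    tibble(group = nm, n = nrow(df), mean_grade = round(mean(df$grade_num), 2))
  })
  class(out) <- c("grade_distribution", class(out))
  out
}

#' Mobility enrichment within a host-range grade
#'
#' Two-sided Fisher's exact test for over-representation of one mobility
#' class within a grade, on the 2x2 table (in grade vs not) x (MOB- vs
#' MOB+).
#'
#' @param in_grade Length-2 integer vector `c(mob_minus, mob_plus)` counts
#'   inside the grade.
#' @param out_grade Length-2 integer vector of the same counts outside the
#'   grade.
#' @return A one-row tibble: `odds_ratio` (conditional MLE), `p_value`,
#'   `method`. If any table margin is zero the test is undefined and
#'   `p_value = 1` is returned with a warning.
#' @export
mob_enrichment_test <- function(in_grade, out_grade) {
  tab <- rbind(as.integer(in_grade), as.integer(out_grade))
  if (any(tab < 0) || any(is.na(tab))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("A table margin is zero; the enrichment test is undefined (p = 1).")
    return(tibble(odds_ratio = NA_real_, p_value = 1,
                  method = "Fisher's exact test (two-sided)"))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
         method = "Fisher's exact test (two-sided)")
}
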