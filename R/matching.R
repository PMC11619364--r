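#' Karlin-Altschul parameters for ungapped nucleotide E-values
#'
#' The matcher filters hits with an ungapped Karlin-Altschul expectation,
#' `E = K * m * n * exp(-lambda * S)`, where `S` is the alignment score under
#' a match/mismatch scheme, `m` the total database (plasmid) length and `n`
#' the query (spacer) length. Defaults use the published ungapped parameters
#' for +1/-2 scoring (`lambda = 1.33`, `K = 0.621`).
#'
#' @param match_score Positive integer score per matching base.
#' @param mismatch_penalty Positive integer penalty per mismatching base
#'   (applied with a negative sign).
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme; both
#'   must be positive.
#' @return An object of class `evalue_params`.
#' @export
evalue_params <- function(match_score = 1L, mismatch_penalty = 2L,
                          lambda = 1.33, K = 0.621) {
  stopifnot(match_score > 0, mismatch_penalty > 0, lambda > 0, K > 0)
  structure(list(match_score = match_score, mismatch_penalty = mismatch_penalty,
                 lambda = lambda, K = K),
            class = "evalue_params")
}

#' Ungapped Karlin-Altschul E-value for a spacer hit
#'
#' @param match_length Number of aligned columns (the spacer length in
#'   full-length mode). Vectorized.
#' @param mismatches Number of mismatching columns, `0 <= mismatches <=
#'   match_length`. Vectorized.
#' @param db_length Total length of the searched plasmid database, in bases.
#'   `0` (an empty database) gives `E = 0`; negative values error.
#' @param query_length Query length `n`; defaults to `match_length`.
#' @param params An [evalue_params()] object.
#' @return Numeric vector of E-values; monotone decreasing in `match_length`
#'   at fixed `mismatches`.
#' @export
#' @examples
#' evalue(30, 0, db_length = 1e4)
evalue <- function(match_length, mismatches, db_length,
                   query_length = match_length, params = evalue_params()) {
  if (any(db_length < 0)) abort("`db_length` must be non-negative.")
  if (any(query_length <= 0)) abort("`query_length` must be positive.")
  if (any(mismatches < 0) || any(mismatches > match_length)) {
    abort("`mismatches` must satisfy 0 <= mismatches <= match_length.")
  }
  S <- params$match_score * (match_length - mismatches) -
    params$mismatch_penalty * mismatches
  params$K * db_length * query_length * exp(-params$lambda * S)
}

#' Matching parameters
#'
#' Matching is always ungapped and full-spacer-length: a hit is a contiguous
#' window of the plasmid, on either strand, whose Hamming identity to the
#' whole spacer is at least `identity`. Gapped alignment is deliberately not
#' supported.
#'
#' @param identity Minimum fraction of identical columns over the full spacer
#'   length, in `(0, 1]`. At `1` (the default) hits are exact.
#' @param min_match_length Minimum spacer length to search; spacers shorter
#'   than this are skipped (matching itself is always over the full spacer).
#'   `NULL` (default) searches every spacer.
#' @param evalue_max Maximum E-value for a hit to be kept (default `1e-5`).
#' @param both_strands Search the reverse complement as well (default `TRUE`).
#' @param circular Treat plasmids as circular by also scanning windows that
#'   span the sequence origin (default `FALSE`, i.e. sequences are scanned as
#'   deposited). Origin-spanning hits report `end0 > plasmid length`.
#' @param scoring An [evalue_params()] object.
#' @return An object of class `match_params`.
#' @export
match_params <- function(identity = 1, min_match_length = NULL,
                         evalue_max = 1e-5, both_strands = TRUE,
                         circular = FALSE, scoring = evalue_params()) {
  stopifnot(identity > 0, identity <= 1, evalue_max >= 0)
  structure(list(identity = identity, min_match_length = min_match_length,
                 evalue_max = evalue_max, both_strands = both_strands,
                 circular = circular, scoring = scoring,
                 allow_gaps = FALSE),
            class = "match_params")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Build a multi-pattern spacer index
#'
#' Validates and indexes a set of spacers for simultaneous search in both
#' orientations. Spacers containing characters outside `A/C/G/T` are skipped
#' with a warning and counted in the load report (ambiguity codes never
#' match). Duplicate spacer sequences from different source strains are all
#' retained and all reported by the scan.
#'
#' @param spacers Tibble with columns `spacer_id`, `sequence`,
#'   `source_accession`. `spacer_id` must be unique.
#' @return An object of class `spacer_index`. The load report (input, indexed
#'   and skipped counts) is available via `attr(x, "load_report")`.
#' @export
build_spacer_index <- function(spacers) {
  stopifnot(all(c("spacer_id", "sequence", "source_accession") %in% names(spacers)))
  if (nrow(spacers) == 0L) abort("`spacers` must be non-empty.")
  if (anyDuplicated(spacers$spacer_id)) {
    abort("`spacer_id` values must be unique within a dataset.")
  }
  seqs <- toupper(spacers$sequence)
  ok <- !is.na(seqs) & nzchar(seqs) & !stringr::str_detect(seqs, "[^ACGT]")
  if (any(!ok)) {
    warn(sprintf("Skipping %d spacer(s) with non-ACGT characters: %s",
                 sum(!ok),
                 paste(head(spacers$spacer_id[!ok], 5L), collapse = ", ")))
  }
  tbl <- tibble(
    spacer_id = spacers$spacer_id[ok],
    sequence = seqs[ok],
    source_accession = spacers$source_accession[ok],
    width = nchar(seqs[ok])
  )
  tbl$rc_sequence <- revcomp(tbl$sequence)
  tbl$palindromic <- tbl$sequence == tbl$rc_sequence
  structure(
    list(spacers = tbl),
    load_report = tibble(n_input = nrow(spacers), n_indexed = nrow(tbl),
                         n_skipped = nrow(spacers) - nrow(tbl)),
    class = "spacer_index"
  )
}

#' @export
print.spacer_index <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("<spacer_index> %d spacers (%d skipped at load), widths %d-%d\n",
              nrow(x$spacers), rep$n_skipped,
              min(x$spacers$width), max(x$spacers$width)))
  invisible(x)
}

# Exact search of many variable-width patterns in one pass: concatenate all
# subjects with N runs (N never matches an ACGT pattern) and run a single
# trusted-band Aho-Corasick dictionary (band = shortest pattern width,
# max.mismatch = 0, i.e. full-length exact matches).
scan_exact <- function(patterns, subj_seqs, offsets) {
  big <- Biostrings::DNAString(paste(subj_seqs, collapse = strrep("N", 100L)))
  pset <- Biostrings::DNAStringSet(patterns)
  pd <- Biostrings::PDict(pset, tb.start = 1L,
                          tb.width = min(Biostrings::width(pset)))
  m <- Biostrings::matchPDict(pd, big, max.mismatch = 0)
  n_per <- S4Vectors::elementNROWS(m)
  if (sum(n_per) == 0L) return(tibble())
  starts <- BiocGenerics::start(BiocGenerics::unlist(m))
  tibble(
    pattern_idx = rep(seq_along(patterns), n_per),
    subj_idx = findInterval(starts, offsets),
    start_global = starts
  )
}

#' Scan plasmids for spacer hits
#'
#' Finds every position where a spacer matches a plasmid with at least the
#' configured Hamming identity over its full length, on either strand,
#' computes the ungapped E-value per hit and drops hits above the E-value
#' threshold. Coordinates are 0-based half-open on the plasmid forward
#' strand. Output is sorted by (plasmid, start, spacer, strand) for
#' reproducibility. Palindromic spacers matching a window identically in both
#' orientations report the hit once, on strand `+`.
#'
#' @param plasmids Tibble with columns `accession`, `sequence` (one row per
#'   plasmid; sequences must be non-empty).
#' @param index A [build_spacer_index()] object.
#' @param params A [match_params()] object.
#' @return A tibble of hits with columns `plasmid_accession`, `spacer_id`,
#'   `spacer_source_accession`, `start0`, `end0`, `strand`, `match_length`,
#'   `mismatches`, `identity`, `evalue`.
#' @export
scan_plasmids <- function(plasmids, index, params = match_params()) {
  stopifnot(inherits(index, "spacer_index"))
  if (nrow(plasmids) == 0L) abort("`plasmids` must be non-empty.")
  seqs <- toupper(plasmids$sequence)
  if (any(is.na(seqs) | !nzchar(seqs))) abort("Empty plasmid sequence.")
  lens <- nchar(seqs)
  db_length <- sum(as.numeric(lens))

  sp <- index$spacers
  if (!is.null(params$min_match_length)) {
    sp <- sp[sp$width >= params$min_match_length, , drop = FALSE]
  }
  if (nrow(sp) == 0L) return(empty_hits())
  k <- floor(sp$width * (1 - params$identity))

  # oriented patterns; palindromes searched once, reported on '+'
  ori <- bind_rows(
    tibble(row = seq_len(nrow(sp)), strand = "+", pattern = sp$sequence),
    if (params$both_strands) {
      tibble(row = which(!sp$palindromic), strand = "-",
             pattern = sp$rc_sequence[!sp$palindromic])
    }
  )

  subj_seqs <- seqs
  if (params$circular) {
    ext <- pmin(lens, max(sp$width) - 1L)
    subj_seqs <- paste0(seqs, substr(seqs, 1L, ext))
  }
  subj_lens <- nchar(subj_seqs)
  offsets <- cumsum(c(1, head(subj_lens + 100L, -1L)))  # 1-based global starts

  exact_rows <- which(k[ori$row] == 0L)
  mm_rows <- setdiff(seq_len(nrow(ori)), exact_rows)

  res <- list()
  if (length(exact_rows) > 0L) {
    ex <- scan_exact(ori$pattern[exact_rows], subj_seqs, offsets)
    if (nrow(ex) > 0L) {
      oi <- exact_rows[ex$pattern_idx]
      res[[length(res) + 1L]] <- tibble(
        row = ori$row[oi], strand = ori$strand[oi],
        subj_idx = ex$subj_idx,
        start0 = ex$start_global - offsets[ex$subj_idx],
        mismatches = 0L
      )
    }
  }
  if (length(mm_rows) > 0L) {
    subjects <- Biostrings::DNAStringSet(subj_seqs)
    for (j in mm_rows) {
      w <- nchar(ori$pattern[j])
      kj <- k[ori$row[j]]
      searchable <- which(subj_lens >= w)
      if (length(searchable) == 0L) next
      m <- Biostrings::vmatchPattern(ori$pattern[j], subjects[searchable],
                                     max.mismatch = kj, with.indels = FALSE,
                                     fixed = TRUE)
      n_per <- S4Vectors::elementNROWS(m)
      if (sum(n_per) == 0L) next
      st_all <- BiocGenerics::start(BiocGenerics::unlist(m))
      sidx <- rep(searchable, n_per)
      # windows partially outside the subject are not fixed-length Hamming
      # windows; drop them
      keep <- st_all >= 1L & st_all + w - 1L <= subj_lens[sidx]
      if (!any(keep)) next
      st_all <- st_all[keep]
      sidx <- sidx[keep]
      pat <- Biostrings::DNAString(ori$pattern[j])
      mm_all <- integer(length(st_all))
      for (s in unique(sidx)) {
        sel <- sidx == s
        mm_all[sel] <- as.integer(Biostrings::neditStartingAt(
          pat, subjects[[s]], starting.at = st_all[sel], with.indels = FALSE))
      }
      res[[length(res) + 1L]] <- tibble(
        row = ori$row[j], strand = ori$strand[j],
        subj_idx = sidx, start0 = st_all - 1L, mismatches = mm_all)
    }
  }
  hits <- bind_rows(res)
  if (nrow(hits) == 0L) return(empty_hits())

  hits <- hits %>%
    mutate(
      start0 = as.integer(.data$start0),
      plasmid_accession = plasmids$accession[.data$subj_idx],
      spacer_id = sp$spacer_id[.data$row],
      spacer_source_accession = sp$source_accession[.data$row],
      match_length = sp$width[.data$row],
      end0 = .data$start0 + .data$match_length,
      identity = (.data$match_length - .data$mismatches) / .data$match_length,
      evalue = evalue(.data$match_length, .data$mismatches,
                      db_length = db_length, params = params$scoring)
    )
  if (params$circular) {
    # drop duplicates living entirely in the wrapped extension
    hits <- hits %>% filter(.data$start0 < lens[.data$subj_idx])
  }
  hits %>%
    filter(.data$evalue <= params$evalue_max) %>%
    arrange(.data$plasmid_accession, .data$start0, .data$spacer_id, .data$strand) %>%
    select(dplyr::all_of(hit_cols()))
}

empty_hits <- function() {
  tibble(plasmid_accession = character(), spacer_id = character(),
         spacer_source_accession = character(), start0 = integer(),
         end0 = integer(), strand = character(), match_length = integer(),
         mismatches = integer(), identity = double(), evalue = double())
}

#' Remove plasmid-borne (self) spacer hits
#'
#' A spacer whose source accession equals the plasmid it matches is carried
#' on the plasmid itself and records no host-targeting event; such hits are
#' removed before host prediction.
#'
#' @param hits A hit tibble (see [scan_plasmids()]).
#' @return The remaining hits, unchanged and in the same order, with the
#'   number of removed records in `attr(x, "n_self_removed")`.
#' @export
remove_self_hits <- function(hits) {
  is_self <- hits$plasmid_accession == hits$spacer_source_accession
  out <- hits[!is_self, , drop = FALSE]
  inform(sprintf("Removed %d self-hit(s) (plasmid-borne spacers).", sum(is_self)))
  attr(out, "n_self_removed") <- sum(is_self)
  out
}

#' Hit counts across identity thresholds
#'
#' Reruns the full matching at each identity cutoff (the index is built
#' once). Hit sets are nested across thresholds, so both counts are
#' non-increasing as the threshold rises.
#'
#' @param plasmids,spacers As for [build_spacer_index()] / [scan_plasmids()].
#' @param thresholds Numeric vector of identity cutoffs in `(0, 1]`.
#' @param params Base [match_params()]; its `identity` is overridden per run.
#' @param remove_self Drop self-hits before counting (default `TRUE`).
#' @return A tibble with columns `identity_threshold`, `n_hits`,
#'   `n_matched_plasmids`.
#' @export
threshold_sweep <- function(plasmids, spacers, thresholds = c(0.9, 0.95, 1),
                            params = match_params(), remove_self = TRUE) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  index <- build_spacer_index(spacers)
  purrr::map_dfr(thresholds, function(t) {
    p <- params
    p$identity <- t
    hits <- scan_plasmids(plasmids, index, p)
    if (remove_self) {
      hits <- withCallingHandlers(remove_self_hits(hits),
                                  message = function(m) invokeRestart("muffleMessage"))
    }
    tibble(identity_threshold = t, n_hits = nrow(hits),
           n_matched_plasmids = n_distinct(hits$plasmid_accession))
  })
}
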