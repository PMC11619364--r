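# Independent brute-force oracles, deliberately written with different
# algorithms from the package internals (no Biostrings, no IRanges).

# Reverse complement via an explicit base lookup.
oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# All-offset, both-strand fixed-length Hamming scan. Mismatch counts are
# accumulated position-by-position over vectorized offset windows, an O(w*L)
# scheme unrelated to the Aho-Corasick/Boyer-Moore paths in the package.
# Mirrors the reporting conventions: 0-based half-open coordinates,
# palindromic spacers reported once on '+'.
oracle_scan <- function(plasmids, spacers, identity = 1, both_strands = TRUE) {
  out <- list()
  for (pi in seq_len(nrow(plasmids))) {
    pl <- strsplit(plasmids$sequence[pi], "", fixed = TRUE)[[1]]
    L <- length(pl)
    for (si in seq_len(nrow(spacers))) {
      sp_fwd <- spacers$sequence[si]
      w <- nchar(sp_fwd)
      if (w > L) next
      k <- floor(w * (1 - identity))
      pal <- identical(sp_fwd, oracle_rc(sp_fwd))
      oris <- if (both_strands && !pal) c("+", "-") else "+"
      for (strand in oris) {
        seg <- if (strand == "+") sp_fwd else oracle_rc(sp_fwd)
        sp <- strsplit(seg, "", fixed = TRUE)[[1]]
        n_off <- L - w + 1L
        mm <- integer(n_off)
        for (i in seq_len(w)) {
          mm <- mm + (pl[i:(i + n_off - 1L)] != sp[i])
        }
        hit_at <- which(mm <= k)
        if (length(hit_at) > 0L) {
          out[[length(out) + 1L]] <- tibble::tibble(
            plasmid_accession = plasmids$accession[pi],
            spacer_id = spacers$spacer_id[si],
            start0 = hit_at - 1L,
            end0 = hit_at - 1L + w,
            strand = strand,
            mismatches = mm[hit_at]
          )
        }
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(plasmid_accession = character(),
                          spacer_id = character(), start0 = integer(),
                          end0 = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(res, plasmid_accession, start0, spacer_id, strand)
}

# Two-sided Fisher p-value by exhaustive enumeration of the hypergeometric
# support (sum of outcome probabilities no larger than the observed one).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  support <- max(0L, r1 + c1 - N):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1)
  }, numeric(1))
  obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
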