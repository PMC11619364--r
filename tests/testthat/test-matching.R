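spacer_tbl <- function(ids, seqs, src = "SRC1") {
  tibble::tibble(spacer_id = ids, sequence = seqs,
                 source_accession = rep_len(src, length(ids)))
}
plasmid_tbl <- function(accs, seqs) {
  tibble::tibble(accession = accs, sequence = seqs)
}
loose <- function(...) match_params(evalue_max = Inf, ...)

test_that("exact forward and reverse-complement matches are found at the right coordinates", {
  idx <- build_spacer_index(spacer_tbl("sp1", "CGTACG"))
  hits <- scan_plasmids(plasmid_tbl("p1", "AAACGTACGTTT"), idx, loose())
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start0, 3L)
  expect_identical(hits$end0, 9L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$identity, 1)

  # spacer GGGAT matches the ATCCC interval on the minus strand
  idx2 <- build_spacer_index(spacer_tbl("sp2", "GGGAT"))
  hits2 <- scan_plasmids(plasmid_tbl("p1", "TTATCCCTT"), idx2, loose())
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$strand, "-")
  expect_identical(hits2$start0, 2L)
  expect_identical(hits2$end0, 7L)
})

test_that("palindromic spacers report one hit per position, on the plus strand", {
  pal <- "ACGCGT"
  expect_identical(pal, oracle_rc(pal))
  idx <- build_spacer_index(spacer_tbl("pal", pal))
  hits <- scan_plasmids(plasmid_tbl("p1", paste0("TT", pal, "TTTT", pal)), idx,
                        loose())
  expect_identical(nrow(hits), 2L)
  expect_true(all(hits$strand == "+"))
})

test_that("spacers with ambiguity codes are skipped with a warning and counted", {
  sp <- spacer_tbl(c("ok", "bad"), c("ACGTACGTACGT", "ACGTNCGTACGT"))
  expect_warning(idx <- build_spacer_index(sp), "non-ACGT")
  expect_identical(attr(idx, "load_report")$n_skipped, 1L)
  expect_identical(idx$spacers$spacer_id, "ok")
})

test_that("index and scan validate their inputs", {
  expect_error(build_spacer_index(spacer_tbl(character(), character())),
               "non-empty")
  expect_error(build_spacer_index(spacer_tbl(c("a", "a"), c("ACGT", "ACGT"))),
               "unique")
  idx <- build_spacer_index(spacer_tbl("sp1", "ACGTACGT"))
  expect_error(scan_plasmids(plasmid_tbl("p1", ""), idx), "Empty plasmid")
  expect_error(scan_plasmids(plasmid_tbl(character(), character()), idx),
               "non-empty")
})

test_that("the matcher equals the brute-force Hamming oracle, exact and with mismatches", {
  withr::local_seed(101)
  # random spacers, some planted exactly, some planted with 1-2 substitutions
  spacers <- spacer_tbl(sprintf("sp%02d", 1:20),
                        replicate(20, random_seq(sample(26:40, 1))))
  plasmids <- plasmid_tbl(sprintf("p%d", 1:3),
                          replicate(3, random_seq(3000)))
  plant <- function(seq, insert, at) {
    paste0(substr(seq, 1, at - 1), insert,
           substr(seq, at + nchar(insert), nchar(seq)))
  }
  corrupt <- function(s, k) {
    pos <- sample(nchar(s), k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  plasmids$sequence[1] <- plant(plasmids$sequence[1], spacers$sequence[1], 100)
  plasmids$sequence[1] <- plant(plasmids$sequence[1],
                                oracle_rc(spacers$sequence[2]), 500)
  plasmids$sequence[2] <- plant(plasmids$sequence[2],
                                corrupt(spacers$sequence[3], 1), 700)
  plasmids$sequence[3] <- plant(plasmids$sequence[3],
                                corrupt(spacers$sequence[4], 2), 1500)

  idx <- build_spacer_index(spacers)
  for (ident in c(1, 0.95, 0.9)) {
    got <- scan_plasmids(plasmids, idx, loose(identity = ident)) %>%
      dplyr::select(plasmid_accession, spacer_id, start0, end0, strand,
                    mismatches)
    want <- oracle_scan(plasmids, spacers, identity = ident) %>%
      dplyr::select(plasmid_accession, spacer_id, start0, end0, strand,
                    mismatches)
    expect_identical(as.data.frame(got), as.data.frame(want),
                     label = paste("identity", ident))
  }
  # exact mode: every reported hit has zero mismatches
  exact <- scan_plasmids(plasmids, idx, loose(identity = 1))
  expect_true(all(exact$mismatches == 0L))
  expect_true(all(exact$end0 - exact$start0 == exact$match_length))
})

test_that("matching a spacer on '-' equals matching its reverse complement on '+'", {
  withr::local_seed(7)
  pl <- plasmid_tbl("p1", random_seq(2000))
  s <- random_seq(30)
  pl$sequence <- paste0(substr(pl$sequence, 1, 800), oracle_rc(s),
                        substr(pl$sequence, 831, 2000))
  h_minus <- scan_plasmids(pl, build_spacer_index(spacer_tbl("s", s)), loose())
  h_plus <- scan_plasmids(pl, build_spacer_index(spacer_tbl("s", oracle_rc(s))),
                          loose())
  expect_identical(h_minus$strand, "-")
  expect_identical(h_plus$strand, "+")
  expect_identical(h_minus[c("start0", "end0", "mismatches")],
                   h_plus[c("start0", "end0", "mismatches")])
})

test_that("scans are deterministic and sorted by (plasmid, start, spacer, strand)", {
  withr::local_seed(21)
  spacers <- spacer_tbl(sprintf("s%d", 1:10),
                        replicate(10, random_seq(28)))
  pl <- plasmid_tbl("p1", paste0(random_seq(200), spacers$sequence[5],
                                 random_seq(200), spacers$sequence[2],
                                 random_seq(100)))
  idx <- build_spacer_index(spacers)
  a <- scan_plasmids(pl, idx, loose())
  b <- scan_plasmids(pl, idx, loose())
  expect_identical(a, b)
  expect_false(is.unsorted(a$start0))
})

test_that("E-values follow the closed Karlin-Altschul form and its limits", {
  # frozen: independently evaluated with 40-digit arithmetic
  expect_equal(evalue(30, 0, db_length = 30, query_length = 10000),
               8.747078557811906e-13, tolerance = 1e-12)
  expect_identical(evalue(30, 0, db_length = 0), 0)
  expect_error(evalue(30, 0, db_length = -1), "non-negative")
  expect_error(evalue(30, 5, db_length = 10, query_length = 0), "positive")
  expect_error(evalue(10, 11, db_length = 10), "mismatches")
  # monotone decreasing in match length; increasing in mismatches
  expect_lt(evalue(31, 0, db_length = 1e4), evalue(30, 0, db_length = 1e4))
  expect_gt(evalue(30, 1, db_length = 1e4), evalue(30, 0, db_length = 1e4))
})

test_that("the E-value threshold filters weak hits in context", {
  # a 6-mer exact hit in a 12 bp database has E ~ 1.5e-2, far above 1e-5
  idx <- build_spacer_index(spacer_tbl("sp1", "CGTACG"))
  pl <- plasmid_tbl("p1", "AAACGTACGTTT")
  expect_identical(nrow(scan_plasmids(pl, idx, match_params())), 0L)
  # a 30-mer exact hit passes easily
  withr::local_seed(3)
  s30 <- random_seq(30)
  pl2 <- plasmid_tbl("p2", paste0(random_seq(500), s30, random_seq(500)))
  expect_identical(
    nrow(scan_plasmids(pl2, build_spacer_index(spacer_tbl("s", s30)),
                       match_params())), 1L)
})

test_that("self-hits are removed exactly and counted", {
  hits <- tibble::tibble(
    plasmid_accession = c("NZ_X1", "NZ_X1", "NZ_X2"),
    spacer_id = c("a", "b", "c"),
    spacer_source_accession = c("NZ_X1", "STRAIN_Y", "NZ_X1"),
    start0 = 0L, end0 = 10L, strand = "+", match_length = 10L,
    mismatches = 0L, identity = 1, evalue = 0
  )
  expect_message(kept <- remove_self_hits(hits), "1 self-hit")
  expect_identical(kept$spacer_id, c("b", "c"))
  expect_identical(attr(kept, "n_self_removed"), 1L)
  expect_message(empty <- remove_self_hits(hits[0, ]), "0 self-hit")
  expect_identical(nrow(empty), 0L)
})

test_that("short spacers can be excluded with min_match_length", {
  idx <- build_spacer_index(
    spacer_tbl(c("short", "long"),
               c("CGTACG", "CGTACGCGTACGCGTACGCGTACGCGTACG")))
  pl <- plasmid_tbl("p1", paste0("AAA", "CGTACGCGTACGCGTACGCGTACGCGTACG", "TTT"))
  all_hits <- scan_plasmids(pl, idx, loose())
  expect_setequal(unique(all_hits$spacer_id), c("short", "long"))
  floor26 <- scan_plasmids(pl, idx, loose(min_match_length = 26))
  expect_setequal(unique(floor26$spacer_id), "long")
})

test_that("circular mode finds origin-spanning matches, linear mode does not", {
  withr::local_seed(13)
  s <- random_seq(30)
  # last 12 bases of the plasmid are the spacer head; the first 18 its tail
  body <- random_seq(400)
  pl <- plasmid_tbl("p1", paste0(substr(s, 13, 30), body, substr(s, 1, 12)))
  idx <- build_spacer_index(spacer_tbl("s", s))
  expect_identical(nrow(scan_plasmids(pl, idx, loose())), 0L)
  circ <- scan_plasmids(pl, idx, loose(circular = TRUE))
  expect_identical(nrow(circ), 1L)
  expect_identical(circ$start0, nchar(pl$sequence) - 12L)
  expect_identical(circ$end0, circ$start0 + 30L)
})

test_that("hit counts are non-increasing across rising identity thresholds", {
  withr::local_seed(31)
  spacers <- spacer_tbl(sprintf("s%02d", 1:15),
                        replicate(15, random_seq(32)))
  # 10 exact copies, 5 one-mismatch copies, on 3 plasmids
  seqs <- replicate(3, random_seq(2500))
  corrupt1 <- function(s) {
    p <- sample(nchar(s), 1)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  at <- seq(50, 2200, by = 220)
  for (i in 1:10) {
    j <- (i - 1) %% 3 + 1
    substr(seqs[j], at[i], at[i] + 31) <- spacers$sequence[i]
  }
  for (i in 11:15) {
    j <- (i - 1) %% 3 + 1
    substr(seqs[j], at[i - 10] + 110, at[i - 10] + 141) <-
      corrupt1(spacers$sequence[i])
  }
  plasmids <- plasmid_tbl(sprintf("p%d", 1:3), seqs)
  sweep <- threshold_sweep(plasmids, spacers,
                           thresholds = c(0.9, 31 / 32, 1),
                           params = loose())
  expect_identical(sweep$n_hits[sweep$identity_threshold == 1], 10L)
  expect_identical(sweep$n_hits[sweep$identity_threshold == 31 / 32], 15L)
  expect_true(all(diff(sweep$n_hits) <= 0))
  expect_true(all(diff(sweep$n_matched_plasmids) <= 0))
  # single-threshold sweep equals a direct scan
  direct <- scan_plasmids(plasmids, build_spacer_index(spacers), loose())
  expect_identical(sweep$n_hits[3], nrow(direct))
})
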