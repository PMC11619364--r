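mk_hit <- function(acc, start0, end0, id = "h1") {
  tibble::tibble(plasmid_accession = acc, spacer_id = id,
                 spacer_source_accession = "S", start0 = start0, end0 = end0,
                 strand = "+", match_length = end0 - start0, mismatches = 0L,
                 identity = 1, evalue = 0)
}
mk_feat <- function(acc, start1, end1, type = "CDS", id = "f1",
                    product = "hypothetical protein") {
  tibble::tibble(accession = acc, feature_type = type, start1 = start1,
                 end1 = end1, strand = "+", feature_id = id,
                 product = product, go_function = NA_character_)
}

test_that("hits annotate by full containment, preferring the shortest feature", {
  feats <- dplyr::bind_rows(
    mk_feat("P1", 51, 200, id = "big"),
    mk_feat("P1", 90, 140, id = "small"),
    mk_feat("P1", 95, 145, id = "small2")
  )
  # hit [100,130) is inside all three; small (90..140) and small2 (95..145)
  # tie on width, small starts lower
  ann <- annotate_hits(mk_hit("P1", 100L, 130L), feats)
  expect_identical(ann$feature_id, "small")
  # containment in a single feature
  ann2 <- annotate_hits(mk_hit("P1", 60L, 80L), feats)
  expect_identical(ann2$feature_id, "big")
  # a hit straddling the boundary is unannotated under the containment rule
  ann3 <- annotate_hits(mk_hit("P1", 190L, 210L), feats)
  expect_identical(ann3$feature_id, NA_character_)
  # ... but annotated under the any-overlap rule
  ann4 <- annotate_hits(mk_hit("P1", 190L, 210L), feats, rule = "any")
  expect_identical(ann4$feature_id, "big")
  # 1-based inclusive boundaries map to 0-based half-open exactly
  edge <- annotate_hits(mk_hit("P1", 50L, 200L), feats)
  expect_identical(edge$feature_id, "big")
  expect_identical(annotate_hits(mk_hit("P1", 49L, 200L), feats)$feature_id,
                   NA_character_)
})

test_that("annotation equals a brute-force interval containment scan", {
  withr::local_seed(17)
  feats <- purrr::map_dfr(1:40, function(i) {
    s <- sample(1:2000, 1)
    mk_feat("P1", s, s + sample(30:400, 1), id = sprintf("f%02d", i))
  })
  hits <- purrr::map_dfr(1:60, function(i) {
    s <- sample(0:2300, 1)
    mk_hit("P1", s, s + 30L, id = sprintf("h%02d", i))
  })
  got <- annotate_hits(hits, feats)$feature_id
  want <- vapply(seq_len(nrow(hits)), function(i) {
    inside <- feats$start1 - 1L <= hits$start0[i] & hits$end0[i] <= feats$end1
    if (!any(inside)) return(NA_character_)
    cand <- feats[inside, ]
    cand <- cand[order(cand$end1 - cand$start1, cand$start1), ]
    cand$feature_id[1]
  }, character(1))
  expect_identical(got, want)
})

test_that("feature frequencies count annotated hits and sum to one", {
  ann <- dplyr::bind_rows(
    mk_hit("P1", 1L, 10L), mk_hit("P1", 1L, 10L), mk_hit("P1", 1L, 10L)
  )
  ann$feature_id <- c("a", "a", "b")
  ff <- feature_frequencies(ann)
  expect_identical(ff$n, c(2L, 1L))
  expect_equal(ff$rel_freq, c(2 / 3, 1 / 3))
  expect_identical(sum(ff$rel_freq), 1)
  expect_identical(feature_frequencies(ann, top_n = 1)$feature_id, "a")
  empty <- ann[0, ]
  expect_identical(nrow(feature_frequencies(empty)), 0L)
})

test_that("product names categorize deterministically with the right priorities", {
  expect_identical(categorize_feature("hypothetical protein")[1],
                   "FUNCTION_UNKNOWN")
  expect_identical(categorize_feature("DUF4158 domain-containing protein")[1],
                   "FUNCTION_UNKNOWN")
  expect_identical(categorize_feature("nan")[1], "FUNCTION_UNKNOWN")
  expect_identical(categorize_feature("conjugal transfer protein TraG")[1],
                   "PLASMID_BACKBONE")
  expect_identical(categorize_feature("plasmid partition protein ParA")[1],
                   "PLASMID_BACKBONE")
  expect_identical(categorize_feature("IS6 family transposase")[1],
                   "TRANSPOSON_ASSOCIATED")
  # transposase wins over plasmid-like context
  expect_identical(categorize_feature("plasmid replication region transposase")[1],
                   "TRANSPOSON_ASSOCIATED")
  expect_identical(categorize_feature("DNA methyltransferase")[1],
                   "POTENTIAL_BACKBONE")
  expect_identical(categorize_feature("ABC transporter permease")[1],
                   "GENERAL_FUNCTIONAL")
  expect_identical(categorize_feature("")[1], "FUNCTION_UNKNOWN")
  expect_identical(categorize_feature(NA_character_)[1], "FUNCTION_UNKNOWN")
  # unmatched names fall back to general with a miss flag
  odd <- categorize_feature("totally unheard-of widget")
  expect_identical(odd[1], "GENERAL_FUNCTIONAL")
  expect_true(attr(odd, "lexicon_miss")[1])
  # determinism
  nm <- c("hypothetical protein", "IS6 family transposase", "widgetase")
  expect_identical(categorize_feature(nm), categorize_feature(nm))
})

test_that("lexicons round-trip through TSV with priority preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(default_lexicon(), path)
  lx <- read_lexicon(path)
  expect_identical(lx, default_lexicon()[names(lx)])
  expect_identical(names(lx), names(default_lexicon()))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("category\tpattern\nNOT_A_CATEGORY\tfoo", bad)
  expect_error(read_lexicon(bad), "Unknown lexicon category")
})

test_that("category summaries give both denominators and partition the hits", {
  hits <- purrr::map_dfr(1:100, ~ mk_hit("P1", .x * 10L, .x * 10L + 5L,
                                         id = paste0("h", .x)))
  hits$feature_id <- paste0("f", 1:100)
  hits$feature_type <- "CDS"
  hits$product <- c(rep("conjugal transfer protein TraG", 45),
                    rep("DNA methyltransferase", 43),
                    rep("ABC transporter permease", 9),
                    rep("IS6 family transposase", 3))
  cat_hits <- categorize_hits(hits)
  cs <- category_summary(cat_hits)
  expect_identical(cs$pct_known[cs$category == "PLASMID_BACKBONE"], 45)
  expect_identical(cs$pct_known[cs$category == "POTENTIAL_BACKBONE"], 43)
  expect_identical(cs$pct_known[cs$category == "GENERAL_FUNCTIONAL"], 9)
  expect_identical(cs$pct_known[cs$category == "TRANSPOSON_ASSOCIATED"], 3)
  expect_identical(sum(cs$pct_known, na.rm = TRUE), 100)
  expect_identical(sum(cs$n), 100L)
  # repeat features with missing IDs are 'nan' placeholders -> unknown
  rep_hit <- mk_hit("P1", 5L, 20L)
  rep_hit$feature_id <- NA_character_
  rep_hit$feature_type <- "repeat"
  rep_hit$product <- NA_character_
  expect_identical(categorize_hits(rep_hit)$category, "FUNCTION_UNKNOWN")
  # all-unknown warns
  unk <- hits[1:2, ]
  unk$product <- "hypothetical protein"
  expect_warning(cs2 <- category_summary(categorize_hits(unk)), "unknown")
  expect_true(all(is.na(cs2$pct_known)))
})

test_that("mobile-element hits are flagged with their distinct plasmids", {
  withr::local_seed(23)
  # 25 planted IS hits across 9 plasmids, mirroring a real-world report shape
  plas <- sprintf("P%02d", 1:9)
  hits <- purrr::map_dfr(1:25, function(i) {
    mk_hit(plas[(i - 1) %% 9 + 1], 100L + i * 40L, 130L + i * 40L,
           id = sprintf("h%02d", i))
  })
  feats <- purrr::map_dfr(plas, function(a) {
    mk_feat(a, 1, 5000, type = "mobile_element", id = paste0("IS_", a),
            product = "IS6 family transposase")
  })
  other_hits <- mk_hit("P99", 10L, 40L)
  flagged <- flag_mobile_element_hits(dplyr::bind_rows(hits, other_hits), feats)
  expect_identical(nrow(flagged), 25L)
  expect_identical(length(attr(flagged, "plasmid_accessions")), 9L)
  none <- flag_mobile_element_hits(hits, mk_feat("P01", 1, 5000))
  expect_identical(nrow(none), 0L)
})
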