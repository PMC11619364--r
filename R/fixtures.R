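#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the structure of a plasmid database with reported
#' hosts plus a spacer database tied to source strains: a balanced multi-rank
#' taxonomy, strains carrying spacers of realistic lengths (26-72 bp),
#' plasmids whose sequences contain exact planted protospacer copies from
#' designated host strains, decoy IS segments shared verbatim across
#' plasmids, plasmid-borne (self) spacers, feature annotations whose product
#' names map back to known target categories, MOB labels and a partial PTU
#' map. The seed fully determines every output byte.
#'
#' The default taxonomy is 5 phyla x 2 classes x 2 orders x 5 families x
#' 2 genera x 1 species x 1 strain = 200 strains, each carrying 10 spacers
#' (2,000 spacers), targeted by 200 plasmids whose planted host-range grades
#' roughly follow the narrow-skewed distribution seen in real plasmid data
#' (about 60% grade I, 26% grade II, and a thin broad-host tail).
#'
#' @param seed Integer seed (< 2^31).
#' @param n_phyla,classes_per_phylum,orders_per_class,families_per_order,genera_per_family,species_per_genus,strains_per_species
#'   Balanced taxonomy shape; all must be >= 1.
#' @param spacers_per_strain Spacers carried by each strain.
#' @param n_plasmids Number of plasmids.
#' @param plasmid_length Length-2 integer range of plasmid lengths (bp).
#' @param spacer_length Length-2 integer range of spacer lengths (bp).
#' @param planted_grade_targets Named integer vector over grades `I`..`VI`;
#'   must sum to `n_plasmids`.
#' @param decoy_is_elements Number of distinct decoy IS segments, each copied
#'   verbatim onto several plasmids (no spacer is ever sourced from them).
#' @param self_hit_fraction Fraction of plasmids that carry one of their own
#'   spacers (a planted self-hit).
#' @param mutation_rate Per-base substitution probability applied to planted
#'   protospacer copies (0 = exact copies), for identity-sweep experiments.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_phyla = 5L, classes_per_phylum = 2L,
                           orders_per_class = 2L, families_per_order = 5L,
                           genera_per_family = 2L, species_per_genus = 1L,
                           strains_per_species = 1L,
                           spacers_per_strain = 10L,
                           n_plasmids = 200L,
                           plasmid_length = c(5000L, 9000L),
                           spacer_length = c(26L, 72L),
                           planted_grade_targets = c(I = 119L, II = 52L,
                                                     III = 12L, IV = 12L,
                                                     V = 2L, VI = 3L),
                           decoy_is_elements = 5L,
                           self_hit_fraction = 0.05,
                           mutation_rate = 0) {
  counts <- c(n_phyla, classes_per_phylum, orders_per_class, families_per_order,
              genera_per_family, species_per_genus, strains_per_species,
              spacers_per_strain, n_plasmids)
  if (any(counts < 1L)) abort("All taxonomy/sampling counts must be >= 1.")
  if (decoy_is_elements < 0L || self_hit_fraction < 0 || self_hit_fraction > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    abort("Invalid decoy count, self-hit fraction or mutation rate.")
  }
  missing_grades <- setdiff(names(planted_grade_targets), grade_levels())
  if (length(missing_grades) > 0L) {
    abort("`planted_grade_targets` names must be grades I..VI.")
  }
  if (sum(planted_grade_targets) != n_plasmids) {
    abort("`planted_grade_targets` must sum to `n_plasmids`.")
  }
  structure(list(
    seed = as.integer(seed), n_phyla = n_phyla,
    classes_per_phylum = classes_per_phylum, orders_per_class = orders_per_class,
    families_per_order = families_per_order, genera_per_family = genera_per_family,
    species_per_genus = species_per_genus, strains_per_species = strains_per_species,
    spacers_per_strain = spacers_per_strain, n_plasmids = n_plasmids,
    plasmid_length = plasmid_length, spacer_length = spacer_length,
    planted_grade_targets = planted_grade_targets,
    decoy_is_elements = decoy_is_elements,
    self_hit_fraction = self_hit_fraction, mutation_rate = mutation_rate
  ), class = "fixture_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

resample <- function(x, n) x[sample.int(length(x), n)]

#' Generate a balanced synthetic taxonomy
#'
#' Produces one lineage row per strain with globally unique names at every
#' rank, so the rank-consistency validator passes by construction.
#'
#' @param config A [fixture_config()].
#' @return A lineage tibble (strain accessions `STRnnnnn`).
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, generate_taxonomy_impl(config))
}

generate_taxonomy_impl <- function(config) {
  ip <- 0L; ic <- 0L; io <- 0L; ifa <- 0L; ig <- 0L; isp <- 0L; ist <- 0L
  rows <- list()
  for (p in seq_len(config$n_phyla)) {
    ip <- ip + 1L; phy <- sprintf("Phylum%02d", ip)
    for (cl in seq_len(config$classes_per_phylum)) {
      ic <- ic + 1L; cls <- sprintf("Class%03d", ic)
      for (o in seq_len(config$orders_per_class)) {
        io <- io + 1L; ord <- sprintf("Order%03d", io)
        for (f in seq_len(config$families_per_order)) {
          ifa <- ifa + 1L; fam <- sprintf("Family%03d", ifa)
          for (g in seq_len(config$genera_per_family)) {
            ig <- ig + 1L; gen <- sprintf("Genus%03d", ig)
            for (s in seq_len(config$species_per_genus)) {
              isp <- isp + 1L
              spc <- paste(gen, sprintf("fictus%03d", isp))
              for (st in seq_len(config$strains_per_species)) {
                ist <- ist + 1L
                rows[[ist]] <- tibble(
                  accession = sprintf("STR%05d", ist),
                  superkingdom = "Bacteria", phylum = phy, class = cls,
                  order = ord, family = fam, genus = gen,
                  species = spc, strain = sprintf("st%02d", st)
                )
              }
            }
          }
        }
      }
    }
  }
  bind_rows(rows)
}

fixture_products <- function() {
  list(
    FUNCTION_UNKNOWN = c("hypothetical protein",
                         "DUF4158 domain-containing protein"),
    PLASMID_BACKBONE = c("conjugal transfer protein TraG",
                         "plasmid replication initiator protein RepB",
                         "ParA family plasmid partition protein",
                         "toxin-antitoxin system antitoxin RelB"),
    POTENTIAL_BACKBONE = c("DNA methyltransferase",
                           "type I restriction enzyme subunit R",
                           "ATP-dependent DNA helicase"),
    GENERAL_FUNCTIONAL = c("ABC transporter permease",
                           "glucose-6-phosphate dehydrogenase",
                           "two-component system response regulator"),
    TRANSPOSON_ASSOCIATED = c("IS6 family transposase",
                              "site-specific integrase")
  )
}

# Weights loosely follow the observed target-category mix on real plasmids
# (about a third unknown; backbone-like genes dominating the rest).
fixture_category_weights <- function() {
  c(FUNCTION_UNKNOWN = 0.361, PLASMID_BACKBONE = 0.289,
    POTENTIAL_BACKBONE = 0.275, GENERAL_FUNCTIONAL = 0.056,
    TRANSPOSON_ASSOCIATED = 0.019)
}

grade_requirements <- function() {
  list(II = c(vary = "genus", within = "family"),
       III = c(vary = "family", within = "order"),
       IV = c(vary = "order", within = "class"),
       V = c(vary = "class", within = "phylum"),
       VI = c(vary = "phylum", within = "superkingdom"))
}

pick_hosts <- function(tax, grade) {
  if (grade == "I") {
    sp <- resample(unique(tax$species), 1L)
    st <- tax[tax$species == sp, , drop = FALSE]
    return(st[sample.int(nrow(st), min(2L, nrow(st))), , drop = FALSE])
  }
  req <- grade_requirements()[[grade]]
  grp <- tax %>%
    group_by(.data[[req[["within"]]]]) %>%
    filter(n_distinct(.data[[req[["vary"]]]]) >= 2L) %>%
    ungroup()
  if (nrow(grp) == 0L) {
    abort(sprintf("Grade %s target infeasible for this taxonomy (need >= 2 %s within one %s).",
                  grade, req[["vary"]], req[["within"]]))
  }
  w <- resample(unique(grp[[req[["within"]]]]), 1L)
  sub <- grp[grp[[req[["within"]]]] == w, , drop = FALSE]
  vs <- resample(unique(sub[[req[["vary"]]]]), 2L)
  bind_rows(lapply(vs, function(v) {
    s <- sub[sub[[req[["vary"]]]] == v, , drop = FALSE]
    s[sample.int(nrow(s), 1L), , drop = FALSE]
  }))
}

# Sample non-overlapping 1-based [start, start + w - 1] slots on a sequence
# of length L, keeping `gap` free bases between slots.
allocate_slots <- function(L, widths, occupied, gap = 10L) {
  slots <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(500L)) {
      s <- sample.int(L - w + 1L, 1L)
      e <- s + w - 1L
      ok <- !any(s <= occupied$end + gap & e >= occupied$start - gap)
      if (ok) {
        occupied <- bind_rows(occupied, tibble(start = s, end = e))
        slots[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("Could not place a planted segment; plasmid too short.")
  }
  list(starts = slots, occupied = occupied)
}

mutate_copy <- function(seq, rate) {
  if (rate <= 0) return(list(seq = seq, n_mut = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- resample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  list(seq = paste(bases, collapse = ""), n_mut = length(hit))
}

#' Generate a synthetic plasmid/spacer bundle with planted ground truth
#'
#' Builds, deterministically from the config seed, everything the pipeline
#' consumes plus a truth table: plasmid FASTA-ready sequences with planted
#' protospacers at recorded coordinates and strands, spacers tied to source
#' strains, lineages for strains and reported plasmid hosts, feature
#' annotations whose products encode known categories, decoy IS segments,
#' planted self-hits, MOB labels and a partial PTU map.
#'
#' @param config A [fixture_config()].
#' @return An object of class `plasmid_fixture`: a list with elements
#'   `config`, `taxonomy`, `plasmids`, `spacers`, `lineages`, `features`,
#'   `mob`, `ptu`, `truth`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, generate_fixture_impl(config))
}

generate_fixture_impl <- function(config) {
  tax <- generate_taxonomy_impl(config)
  # feasibility of grade targets before any heavy work
  for (g in names(config$planted_grade_targets)) {
    if (config$planted_grade_targets[[g]] > 0L && g != "I") {
      req <- grade_requirements()[[g]]
      feas <- tax %>%
        group_by(.data[[req[["within"]]]]) %>%
        summarise(nv = n_distinct(.data[[req[["vary"]]]]), .groups = "drop")
      if (max(feas$nv) < 2L) {
        abort(sprintf("Grade %s target infeasible for this taxonomy.", g))
      }
    }
  }

  # spacers per strain
  n_strains <- nrow(tax)
  sp_len <- function() sample(config$spacer_length[1]:config$spacer_length[2], 1L)
  spacers <- purrr::map_dfr(seq_len(n_strains), function(i) {
    tibble(
      spacer_id = sprintf("SP%06d", (i - 1L) * config$spacers_per_strain +
                            seq_len(config$spacers_per_strain)),
      sequence = vapply(seq_len(config$spacers_per_strain),
                        function(j) random_dna(sp_len()), character(1)),
      source_accession = tax$accession[i]
    )
  })

  decoys <- tibble(
    decoy_id = sprintf("ISDEC%02d", seq_len(config$decoy_is_elements)),
    sequence = vapply(seq_len(config$decoy_is_elements),
                      function(i) random_dna(400L), character(1))
  )

  grades <- rep(names(config$planted_grade_targets),
                config$planted_grade_targets)
  grades <- resample(grades, length(grades))

  n_self <- round(config$self_hit_fraction * config$n_plasmids)
  self_plasmids <- if (n_self > 0L) {
    sort(resample(seq_len(config$n_plasmids), n_self))
  } else integer()

  decoy_on <- if (config$decoy_is_elements > 0L) {
    purrr::map_dfr(seq_len(config$decoy_is_elements), function(d) {
      tibble(decoy_id = decoys$decoy_id[d],
             plasmid_idx = resample(seq_len(config$n_plasmids),
                                    min(3L, config$n_plasmids)))
    })
  } else tibble(decoy_id = character(), plasmid_idx = integer())

  products <- fixture_products()
  cat_w <- fixture_category_weights()
  self_counter <- 0L

  per_plasmid <- purrr::map(seq_len(config$n_plasmids), function(i) {
    acc <- sprintf("PLS%04d", i)
    L <- sample(config$plasmid_length[1]:config$plasmid_length[2], 1L)
    hosts <- pick_hosts(tax, grades[i])

    planted <- purrr::map_dfr(seq_len(nrow(hosts)), function(h) {
      pool <- spacers[spacers$source_accession == hosts$accession[h], ]
      chosen <- pool[resample(seq_len(nrow(pool)), 2L), ]
      chosen
    })
    if (i %in% self_plasmids) {
      self_counter <<- self_counter + 1L
      self_sp <- tibble(
        spacer_id = sprintf("SPSELF%04d", self_counter),
        sequence = random_dna(sp_len()),
        source_accession = acc
      )
      planted <- bind_rows(planted, self_sp)
    } else {
      self_sp <- NULL
    }
    planted$strand <- sample(c("+", "-"), nrow(planted), replace = TRUE)
    planted$category <- sample(names(cat_w), nrow(planted), replace = TRUE,
                               prob = cat_w)

    my_decoys <- decoys[decoys$decoy_id %in%
                          decoy_on$decoy_id[decoy_on$plasmid_idx == i], ]

    pad <- 20L
    widths <- c(nchar(planted$sequence) + 2L * pad,
                nchar(my_decoys$sequence),
                rep(200L, 2L))  # two extra untargeted features
    alloc <- allocate_slots(L, widths, tibble(start = integer(), end = integer()))
    starts <- alloc$starts
    n_pl <- nrow(planted)
    n_dc <- nrow(my_decoys)

    seq_chars <- strsplit(random_dna(L), "", fixed = TRUE)[[1L]]
    write_seg <- function(s1, seg) {
      seq_chars[s1:(s1 + nchar(seg) - 1L)] <<- strsplit(seg, "", fixed = TRUE)[[1L]]
    }

    proto <- purrr::map_dfr(seq_len(n_pl), function(p) {
      slot1 <- starts[p]
      ps1 <- slot1 + pad
      seg <- planted$sequence[p]
      if (planted$strand[p] == "-") seg <- revcomp(seg)
      mut <- mutate_copy(seg, config$mutation_rate)
      write_seg(ps1, mut$seq)
      tibble(
        spacer_id = planted$spacer_id[p],
        start0 = ps1 - 1L,
        end0 = ps1 - 1L + nchar(seg),
        strand = planted$strand[p],
        category = planted$category[p],
        mismatches = mut$n_mut,
        feature_id = sprintf("FEAT_%s_%03d", acc, p)
      )
    })
    for (d in seq_len(n_dc)) {
      write_seg(starts[n_pl + d], my_decoys$sequence[d])
    }

    feats <- bind_rows(
      tibble(
        accession = acc, feature_type = "CDS",
        start1 = starts[seq_len(n_pl)],
        end1 = starts[seq_len(n_pl)] + widths[seq_len(n_pl)] - 1L,
        strand = proto$strand,
        feature_id = proto$feature_id,
        product = vapply(proto$category,
                         function(cc) resample(products[[cc]], 1L), character(1),
                         USE.NAMES = FALSE),
        go_function = NA_character_
      ),
      if (n_dc > 0L) tibble(
        accession = acc, feature_type = "mobile_element",
        start1 = starts[n_pl + seq_len(n_dc)],
        end1 = starts[n_pl + seq_len(n_dc)] + nchar(my_decoys$sequence) - 1L,
        strand = "+",
        feature_id = paste0(my_decoys$decoy_id, "_", acc),
        product = "IS6 family transposase",
        go_function = NA_character_
      ),
      tibble(
        accession = acc, feature_type = "CDS",
        start1 = starts[n_pl + n_dc + 1:2],
        end1 = starts[n_pl + n_dc + 1:2] + 199L,
        strand = "+",
        feature_id = sprintf("FEAT_%s_X%02d", acc, 1:2),
        product = vapply(1:2, function(j) {
          resample(products$GENERAL_FUNCTIONAL, 1L)
        }, character(1)),
        go_function = NA_character_
      )
    )

    reported <- hosts[1L, ]
    truth_hosts <- sort(hosts$accession)
    truth_species <- sort(unique(normalize_species_name(hosts$species)))
    list(
      plasmid = tibble(accession = acc, sequence = paste(seq_chars, collapse = "")),
      reported_lineage = tibble(
        accession = acc, superkingdom = reported$superkingdom,
        phylum = reported$phylum, class = reported$class,
        order = reported$order, family = reported$family,
        genus = reported$genus, species = reported$species,
        strain = reported$strain
      ),
      features = feats,
      extra_spacers = self_sp,
      truth = tibble(
        plasmid_accession = acc, grade = grades[i],
        hosts = list(truth_hosts),
        species = list(truth_species),
        protospacers = list(proto),
        self_spacer_ids = list(if (is.null(self_sp)) character() else self_sp$spacer_id),
        decoy_is = list(sort(my_decoys$decoy_id))
      )
    )
  })

  plasmids <- purrr::map_dfr(per_plasmid, "plasmid")
  reported <- purrr::map_dfr(per_plasmid, "reported_lineage")
  features <- purrr::map_dfr(per_plasmid, "features")
  truth <- purrr::map_dfr(per_plasmid, "truth")
  all_spacers <- bind_rows(spacers,
                           purrr::map_dfr(per_plasmid, "extra_spacers"))

  mob <- tibble(
    accession = plasmids$accession,
    mob = sample(c("MOB+", "MOB-"), config$n_plasmids, replace = TRUE,
                 prob = c(0.55, 0.45))
  )
  n_ptu <- round(0.3 * config$n_plasmids)
  ptu <- if (n_ptu > 0L) {
    tibble(
      accession = sort(resample(plasmids$accession, n_ptu)),
      ptu = sprintf("PTU-%02d", sample.int(max(1L, ceiling(n_ptu / 4)),
                                           n_ptu, replace = TRUE))
    )
  } else tibble(accession = character(), ptu = character())

  structure(list(
    config = config, taxonomy = tax, plasmids = plasmids,
    spacers = all_spacers,
    lineages = bind_rows(tax, reported),
    features = features, mob = mob, ptu = ptu, truth = truth
  ), class = "plasmid_fixture")
}

#' @export
print.plasmid_fixture <- function(x, ...) {
  cat(sprintf(
    "<plasmid_fixture> %d plasmids, %d spacers (%d strains), %d features, seed %d\n",
    nrow(x$plasmids), nrow(x$spacers), nrow(x$taxonomy),
    nrow(x$features), x$config$seed))
  invisible(x)
}

encode_proto <- function(p) {
  paste(sprintf("%s|%d|%d|%s|%s|%d|%s", p$spacer_id, p$start0, p$end0,
                p$strand, p$category, p$mismatches, p$feature_id),
        collapse = ";")
}

decode_proto <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(tibble(spacer_id = character(), start0 = integer(),
                  end0 = integer(), strand = character(),
                  category = character(), mismatches = integer(),
                  feature_id = character()))
  }
  parts <- stringr::str_split_fixed(strsplit(s, ";", fixed = TRUE)[[1L]],
                                    stringr::fixed("|"), 7L)
  tibble(spacer_id = parts[, 1], start0 = as.integer(parts[, 2]),
         end0 = as.integer(parts[, 3]), strand = parts[, 4],
         category = parts[, 5], mismatches = as.integer(parts[, 6]),
         feature_id = parts[, 7])
}

#' Write / read a fixture bundle on disk
#'
#' Emits the exact file dialects the pipeline consumes: `plasmids.fasta`,
#' `spacers.tsv`, `lineages.tsv`, `features.tsv` (or `features.gff3`),
#' `mob.tsv`, `ptu.tsv` and `truth.tsv`. Re-reading the bundle reproduces
#' the in-memory tables.
#'
#' @param fixture A [generate_fixture()] object.
#' @param dir Output directory (created if needed).
#' @return `write_fixture_bundle()`: `dir`, invisibly;
#'   `read_fixture_bundle()`: a list with elements `plasmids`, `spacers`,
#'   `lineages`, `features`, `mob`, `ptu`, `truth`.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  stopifnot(inherits(fixture, "plasmid_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create fixture directory: ", dir))
  write_plasmid_fasta(fixture$plasmids, file.path(dir, "plasmids.fasta"))
  write_spacers_tsv(fixture$spacers, file.path(dir, "spacers.tsv"))
  write_lineages(fixture$lineages, file.path(dir, "lineages.tsv"))
  write_features_tsv(fixture$features, file.path(dir, "features.tsv"))
  readr::write_tsv(fixture$mob, file.path(dir, "mob.tsv"))
  readr::write_tsv(fixture$ptu, file.path(dir, "ptu.tsv"))
  flat <- fixture$truth %>%
    mutate(
      hosts = purrr::map_chr(.data$hosts, paste, collapse = ","),
      species = purrr::map_chr(.data$species, paste, collapse = ";"),
      protospacers = purrr::map_chr(.data$protospacers, encode_proto),
      self_spacer_ids = purrr::map_chr(.data$self_spacer_ids, paste, collapse = ","),
      decoy_is = purrr::map_chr(.data$decoy_is, paste, collapse = ",")
    )
  readr::write_tsv(flat, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  split_or_empty <- function(x, sep) {
    purrr::map(x, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, sep, fixed = TRUE)[[1L]]
    })
  }
  flat <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  truth <- flat %>%
    mutate(
      hosts = split_or_empty(.data$hosts, ","),
      species = split_or_empty(.data$species, ";"),
      protospacers = purrr::map(.data$protospacers, decode_proto),
      self_spacer_ids = split_or_empty(.data$self_spacer_ids, ","),
      decoy_is = split_or_empty(.data$decoy_is, ",")
    )
  list(
    plasmids = read_plasmid_fasta(file.path(dir, "plasmids.fasta")),
    spacers = read_spacers_tsv(file.path(dir, "spacers.tsv")),
    lineages = read_lineages(file.path(dir, "lineages.tsv")),
    features = read_features_tsv(file.path(dir, "features.tsv")),
    mob = read_mob_tsv(file.path(dir, "mob.tsv")),
    ptu = read_ptu_tsv(file.path(dir, "ptu.tsv")),
    truth = truth
  )
}
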