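# Small deterministic configurations and lineage constructors shared by the
# unit tests. The full-scale defaults are exercised in test-acceptance.R.

small_config <- function(seed = 11L, ...) {
  fixture_config(
    seed = seed,
    n_phyla = 3L, classes_per_phylum = 2L, orders_per_class = 2L,
    families_per_order = 2L, genera_per_family = 2L, species_per_genus = 1L,
    strains_per_species = 1L, spacers_per_strain = 3L,
    n_plasmids = 16L, plasmid_length = c(2500L, 4000L),
    planted_grade_targets = c(I = 6L, II = 4L, III = 2L, IV = 2L, V = 1L, VI = 1L),
    decoy_is_elements = 2L, self_hit_fraction = 0.125,
    ...
  )
}

# One lineage row; unspecified ranks fall back to a shared default so two
# rows differ exactly where the caller says they differ.
make_lineage <- function(species = "Escherichia coli", genus = "Escherichia",
                         family = "Enterobacteriaceae", order = "Enterobacterales",
                         class = "Gammaproteobacteria", phylum = "Pseudomonadota",
                         superkingdom = "Bacteria", strain = NA_character_) {
  tibble::tibble(superkingdom = superkingdom, phylum = phylum, class = class,
                 order = order, family = family, genus = genus,
                 species = species, strain = strain)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
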