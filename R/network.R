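new_host_network <- function(nodes, edges, unit = "plasmid") {
  nodes <- nodes %>% arrange(.data$node_class, .data$name)
  edges <- edges %>% distinct() %>% arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, unit = unit),
            class = "host_network")
}

#' @export
print.host_network <- function(x, ...) {
  cat(sprintf("<host_network> %d %s node(s), %d family node(s), %d edge(s)\n",
              sum(x$nodes$node_class == x$unit), x$unit,
              sum(x$nodes$node_class == "family"), nrow(x$edges)))
  invisible(x)
}

#' Bipartite plasmid-family (or PTU-family) host network
#'
#' One node per plasmid (or PTU) and per predicted host family; an edge
#' records the predicted presence of the plasmid in a host of that family.
#' Duplicate host species within a family collapse to a single edge. Family
#' nodes carry their phylum for coloring. Lineages without a family cannot
#' contribute and are skipped with a message.
#'
#' @param predictions Output of [predict_hosts()], or any tibble with the
#'   unit column, `family` and `phylum`.
#' @param unit_col Name of the unit column (default `"plasmid_accession"`).
#' @param unit_class Node class label for unit nodes (default `"plasmid"`).
#' @return An object of class `host_network` with tibbles `nodes` (`name`,
#'   `node_class`, `phylum`) and `edges` (`from` = unit, `to` = family,
#'   `relation = "hosts"`).
#' @export
build_family_network <- function(predictions, unit_col = "plasmid_accession",
                                 unit_class = "plasmid") {
  no_fam <- is.na(predictions$family)
  if (any(no_fam)) {
    inform(sprintf("Skipping %d prediction(s) without a family.", sum(no_fam)))
  }
  pred <- predictions[!no_fam, , drop = FALSE]
  edges <- pred %>%
    distinct(from = .data[[unit_col]], to = .data$family) %>%
    mutate(relation = "hosts")
  fam_nodes <- pred %>%
    distinct(name = .data$family, phylum = .data$phylum) %>%
    distinct(.data$name, .keep_all = TRUE) %>%
    mutate(node_class = "family")
  unit_nodes <- tibble(name = unique(pred[[unit_col]]),
                       phylum = NA_character_, node_class = unit_class)
  new_host_network(bind_rows(unit_nodes, fam_nodes), edges, unit = unit_class)
}

#' Prune small isolated families from a host network
#'
#' Removes each family node connected to fewer than `min_plasmids` plasmids
#' *and* not connected, via any of its plasmids, to another family (both
#' conditions must hold). Plasmid nodes left without any family are dropped
#' from the rendered graph. The rule is applied in a single pass over the
#' initial graph and is idempotent.
#'
#' @param net A `host_network`.
#' @param min_plasmids Minimum family degree to be kept unconditionally
#'   (default 10).
#' @return The pruned `host_network`.
#' @export
prune_isolated_families <- function(net, min_plasmids = 10L) {
  stopifnot(inherits(net, "host_network"), min_plasmids >= 0)
  fam_degree <- net$edges %>% count(.data$to, name = "degree")
  multi_family_units <- net$edges %>%
    count(.data$from, name = "n_families") %>%
    filter(.data$n_families >= 2L) %>%
    pull("from")
  connected <- net$edges %>%
    filter(.data$from %in% multi_family_units) %>%
    pull("to") %>%
    unique()
  drop_fams <- fam_degree %>%
    filter(.data$degree < min_plasmids, !.data$to %in% connected) %>%
    pull("to")
  edges <- net$edges %>% filter(!.data$to %in% drop_fams)
  keep_units <- unique(edges$from)
  nodes <- net$nodes %>%
    filter((.data$node_class == "family" & !.data$name %in% drop_fams) |
             (.data$node_class != "family" & .data$name %in% keep_units))
  new_host_network(nodes, edges, unit = net$unit)
}

#' Collapse plasmid predictions to plasmid taxonomic units
#'
#' All plasmids mapped to the same PTU are collapsed into one record whose
#' host set is the union of the member plasmids' predicted hosts. Plasmids
#' without a PTU assignment are absent from the PTU-level analysis.
#'
#' @param predictions Output of [predict_hosts()].
#' @param ptu_map Tibble with columns `accession`, `ptu`.
#' @return A tibble with one row per (PTU, family): `ptu`, `family`,
#'   `phylum`.
#' @export
collapse_to_ptu <- function(predictions, ptu_map) {
  predictions %>%
    dplyr::inner_join(ptu_map, by = c(plasmid_accession = "accession")) %>%
    filter(!is.na(.data$ptu), !is.na(.data$family)) %>%
    distinct(.data$ptu, .data$family, .keep_all = TRUE) %>%
    select("ptu", "family", "phylum")
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "relation")],
    directed = FALSE,
    vertices = net$nodes[, c("name", "node_class", "phylum")]
  )
}

#' Export a host network for Cytoscape and friends
#'
#' GraphML carries node attributes (`node_class`, `phylum`); SIF uses the
#' relation `hosts`; `edge_tsv` is a plain three-column table. Node and edge
#' ordering is deterministic, so identical networks export byte-identically.
#'
#' @param net A `host_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif", "edge_tsv")) {
  stopifnot(inherits(net, "host_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::V(g)$phylum <- ifelse(is.na(igraph::V(g)$phylum), "",
                                  igraph::V(g)$phylum)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(paste(net$edges$from, net$edges$relation, net$edges$to,
                     sep = "\t"), path)
  } else {
    readr::write_tsv(
      tibble(source = net$edges$from, target = net$edges$to,
             relation = net$edges$relation),
      path
    )
  }
  invisible(path)
}
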