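# The merged gene-pathway interaction multigraph: text-mined regulatory and
# binding edges plus curated pathway-membership edges, with the topology
# metrics used to characterise it (clustering, components, path lengths,
# degree hubs, betweenness bottlenecks).

#' Construct an interaction network object
#'
#' An interaction network is a multigraph over typed node keys: genes are
#' labelled by their bare Entrez ID, pathways by a `PW:`-prefixed canonical
#' id. Edges form a multiset — a text-mined interaction and a curated
#' membership edge between the same endpoints coexist — and path-based
#' statistics are computed on the simplified (parallel-edge-collapsed)
#' projection.
#'
#' @param edges Tibble with columns `node_a`, `node_b`, `relation`
#'   (`reg`, `pos_reg`, `neg_reg`, `binding`, `member_of`), `origin`
#'   (`TEXT_MINED`, `CURATED`).
#' @param nodes Optional tibble with columns `node`, `kind`; defaults to the
#'   endpoints of `edges`.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble(
      node_a = character(), node_b = character(),
      relation = character(), origin = character()
    )
  }
  edges <- as_tibble(edges)
  stopifnot(all(c("node_a", "node_b", "relation", "origin") %in% names(edges)))
  if (any(edges$node_a == edges$node_b)) {
    abort("Self-loop edges are not allowed", class = "pathevents_network_error")
  }
  if (!all(edges$relation %in% unname(SIF_RELATIONS))) {
    abort("Unknown edge relation", class = "pathevents_network_error")
  }
  edges <- canonicalize_edges(edges)
  if (is.null(nodes)) {
    keys <- sort(unique(c(edges$node_a, edges$node_b)))
    nodes <- tibble(node = keys, kind = node_kind(keys))
  } else {
    nodes <- dplyr::arrange(as_tibble(nodes), .data$node)
    missing <- setdiff(c(edges$node_a, edges$node_b), nodes$node)
    if (length(missing) > 0) {
      abort(
        paste0("Edge endpoint(s) missing from node set: ", paste(missing, collapse = ", ")),
        class = "pathevents_network_error"
      )
    }
  }
  bad_member <- edges$relation == "member_of" &
    !(node_kind(edges$node_a) == "GENE" & node_kind(edges$node_b) == "PATHWAY")
  if (any(bad_member)) {
    abort(
      "member_of edges must connect exactly one gene and one pathway",
      class = "pathevents_network_error"
    )
  }
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

# store edges in a canonical orientation: member_of as gene -> pathway,
# everything else with the lexicographically smaller key first; row order
# sorted so identical networks are identical objects
canonicalize_edges <- function(edges) {
  memb <- edges$relation == "member_of"
  flip <- !memb & edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  flip_m <- memb & node_kind(edges$node_a) == "PATHWAY"
  tmp <- edges$node_a[flip_m]
  edges$node_a[flip_m] <- edges$node_b[flip_m]
  edges$node_b[flip_m] <- tmp
  dplyr::arrange(edges, .data$node_a, .data$relation, .data$node_b, .data$origin)
}

#' @export
print.interaction_network <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = c("GENE", "PATHWAY")))
  cat(
    "<interaction_network> ", nrow(x$nodes), " nodes (",
    kinds[["GENE"]], " genes, ", kinds[["PATHWAY"]], " pathways), ",
    nrow(x$edges), " edges (", sum(x$edges$origin == "TEXT_MINED"), " text-mined, ",
    sum(x$edges$origin == "CURATED"), " curated)\n",
    sep = ""
  )
  invisible(x)
}

# simplified undirected igraph projection (parallel edges collapsed); used by
# all path-based statistics
as_simple_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")],
    directed = FALSE,
    vertices = net$nodes$node
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Build the text-mined interaction network from unique pairs
#'
#' Adds one `TEXT_MINED` edge per unique interaction pair; the node set is
#' exactly the set of pair endpoints.
#'
#' @param pairs Unique-pairs tibble from [extract_unique_pairs()] (columns
#'   `node_a`, `node_b`, `category`).
#' @return An `interaction_network`.
#' @export
build_network <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(interaction_network())
  }
  interaction_network(tibble(
    node_a = pairs$node_a, node_b = pairs$node_b,
    relation = category_to_relation(pairs$category),
    origin = "TEXT_MINED"
  ))
}

#' Add curated pathway-membership edges
#'
#' For every gene node A and pathway node C present in the network with A a
#' curated member of C, a `member_of` edge `<A, C>` of origin `CURATED` is
#' added. With `expand_members = TRUE`, all curated member genes of pathways
#' present in the network are additionally added as new nodes with their
#' membership edges; by default no nodes are added. The operation is
#' idempotent: an existing curated membership edge is not duplicated.
#'
#' @param net An `interaction_network`.
#' @param db Pathway DB tibble from [read_pathway_db()].
#' @param expand_members Add member genes absent from the network as nodes?
#' @return The augmented `interaction_network`.
#' @export
add_curated_edges <- function(net, db, expand_members = FALSE) {
  pw_nodes <- net$nodes$node[net$nodes$kind == "PATHWAY"]
  if (length(pw_nodes) == 0) {
    return(net)
  }
  gene_nodes <- net$nodes$node[net$nodes$kind == "GENE"]
  db_present <- db[pathway_key(db$canonical_id) %in% pw_nodes, ]
  new_edges <- purrr::map_dfr(seq_len(nrow(db_present)), function(i) {
    members <- gene_key(db_present$members[[i]])
    if (!expand_members) members <- intersect(members, gene_nodes)
    if (length(members) == 0) {
      return(NULL)
    }
    tibble(
      node_a = members,
      node_b = pathway_key(db_present$canonical_id[[i]]),
      relation = "member_of", origin = "CURATED"
    )
  })
  if (nrow(new_edges) == 0) {
    return(net)
  }
  existing <- paste(net$edges$node_a, net$edges$node_b, net$edges$relation, net$edges$origin)
  new_edges <- new_edges[!paste(
    new_edges$node_a, new_edges$node_b,
    new_edges$relation, new_edges$origin
  ) %in% existing, ]
  nodes <- net$nodes
  extra <- setdiff(c(new_edges$node_a, new_edges$node_b), nodes$node)
  if (length(extra) > 0) {
    nodes <- dplyr::bind_rows(nodes, tibble(node = extra, kind = node_kind(extra)))
  }
  interaction_network(dplyr::bind_rows(net$edges, new_edges), nodes)
}

#' Compute network topology statistics
#'
#' Statistics follow the conventions of Cytoscape's NetworkAnalyzer: the mean
#' clustering coefficient averages the local coefficient `2e / (k (k - 1))`
#' over all nodes (nodes with fewer than two neighbours contribute 0);
#' diameter and characteristic path length are taken over connected unordered
#' node pairs of the simplified graph (unweighted shortest paths,
#' disconnected pairs ignored); density is the mean distinct-neighbour count
#' divided by `n - 1`. Parallel edges only affect `edge_count` and
#' `multi_edge_node_pairs`. Path statistics are `NA` on an edgeless network.
#'
#' @param net An `interaction_network`.
#' @return A one-row tibble of statistics.
#' @export
compute_stats <- function(net) {
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  if (n == 0) {
    return(tibble(
      node_count = 0L, edge_count = 0L, clustering_coefficient = NA_real_,
      connected_components = 0L, diameter = NA_real_,
      characteristic_path_length = NA_real_, avg_neighbors = NA_real_,
      density = NA_real_, multi_edge_node_pairs = 0L
    ))
  }
  gs <- as_simple_igraph(net)
  cc_local <- igraph::transitivity(gs, type = "local", isolates = "zero")
  cc_local[is.nan(cc_local)] <- 0
  comps <- as.integer(igraph::components(gs)$no)
  if (igraph::ecount(gs) == 0) {
    diam <- NA_real_
    cpl <- NA_real_
  } else {
    diam <- igraph::diameter(gs, unconnected = TRUE, weights = NA)
    cpl <- igraph::mean_distance(gs, weights = NA, unconnected = TRUE)
  }
  avg_nb <- mean(igraph::degree(gs))
  multi <- net$edges %>%
    dplyr::count(.data$node_a, .data$node_b) %>%
    dplyr::filter(.data$n > 1) %>%
    nrow()
  tibble(
    node_count = n, edge_count = m,
    clustering_coefficient = mean(cc_local),
    connected_components = comps,
    diameter = as.numeric(diam),
    characteristic_path_length = cpl,
    avg_neighbors = avg_nb,
    density = if (n > 1) avg_nb / (n - 1) else NA_real_,
    multi_edge_node_pairs = as.integer(multi)
  )
}

#' Rank hub nodes by degree
#'
#' Degree counts edge multiplicity (a node joined to another by both a
#' text-mined and a curated edge gains 2). Ties are broken by node key,
#' ascending.
#'
#' @param net An `interaction_network`.
#' @param k Number of top nodes to return.
#' @return A tibble with columns `node`, `kind`, `score`, `rank`.
#' @export
rank_hubs <- function(net, k = 10) {
  stopifnot(k >= 0)
  deg <- table(factor(c(net$edges$node_a, net$edges$node_b), levels = net$nodes$node))
  ranked <- tibble(node = names(deg), score = as.numeric(deg)) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$node) %>%
    head(k)
  ranked$kind <- node_kind(ranked$node)
  ranked$rank <- seq_len(nrow(ranked))
  ranked[, c("node", "kind", "score", "rank")]
}

#' Rank bottleneck nodes by betweenness centrality
#'
#' Bottlenecks are nodes through which many shortest paths pass. Scores are
#' unnormalized vertex betweenness on the simplified undirected graph, with
#' fractional credit when several shortest paths tie. Ties in score are
#' broken by node key, ascending.
#'
#' @inheritParams rank_hubs
#' @return A tibble with columns `node`, `kind`, `score`, `rank`.
#' @export
rank_bottlenecks <- function(net, k = 10) {
  stopifnot(k >= 0)
  if (nrow(net$nodes) == 0) {
    return(tibble(
      node = character(), kind = character(),
      score = numeric(), rank = integer()
    ))
  }
  gs <- as_simple_igraph(net)
  btw <- igraph::betweenness(gs, directed = FALSE, weights = NA)
  ranked <- tibble(node = names(btw), score = as.numeric(btw)) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$node) %>%
    head(k)
  ranked$kind <- node_kind(ranked$node)
  ranked$rank <- seq_len(nrow(ranked))
  ranked[, c("node", "kind", "score", "rank")]
}

# SIF ------------------------------------------------------------------------

#' Write an interaction network in SIF format
#'
#' One tab-separated line per edge, `nodeA<TAB>relation<TAB>nodeB`, with
#' genes labelled by bare Entrez ID and pathways by `PW:`-prefixed canonical
#' id. Lines are sorted lexicographically, so identical networks produce
#' byte-identical files.
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  lines <- sprintf("%s\t%s\t%s", net$edges$node_a, net$edges$relation, net$edges$node_b)
  writeLines(sort(lines), path)
  invisible(path)
}

#' Read an interaction network from SIF format
#'
#' Inverse of [write_sif()]: `member_of` edges become `CURATED`, all other
#' relations `TEXT_MINED`. Isolated nodes are not representable in SIF, so
#' the node set is the set of edge endpoints.
#'
#' @param path Path to a SIF file.
#' @return An `interaction_network`.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SIF file not found: ", path), class = "pathevents_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(interaction_network())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    abort(
      paste0("Malformed SIF line: ", lines[lengths(parts) != 3][[1]]),
      class = "pathevents_parse_error"
    )
  }
  rel <- vapply(parts, `[[`, character(1), 2)
  if (!all(rel %in% unname(SIF_RELATIONS))) {
    abort(
      paste0("Unknown SIF relation(s): ", paste(setdiff(rel, SIF_RELATIONS), collapse = ", ")),
      class = "pathevents_parse_error"
    )
  }
  interaction_network(tibble(
    node_a = vapply(parts, `[[`, character(1), 1),
    node_b = vapply(parts, `[[`, character(1), 3),
    relation = rel,
    origin = ifelse(rel == "member_of", "CURATED", "TEXT_MINED")
  ))
}

# broom-style accessors -------------------------------------------------------

#' Tidy an interaction network into its edge table
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return The edge tibble (`node_a`, `node_b`, `relation`, `origin`).
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) {
  x$edges
}

#' One-row topology summary of an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return The [compute_stats()] tibble.
#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  compute_stats(x)
}

#' Plot the degree structure of an interaction network
#'
#' Shows the top-degree nodes as a horizontal lollipop chart, coloured by
#' node kind — a quick visual of where the hubs sit and whether they are
#' genes or pathways.
#'
#' @param object An `interaction_network`.
#' @param k Number of top-degree nodes to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_network
#' @export
autoplot.interaction_network <- function(object, k = 15, ...) {
  hubs <- rank_hubs(object, k)
  ggplot2::ggplot(hubs, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$node, .data$score),
    colour = .data$kind
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(.data$node, .data$score))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "degree (edge multiplicity counted)", y = NULL, colour = NULL,
      title = "Highest-degree nodes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ranked-node table
#'
#' @param object A tibble from [rank_hubs()] or [rank_bottlenecks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ranked_nodes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$node, .data$score),
    colour = .data$kind
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "score", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
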