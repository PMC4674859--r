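pair_row <- function(a, b, category = "NEGATIVE_REGULATION") {
  tibble::tibble(node_a = a, node_b = b, category = category)
}

test_that("network construction uses exactly the pair endpoints as nodes", {
  net <- build_network(pair_row("5329", "PW:fak_pi3k_akt"))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$relation, "neg_reg")
  expect_equal(sort(net$nodes$kind), c("GENE", "PATHWAY"))

  expect_equal(nrow(build_network(pair_row(character(0), character(0)))$nodes), 0)

  # node set is the union of endpoint sets on random pair tables
  withr::with_seed(3, {
    for (rep in 1:10) {
      pairs <- tibble::tibble(
        node_a = as.character(sample(1:9, 6, replace = TRUE)),
        node_b = as.character(sample(11:19, 6, replace = TRUE)),
        category = sample(PAIR_CATEGORIES, 6, replace = TRUE)
      )
      net <- build_network(pairs)
      expect_setequal(net$nodes$node, unique(c(pairs$node_a, pairs$node_b)))
      expect_equal(nrow(net$edges), nrow(pairs))
    }
  })

  # self-loops are rejected by the container
  expect_error(
    interaction_network(tibble::tibble(
      node_a = "1", node_b = "1", relation = "reg", origin = "TEXT_MINED"
    )),
    class = "pathevents_network_error"
  )
})

test_that("curated membership edges join co-present gene/pathway nodes", {
  db <- read_pathway_db_from_lines(c(
    "pi3k_akt\tPI3K/Akt pathway\tKEGG\tPI3K/Akt pathway\t207;5290",
    "apop\tApoptosis\tKEGG\tApoptosis\t207;7157"
  ))
  net <- build_network(dplyr::bind_rows(
    pair_row("207", "PW:pi3k_akt", "POSITIVE_REGULATION"),
    pair_row("5979", "PW:pi3k_akt", "REGULATION")
  ))
  aug <- add_curated_edges(net, db)
  # AKT1 (207) is a member of PI3K/Akt and both are present: one new edge
  expect_equal(nrow(aug$edges), nrow(net$edges) + 1)
  memb <- aug$edges[aug$edges$relation == "member_of", ]
  expect_equal(memb$node_a, "207")
  expect_equal(memb$node_b, "PW:pi3k_akt")
  expect_equal(memb$origin, "CURATED")
  # no nodes added by default, idempotent on reapplication
  expect_equal(aug$nodes, net$nodes)
  expect_equal(add_curated_edges(aug, db), aug)

  # no gene/pathway co-presence -> unchanged
  lone <- build_network(pair_row("1", "2", "BINDING"))
  expect_equal(add_curated_edges(lone, db), lone)

  # expand_members adds the missing member genes with their edges
  exp <- add_curated_edges(net, db, expand_members = TRUE)
  expect_true("5290" %in% exp$nodes$node)
  expect_equal(sum(exp$edges$relation == "member_of"), 2)

  # edge-count increase equals a brute-force double loop over the defaults
  withr::with_seed(13, {
    for (rep in 1:10) {
      genes <- as.character(sample(200:220, 5))
      pws <- sprintf("pw%d", 1:3)
      pairs <- tibble::tibble(
        node_a = genes[1:3],
        node_b = paste0("PW:", sample(pws, 3, replace = TRUE)),
        category = "REGULATION"
      )
      db_r <- tibble::tibble(
        canonical_id = pws,
        canonical_name = paste(pws, "signaling"),
        synonyms = replicate(3, tibble::tibble(
          source_db = character(0), name = character(0)
        ), simplify = FALSE),
        members = replicate(3, as.integer(sample(200:220, 6)), simplify = FALSE)
      )
      net_r <- build_network(pairs)
      aug_r <- add_curated_edges(net_r, db_r)
      count <- 0
      for (g in net_r$nodes$node[net_r$nodes$kind == "GENE"]) {
        for (p in net_r$nodes$node[net_r$nodes$kind == "PATHWAY"]) {
          cid <- sub("^PW:", "", p)
          if (as.integer(g) %in% db_r$members[[match(cid, db_r$canonical_id)]]) {
            count <- count + 1
          }
        }
      }
      expect_equal(nrow(aug_r$edges) - nrow(net_r$edges), count)
    }
  })
})

test_that("topology statistics match closed forms on canonical small graphs", {
  triangle <- interaction_network(tibble::tibble(
    node_a = c("a", "a", "b"), node_b = c("b", "c", "c"),
    relation = "reg", origin = "TEXT_MINED"
  ))
  st <- compute_stats(triangle)
  expect_equal(st$clustering_coefficient, 1)
  expect_equal(st$connected_components, 1L)
  expect_equal(st$diameter, 1)
  expect_equal(st$density, 1)

  # path a-b-c: distances 1, 1, 2 -> mean 4/3, diameter 2, clustering 0
  path3 <- interaction_network(tibble::tibble(
    node_a = c("a", "b"), node_b = c("b", "c"),
    relation = "reg", origin = "TEXT_MINED"
  ))
  sp <- compute_stats(path3)
  expect_equal(sp$characteristic_path_length, 4 / 3)
  expect_equal(sp$diameter, 2)
  expect_equal(sp$clustering_coefficient, 0)
  expect_equal(sp$avg_neighbors, 4 / 3)
  expect_equal(sp$density, 2 / 3)

  # edgeless network: path statistics undefined
  iso <- interaction_network(NULL, tibble::tibble(node = c("a", "b"), kind = "GENE"))
  si <- compute_stats(iso)
  expect_true(is.na(si$diameter) && is.na(si$characteristic_path_length))
  expect_equal(si$connected_components, 2L)

  # empty network
  expect_equal(compute_stats(interaction_network())$node_count, 0L)

  # parallel edges change only edge_count and multi_edge_node_pairs
  multi <- interaction_network(tibble::tibble(
    node_a = c("a", "a", "b"), node_b = c("b", "b", "c"),
    relation = c("reg", "pos_reg", "reg"), origin = "TEXT_MINED"
  ))
  sm <- compute_stats(multi)
  expect_equal(sm$edge_count, 3L)
  expect_equal(sm$multi_edge_node_pairs, 1L)
  expect_equal(sm$characteristic_path_length, compute_stats(path3)$characteristic_path_length)
})

test_that("hub ranking counts edge multiplicity and breaks ties by node key", {
  star <- interaction_network(tibble::tibble(
    node_a = c("x", "x", "x"), node_b = c("a", "b", "c"),
    relation = "reg", origin = "TEXT_MINED"
  ))
  top <- rank_hubs(star, 1)
  expect_equal(top$node, "x")
  expect_equal(top$score, 3)
  expect_equal(top$rank, 1L)

  expect_equal(nrow(rank_hubs(star, 0)), 0)

  # ties: equal degree ranks ascend by node key
  tied <- rank_hubs(star, 4)
  expect_equal(tied$node, c("x", "a", "b", "c"))

  # equals a full sort oracle on random multigraphs
  withr::with_seed(29, {
    for (rep in 1:15) {
      net <- random_network(sample(3:8, 1))
      got <- rank_hubs(net, nrow(net$nodes))
      deg <- vapply(net$nodes$node, function(v) {
        sum(net$edges$node_a == v) + sum(net$edges$node_b == v)
      }, numeric(1))
      ord <- order(-deg, names(deg))
      expect_equal(got$node, names(deg)[ord])
      expect_equal(got$score, unname(deg[ord]))
      expect_true(all(diff(got$score) <= 0))
    }
  })
})

test_that("bottleneck scores equal brute-force shortest-path betweenness", {
  path3 <- interaction_network(tibble::tibble(
    node_a = c("a", "b"), node_b = c("b", "c"),
    relation = "reg", origin = "TEXT_MINED"
  ))
  r <- rank_bottlenecks(path3, 3)
  expect_equal(r$score[r$node == "b"], 1)
  expect_equal(sum(r$score), 1)

  single <- interaction_network(NULL, tibble::tibble(node = "a", kind = "GENE"))
  expect_equal(rank_bottlenecks(single, 1)$score, 0)

  withr::with_seed(37, {
    for (rep in 1:20) {
      net <- random_network(sample(2:8, 1), p = 0.45)
      adj <- net_adjacency(net)
      expected <- oracle_betweenness(adj)
      got <- rank_bottlenecks(net, nrow(net$nodes))
      expect_equal(
        got$score[match(names(expected), got$node)],
        unname(expected),
        tolerance = 1e-10
      )
      # leaves always score zero
      leaves <- names(which(rowSums(adj) == 1))
      expect_true(all(got$score[got$node %in% leaves] == 0))
    }
  })

  # over a tree every pair has a unique path, so total betweenness equals
  # the summed interior-vertex count: sum of (d - 1) over connected pairs
  tree <- interaction_network(tibble::tibble(
    node_a = c("r", "r", "a", "a"), node_b = c("a", "b", "c", "d"),
    relation = "reg", origin = "TEXT_MINED"
  ))
  d <- oracle_dist(net_adjacency(tree))
  du <- d[upper.tri(d)]
  expect_equal(sum(rank_bottlenecks(tree, 5)$score), sum(du[is.finite(du)] - 1))
})

test_that("stats agree with the Floyd-Warshall and triangle-count oracles on random graphs", {
  withr::with_seed(43, {
    for (rep in 1:25) {
      net <- random_network(sample(2:8, 1), p = 0.4)
      st <- compute_stats(net)
      adj <- net_adjacency(net)
      expect_equal(st$clustering_coefficient, oracle_clustering(adj), tolerance = 1e-12)
      expect_equal(st$connected_components, oracle_components(adj))
      ps <- oracle_path_stats(adj)
      if (is.na(ps$diameter)) {
        expect_true(is.na(st$diameter))
      } else {
        expect_equal(st$diameter, ps$diameter)
        expect_equal(st$characteristic_path_length, ps$cpl, tolerance = 1e-12)
      }
      expect_equal(st$avg_neighbors, mean(rowSums(adj)), tolerance = 1e-12)
      expect_true(st$density >= 0 && st$density <= 1)
      expect_true(st$connected_components >= 1 && st$connected_components <= st$node_count)
    }
  })
})

test_that("broom accessors and plots expose the network tabularly", {
  net <- build_network(dplyr::bind_rows(
    pair_row("1", "2", "BINDING"), pair_row("2", "3", "REGULATION")
  ))
  expect_equal(tidy(net), net$edges)
  expect_equal(glance(net), compute_stats(net))
  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
  p2 <- plot_ranked_nodes(rank_bottlenecks(net, 3))
  expect_s3_class(p2, "ggplot")
})
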