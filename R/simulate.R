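# Synthetic corpus generator: templated sentences with exactly controlled
# character offsets, standoff annotations, matching gene lexicon and pathway
# dictionary, and planted ground-truth interaction pairs, so every pipeline
# stage can be validated end to end without external corpora.

#' Configuration for the synthetic corpus generator
#'
#' The defaults describe the study conditions used throughout the package's
#' own validation: 100 abstracts-worth of documents, a Poisson(3) number of
#' event sentences per document, a vocabulary of 40 genes and 8 pathways,
#' 30% of regulation events nested (the cause wrapped in an
#' over/under-expression sub-event), 20% binding events, and a 35% chance
#' for each regulation endpoint to be a pathway. `unmappable_fraction` is
#' the per-event probability that one participant's surface form is swapped
#' for an out-of-lexicon form, making the whole event tree unmappable — so
#' the expected fraction of discarded event rows equals this value exactly.
#'
#' @param n_docs Number of documents.
#' @param n_genes Gene vocabulary size.
#' @param n_pathways Pathway dictionary size.
#' @param events_per_doc Mean of the Poisson event-sentence count per
#'   document.
#' @param nesting_probability Probability a regulation event nests its cause
#'   in a sub-event.
#' @param binding_fraction Fraction of events that are multi-theme bindings.
#' @param pathway_probability Probability a regulation endpoint is a pathway
#'   rather than a gene.
#' @param phospho_fraction Fraction of (non-binding) events that are plain
#'   phosphorylations — pairless noise exercising the event-type filter.
#' @param unmappable_fraction Per-event probability of planting an
#'   unmappable participant.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_docs = 100, n_genes = 40, n_pathways = 8,
                           events_per_doc = 3, nesting_probability = 0.3,
                           binding_fraction = 0.2, pathway_probability = 0.35,
                           phospho_fraction = 0.1, unmappable_fraction = 0,
                           seed = 1) {
  fracs <- c(
    nesting_probability = nesting_probability, binding_fraction = binding_fraction,
    pathway_probability = pathway_probability, phospho_fraction = phospho_fraction,
    unmappable_fraction = unmappable_fraction
  )
  if (any(fracs < 0 | fracs > 1)) {
    abort(
      paste0(
        "Fractions must lie in [0, 1]: ",
        paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", ")
      ),
      class = "pathevents_config_error"
    )
  }
  counts <- c(n_docs = n_docs, n_genes = n_genes, n_pathways = n_pathways)
  if (any(counts < 0) || events_per_doc < 0) {
    abort("Counts must be non-negative", class = "pathevents_config_error")
  }
  if (n_docs > 0 && (n_genes < 4 || n_pathways < 1)) {
    abort("Need at least 4 genes and 1 pathway to generate documents",
      class = "pathevents_config_error"
    )
  }
  structure(
    list(
      n_docs = as.integer(n_docs), n_genes = as.integer(n_genes),
      n_pathways = as.integer(n_pathways), events_per_doc = events_per_doc,
      nesting_probability = nesting_probability, binding_fraction = binding_fraction,
      pathway_probability = pathway_probability, phospho_fraction = phospho_fraction,
      unmappable_fraction = unmappable_fraction, seed = as.integer(seed)
    ),
    class = "fixture_config"
  )
}

# distinct pronounceable-ish uppercase symbols, guaranteed unique
make_symbols <- function(n, width, prefix = "") {
  if (n == 0) {
    return(character(0))
  }
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i) {
      paste0(prefix, paste(sample(LETTERS, width, replace = TRUE), collapse = ""), sample(1:9, 1))
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

# sentence accumulator with exact character offsets
new_sentence <- function() {
  env <- new.env(parent = emptyenv())
  env$text <- ""
  env$mentions <- list()
  env$triggers <- list()
  env$events <- list()
  env
}

s_text <- function(s, str) {
  s$text <- paste0(s$text, str)
  invisible(NULL)
}

s_mention <- function(s, local, surface, entity_class) {
  start <- nchar(s$text)
  s_text(s, surface)
  s$mentions[[local]] <- list(
    local = local, start = start, end = nchar(s$text),
    surface = surface, entity_class = entity_class
  )
}

s_trigger <- function(s, local, word) {
  start <- nchar(s$text)
  s_text(s, word)
  s$triggers[[local]] <- list(local = local, start = start, end = nchar(s$text), text = word)
}

s_event <- function(s, local, type, trigger, themes, cause = NA_character_) {
  s$events[[local]] <- list(
    local = local, type = type, trigger = trigger,
    themes = themes, cause = cause
  )
}

REG_TRIGGERS <- list(
  Positive_regulation = c(main = "activates", sub = "Overexpression"),
  Negative_regulation = c(main = "inhibits", sub = "Downregulation"),
  Regulation = c(main = "regulates", sub = "Modulation")
)

# A and B are lists: (surface, entity_class, key) — key NA when unmappable
sentence_regulation <- function(type, A, B, nested) {
  s <- new_sentence()
  tr <- REG_TRIGGERS[[type]]
  if (nested) {
    s_trigger(s, "t1", tr[["sub"]])
    s_text(s, " of ")
    s_mention(s, "m1", A$surface, A$entity_class)
    s_text(s, " ")
    s_trigger(s, "t2", tr[["main"]])
    s_text(s, " ")
    s_mention(s, "m2", B$surface, B$entity_class)
    s_text(s, ".")
    s_event(s, "e1", type, "t1", themes = "m1")
    s_event(s, "e2", type, "t2", themes = "m2", cause = "e1")
  } else {
    s_mention(s, "m1", A$surface, A$entity_class)
    s_text(s, " ")
    s_trigger(s, "t1", tr[["main"]])
    s_text(s, " ")
    s_mention(s, "m2", B$surface, B$entity_class)
    s_text(s, ".")
    s_event(s, "e1", type, "t1", themes = "m2", cause = "m1")
  }
  s
}

sentence_binding <- function(participants) {
  s <- new_sentence()
  s_mention(s, "m1", participants[[1]]$surface, "GENE")
  s_text(s, " ")
  s_trigger(s, "t1", "interacts")
  s_text(s, " with ")
  s_mention(s, "m2", participants[[2]]$surface, "GENE")
  if (length(participants) > 2) {
    s_text(s, " and ")
    s_mention(s, "m3", participants[[3]]$surface, "GENE")
  }
  s_text(s, ".")
  s_event(s, "e1", "Binding", "t1", themes = paste0("m", seq_along(participants)))
  s
}

sentence_phospho <- function(A) {
  s <- new_sentence()
  s_mention(s, "m1", A$surface, "GENE")
  s_text(s, " is ")
  s_trigger(s, "t1", "phosphorylated")
  s_text(s, ".")
  s_event(s, "e1", "Phosphorylation", "t1", themes = "m1")
  s
}

#' Generate a synthetic standoff corpus with planted ground truth
#'
#' Produces documents, standoff mentions and events, a gene lexicon, a
#' pathway dictionary, and the planted interaction pairs that a correct
#' pipeline run must recover. Pathway-involved events are always regulation
#' typed, nesting wraps regulation causes in expression-change sub-events,
#' and binding sentences carry two or three gene themes. Identical configs
#' produce byte-identical corpora.
#'
#' @param cfg A [fixture_config()].
#' @return A `synthetic_corpus` list with elements `documents`, `mentions`,
#'   `events`, `lexicon`, `pathway_db`, and `truth` (list: `pairs`,
#'   `n_event_rows`, `n_discard_rows`, `n_corrupted_trees`).
#' @export
generate_corpus <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_local_seed(cfg$seed, generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  empty_truth <- list(
    pairs = tibble(node_a = character(), node_b = character(), category = character()),
    n_event_rows = 0L, n_discard_rows = 0L, n_corrupted_trees = 0L
  )
  # vocabulary ---------------------------------------------------------------
  gene_surfaces <- make_symbols(cfg$n_genes, 4)
  lexicon <- tibble(surface = gene_surfaces, entrez_id = 1000L + seq_len(cfg$n_genes))
  pw_tokens <- make_symbols(cfg$n_pathways, 5)
  pathway_db <- tibble(
    canonical_id = sprintf("pw%02d", seq_len(cfg$n_pathways)),
    canonical_name = paste(pw_tokens, "signaling pathway"),
    synonyms = lapply(pw_tokens, function(tok) {
      tibble(
        source_db = c("KEGG", "WikiPathways"),
        name = c(paste(tok, "signaling"), paste(tok, "pathway"))
      )
    }),
    members = replicate(cfg$n_pathways,
      sort(sample(lexicon$entrez_id, sample(3:min(8, cfg$n_genes), 1))),
      simplify = FALSE
    )
  )
  if (cfg$n_docs == 0) {
    return(structure(
      list(
        documents = tibble(doc_id = character(), text = character()),
        mentions = empty_mentions(), events = empty_events(),
        lexicon = lexicon, pathway_db = pathway_db, truth = empty_truth
      ),
      class = "synthetic_corpus"
    ))
  }
  # out-of-lexicon surfaces used to plant unmappable participants
  unk_genes <- make_symbols(50, 3, prefix = "ORF")
  unk_pathways <- paste(make_symbols(50, 6, prefix = "X"), "signaling")

  draw_gene <- function() {
    i <- sample.int(cfg$n_genes, 1)
    list(
      surface = lexicon$surface[[i]], entity_class = "GENE",
      key = gene_key(lexicon$entrez_id[[i]])
    )
  }
  draw_pathway <- function() {
    i <- sample.int(cfg$n_pathways, 1)
    forms <- c(pathway_db$canonical_name[[i]], pathway_db$synonyms[[i]]$name)
    list(
      surface = forms[[sample.int(length(forms), 1)]], entity_class = "PATHWAY",
      key = pathway_key(pathway_db$canonical_id[[i]])
    )
  }
  draw_endpoint <- function() {
    if (stats::runif(1) < cfg$pathway_probability) draw_pathway() else draw_gene()
  }
  corrupt <- function(p) {
    if (p$entity_class == "GENE") {
      p$surface <- unk_genes[[sample.int(length(unk_genes), 1)]]
    } else {
      p$surface <- unk_pathways[[sample.int(length(unk_pathways), 1)]]
    }
    p$key <- NA_character_
    p
  }

  docs <- vector("list", cfg$n_docs)
  mention_rows <- list()
  event_rows <- list()
  planted <- list()
  n_discard_rows <- 0L
  n_corrupted <- 0L

  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("D%04d", d)
    n_ev <- rpois(1, cfg$events_per_doc)
    sentences <- list()
    for (k in seq_len(n_ev)) {
      corrupted <- stats::runif(1) < cfg$unmappable_fraction
      if (stats::runif(1) < cfg$binding_fraction) {
        n_th <- if (stats::runif(1) < 0.3) 3 else 2
        parts <- list()
        while (length(parts) < n_th) {
          g <- draw_gene()
          if (!g$key %in% vapply(parts, `[[`, character(1), "key")) {
            parts[[length(parts) + 1]] <- g
          }
        }
        if (corrupted) {
          ci <- sample.int(n_th, 1)
          parts[[ci]] <- corrupt(parts[[ci]])
        }
        sent <- sentence_binding(parts)
        if (!corrupted) {
          keys <- sort(vapply(parts, `[[`, character(1), "key"))
          cmb <- combn(keys, 2)
          planted[[length(planted) + 1]] <- tibble(
            node_a = cmb[1, ], node_b = cmb[2, ], category = "BINDING"
          )
        }
      } else if (stats::runif(1) < cfg$phospho_fraction) {
        a <- draw_gene()
        if (corrupted) a <- corrupt(a)
        sent <- sentence_phospho(a)
        # phosphorylation yields no interaction pair either way
      } else {
        type <- sample(REGULATION_TYPES, 1)
        a <- draw_endpoint()
        b <- draw_endpoint()
        while (identical(b$key, a$key)) b <- draw_endpoint()
        nested <- stats::runif(1) < cfg$nesting_probability
        if (corrupted) {
          # in nested sentences the sub-event theme is corrupted, so the
          # whole tree (sub-event and parent) becomes unmappable and the
          # expected discarded-row fraction equals unmappable_fraction
          if (nested || stats::runif(1) < 0.5) a <- corrupt(a) else b <- corrupt(b)
        }
        sent <- sentence_regulation(type, a, b, nested)
        if (!corrupted) {
          planted[[length(planted) + 1]] <- tibble(
            node_a = min(a$key, b$key), node_b = max(a$key, b$key),
            category = toupper(type)
          )
        }
      }
      n_rows <- length(sent$events)
      if (corrupted) {
        n_discard_rows <- n_discard_rows + n_rows
        n_corrupted <- n_corrupted + 1L
      }
      sentences[[k]] <- sent
    }
    # assemble the document: sentences joined by a single space -------------
    doc_text <- ""
    doc_mentions <- list()
    doc_triggers <- list()
    doc_events <- list()
    for (k in seq_along(sentences)) {
      s <- sentences[[k]]
      base <- nchar(doc_text) + (if (nzchar(doc_text)) 1L else 0L)
      doc_text <- if (nzchar(doc_text)) paste(doc_text, s$text) else s$text
      pre <- paste0("s", k, ":")
      for (m in s$mentions) {
        doc_mentions[[paste0(pre, m$local)]] <- tibble(
          start = m$start + base, end = m$end + base,
          surface = m$surface, entity_class = m$entity_class
        )
      }
      for (tr in s$triggers) {
        doc_triggers[[paste0(pre, tr$local)]] <- tibble(
          start = tr$start + base, end = tr$end + base, text = tr$text
        )
      }
      for (e in s$events) {
        doc_events[[length(doc_events) + 1]] <- list(
          local = paste0(pre, e$local), type = e$type,
          trigger = paste0(pre, e$trigger),
          themes = paste0(pre, e$themes),
          cause = if (is.na(e$cause)) NA_character_ else paste0(pre, e$cause)
        )
      }
    }
    docs[[d]] <- tibble(doc_id = doc_id, text = doc_text)
    # assign standoff ids: mentions T1..Tn by start, then triggers ----------
    if (length(doc_mentions) > 0) {
      mt <- dplyr::bind_rows(doc_mentions)
      mt$local <- names(doc_mentions)
      mt <- mt[order(mt$start), ]
      mt$mention_id <- paste0("T", seq_len(nrow(mt)))
      mt$doc_id <- doc_id
      n_m <- nrow(mt)
      tt <- dplyr::bind_rows(doc_triggers)
      tt$local <- names(doc_triggers)
      tt <- tt[order(tt$start), ]
      tt$trigger_id <- paste0("T", n_m + seq_len(nrow(tt)))
      m_map <- stats::setNames(mt$mention_id, mt$local)
      t_map <- stats::setNames(tt$trigger_id, tt$local)
      e_map <- stats::setNames(
        paste0("E", seq_along(doc_events)),
        vapply(doc_events, `[[`, character(1), "local")
      )
      resolve <- function(ref) {
        if (is.na(ref)) {
          NA_character_
        } else if (ref %in% names(m_map)) {
          unname(m_map[[ref]])
        } else {
          unname(e_map[[ref]])
        }
      }
      ev <- purrr::map_dfr(seq_along(doc_events), function(j) {
        e <- doc_events[[j]]
        trow <- tt[tt$local == e$trigger, ]
        tibble(
          doc_id = doc_id, event_id = unname(e_map[[e$local]]), event_type = e$type,
          trigger_id = trow$trigger_id, trigger_start = trow$start,
          trigger_end = trow$end, trigger_text = trow$text,
          themes = list(vapply(e$themes, resolve, character(1), USE.NAMES = FALSE)),
          cause = resolve(e$cause), other_args = list(character(0))
        )
      })
      mention_rows[[d]] <- mt[, c("doc_id", "mention_id", "start", "end", "surface", "entity_class")]
      event_rows[[d]] <- ev
    }
  }
  truth_pairs <- if (length(planted) > 0) {
    dplyr::arrange(
      dplyr::distinct(dplyr::bind_rows(planted)),
      .data$node_a, .data$node_b, .data$category
    )
  } else {
    empty_truth$pairs
  }
  events <- if (length(event_rows) > 0) dplyr::bind_rows(event_rows) else empty_events()
  structure(
    list(
      documents = dplyr::bind_rows(docs),
      mentions = if (length(mention_rows) > 0) dplyr::bind_rows(mention_rows) else empty_mentions(),
      events = events,
      lexicon = lexicon, pathway_db = pathway_db,
      truth = list(
        pairs = truth_pairs,
        n_event_rows = nrow(events),
        n_discard_rows = n_discard_rows,
        n_corrupted_trees = n_corrupted
      )
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(
    "<synthetic_corpus> ", nrow(x$documents), " documents, ",
    nrow(x$mentions), " mentions, ", nrow(x$events), " events, ",
    nrow(x$truth$pairs), " planted unique pairs\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic corpus as a standoff corpus directory
#'
#' Writes `<doc_id>.txt`, `<doc_id>.a1` (true entity classes) and
#' `<doc_id>.a2` per document, plus `gene_lexicon.tsv`, `pathway_db.tsv`,
#' and `truth_pairs.tsv` — a directory layout directly consumable by
#' [run_pipeline()].
#'
#' @param corpus A `synthetic_corpus` from [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$documents))) {
    doc <- corpus$documents[i, ]
    write_document(doc, file.path(dir, paste0(doc$doc_id, ".txt")))
    write_a1(
      corpus$mentions[corpus$mentions$doc_id == doc$doc_id, ],
      file.path(dir, paste0(doc$doc_id, ".a1"))
    )
    write_a2(
      corpus$events[corpus$events$doc_id == doc$doc_id, ],
      file.path(dir, paste0(doc$doc_id, ".a2"))
    )
  }
  write_gene_lexicon(corpus$lexicon, file.path(dir, "gene_lexicon.tsv"))
  write_pathway_db(corpus$pathway_db, file.path(dir, "pathway_db.tsv"))
  tp <- corpus$truth$pairs
  writeLines(
    c("node_a\tnode_b\tcategory", sprintf("%s\t%s\t%s", tp$node_a, tp$node_b, tp$category)),
    file.path(dir, "truth_pairs.tsv")
  )
  invisible(dir)
}

#' Reference network construction from planted ground truth
#'
#' An independent, deliberately naive re-application of the two edge rules —
#' one text-mined edge per planted pair, plus a curated `member_of` edge for
#' every (gene, pathway) with the gene a member of a pathway present in the
#' network — written with plain nested loops. It serves as the
#' dual-implementation oracle for [build_network()] +
#' [add_curated_edges()].
#'
#' @param gt A `synthetic_corpus`, its `truth` list, or a plain pairs tibble
#'   (`node_a`, `node_b`, `category`).
#' @param db Pathway DB tibble.
#' @param expand_members Add member genes absent from the pairs as nodes?
#' @return An `interaction_network`.
#' @export
expected_network <- function(gt, db, expand_members = FALSE) {
  pairs <- if (inherits(gt, "synthetic_corpus")) {
    gt$truth$pairs
  } else if (is.list(gt) && !is.data.frame(gt) && !is.null(gt$pairs)) {
    gt$pairs
  } else {
    gt
  }
  edges <- list()
  nodes <- character(0)
  for (i in seq_len(nrow(pairs))) {
    edges[[length(edges) + 1]] <- tibble(
      node_a = pairs$node_a[[i]], node_b = pairs$node_b[[i]],
      relation = category_to_relation(pairs$category[[i]]), origin = "TEXT_MINED"
    )
    nodes <- unique(c(nodes, pairs$node_a[[i]], pairs$node_b[[i]]))
  }
  base_nodes <- nodes
  for (i in seq_len(nrow(db))) {
    pkey <- pathway_key(db$canonical_id[[i]])
    if (!pkey %in% base_nodes) next
    for (g in db$members[[i]]) {
      gkey <- gene_key(g)
      if (expand_members || gkey %in% base_nodes) {
        edges[[length(edges) + 1]] <- tibble(
          node_a = gkey, node_b = pkey,
          relation = "member_of", origin = "CURATED"
        )
        nodes <- unique(c(nodes, gkey))
      }
    }
  }
  if (length(edges) == 0) {
    return(interaction_network())
  }
  interaction_network(
    dplyr::bind_rows(edges),
    tibble(node = sort(nodes), kind = node_kind(sort(nodes)))
  )
}
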