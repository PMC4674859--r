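test_that("pathway participants restrict events to regulation types", {
  doc <- tibble::tibble(doc_id = "d", text = "PLD binds the STAT3 signaling cascade today")
  m <- dplyr::bind_rows(
    mk_mentions(doc, "T1", 0, 3, "GENE"),
    mk_mentions(doc, "T2", 14, 29, "PATHWAY")
  )
  # Binding with a pathway theme is invalid
  bind_ev <- mk_event("d", "E1", "Binding", "T3", 4, 9, "binds", themes = c("T1", "T2"))
  expect_false(is_valid_pathway_event("E1", bind_ev, m))

  # Positive regulation with a pathway cause is valid
  pos_ev <- mk_event("d", "E1", "Positive_regulation", "T3", 4, 9, "binds",
    themes = "T1", cause = "T2"
  )
  expect_true(is_valid_pathway_event("E1", pos_ev, m))

  # an all-gene phosphorylation is untouched by the restriction
  phos_ev <- mk_event("d", "E1", "Phosphorylation", "T3", 4, 9, "binds", themes = "T1")
  expect_true(is_valid_pathway_event("E1", phos_ev, m))

  # a regulation over a nested non-regulation sub-event holding the pathway
  # is still invalid: every node above the pathway must be regulation-typed
  nested <- dplyr::bind_rows(
    mk_event("d", "E1", "Binding", "T3", 4, 9, "binds", themes = c("T1", "T2")),
    mk_event("d", "E2", "Positive_regulation", "T4", 30, 35, "today", themes = "E1")
  )
  expect_false(is_valid_pathway_event("E2", nested, m))
  # and filter_valid_pathway_events removes both rows
  expect_equal(nrow(filter_valid_pathway_events(nested, m)), 0)

  # gene-only nesting under regulation is fine
  nested_ok <- dplyr::bind_rows(
    mk_event("d", "E1", "Gene_expression", "T3", 4, 9, "binds", themes = "T1"),
    mk_event("d", "E2", "Negative_regulation", "T4", 30, 35, "today", themes = "E1", cause = "T2")
  )
  expect_true(is_valid_pathway_event("E2", nested_ok, m))
})

test_that("participant expansion unwinds nested events and equals a tree-walk oracle", {
  fx <- nested_reg_fixture()
  expect_equal(expand_participants("E2", fx$events, fx$mentions), "T1") # HIPK2 side
  expect_equal(expand_participants("E1", fx$events, fx$mentions), "T2") # Gal-3 side
  expect_setequal(expand_participants("E3", fx$events, fx$mentions), c("T1", "T2"))
  expect_equal(expand_participants("T1", fx$events, fx$mentions), "T1") # bare mention

  # random trees of depth <= 4 against a brute-force traversal
  withr::with_seed(83, {
    for (rep in 1:20) {
      doc <- tibble::tibble(doc_id = "d", text = random_text(25))
      m <- random_mentions(doc, n = 5)
      ev <- random_events(doc, m, n = 5)
      walk <- function(ref) {
        if (startsWith(ref, "E")) {
          i <- match(ref, ev$event_id)
          kids <- c(ev$themes[[i]], ev$cause[[i]])
          unique(unlist(lapply(kids[!is.na(kids)], walk)))
        } else {
          ref
        }
      }
      for (eid in ev$event_id) {
        expect_setequal(expand_participants(eid, ev, m), walk(eid))
      }
    }
  })

  # a cycle is a structure error
  doc <- tibble::tibble(doc_id = "d", text = "abcdefgh")
  cyc <- dplyr::bind_rows(
    mk_event("d", "E1", "Regulation", "T1", 0, 1, "a", themes = "E2"),
    mk_event("d", "E2", "Regulation", "T2", 1, 2, "b", themes = "E1")
  )
  expect_error(
    expand_participants("E1", cyc, empty_mentions()),
    class = "pathevents_structure_error"
  )
})

test_that("nested regulation events yield the cause-by-theme pair with the top type", {
  fx <- nested_reg_fixture()
  m <- normalize_mentions(
    fx$mentions, fx$lexicon,
    read_pathway_db_from_lines(character(0))
  )
  pairs <- pairs_from_event("E3", fx$events, m)
  expect_equal(nrow(pairs), 1)
  expect_setequal(c(pairs$node_a, pairs$node_b), c("28996", "3958")) # HIPK2, Gal-3
  expect_equal(pairs$category, "POSITIVE_REGULATION")
  # the sub-events alone yield nothing (no cause)
  expect_equal(nrow(pairs_from_event("E1", fx$events, m)), 0)

  fd <- downreg_fixture()
  md <- normalize_mentions(fd$mentions, fd$lexicon, fd$db)
  p <- pairs_from_event("E2", fd$events, md)
  expect_equal(nrow(p), 1)
  expect_setequal(c(p$node_a, p$node_b), c("5329", "PW:fak_pi3k_akt"))
  expect_equal(p$category, "NEGATIVE_REGULATION")
})

test_that("binding events emit all theme pairs: n distinct themes give choose(n, 2)", {
  doc <- tibble::tibble(doc_id = "d", text = "Aa interacts with Bb and Cc now")
  m <- dplyr::bind_rows(
    mk_mentions(doc, "T1", 0, 2, "GENE"),
    mk_mentions(doc, "T2", 18, 20, "GENE"),
    mk_mentions(doc, "T3", 25, 27, "GENE")
  )
  lex <- read_gene_lexicon_from_lines(c("Aa\t1", "Bb\t2", "Cc\t3"))
  mn <- normalize_mentions(m, lex, read_pathway_db_from_lines(character(0)))

  ev3 <- mk_event("d", "E1", "Binding", "T4", 3, 12, "interacts", themes = c("T1", "T2", "T3"))
  p <- pairs_from_event("E1", ev3, mn)
  expect_equal(nrow(p), 3)
  expect_setequal(
    paste(p$node_a, p$node_b),
    c("1 2", "1 3", "2 3")
  )
  expect_true(all(p$category == "BINDING"))

  # one theme -> nothing; duplicate themes collapse before enumeration
  ev1 <- mk_event("d", "E1", "Binding", "T4", 3, 12, "interacts", themes = "T1")
  expect_equal(nrow(pairs_from_event("E1", ev1, mn)), 0)
  evdup <- mk_event("d", "E1", "Binding", "T4", 3, 12, "interacts", themes = c("T1", "T1"))
  expect_equal(nrow(pairs_from_event("E1", evdup, mn)), 0)

  # the count law across n = 2..4 (4 via an extra mention)
  doc2 <- tibble::tibble(doc_id = "d", text = "Aa Bb Cc Dd")
  m4 <- dplyr::bind_rows(lapply(0:3, function(i) {
    mk_mentions(doc2, paste0("T", i + 1), i * 3, i * 3 + 2, "GENE")
  }))
  lex4 <- read_gene_lexicon_from_lines(c("Aa\t1", "Bb\t2", "Cc\t3", "Dd\t4"))
  m4n <- normalize_mentions(m4, lex4, read_pathway_db_from_lines(character(0)))
  for (n in 2:4) {
    ev <- mk_event("d", "E1", "Binding", "T9", 0, 2, "Aa", themes = paste0("T", 1:n))
    expect_equal(nrow(pairs_from_event("E1", ev, m4n)), choose(n, 2))
  }
})

test_that("regulation without a cause yields nothing; self-pairs are removed", {
  doc <- tibble::tibble(doc_id = "d", text = "Aa regulates Aa")
  m <- dplyr::bind_rows(
    mk_mentions(doc, "T1", 0, 2, "GENE"),
    mk_mentions(doc, "T2", 13, 15, "GENE")
  )
  lex <- read_gene_lexicon_from_lines("Aa\t1")
  mn <- normalize_mentions(m, lex, read_pathway_db_from_lines(character(0)))
  no_cause <- mk_event("d", "E1", "Regulation", "T3", 3, 12, "regulates", themes = "T1")
  expect_equal(nrow(pairs_from_event("E1", no_cause, mn)), 0)
  # both mentions normalize to the same gene: the pair would be a self-loop
  self_pair <- mk_event("d", "E1", "Regulation", "T3", 3, 12, "regulates",
    themes = "T2", cause = "T1"
  )
  expect_equal(nrow(pairs_from_event("E1", self_pair, mn)), 0)
})

test_that("unique-pair extraction deduplicates corpus-wide and merges provenance", {
  fx <- nested_reg_fixture()
  m1 <- normalize_mentions(fx$mentions, fx$lexicon, read_pathway_db_from_lines(character(0)))
  # the same nested event in a second document
  fx2_events <- dplyr::mutate(fx$events, doc_id = "doc2")
  fx2_mentions <- dplyr::mutate(m1, doc_id = "doc2")
  events <- dplyr::bind_rows(fx$events, fx2_events)
  mentions <- dplyr::bind_rows(m1, fx2_mentions)
  up <- extract_unique_pairs(events, mentions)
  expect_equal(nrow(up), 1)
  expect_equal(up$n_docs, 2)
  expect_equal(nrow(up$provenance[[1]]), 2)

  # empty input
  expect_equal(nrow(extract_unique_pairs(empty_events(), empty_mentions())), 0)

  # idempotence/order-insensitivity and agreement with brute-force dedup
  withr::with_seed(97, {
    db0 <- read_pathway_db_from_lines(character(0))
    for (rep in 1:10) {
      doc <- tibble::tibble(doc_id = "d", text = random_text(25))
      m <- random_mentions(doc, 5)
      m$entity_class <- "GENE"
      lex <- tibble::tibble(
        surface = unique(m$surface),
        entrez_id = seq_along(unique(m$surface)) + 100L
      )
      if (anyDuplicated(tolower(lex$surface))) next
      ev <- random_events(doc, m, n = 5)
      mn <- normalize_mentions(m, lex, db0)
      up <- extract_unique_pairs(ev, mn)
      # brute force: concatenate per-event pairs, collapse on (pair, category)
      all_pairs <- dplyr::bind_rows(lapply(ev$event_id, pairs_from_event, ev, mn))
      if (nrow(all_pairs) == 0) {
        expect_equal(nrow(up), 0)
        next
      }
      key <- unique(sprintf(
        "%s|%s|%s", pmin(all_pairs$node_a, all_pairs$node_b),
        pmax(all_pairs$node_a, all_pairs$node_b), all_pairs$category
      ))
      expect_setequal(sprintf("%s|%s|%s", up$node_a, up$node_b, up$category), key)
      # order-insensitive
      perm <- extract_unique_pairs(ev[sample(nrow(ev)), ], mn)
      expect_equal(perm[, 1:4], up[, 1:4])
    }
  })
})
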