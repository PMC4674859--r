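test_that("documents round-trip byte-for-byte and take their id from the filename stem", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "21191179.txt")
  writeLines("Downregulation of uPAR inhibits migration", p, sep = "")
  doc <- read_document(p)
  expect_equal(doc$doc_id, "21191179")
  expect_equal(doc$text, "Downregulation of uPAR inhibits migration")

  # empty file -> empty text
  p2 <- file.path(dir, "empty.txt")
  file.create(p2)
  expect_equal(read_document(p2)$text, "")

  # write-then-read identity on random text
  withr::with_seed(11, {
    for (i in 1:20) {
      doc <- tibble::tibble(doc_id = paste0("d", i), text = random_text(40))
      out <- file.path(dir, paste0(doc$doc_id, ".txt"))
      write_document(doc, out)
      expect_identical(read_document(out)$text, doc$text)
    }
  })
  expect_error(read_document(file.path(dir, "nope.txt")), class = "pathevents_io_error")
})

test_that("a1 parsing maps entity types, validates spans, and rejects bad lines", {
  dir <- withr::local_tempdir()
  doc <- tibble::tibble(
    doc_id = "d1",
    text = "Downregulation of uPAR inhibits FAK/PI3K/Akt signaling"
  )
  a1 <- file.path(dir, "d1.a1")
  writeLines(c(
    "T1\tProtein 18 22\tuPAR",
    "T2\tPathway 32 54\tFAK/PI3K/Akt signaling"
  ), a1)
  m <- read_a1(a1, doc)
  expect_equal(m$entity_class, c("GENE", "PATHWAY"))
  expect_equal(m$surface, c("uPAR", "FAK/PI3K/Akt signaling"))
  expect_equal(m$start, c(18L, 32L))

  # empty file
  writeLines(character(0), a1)
  expect_equal(nrow(read_a1(a1, doc)), 0)

  # surface/span mismatch names the line
  writeLines("T1\tProtein 18 22\tuPAX", a1)
  err <- expect_error(read_a1(a1, doc), class = "pathevents_integrity_error")
  expect_match(conditionMessage(err), "line 1")

  # malformed line
  writeLines("T1\tProtein eighteen 22\tuPAR", a1)
  expect_error(read_a1(a1, doc), class = "pathevents_parse_error")

  # span beyond the document
  writeLines("T1\tProtein 50 99\tx", a1)
  expect_error(read_a1(a1, doc), class = "pathevents_integrity_error")

  # unknown entity type preserved but flagged
  writeLines("T1\tEntity 18 22\tuPAR", a1)
  expect_warning(m <- read_a1(a1, doc), "Unknown entity type")
  expect_equal(m$entity_class, "Entity")
})

test_that("a1 read/write is the identity on random mention sets", {
  dir <- withr::local_tempdir()
  withr::with_seed(23, {
    for (i in 1:30) {
      doc <- tibble::tibble(doc_id = "d", text = random_text(25))
      m <- random_mentions(doc, n = sample(0:8, 1))
      p <- file.path(dir, "d.a1")
      write_a1(m, p)
      back <- suppressWarnings(read_a1(p, doc))
      expect_equal(back, m[order(standoff_id_num(m$mention_id)), ], ignore_attr = TRUE)
      # writers are deterministic
      p2 <- file.path(dir, "d2.a1")
      write_a1(m, p2)
      expect_identical(readLines(p), readLines(p2))
    }
  })
})

test_that("a2 parsing resolves nested events and rejects dangling or cyclic refs", {
  dir <- withr::local_tempdir()
  fx <- nested_reg_fixture()
  a2 <- file.path(dir, "d.a2")
  writeLines(c(
    "T3\tGene_expression 65 79\toverexpression",
    "T4\tNegative_regulation 6 16\tdeficiency",
    "T5\tPositive_regulation 26 37\tresponsible",
    "E1\tGene_expression:T3 Theme:T2",
    "E2\tNegative_regulation:T4 Theme:T1",
    "E3\tPositive_regulation:T5 Theme:E1 Cause:E2"
  ), a2)
  ev <- read_a2(a2, fx$mentions)
  expect_equal(nrow(ev), 3)
  e3 <- ev[ev$event_id == "E3", ]
  expect_equal(e3$themes[[1]], "E1")
  expect_equal(e3$cause, "E2")
  # the tree is depth 2: closure of E3 covers both gene mentions
  expect_setequal(expand_participants("E3", ev, fx$mentions), c("T1", "T2"))

  # only trigger lines -> no events
  writeLines("T3\tGene_expression 65 79\toverexpression", a2)
  expect_equal(nrow(read_a2(a2, fx$mentions)), 0)

  # dangling theme
  writeLines(c(
    "T3\tGene_expression 65 79\toverexpression",
    "E1\tGene_expression:T3 Theme:T9"
  ), a2)
  expect_error(read_a2(a2, fx$mentions), class = "pathevents_structure_error")

  # cyclic reference
  writeLines(c(
    "T3\tPositive_regulation 26 37\tresponsible",
    "T4\tNegative_regulation 6 16\tdeficiency",
    "E1\tPositive_regulation:T3 Theme:E2",
    "E2\tNegative_regulation:T4 Theme:E1"
  ), a2)
  expect_error(read_a2(a2, fx$mentions), class = "pathevents_structure_error")

  # unknown event type
  writeLines(c(
    "T3\tFrobnication 26 37\tresponsible",
    "E1\tFrobnication:T3 Theme:T1"
  ), a2)
  expect_error(read_a2(a2, fx$mentions), class = "pathevents_parse_error")

  # Binding with a Cause violates arity
  writeLines(c(
    "T3\tBinding 26 37\tresponsible",
    "E1\tBinding:T3 Theme:T1 Cause:T2"
  ), a2)
  expect_error(read_a2(a2, fx$mentions), class = "pathevents_structure_error")
})

test_that("a2 read/write is the identity on random cycle-free event forests", {
  dir <- withr::local_tempdir()
  withr::with_seed(31, {
    for (i in 1:30) {
      doc <- tibble::tibble(doc_id = "d", text = random_text(25))
      m <- random_mentions(doc, n = 5)
      ev <- random_events(doc, m, n = sample(1:5, 1))
      p <- file.path(dir, "d.a2")
      write_a2(ev, p)
      back <- read_a2(p, m)
      ord <- order(standoff_id_num(ev$event_id))
      expect_equal(back, ev[ord, ], ignore_attr = TRUE)
    }
  })
})

test_that("gene lexicon loading folds case, tolerates duplicates, rejects conflicts", {
  lex <- read_gene_lexicon_from_lines(c(
    "AKT1\t207", "AKT1\t207", "RET\t5979", "ret\t5979"
  ))
  expect_equal(nrow(lex), 2)
  expect_equal(lex$entrez_id[lex$surface == "AKT1"], 207L)

  expect_equal(nrow(read_gene_lexicon_from_lines(character(0))), 0)

  err <- expect_error(
    read_gene_lexicon_from_lines(c("AKT1\t207", "akt1\t208")),
    class = "pathevents_load_error"
  )
  expect_match(conditionMessage(err), "akt1")

  expect_error(
    read_gene_lexicon_from_lines("AKT1\tzzz"),
    class = "pathevents_load_error"
  )
})

test_that("pathway records with one canonical id union their synonyms and members", {
  db <- read_pathway_db_from_lines(c(
    "wnt\tWnt signaling pathway\tKEGG\tWnt signaling pathway\t1;2",
    "wnt\tWnt signaling pathway\tWikiPathways\tWnt pathway\t2;3"
  ))
  expect_equal(nrow(db), 1)
  expect_equal(db$members[[1]], c(1L, 2L, 3L))
  expect_equal(nrow(db$synonyms[[1]]), 2)

  expect_equal(nrow(read_pathway_db_from_lines(character(0))), 0)

  # union property against brute-force set union over random rows
  withr::with_seed(5, {
    for (rep in 1:10) {
      ids <- sample(c("a", "b", "c"), 6, replace = TRUE)
      members <- lapply(1:6, function(i) sample(1:9, sample(1:4, 1)))
      lines <- vapply(1:6, function(i) {
        sprintf(
          "%s\tName %s\tsrc%d\tsyn%d\t%s",
          ids[i], ids[i], i, i, paste(members[[i]], collapse = ";")
        )
      }, character(1))
      db <- read_pathway_db_from_lines(lines)
      for (cid in unique(ids)) {
        expected <- sort(unique(unlist(members[ids == cid])))
        expect_equal(db$members[[which(db$canonical_id == cid)]], expected)
      }
    }
  })

  # round trip through the writer preserves the unioned records
  p <- withr::local_tempfile(fileext = ".tsv")
  db2 <- read_pathway_db_from_lines(c(
    "wnt\tWnt signaling pathway\tKEGG\tWnt signaling pathway\t1;2",
    "wnt\tWnt signaling pathway\tWikiPathways\tWnt pathway\t2;3",
    "tgfb\tTGFbeta transduction\tPID\tTGFbeta transduction\t4"
  ))
  write_pathway_db(db2, p)
  expect_equal(read_pathway_db(p), db2)
})

test_that("SIF export labels nodes by namespace, sorts lines, and round-trips", {
  net <- interaction_network(tibble::tibble(
    node_a = "207", node_b = "PW:PI3K_AKT",
    relation = "member_of", origin = "CURATED"
  ))
  p <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, p)
  expect_identical(readLines(p), "207\tmember_of\tPW:PI3K_AKT")

  # empty network -> empty file
  write_sif(interaction_network(), p)
  expect_equal(length(readLines(p)), 0)

  # read(write(net)) preserves the edge multiset on random multigraphs
  withr::with_seed(41, {
    for (i in 1:20) {
      net <- random_network(sample(2:8, 1))
      write_sif(net, p)
      back <- read_sif(p)
      expect_equal(
        sort(sprintf("%s|%s|%s", net$edges$node_a, net$edges$relation, net$edges$node_b)),
        sort(sprintf("%s|%s|%s", back$edges$node_a, back$edges$relation, back$edges$node_b))
      )
      # deterministic writer
      p2 <- withr::local_tempfile(fileext = ".sif")
      write_sif(net, p2)
      expect_identical(readLines(p), readLines(p2))
    }
  })

  expect_error(read_sif(withr::local_tempfile()), class = "pathevents_io_error")
})
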