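# In-code fixtures: tiny documents with hand-placed offsets, random standoff
# instances for round-trip properties, and a mock event extractor.

# build a mentions tibble over a document from (id, start, end, class) rows;
# surfaces are sliced from the text so the span invariant holds by
# construction
mk_mentions <- function(doc, ids, starts, ends, classes) {
  tibble::tibble(
    doc_id = doc$doc_id, mention_id = ids,
    start = as.integer(starts), end = as.integer(ends),
    surface = substring(doc$text, starts + 1, ends),
    entity_class = classes
  )
}

mk_event <- function(doc_id, event_id, event_type, trigger_id,
                     trigger_start, trigger_end, trigger_text,
                     themes, cause = NA_character_, other = character(0)) {
  tibble::tibble(
    doc_id = doc_id, event_id = event_id, event_type = event_type,
    trigger_id = trigger_id, trigger_start = as.integer(trigger_start),
    trigger_end = as.integer(trigger_end), trigger_text = trigger_text,
    themes = list(themes), cause = cause, other_args = list(other)
  )
}

# "Downregulation of uPAR inhibits ... FAK/PI3K/Akt signaling": a nested
# negative regulation whose cause is an expression-change sub-event on a
# gene and whose theme is a pathway mention
downreg_fixture <- function() {
  text <- "Downregulation of uPAR inhibits migration, invasion, proliferation, FAK/PI3K/Akt signaling"
  doc <- tibble::tibble(doc_id = "21191179", text = text)
  mentions <- mk_mentions(
    doc,
    ids = c("T1", "T2"),
    starts = c(18, 68),
    ends = c(22, 90),
    classes = c("GENE", "PATHWAY")
  )
  stopifnot(mentions$surface[[1]] == "uPAR")
  stopifnot(mentions$surface[[2]] == "FAK/PI3K/Akt signaling")
  events <- dplyr::bind_rows(
    mk_event(doc$doc_id, "E1", "Negative_regulation", "T3", 0, 14, "Downregulation",
      themes = "T1"
    ),
    mk_event(doc$doc_id, "E2", "Negative_regulation", "T4", 23, 31, "inhibits",
      themes = "T2", cause = "E1"
    )
  )
  lexicon <- tibble::tibble(surface = "uPAR", entrez_id = 5329L)
  db <- read_pathway_db_from_lines(
    "fak_pi3k_akt\tFAK/PI3K/Akt signaling\tcanonical\tFAK/PI3K/Akt signaling\t5329"
  )
  list(doc = doc, mentions = mentions, events = events, lexicon = lexicon, db = db)
}

# depth-2 nested event: an over-expression sub-event as theme and a
# deficiency sub-event as cause under a positive regulation
nested_reg_fixture <- function() {
  text <- "HIPK2 deficiency might be responsible for such paradoxical Gal-3 overexpression in WDTC."
  doc <- tibble::tibble(doc_id = "21698151", text = text)
  mentions <- mk_mentions(
    doc,
    ids = c("T1", "T2"),
    starts = c(0, 59),
    ends = c(5, 64),
    classes = c("GENE", "GENE")
  )
  stopifnot(mentions$surface[[1]] == "HIPK2")
  stopifnot(mentions$surface[[2]] == "Gal-3")
  events <- dplyr::bind_rows(
    mk_event(doc$doc_id, "E1", "Gene_expression", "T3", 65, 79, "overexpression",
      themes = "T2"
    ),
    mk_event(doc$doc_id, "E2", "Negative_regulation", "T4", 6, 16, "deficiency",
      themes = "T1"
    ),
    mk_event(doc$doc_id, "E3", "Positive_regulation", "T5", 26, 37, "responsible",
      themes = "E1", cause = "E2"
    )
  )
  lexicon <- tibble::tibble(
    surface = c("HIPK2", "Gal-3"),
    entrez_id = c(28996L, 3958L)
  )
  list(doc = doc, mentions = mentions, events = events, lexicon = lexicon)
}

read_pathway_db_from_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  read_pathway_db(p)
}

read_gene_lexicon_from_lines <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  read_gene_lexicon(p)
}

# random text made of letter runs separated by single spaces
random_text <- function(n_words = 30) {
  paste(
    replicate(n_words, paste(sample(c(letters, LETTERS), sample(2:8, 1), replace = TRUE),
      collapse = ""
    )),
    collapse = " "
  )
}

# random valid mentions over a document (word-aligned spans, may overlap)
random_mentions <- function(doc, n = 6) {
  if (n == 0) {
    return(empty_mentions())
  }
  nc <- nchar(doc$text)
  rows <- lapply(seq_len(n), function(i) {
    start <- sample.int(nc - 1, 1) - 1L
    end <- min(nc, start + sample.int(8, 1))
    tibble::tibble(start = start, end = as.integer(end))
  })
  m <- dplyr::bind_rows(rows)
  m <- m[!duplicated(m), ]
  tibble::tibble(
    doc_id = doc$doc_id,
    mention_id = paste0("T", seq_len(nrow(m))),
    start = m$start, end = m$end,
    surface = substring(doc$text, m$start + 1, m$end),
    entity_class = sample(c("GENE", "PATHWAY"), nrow(m), replace = TRUE)
  )
}

# random cycle-free event forest over a mention set; nested arguments only
# reference earlier events
random_events <- function(doc, mentions, n = 4) {
  nc <- nchar(doc$text)
  n_m <- nrow(mentions)
  trig_base <- n_m
  rows <- list()
  for (i in seq_len(n)) {
    type <- sample(GENIA_EVENT_TYPES, 1)
    tstart <- sample.int(nc - 1, 1) - 1L
    tend <- min(nc, tstart + sample.int(6, 1))
    prior_events <- if (length(rows) > 0) vapply(rows, function(r) r$event_id, character(1)) else character(0)
    arg_pool <- c(mentions$mention_id, prior_events)
    if (type == "Binding") {
      themes <- sample(mentions$mention_id, min(n_m, sample.int(3, 1)))
      cause <- NA_character_
    } else {
      themes <- sample(arg_pool, 1)
      cause <- if (type %in% REGULATION_TYPES && stats::runif(1) < 0.6) {
        sample(arg_pool, 1)
      } else {
        NA_character_
      }
    }
    other <- if (stats::runif(1) < 0.3 && type == "Phosphorylation") {
      stats::setNames(sample(mentions$mention_id, 1), "Site")
    } else {
      character(0)
    }
    rows[[i]] <- mk_event(
      doc$doc_id, paste0("E", i), type,
      paste0("T", trig_base + i), tstart, tend,
      substring(doc$text, tstart + 1, tend),
      themes = themes, cause = cause, other = other
    )
  }
  dplyr::bind_rows(rows)
}

# mock extractor: reads the disguised .a1 lines it is handed and emits one
# Positive_regulation event over the first two entities, exactly as a
# GENIA-style extractor would (trigger ids continue the T namespace)
mock_extractor <- function(doc, a1_lines) {
  if (length(a1_lines) < 2) {
    return(character(0))
  }
  ids <- sub("\t.*", "", a1_lines)
  n <- length(ids)
  c(
    sprintf("T%d\tPositive_regulation 0 1\t%s", n + 1, substr(doc$text, 1, 1)),
    sprintf("E1\tPositive_regulation:T%d Theme:%s Cause:%s", n + 1, ids[[2]], ids[[1]])
  )
}
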