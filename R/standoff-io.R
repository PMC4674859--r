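# Readers and writers for the BioNLP-ST standoff dialect (<doc>.txt, <doc>.a1,
# <doc>.a2), SIF networks, and the two mapping tables (gene lexicon, pathway
# dictionary). All character offsets are 0-based, half-open, and measured in
# characters, matching the standoff convention.

#' Read a plain-text document
#'
#' Reads one document of a standoff-annotated corpus. The document identifier
#' is the filename stem (typically a PMID), and the text is preserved exactly,
#' including newlines.
#'
#' @param txt_path Path to a `.txt` file, UTF-8 encoded.
#' @return A one-row tibble with columns `doc_id` and `text`.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines("uPAR inhibits FAK signaling.", p)
#' read_document(p)
#' @export
read_document <- function(txt_path) {
  if (!file.exists(txt_path)) {
    abort(paste0("Document file not found: ", txt_path), class = "pathevents_io_error")
  }
  raw <- readBin(txt_path, what = "raw", n = file.size(txt_path))
  text <- rawToChar(raw)
  Encoding(text) <- "UTF-8"
  if (!validUTF8(text)) {
    abort(paste0("File is not valid UTF-8: ", txt_path), class = "pathevents_format_error")
  }
  doc_id <- sub("\\.txt$", "", basename(txt_path))
  if (!nzchar(doc_id)) {
    abort("Document id (filename stem) must be non-empty", class = "pathevents_format_error")
  }
  tibble(doc_id = doc_id, text = text)
}

#' Write a document's text
#'
#' Inverse of [read_document()]: writes `doc$text` byte-for-byte (no trailing
#' newline is appended).
#'
#' @param doc One-row document tibble (`doc_id`, `text`).
#' @param txt_path Output path.
#' @return `txt_path`, invisibly.
#' @export
write_document <- function(doc, txt_path) {
  stopifnot(nrow(doc) == 1)
  con <- file(txt_path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(doc$text)), con)
  invisible(txt_path)
}

#' Read all documents in a corpus directory
#'
#' @param dir Directory containing `<doc_id>.txt` files.
#' @return A tibble with one row per document, sorted by `doc_id`.
#' @export
read_corpus_documents <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(paths) == 0) {
    return(tibble(doc_id = character(), text = character()))
  }
  dplyr::bind_rows(lapply(paths, read_document))
}

empty_mentions <- function() {
  tibble(
    doc_id = character(), mention_id = character(),
    start = integer(), end = integer(),
    surface = character(), entity_class = character()
  )
}

# map a standoff entity type to the internal entity class; unknown types are
# preserved verbatim (callers may warn)
a1_type_to_class <- function(type) {
  dplyr::case_match(type, "Protein" ~ "GENE", "Pathway" ~ "PATHWAY", .default = type)
}

class_to_a1_type <- function(entity_class) {
  dplyr::case_match(entity_class, "GENE" ~ "Protein", "PATHWAY" ~ "Pathway",
    .default = entity_class
  )
}

#' Read entity mentions from a standoff .a1 file
#'
#' Each line has the form `Tid<TAB>Type start end<TAB>surface`. Entity type
#' `Protein` maps to entity class `GENE` and `Pathway` to `PATHWAY`; any other
#' type is preserved verbatim and flagged with a warning. Every span is
#' validated against the document text: the surface string must equal
#' `text[start:end)` or an integrity error naming the line is raised.
#'
#' @param a1_path Path to the `.a1` file.
#' @param doc One-row document tibble from [read_document()].
#' @return A tibble of mentions with columns `doc_id`, `mention_id`, `start`,
#'   `end`, `surface`, `entity_class`.
#' @export
read_a1 <- function(a1_path, doc) {
  stopifnot(nrow(doc) == 1)
  if (!file.exists(a1_path)) {
    abort(paste0("Annotation file not found: ", a1_path), class = "pathevents_io_error")
  }
  lines <- readLines(a1_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_mentions())
  }
  rows <- lapply(seq_along(lines), function(i) {
    parse_entity_line(lines[[i]], i, a1_path, doc)
  })
  out <- dplyr::bind_rows(rows)
  unknown <- setdiff(unique(out$entity_class), c("GENE", "PATHWAY"))
  if (length(unknown) > 0) {
    warn(paste0(
      "Unknown entity type(s) in ", basename(a1_path), ": ",
      paste(unknown, collapse = ", "), " (preserved verbatim)"
    ))
  }
  out
}

parse_entity_line <- function(line, lineno, path, doc) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 3 || !grepl("^T[0-9]+$", fields[[1]])) {
    abort(
      paste0("Malformed entity line ", lineno, " in ", basename(path), ": ", line),
      class = "pathevents_parse_error"
    )
  }
  mid <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
  if (length(mid) != 3 || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
    abort(
      paste0("Malformed entity line ", lineno, " in ", basename(path), ": ", line),
      class = "pathevents_parse_error"
    )
  }
  start <- as.integer(mid[[2]])
  end <- as.integer(mid[[3]])
  if (start < 0 || start >= end || end > nchar(doc$text)) {
    abort(
      paste0("Span out of range on line ", lineno, " in ", basename(path), ": ", line),
      class = "pathevents_integrity_error"
    )
  }
  slice <- substr(doc$text, start + 1L, end)
  if (!identical(slice, fields[[3]])) {
    abort(
      paste0(
        "Surface/span mismatch on line ", lineno, " in ", basename(path),
        ": annotation says ", encodeString(fields[[3]], quote = "\""),
        " but text[", start, ":", end, ") is ", encodeString(slice, quote = "\"")
      ),
      class = "pathevents_integrity_error"
    )
  }
  tibble(
    doc_id = doc$doc_id, mention_id = fields[[1]],
    start = start, end = end, surface = fields[[3]],
    entity_class = a1_type_to_class(mid[[1]])
  )
}

#' Write entity mentions to a standoff .a1 file
#'
#' Deterministic inverse of [read_a1()]: mentions are written in ascending
#' numeric id order, entity class `GENE` as type `Protein` and `PATHWAY` as
#' `Pathway`.
#'
#' @param mentions Mentions tibble (single document).
#' @param a1_path Output path.
#' @return `a1_path`, invisibly.
#' @export
write_a1 <- function(mentions, a1_path) {
  lines <- character(0)
  if (nrow(mentions) > 0) {
    ord <- order(standoff_id_num(mentions$mention_id))
    m <- mentions[ord, ]
    lines <- sprintf(
      "%s\t%s %d %d\t%s",
      m$mention_id, class_to_a1_type(m$entity_class), m$start, m$end, m$surface
    )
  }
  writeLines(lines, a1_path, useBytes = FALSE)
  invisible(a1_path)
}

standoff_id_num <- function(ids) as.integer(sub("^[TE]", "", ids))

empty_events <- function() {
  tibble(
    doc_id = character(), event_id = character(), event_type = character(),
    trigger_id = character(), trigger_start = integer(),
    trigger_end = integer(), trigger_text = character(),
    themes = list(), cause = character(), other_args = list()
  )
}

#' Read events from a standoff .a2 file
#'
#' Parses trigger lines (`Tid<TAB>Type start end<TAB>keyword`) and event lines
#' (`Eid<TAB>Type:Ttrig Theme:X [Theme2:Y ...] [Cause:Z] [Site:W ...]`).
#' Theme and Cause arguments may reference entity mentions (`T` ids declared
#' in the companion `.a1`) or other events (`E` ids), giving nested event
#' trees. Unresolved references and cyclic event references are rejected.
#' Site/location arguments are preserved in `other_args` but take no part in
#' interaction-pair extraction.
#'
#' @param a2_path Path to the `.a2` file.
#' @param mentions Mentions tibble for the same document (from [read_a1()]).
#' @return An events tibble with columns `doc_id`, `event_id`, `event_type`,
#'   trigger span columns, `themes` (list of argument ids, ordered), `cause`
#'   (argument id or `NA`), and `other_args` (named character vectors).
#' @export
read_a2 <- function(a2_path, mentions) {
  if (!file.exists(a2_path)) {
    abort(paste0("Annotation file not found: ", a2_path), class = "pathevents_io_error")
  }
  doc_id <- if (nrow(mentions) > 0) mentions$doc_id[[1]] else sub("\\.a2$", "", basename(a2_path))
  lines <- readLines(a2_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  tlines <- lines[startsWith(lines, "T")]
  elines <- lines[startsWith(lines, "E")]
  bad <- setdiff(lines, c(tlines, elines))
  if (length(bad) > 0) {
    abort(
      paste0("Malformed line in ", basename(a2_path), ": ", bad[[1]]),
      class = "pathevents_parse_error"
    )
  }
  triggers <- parse_trigger_lines(tlines, a2_path)
  if (length(elines) == 0) {
    return(empty_events())
  }
  ev <- dplyr::bind_rows(lapply(elines, parse_event_line, path = a2_path))
  if (anyDuplicated(ev$event_id)) {
    abort(
      paste0("Duplicate event id in ", basename(a2_path)),
      class = "pathevents_structure_error"
    )
  }
  # resolve references: triggers must be declared T lines, arguments must be
  # declared mentions or events
  known_args <- c(mentions$mention_id, ev$event_id)
  for (i in seq_len(nrow(ev))) {
    trig <- ev$trigger_id[[i]]
    if (!trig %in% triggers$trigger_id) {
      abort(
        paste0("Event ", ev$event_id[[i]], " references undeclared trigger ", trig),
        class = "pathevents_structure_error"
      )
    }
    refs <- c(ev$themes[[i]], ev$cause[[i]], ev$other_args[[i]])
    refs <- refs[!is.na(refs)]
    dangling <- setdiff(refs, known_args)
    if (length(dangling) > 0) {
      abort(
        paste0(
          "Event ", ev$event_id[[i]], " in ", basename(a2_path),
          " has dangling reference(s): ", paste(dangling, collapse = ", ")
        ),
        class = "pathevents_structure_error"
      )
    }
  }
  ev <- dplyr::left_join(ev, triggers, by = "trigger_id")
  ev <- dplyr::mutate(ev, doc_id = doc_id, .before = 1)
  check_event_forest(ev, basename(a2_path))
  ev[, names(empty_events())]
}

parse_trigger_lines <- function(tlines, path) {
  if (length(tlines) == 0) {
    return(tibble(
      trigger_id = character(), trigger_type = character(),
      trigger_start = integer(), trigger_end = integer(), trigger_text = character()
    ))
  }
  rows <- lapply(tlines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    mid <- if (length(fields) >= 2) strsplit(fields[[2]], " ", fixed = TRUE)[[1]] else character(0)
    if (length(fields) != 3 || length(mid) != 3 ||
      anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      abort(
        paste0("Malformed trigger line in ", basename(path), ": ", line),
        class = "pathevents_parse_error"
      )
    }
    tibble(
      trigger_id = fields[[1]], trigger_type = mid[[1]],
      trigger_start = as.integer(mid[[2]]), trigger_end = as.integer(mid[[3]]),
      trigger_text = fields[[3]]
    )
  })
  dplyr::bind_rows(rows)
}

parse_event_line <- function(line, path) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 2 || !grepl("^E[0-9]+$", fields[[1]])) {
    abort(
      paste0("Malformed event line in ", basename(path), ": ", line),
      class = "pathevents_parse_error"
    )
  }
  toks <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
  head_tok <- strsplit(toks[[1]], ":", fixed = TRUE)[[1]]
  if (length(head_tok) != 2 || !head_tok[[1]] %in% GENIA_EVENT_TYPES) {
    abort(
      paste0("Unknown or malformed event type in ", basename(path), ": ", line),
      class = "pathevents_parse_error"
    )
  }
  themes <- character(0)
  theme_rank <- integer(0)
  cause <- NA_character_
  other <- character(0)
  for (tok in toks[-1]) {
    kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      abort(
        paste0("Malformed argument in ", basename(path), ": ", tok),
        class = "pathevents_parse_error"
      )
    }
    role <- kv[[1]]
    if (grepl("^Theme[0-9]*$", role)) {
      themes <- c(themes, kv[[2]])
      sfx <- sub("^Theme", "", role)
      theme_rank <- c(theme_rank, if (nzchar(sfx)) as.integer(sfx) else 1L)
    } else if (role == "Cause") {
      if (!is.na(cause)) {
        abort(
          paste0("Multiple Cause arguments in ", basename(path), ": ", line),
          class = "pathevents_parse_error"
        )
      }
      cause <- kv[[2]]
    } else {
      other <- c(other, stats::setNames(kv[[2]], role))
    }
  }
  themes <- themes[order(theme_rank)]
  tibble(
    event_id = fields[[1]], event_type = head_tok[[1]], trigger_id = head_tok[[2]],
    themes = list(themes), cause = cause, other_args = list(other)
  )
}

# enforce the structural invariants of an event table: cycle-free nesting and
# Binding arity (>= 1 theme, no cause)
check_event_forest <- function(events, where = "events") {
  bad_binding <- events$event_type == "Binding" &
    (lengths(events$themes) < 1 | !is.na(events$cause))
  if (any(bad_binding)) {
    abort(
      paste0(
        "Binding event(s) violating arity (>=1 Theme, no Cause) in ", where, ": ",
        paste(events$event_id[bad_binding], collapse = ", ")
      ),
      class = "pathevents_structure_error"
    )
  }
  children <- stats::setNames(
    purrr::map2(events$themes, events$cause, function(th, ca) {
      refs <- c(th, ca)
      refs[!is.na(refs) & startsWith(refs, "E")]
    }),
    events$event_id
  )
  state <- stats::setNames(rep(0L, length(children)), names(children)) # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) {
      abort(
        paste0("Cyclic event reference involving ", id, " in ", where),
        class = "pathevents_structure_error"
      )
    }
    if (state[[id]] == 2L) {
      return(invisible(NULL))
    }
    state[[id]] <<- 1L
    for (ch in children[[id]]) visit(ch)
    state[[id]] <<- 2L
    invisible(NULL)
  }
  for (id in names(children)) visit(id)
  invisible(events)
}

#' Write events to a standoff .a2 file
#'
#' Deterministic inverse of [read_a2()]: trigger lines first (ascending
#' numeric id), then event lines (ascending numeric id), with arguments in
#' Theme, Cause, other order.
#'
#' @param events Events tibble (single document).
#' @param a2_path Output path.
#' @return `a2_path`, invisibly.
#' @export
write_a2 <- function(events, a2_path) {
  if (nrow(events) == 0) {
    writeLines(character(0), a2_path)
    return(invisible(a2_path))
  }
  trig <- dplyr::distinct(
    events,
    .data$trigger_id, .data$event_type, .data$trigger_start,
    .data$trigger_end, .data$trigger_text
  )
  if (anyDuplicated(trig$trigger_id)) {
    abort("Trigger shared by events of differing type/span", class = "pathevents_structure_error")
  }
  trig <- trig[order(standoff_id_num(trig$trigger_id)), ]
  tlines <- sprintf(
    "%s\t%s %d %d\t%s",
    trig$trigger_id, trig$event_type, trig$trigger_start, trig$trigger_end, trig$trigger_text
  )
  ev <- events[order(standoff_id_num(events$event_id)), ]
  elines <- vapply(seq_len(nrow(ev)), function(i) {
    th <- ev$themes[[i]]
    roles <- if (length(th) > 0) {
      paste0(c("Theme", paste0("Theme", seq_along(th))[-1]), ":", th)
    } else {
      character(0)
    }
    if (!is.na(ev$cause[[i]])) roles <- c(roles, paste0("Cause:", ev$cause[[i]]))
    oth <- ev$other_args[[i]]
    if (length(oth) > 0) roles <- c(roles, paste0(names(oth), ":", unname(oth)))
    paste0(
      ev$event_id[[i]], "\t", ev$event_type[[i]], ":", ev$trigger_id[[i]],
      if (length(roles) > 0) paste0(" ", paste(roles, collapse = " ")) else ""
    )
  }, character(1))
  writeLines(c(tlines, elines), a2_path)
  invisible(a2_path)
}

# mapping tables --------------------------------------------------------------

#' Read a gene lexicon table
#'
#' The lexicon maps surface forms to Entrez Gene IDs (the normalization
#' stand-in for a gene-normalization system). Format: headerless TSV,
#' `surface<TAB>entrez_id`. Duplicate rows with identical mappings are
#' tolerated; conflicting mappings for the same case-folded surface are a
#' hard load error listing the offenders.
#'
#' @param tsv_path Path to the TSV file.
#' @return A tibble with columns `surface` and `entrez_id` (integer).
#' @export
read_gene_lexicon <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    abort(paste0("Lexicon file not found: ", tsv_path), class = "pathevents_io_error")
  }
  lines <- readLines(tsv_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(surface = character(), entrez_id = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort(
      paste0("Malformed lexicon line: ", lines[lengths(parts) != 2][[1]]),
      class = "pathevents_parse_error"
    )
  }
  surface <- vapply(parts, `[[`, character(1), 1)
  id_raw <- vapply(parts, `[[`, character(1), 2)
  bad <- !grepl("^[0-9]+$", id_raw)
  if (any(bad)) {
    abort(
      paste0(
        "Non-integer Entrez ID(s) in lexicon: ",
        paste(unique(surface[bad]), collapse = ", ")
      ),
      class = "pathevents_load_error"
    )
  }
  lex <- dplyr::distinct(tibble(surface = surface, entrez_id = as.integer(id_raw)))
  folded <- stringi::stri_trans_tolower(lex$surface)
  conflicts <- unique(folded[duplicated(folded)])
  conflicts <- conflicts[vapply(conflicts, function(f) {
    length(unique(lex$entrez_id[folded == f])) > 1
  }, logical(1))]
  if (length(conflicts) > 0) {
    abort(
      paste0(
        "Conflicting gene mappings for surface(s): ",
        paste(conflicts, collapse = ", ")
      ),
      class = "pathevents_load_error"
    )
  }
  # case-insensitive duplicates with a single ID collapse to the first spelling
  lex[!duplicated(folded), ]
}

#' Write a gene lexicon table
#'
#' @param lexicon Lexicon tibble (`surface`, `entrez_id`).
#' @param tsv_path Output path.
#' @return `tsv_path`, invisibly.
#' @export
write_gene_lexicon <- function(lexicon, tsv_path) {
  lex <- lexicon[order(lexicon$surface), ]
  writeLines(sprintf("%s\t%d", lex$surface, lex$entrez_id), tsv_path)
  invisible(tsv_path)
}

#' Read a pathway dictionary table
#'
#' Format: headerless TSV with columns `canonical_id`, `canonical_name`,
#' `source_db`, `synonym`, `member_ids` (semicolon-separated Entrez IDs).
#' Rows sharing a `canonical_id` are merged: the synonym set and the member
#' set are each the union over all source-database representations, mirroring
#' how integrated pathway resources collapse multiple versions of the same
#' pathway.
#'
#' @param tsv_path Path to the TSV file.
#' @return A tibble with one row per canonical pathway: `canonical_id`,
#'   `canonical_name`, `synonyms` (list of tibbles with `source_db`, `name`),
#'   `members` (list of integer vectors).
#' @export
read_pathway_db <- function(tsv_path) {
  if (!file.exists(tsv_path)) {
    abort(paste0("Pathway DB file not found: ", tsv_path), class = "pathevents_io_error")
  }
  lines <- readLines(tsv_path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      canonical_id = character(), canonical_name = character(),
      synonyms = list(), members = list()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 5)) {
    abort(
      paste0("Malformed pathway DB line: ", lines[lengths(parts) != 5][[1]]),
      class = "pathevents_parse_error"
    )
  }
  raw <- tibble(
    canonical_id = vapply(parts, `[[`, character(1), 1),
    canonical_name = vapply(parts, `[[`, character(1), 2),
    source_db = vapply(parts, `[[`, character(1), 3),
    synonym = vapply(parts, `[[`, character(1), 4),
    member_ids = vapply(parts, `[[`, character(1), 5)
  )
  member_lists <- lapply(strsplit(raw$member_ids, ";", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    if (length(x) > 0 && any(!grepl("^[0-9]+$", x))) {
      abort(
        paste0("Non-integer member ID(s): ", paste(x[!grepl("^[0-9]+$", x)], collapse = ", ")),
        class = "pathevents_load_error"
      )
    }
    as.integer(x)
  })
  raw$member_list <- member_lists
  raw %>%
    dplyr::group_by(.data$canonical_id) %>%
    dplyr::summarise(
      canonical_name = dplyr::first(.data$canonical_name),
      synonyms = list(dplyr::distinct(tibble(
        source_db = source_db, name = synonym
      ))),
      members = list(sort(unique(unlist(member_list)))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$canonical_id)
}

#' Write a pathway dictionary table
#'
#' One row per (canonical pathway, synonym); all rows of a pathway repeat its
#' full member list, so `read_pathway_db(write_pathway_db(db))` restores the
#' unioned records.
#'
#' @param db Pathway DB tibble (see [read_pathway_db()]).
#' @param tsv_path Output path.
#' @return `tsv_path`, invisibly.
#' @export
write_pathway_db <- function(db, tsv_path) {
  lines <- unlist(lapply(seq_len(nrow(db)), function(i) {
    syn <- db$synonyms[[i]]
    if (nrow(syn) == 0) syn <- tibble(source_db = "canonical", name = db$canonical_name[[i]])
    members <- paste(db$members[[i]], collapse = ";")
    sprintf(
      "%s\t%s\t%s\t%s\t%s",
      db$canonical_id[[i]], db$canonical_name[[i]], syn$source_db, syn$name, members
    )
  }))
  writeLines(lines, tsv_path)
  invisible(tsv_path)
}
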