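# Event-level logic: recursive expansion of nested events into participant
# sets, the pathway event-type restriction, and the conversion of events into
# undirected interaction pairs.

# Recursive participant closure for all events of ONE document: a named list
# mapping event_id -> character vector of mention ids occurring anywhere in
# the event's argument subtree (themes and cause). Errors on cyclic
# references.
doc_participant_closure <- function(events) {
  memo <- list()
  get_refs <- function(i) {
    refs <- c(events$themes[[i]], events$cause[[i]])
    refs[!is.na(refs)]
  }
  idx <- stats::setNames(seq_len(nrow(events)), events$event_id)
  visit <- function(eid, path) {
    if (eid %in% path) {
      abort(
        paste0("Cyclic event reference involving ", eid),
        class = "pathevents_structure_error"
      )
    }
    if (!is.null(memo[[eid]])) {
      return(memo[[eid]])
    }
    i <- idx[[eid]]
    out <- character(0)
    for (ref in get_refs(i)) {
      if (startsWith(ref, "E")) {
        if (is.na(idx[ref])) {
          abort(paste0("Dangling event reference: ", ref), class = "pathevents_structure_error")
        }
        out <- c(out, visit(ref, c(path, eid)))
      } else {
        out <- c(out, ref)
      }
    }
    out <- unique(out)
    memo[[eid]] <<- out
    out
  }
  for (eid in events$event_id) visit(eid, character(0))
  memo
}

# expand a single argument reference (mention id or event id) within one
# document's event table
expand_ref <- function(ref, closure, mentions) {
  if (startsWith(ref, "E")) {
    cl <- closure[[ref]]
    if (is.null(cl)) {
      abort(paste0("Dangling event reference: ", ref), class = "pathevents_structure_error")
    }
    cl
  } else {
    ref
  }
}

#' Expand an event argument into its participant set
#'
#' A bare mention expands to itself; an event expands to the union of the
#' recursive expansions of all its themes and its cause — nested events are
#' unwound until only entity mentions remain. Cyclic references raise a
#' structure error.
#'
#' @param ref A mention id (`Tn`) or event id (`En`).
#' @param events Events tibble of the owning document.
#' @param mentions Mentions tibble of the owning document.
#' @return Character vector of mention ids.
#' @export
expand_participants <- function(ref, events, mentions) {
  if (startsWith(ref, "E")) {
    closure <- doc_participant_closure(events)
    expand_ref(ref, closure, mentions)
  } else {
    ref
  }
}

# per-event flag: does any PATHWAY mention occur anywhere in the subtree?
subtree_has_pathway <- function(events, mentions) {
  closure <- doc_participant_closure(events)
  pw_ids <- mentions$mention_id[mentions$entity_class == "PATHWAY"]
  vapply(events$event_id, function(eid) any(closure[[eid]] %in% pw_ids), logical(1))
}

#' Test whether an event is valid for pathway participants
#'
#' Pathways cannot take part in gene expression, transcription, protein
#' catabolism, phosphorylation, localization or binding; only the three
#' regulation types are admissible for pathway-involved events. An event is
#' valid iff no pathway mention occurs anywhere in its argument subtree, or
#' every event node (itself and any nested sub-event) whose subtree contains
#' a pathway has a regulation type.
#'
#' @param event_id Id of the event to test.
#' @param events Events tibble of the owning document (undisguised).
#' @param mentions Mentions tibble of the owning document.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_pathway_event <- function(event_id, events, mentions) {
  valid <- valid_pathway_flags(events, mentions)
  if (is.na(match(event_id, events$event_id))) {
    abort(paste0("Unknown event id: ", event_id), class = "pathevents_usage_error")
  }
  valid[[match(event_id, events$event_id)]]
}

# vectorized validity over one document's events
valid_pathway_flags <- function(events, mentions) {
  if (nrow(events) == 0) {
    return(logical(0))
  }
  has_pw <- subtree_has_pathway(events, mentions)
  idx <- stats::setNames(seq_len(nrow(events)), events$event_id)
  # an event is clean iff every event node in its subtree containing a
  # pathway (including itself) is regulation-typed
  memo <- rep(NA, nrow(events))
  visit <- function(i) {
    if (!is.na(memo[[i]])) {
      return(memo[[i]])
    }
    ok <- if (!has_pw[[i]]) {
      TRUE
    } else if (!events$event_type[[i]] %in% REGULATION_TYPES) {
      FALSE
    } else {
      refs <- c(events$themes[[i]], events$cause[[i]])
      refs <- refs[!is.na(refs) & startsWith(refs, "E")]
      all(vapply(refs, function(r) visit(idx[[r]]), logical(1)))
    }
    memo[[i]] <<- ok
    ok
  }
  vapply(seq_len(nrow(events)), visit, logical(1))
}

#' Filter a corpus of events to those valid for pathway participants
#'
#' Applies [is_valid_pathway_event()] across documents.
#'
#' @param events Events tibble (any number of documents).
#' @param mentions Mentions tibble.
#' @return The subset of `events` that is valid.
#' @export
filter_valid_pathway_events <- function(events, mentions) {
  if (nrow(events) == 0) {
    return(events)
  }
  keep <- rep(TRUE, nrow(events))
  for (ii in split(seq_len(nrow(events)), events$doc_id)) {
    ev <- events[ii, ]
    me <- mentions[mentions$doc_id == ev$doc_id[[1]], ]
    keep[ii] <- valid_pathway_flags(ev, me)
  }
  events[keep, ]
}

#' Interaction pairs of a single event
#'
#' Regulation events with a cause yield the cross product of the cause-side
#' and theme-side participant sets (after recursive nested expansion), with
#' self-pairs removed and the pair category taken from the event type;
#' regulation events without a cause yield nothing. Binding events yield all
#' unordered pairs of their distinct theme participants (`n` distinct themes
#' give `n (n - 1) / 2` pairs of category `BINDING`). All other event types
#' yield nothing. Mentions must carry normalized `node_key`s; participants
#' without one are skipped.
#'
#' @param event_id Id of the event.
#' @param events Events tibble of the owning document.
#' @param mentions Mentions tibble of the owning document, carrying a
#'   `node_key` column (see [normalize_mentions()]).
#' @return A tibble with columns `node_a`, `node_b`, `category`.
#' @export
pairs_from_event <- function(event_id, events, mentions) {
  closure <- doc_participant_closure(events)
  event_pairs_one(match(event_id, events$event_id), events, mentions, closure)
}

empty_pairs <- function() {
  tibble(node_a = character(), node_b = character(), category = character())
}

# node keys of a set of mention ids (NA keys dropped)
mention_keys <- function(ids, mentions) {
  keys <- mentions$node_key[match(ids, mentions$mention_id)]
  unique(keys[!is.na(keys)])
}

event_pairs_one <- function(i, events, mentions, closure) {
  type <- events$event_type[[i]]
  if (type %in% REGULATION_TYPES) {
    cause <- events$cause[[i]]
    if (is.na(cause)) {
      return(empty_pairs())
    }
    cause_ids <- expand_ref(cause, closure, mentions)
    theme_ids <- unique(unlist(lapply(events$themes[[i]], expand_ref, closure, mentions)))
    ck <- mention_keys(cause_ids, mentions)
    tk <- mention_keys(theme_ids, mentions)
    if (length(ck) == 0 || length(tk) == 0) {
      return(empty_pairs())
    }
    grid <- expand.grid(node_a = ck, node_b = tk, stringsAsFactors = FALSE)
    grid <- grid[grid$node_a != grid$node_b, , drop = FALSE]
    if (nrow(grid) == 0) {
      return(empty_pairs())
    }
    tibble(
      node_a = grid$node_a, node_b = grid$node_b,
      category = toupper(type)
    )
  } else if (type == "Binding") {
    ids <- unique(unlist(lapply(events$themes[[i]], expand_ref, closure, mentions)))
    keys <- sort(mention_keys(ids, mentions))
    if (length(keys) < 2) {
      return(empty_pairs())
    }
    cmb <- combn(keys, 2)
    tibble(node_a = cmb[1, ], node_b = cmb[2, ], category = "BINDING")
  } else {
    empty_pairs()
  }
}

#' Extract unique interaction pairs from a corpus of events
#'
#' Runs [pairs_from_event()] over every event and deduplicates corpus-wide
#' on the unordered node pair plus category (directionality is ignored).
#' Provenance — the set of `(doc_id, event_id)` an interaction was seen in —
#' is merged across duplicates.
#'
#' @param events Events tibble (filtered and normalized; any number of
#'   documents).
#' @param mentions Mentions tibble carrying `node_key`s.
#' @return A tibble with columns `node_a`, `node_b` (sorted within pair),
#'   `category`, `n_docs`, and `provenance` (list of tibbles with `doc_id`,
#'   `event_id`), sorted by node keys and category.
#' @export
extract_unique_pairs <- function(events, mentions) {
  empty <- tibble(
    node_a = character(), node_b = character(), category = character(),
    n_docs = integer(), provenance = list()
  )
  if (nrow(events) == 0) {
    return(empty)
  }
  per_event <- purrr::map_dfr(split(seq_len(nrow(events)), events$doc_id), function(ii) {
    ev <- events[ii, ]
    me <- mentions[mentions$doc_id == ev$doc_id[[1]], ]
    closure <- doc_participant_closure(ev)
    purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      p <- event_pairs_one(i, ev, me, closure)
      if (nrow(p) == 0) {
        return(NULL)
      }
      p$doc_id <- ev$doc_id[[1]]
      p$event_id <- ev$event_id[[i]]
      p
    })
  })
  if (nrow(per_event) == 0) {
    return(empty)
  }
  per_event <- per_event %>%
    dplyr::mutate(
      a = pmin(.data$node_a, .data$node_b),
      b = pmax(.data$node_a, .data$node_b)
    )
  per_event %>%
    dplyr::group_by(node_a = .data$a, node_b = .data$b, category = .data$category) %>%
    dplyr::summarise(
      provenance = list(dplyr::distinct(tibble(
        doc_id = doc_id, event_id = event_id
      ))),
      .groups = "drop"
    ) %>%
    dplyr::mutate(n_docs = vapply(
      .data$provenance,
      function(p) length(unique(p$doc_id)), integer(1)
    )) %>%
    dplyr::arrange(.data$node_a, .data$node_b, .data$category) %>%
    dplyr::select("node_a", "node_b", "category", "n_docs", "provenance")
}

#' Write unique interaction pairs as TSV
#'
#' Columns: `node_a`, `node_b`, `category`, `n_docs`, `doc_ids`
#' (semicolon-separated).
#'
#' @param pairs Tibble from [extract_unique_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  doc_ids <- vapply(
    pairs$provenance,
    function(p) paste(sort(unique(p$doc_id)), collapse = ";"), character(1)
  )
  lines <- c(
    "node_a\tnode_b\tcategory\tn_docs\tdoc_ids",
    sprintf("%s\t%s\t%s\t%d\t%s", pairs$node_a, pairs$node_b, pairs$category, pairs$n_docs, doc_ids)
  )
  writeLines(lines, path)
  invisible(path)
}
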