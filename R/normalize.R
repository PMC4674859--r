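# Entity normalization: gene mentions to Entrez Gene IDs by exact
# (case-folded) lexicon lookup, pathway mentions to canonical pathway
# records by best soft-match synonym, and the all-or-nothing discard of
# events with unmappable participants.

#' Normalize a gene mention to an Entrez Gene ID
#'
#' Exact lookup of the case-folded surface form in the gene lexicon. No
#' fuzzy matching is attempted: an absent surface is simply unmappable.
#'
#' @param mention One-row mentions tibble with `entity_class == "GENE"`.
#' @param lexicon Lexicon tibble from [read_gene_lexicon()].
#' @return The Entrez Gene ID (integer), or `NA` when the surface is absent.
#' @export
normalize_gene <- function(mention, lexicon) {
  stopifnot(nrow(mention) == 1)
  if (mention$entity_class != "GENE") {
    abort("normalize_gene() requires a GENE mention", class = "pathevents_usage_error")
  }
  lookup_gene(mention$surface, lexicon)
}

lookup_gene <- function(surface, lexicon) {
  folded <- stringi::stri_trans_tolower(surface)
  lex_folded <- stringi::stri_trans_tolower(lexicon$surface)
  lexicon$entrez_id[match(folded, lex_folded)]
}

#' Normalize a pathway mention to a canonical pathway record
#'
#' Scores the mention surface against every synonym (and canonical name) in
#' the pathway dictionary using the same token-set similarity as
#' [soft_match()]; the best-scoring synonym at or above the threshold wins,
#' with ties broken by lexicographically smallest canonical id for
#' determinism.
#'
#' @param mention One-row mentions tibble with `entity_class == "PATHWAY"`.
#' @param db Pathway DB tibble from [read_pathway_db()].
#' @param cfg A [soft_match_config()].
#' @return The canonical pathway id (character), or `NA` when no synonym
#'   reaches the threshold.
#' @export
normalize_pathway <- function(mention, db, cfg = soft_match_config()) {
  stopifnot(nrow(mention) == 1)
  if (mention$entity_class != "PATHWAY") {
    abort("normalize_pathway() requires a PATHWAY mention", class = "pathevents_usage_error")
  }
  lookup_pathway(mention$surface, synonym_table(db, cfg), cfg)
}

lookup_pathway <- function(surface, syn, cfg) {
  if (nrow(syn) == 0) {
    return(NA_character_)
  }
  toks <- normalize_token_set(surface, head_tokens = head_token_set(cfg))
  if (length(toks) == 0) {
    return(NA_character_)
  }
  scores <- vapply(syn$tokens, jaccard, numeric(1), a = toks)
  ok <- scores >= cfg$similarity_threshold
  if (!any(ok)) {
    return(NA_character_)
  }
  best <- max(scores[ok])
  min(syn$canonical_id[ok & scores == best])
}

#' Normalize all mentions of a corpus
#'
#' Adds a `node_key` column: bare Entrez ID for mappable genes,
#' `PW:`-prefixed canonical id for mappable pathways, `NA` for unmappable
#' mentions (and for mentions of unknown entity class).
#'
#' @param mentions Mentions tibble (any number of documents).
#' @param lexicon Lexicon tibble from [read_gene_lexicon()].
#' @param db Pathway DB tibble from [read_pathway_db()].
#' @param cfg A [soft_match_config()].
#' @return The mentions tibble with a `node_key` column.
#' @export
normalize_mentions <- function(mentions, lexicon, db, cfg = soft_match_config()) {
  if (nrow(mentions) == 0) {
    mentions$node_key <- character(0)
    return(mentions)
  }
  syn <- synonym_table(db, cfg)
  key <- rep(NA_character_, nrow(mentions))
  is_gene <- mentions$entity_class == "GENE"
  if (any(is_gene)) {
    ids <- lookup_gene(mentions$surface[is_gene], lexicon)
    key[is_gene] <- ifelse(is.na(ids), NA_character_, gene_key(ids))
  }
  is_pw <- mentions$entity_class == "PATHWAY"
  if (any(is_pw)) {
    # pathway matching is surface-level, so memoise per distinct surface
    surfaces <- unique(mentions$surface[is_pw])
    hits <- vapply(surfaces, lookup_pathway, character(1), syn = syn, cfg = cfg)
    mapped <- hits[match(mentions$surface[is_pw], surfaces)]
    key[is_pw] <- ifelse(is.na(mapped), NA_character_, pathway_key(mapped))
  }
  mentions$node_key <- key
  mentions
}

#' Discard events with unmappable participants
#'
#' An event is kept iff every mention in its recursive argument closure —
#' through any depth of nested sub-events — normalizes to an Entrez ID or a
#' canonical pathway record. Discarding is all-or-nothing per event: one bad
#' mention anywhere in the tree discards the whole event. Kept events are
#' returned unaltered, and `nrow(kept) + nrow(discarded) == nrow(events)`.
#'
#' @param events Events tibble (undisguised; any number of documents).
#' @param mentions Mentions tibble.
#' @param lexicon Lexicon tibble from [read_gene_lexicon()].
#' @param db Pathway DB tibble from [read_pathway_db()].
#' @param cfg A [soft_match_config()].
#' @return A list with `kept` (events tibble), `discarded` (log tibble with
#'   columns `doc_id`, `event_id`, `reason`, `surface` — one row per
#'   discarded event, naming the first offending mention), and `mentions`
#'   (the normalized mentions tibble, with `node_key`).
#' @export
filter_normalizable <- function(events, mentions, lexicon, db, cfg = soft_match_config()) {
  norm <- normalize_mentions(mentions, lexicon, db, cfg)
  empty_log <- tibble(
    doc_id = character(), event_id = character(),
    reason = character(), surface = character()
  )
  if (nrow(events) == 0) {
    return(list(kept = events, discarded = empty_log, mentions = norm))
  }
  rows <- split(seq_len(nrow(events)), events$doc_id)
  verdicts <- purrr::map_dfr(rows, function(ii) {
    ev <- events[ii, ]
    me <- norm[norm$doc_id == ev$doc_id[[1]], ]
    closure <- doc_participant_closure(ev)
    purrr::map_dfr(seq_len(nrow(ev)), function(i) {
      ids <- closure[[ev$event_id[[i]]]]
      keys <- me$node_key[match(ids, me$mention_id)]
      bad <- which(is.na(keys))
      if (length(bad) == 0) {
        tibble(
          row = ii[[i]], keep = TRUE,
          reason = NA_character_, surface = NA_character_
        )
      } else {
        off <- me[match(ids[bad[[1]]], me$mention_id), ]
        tibble(
          row = ii[[i]], keep = FALSE,
          reason = if (off$entity_class == "PATHWAY") "unmappable_pathway" else "unmappable_gene",
          surface = off$surface
        )
      }
    })
  })
  verdicts <- verdicts[order(verdicts$row), ]
  kept <- events[verdicts$row[verdicts$keep], ]
  disc <- verdicts[!verdicts$keep, ]
  discarded <- tibble(
    doc_id = events$doc_id[disc$row],
    event_id = events$event_id[disc$row],
    reason = disc$reason,
    surface = disc$surface
  )
  list(kept = kept, discarded = discarded, mentions = norm)
}

#' Write a discard log as TSV
#'
#' Columns: `doc_id`, `event_id`, `reason`, `surface`.
#'
#' @param discarded Discard log tibble from [filter_normalizable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discard_log <- function(discarded, path) {
  lines <- c(
    "doc_id\tevent_id\treason\tsurface",
    sprintf(
      "%s\t%s\t%s\t%s",
      discarded$doc_id, discarded$event_id, discarded$reason, discarded$surface
    )
  )
  writeLines(lines, path)
  invisible(path)
}
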