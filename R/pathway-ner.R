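# Pathway mention recognition: a transparent soft dictionary matcher plus a
# head-term extension rule, overlap merging between gene and pathway
# mentions, and the disguise/undisguise bridge that lets a gene-only event
# extractor process pathway entities.

#' Soft-matching configuration for pathway recognition
#'
#' Controls the dictionary matcher and the rule-based detector. Similarity is
#' token-set Jaccard after lowercasing, splitting on whitespace, slashes,
#' hyphens and other punctuation, and removing head terms (the generic
#' pathway trigger words such as "pathway" or "signaling"); the default
#' threshold of 0.8 accepts one token of disagreement on most dictionary
#' names while rejecting unrelated spans.
#'
#' @param similarity_threshold Minimum Jaccard similarity in `[0, 1]`.
#' @param head_terms Pathway trigger tokens/phrases.
#' @param max_entity_tokens Maximum number of specific (non-head) tokens a
#'   candidate span may contain.
#' @return A `soft_match_config` list.
#' @export
soft_match_config <- function(similarity_threshold = 0.8,
                              head_terms = c(
                                "pathway", "pathways", "signaling", "signalling",
                                "cascade", "signal transduction"
                              ),
                              max_entity_tokens = 5) {
  if (!is.numeric(similarity_threshold) || similarity_threshold < 0 || similarity_threshold > 1) {
    abort("similarity_threshold must be in [0, 1]", class = "pathevents_config_error")
  }
  if (length(head_terms) == 0) {
    abort("head_terms must be non-empty", class = "pathevents_config_error")
  }
  if (!is.numeric(max_entity_tokens) || max_entity_tokens < 1) {
    abort("max_entity_tokens must be a positive integer", class = "pathevents_config_error")
  }
  structure(
    list(
      similarity_threshold = similarity_threshold,
      head_terms = tolower(head_terms),
      max_entity_tokens = as.integer(max_entity_tokens)
    ),
    class = "soft_match_config"
  )
}

# tokens of head terms, used to strip generic words before similarity scoring
head_token_set <- function(cfg) {
  unique(unlist(strsplit(cfg$head_terms, "[^\\p{L}\\p{N}]+", perl = TRUE)))
}

# lowercase token set of a string: split on anything that is not a letter or
# digit (so slashes and hyphens separate), optionally drop head tokens
normalize_token_set <- function(x, head_tokens = character(0)) {
  toks <- unlist(stringi::stri_split_regex(stringi::stri_trans_tolower(x), "[^\\p{L}\\p{N}]+"))
  toks <- toks[nzchar(toks)]
  unique(setdiff(toks, head_tokens))
}

jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(0)
  }
  length(intersect(a, b)) / length(union(a, b))
}

# locate word-like tokens in text; slash/hyphen/apostrophe compounds such as
# "Wnt/β-catenin" stay one token. Returns 0-based half-open spans.
tokenize_spans <- function(text) {
  loc <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}][\\p{L}\\p{N}/'\\-]*"
  )[[1]]
  if (nrow(loc) == 0 || anyNA(loc[, 1])) {
    return(tibble(start = integer(), end = integer(), token = character()))
  }
  tibble(
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2]),
    token = stringi::stri_sub(text, loc[, 1], loc[, 2])
  )
}

# all synonym strings of a pathway DB (canonical names included), with
# precomputed normalized token sets
synonym_table <- function(db, cfg) {
  ht <- head_token_set(cfg)
  syn <- purrr::map_dfr(seq_len(nrow(db)), function(i) {
    s <- db$synonyms[[i]]
    tibble(
      canonical_id = db$canonical_id[[i]],
      name = unique(c(db$canonical_name[[i]], if (nrow(s) > 0) s$name))
    )
  })
  if (nrow(syn) == 0) {
    return(tibble(canonical_id = character(), name = character(), tokens = list()))
  }
  syn$tokens <- lapply(syn$name, normalize_token_set, head_tokens = ht)
  syn[lengths(syn$tokens) > 0, ]
}

#' Soft dictionary matching of pathway mentions
#'
#' Scans token windows of the document against all pathway synonyms. A window
#' qualifies when its normalized token set (lowercased, punctuation-split,
#' head terms removed) has Jaccard similarity at or above the configured
#' threshold with some synonym. Overlapping matches are resolved longest span
#' first (ties by smaller start offset), so the returned pathway mentions
#' never overlap.
#'
#' @param doc One-row document tibble.
#' @param db Pathway DB tibble from [read_pathway_db()].
#' @param cfg A [soft_match_config()].
#' @return A tibble of `PATHWAY` mentions (possibly empty).
#' @export
soft_match <- function(doc, db, cfg = soft_match_config()) {
  stopifnot(nrow(doc) == 1)
  syn <- synonym_table(db, cfg)
  if (nrow(syn) == 0) {
    return(empty_mentions())
  }
  toks <- tokenize_spans(doc$text)
  n <- nrow(toks)
  if (n == 0) {
    return(empty_mentions())
  }
  ht <- head_token_set(cfg)
  # windows may not cross non-whitespace gaps (punctuation, sentence breaks)
  gap_ok <- if (n > 1) {
    vapply(seq_len(n - 1), function(i) {
      gap <- substr(doc$text, toks$end[[i]] + 1L, toks$start[[i + 1]])
      grepl("^\\s*$", gap)
    }, logical(1))
  } else {
    logical(0)
  }
  max_win <- cfg$max_entity_tokens + length(ht)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:min(n, i + max_win - 1L)) {
      if (j > i && !all(gap_ok[i:(j - 1)])) break
      span_txt <- substr(doc$text, toks$start[[i]] + 1L, toks$end[[j]])
      cand_toks <- normalize_token_set(span_txt, head_tokens = ht)
      if (length(cand_toks) == 0 || length(cand_toks) > cfg$max_entity_tokens) next
      best <- max(vapply(syn$tokens, jaccard, numeric(1), a = cand_toks))
      if (best >= cfg$similarity_threshold) {
        cand[[length(cand) + 1]] <- tibble(
          start = toks$start[[i]], end = toks$end[[j]], surface = span_txt
        )
      }
    }
  }
  if (length(cand) == 0) {
    return(empty_mentions())
  }
  spans <- resolve_overlapping_spans(dplyr::bind_rows(cand))
  tibble(
    doc_id = doc$doc_id,
    mention_id = paste0("SM", seq_len(nrow(spans))),
    start = spans$start, end = spans$end, surface = spans$surface,
    entity_class = "PATHWAY"
  )
}

# longest span wins; ties broken by smaller start offset
resolve_overlapping_spans <- function(spans) {
  spans <- dplyr::distinct(spans)
  spans <- spans[order(-(spans$end - spans$start), spans$start), ]
  kept <- spans[0, ]
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    if (nrow(kept) == 0 || all(s$end <= kept$start | s$start >= kept$end)) {
      kept <- dplyr::bind_rows(kept, s)
    }
  }
  dplyr::arrange(kept, .data$start)
}

entity_like_token <- function(token) {
  stringi::stri_detect_regex(token, "[A-Z0-9/\\-]|\\p{Greek}")
}

#' Rule-based pathway mention detection
#'
#' Every occurrence of a head term (e.g. "signaling", "pathway") is extended
#' leftwards over up to `max_entity_tokens` contiguous entity-like tokens
#' (tokens containing capitals, digits, Greek letters, or hyphen/slash
#' compounds) to form a pathway mention. Occurrences with no entity-like
#' token to their left are dropped, and the returned spans never overlap.
#'
#' @inheritParams soft_match
#' @return A tibble of `PATHWAY` mentions (possibly empty).
#' @export
rule_detect <- function(doc, cfg = soft_match_config()) {
  stopifnot(nrow(doc) == 1)
  toks <- tokenize_spans(doc$text)
  if (nrow(toks) == 0) {
    return(empty_mentions())
  }
  pat <- paste0(
    "(?i)\\b(",
    paste(stringi::stri_replace_all_regex(cfg$head_terms, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"),
      collapse = "|"
    ),
    ")\\b"
  )
  occ <- stringi::stri_locate_all_regex(doc$text, pat)[[1]]
  if (nrow(occ) == 0 || anyNA(occ[, 1])) {
    return(empty_mentions())
  }
  # whitespace-only separation between consecutive tokens
  n <- nrow(toks)
  gap_ok <- if (n > 1) {
    vapply(seq_len(n - 1), function(i) {
      grepl("^\\s*$", substr(doc$text, toks$end[[i]] + 1L, toks$start[[i + 1]]))
    }, logical(1))
  } else {
    logical(0)
  }
  spans <- list()
  for (r in seq_len(nrow(occ))) {
    h_start <- as.integer(occ[r, 1] - 1L)
    h_end <- as.integer(occ[r, 2])
    # index of last token ending at or before the head occurrence start
    prev <- which(toks$end <= h_start)
    if (length(prev) == 0) next
    i <- max(prev)
    # the token immediately before the head must be whitespace-adjacent
    if (!grepl("^\\s*$", substr(doc$text, toks$end[[i]] + 1L, h_start))) next
    left <- i
    taken <- 0L
    while (left >= 1 && taken < cfg$max_entity_tokens && entity_like_token(toks$token[[left]])) {
      taken <- taken + 1L
      if (left == 1 || !gap_ok[[left - 1]] || !entity_like_token(toks$token[[left - 1]])) break
      left <- left - 1L
    }
    if (taken == 0L) next
    start <- toks$start[[left]]
    spans[[length(spans) + 1]] <- tibble(
      start = start, end = h_end,
      surface = substr(doc$text, start + 1L, h_end)
    )
  }
  if (length(spans) == 0) {
    return(empty_mentions())
  }
  spans <- resolve_overlapping_spans(dplyr::bind_rows(spans))
  tibble(
    doc_id = doc$doc_id,
    mention_id = paste0("RD", seq_len(nrow(spans))),
    start = spans$start, end = spans$end, surface = spans$surface,
    entity_class = "PATHWAY"
  )
}

#' Detect pathway mentions by combining soft matching and rules
#'
#' Union of [soft_match()] and [rule_detect()] candidates, with overlapping
#' candidates resolved by keeping the longer span (ties by smaller start
#' offset) so that pathway mentions never overlap.
#'
#' @inheritParams soft_match
#' @return A tibble of `PATHWAY` mentions with ids `P1`, `P2`, ... in start
#'   order.
#' @export
detect_pathways <- function(doc, db, cfg = soft_match_config()) {
  cand <- dplyr::bind_rows(soft_match(doc, db, cfg), rule_detect(doc, cfg))
  if (nrow(cand) == 0) {
    return(empty_mentions())
  }
  spans <- resolve_overlapping_spans(cand[, c("start", "end", "surface")])
  tibble(
    doc_id = doc$doc_id,
    mention_id = paste0("P", seq_len(nrow(spans))),
    start = spans$start, end = spans$end, surface = spans$surface,
    entity_class = "PATHWAY"
  )
}

#' Merge overlapping gene and pathway mentions
#'
#' Gene/protein names are frequently nested in pathway names; any gene
#' mention sharing at least one character with a pathway mention is absorbed
#' into a single pathway mention spanning the union of text boundaries.
#' Merging is transitive: a connected component of mutually overlapping
#' mentions collapses to one mention whose span is the interval union and
#' whose class is `PATHWAY` if any component member is a pathway (`GENE`
#' otherwise). Disjoint mentions pass through unchanged; the output is
#' overlap-free and sorted by start offset.
#'
#' @param genes Gene mentions tibble.
#' @param pathways Pathway mentions tibble.
#' @param doc One-row document tibble owning both mention sets.
#' @return A merged mentions tibble.
#' @export
merge_overlaps <- function(genes, pathways, doc) {
  stopifnot(nrow(doc) == 1)
  m <- dplyr::bind_rows(genes, pathways)
  if (nrow(m) == 0) {
    return(empty_mentions())
  }
  if (!all(m$doc_id == doc$doc_id)) {
    abort("All mentions must belong to the given document", class = "pathevents_usage_error")
  }
  m <- m[order(m$start, m$end), ]
  comp <- integer(nrow(m))
  comp[[1]] <- 1L
  cur_end <- m$end[[1]]
  for (i in seq_len(nrow(m))[-1]) {
    if (m$start[[i]] < cur_end) {
      comp[[i]] <- comp[[i - 1]]
      cur_end <- max(cur_end, m$end[[i]])
    } else {
      comp[[i]] <- comp[[i - 1]] + 1L
      cur_end <- m$end[[i]]
    }
  }
  merged <- purrr::map_dfr(split(m, comp), function(grp) {
    if (nrow(grp) == 1) {
      return(grp)
    }
    start <- min(grp$start)
    end <- max(grp$end)
    tibble(
      doc_id = doc$doc_id,
      mention_id = grp$mention_id[[which.min(grp$start)]],
      start = start, end = end,
      surface = substr(doc$text, start + 1L, end),
      entity_class = if (any(grp$entity_class == "PATHWAY")) "PATHWAY" else "GENE"
    )
  })
  dplyr::arrange(as_tibble(merged), .data$start)
}

#' Disguise pathway mentions as proteins for a gene-only event extractor
#'
#' Writes every mention — gene or pathway — with the extractor-facing entity
#' type `Protein`, relabelling ids `T1 ... Tn` in start order, and records
#' which ids are really pathways in a sidecar so [undisguise()] can restore
#' their class after event extraction.
#'
#' @param mentions Merged, non-overlapping mentions tibble (one document).
#' @return A list with elements `a1` (character vector of .a1 lines),
#'   `mentions` (the relabelled extractor-facing mentions, all class `GENE`),
#'   and `sidecar` (tibble `mention_id`, `entity_class`, `start`, `end` for
#'   the disguised pathway mentions).
#' @export
disguise <- function(mentions) {
  empty_sidecar <- tibble(
    mention_id = character(), entity_class = character(),
    start = integer(), end = integer()
  )
  if (nrow(mentions) == 0) {
    return(list(a1 = character(0), mentions = empty_mentions(), sidecar = empty_sidecar))
  }
  m <- mentions[order(mentions$start, mentions$end), ]
  if (any(m$start[-1] < m$end[-nrow(m)])) {
    abort("disguise() requires non-overlapping mentions", class = "pathevents_usage_error")
  }
  m$mention_id <- paste0("T", seq_len(nrow(m)))
  sidecar <- m[m$entity_class == "PATHWAY", c("mention_id", "entity_class", "start", "end")]
  out <- m
  out$entity_class <- "GENE"
  a1 <- sprintf("%s\tProtein %d %d\t%s", m$mention_id, m$start, m$end, m$surface)
  list(a1 = a1, mentions = out, sidecar = sidecar)
}

#' Restore disguised pathway mention classes
#'
#' Inverse of [disguise()]: every sidecar entry flags a mention id whose true
#' entity class is `PATHWAY`; those mentions get their class restored.
#' Events referencing the mentions are untouched (entity classes live on the
#' mention table). Idempotent.
#'
#' @param mentions Mentions tibble as read back from the extractor.
#' @param sidecar Sidecar tibble from [disguise()].
#' @return The mentions tibble with entity classes restored.
#' @export
undisguise <- function(mentions, sidecar) {
  if (nrow(sidecar) == 0) {
    return(mentions)
  }
  missing <- setdiff(sidecar$mention_id, mentions$mention_id)
  if (length(missing) > 0) {
    abort(
      paste0("Sidecar id(s) not found in mentions: ", paste(missing, collapse = ", ")),
      class = "pathevents_integrity_error"
    )
  }
  idx <- match(sidecar$mention_id, mentions$mention_id)
  mentions$entity_class[idx] <- sidecar$entity_class
  mentions
}
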