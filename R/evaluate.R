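# Event-level evaluation: precision on a sampled set of reported pathway
# events, pseudo-recall on a sampled candidate set of same-document
# <pathway, gene> pairs within a character-distance threshold, and their F1.

#' Confusion counts for event-level evaluation
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return An `eval_counts` tibble (one row).
#' @export
eval_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("Confusion counts must be non-negative integers", class = "pathevents_usage_error")
  }
  structure(
    tibble(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn), fn = as.integer(fn)),
    class = c("eval_counts", class(tibble()))
  )
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`.
#'
#' @param counts An [eval_counts()] row.
#' @return Precision as a fraction in `[0, 1]`.
#' @export
precision <- function(counts) {
  if (counts$tp + counts$fp == 0) {
    abort("Precision undefined: TP + FP == 0", class = "pathevents_metric_error")
  }
  counts$tp / (counts$tp + counts$fp)
}

#' Pseudo-recall from confusion counts
#'
#' `TP / (TP + FN)`, computed on a sampled candidate-pair set rather than
#' the full event space — hence "pseudo": genuine recall would require
#' sampling from all possible events, where true pathway events are far too
#' sparse.
#'
#' @param counts An [eval_counts()] row.
#' @return Pseudo-recall as a fraction in `[0, 1]`.
#' @export
pseudo_recall <- function(counts) {
  if (counts$tp + counts$fn == 0) {
    abort("Pseudo-recall undefined: TP + FN == 0", class = "pathevents_metric_error")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`, computed from unrounded inputs.
#'
#' @param p Precision fraction.
#' @param r Recall fraction.
#' @return F1 as a fraction in `[0, 1]`.
#' @export
f1_score <- function(p, r) {
  stopifnot(p >= 0, p <= 1, r >= 0, r <= 1)
  if (p + r == 0) {
    abort("F1 undefined: p + r == 0", class = "pathevents_metric_error")
  }
  2 * p * r / (p + r)
}

#' Sample candidate <pathway, gene> pairs for pseudo-recall estimation
#'
#' Enumerates every (pathway mention, gene mention) pair whose members occur
#' in the same document with fewer than `max_dist` characters strictly
#' between the nearer span boundaries (0 for adjacent or overlapping spans),
#' then draws `n` pairs uniformly without replacement under the given seed.
#' If fewer than `n` pairs qualify, all are returned with a warning. The
#' draw is reproducible: the same seed yields the same sample, and the
#' global random-number state is left untouched.
#'
#' @param mentions Mentions tibble (any number of documents).
#' @param n Sample size.
#' @param seed Integer seed for the draw.
#' @param max_dist Strict character-distance threshold (default 100).
#' @return A tibble with columns `doc_id`, `pathway_id`, `gene_id` (mention
#'   ids), `pathway_surface`, `gene_surface`, `char_distance`.
#' @export
sample_candidate_pairs <- function(mentions, n, seed, max_dist = 100) {
  stopifnot(n >= 0)
  all_pairs <- enumerate_candidate_pairs(mentions, max_dist)
  if (nrow(all_pairs) <= n) {
    if (nrow(all_pairs) < n) {
      warn(paste0(
        "Only ", nrow(all_pairs), " candidate pairs qualify (requested ", n, "); returning all"
      ))
    }
    return(all_pairs)
  }
  idx <- with_local_seed(seed, sample.int(nrow(all_pairs), n))
  dplyr::arrange(all_pairs[idx, ], .data$doc_id, .data$pathway_id, .data$gene_id)
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic enumeration of all qualifying candidate pairs
enumerate_candidate_pairs <- function(mentions, max_dist) {
  empty <- tibble(
    doc_id = character(), pathway_id = character(), gene_id = character(),
    pathway_surface = character(), gene_surface = character(),
    char_distance = integer()
  )
  pw <- mentions[mentions$entity_class == "PATHWAY", ]
  ge <- mentions[mentions$entity_class == "GENE", ]
  if (nrow(pw) == 0 || nrow(ge) == 0) {
    return(empty)
  }
  cand <- dplyr::inner_join(
    dplyr::rename(pw,
      pathway_id = "mention_id", pw_start = "start",
      pw_end = "end", pathway_surface = "surface"
    )[, c("doc_id", "pathway_id", "pw_start", "pw_end", "pathway_surface")],
    dplyr::rename(ge,
      gene_id = "mention_id", g_start = "start",
      g_end = "end", gene_surface = "surface"
    )[, c("doc_id", "gene_id", "g_start", "g_end", "gene_surface")],
    by = "doc_id", relationship = "many-to-many"
  )
  if (nrow(cand) == 0) {
    return(empty)
  }
  cand$char_distance <- as.integer(pmax(
    0L,
    pmax(cand$pw_start, cand$g_start) - pmin(cand$pw_end, cand$g_end)
  ))
  cand <- cand[cand$char_distance < max_dist, ]
  dplyr::arrange(
    cand[, names(empty)],
    .data$doc_id, .data$pathway_id, .data$gene_id
  )
}

#' Canonical signatures of events for equivalence testing
#'
#' Two events are equivalent when they come from the same document, have the
#' same event type, and the same normalized participant sets per role (theme
#' side and cause side) after recursive nested expansion. Participants are
#' compared by `node_key` when present, else by case-folded surface.
#'
#' @param events Events tibble.
#' @param mentions Mentions tibble (with `node_key` when available).
#' @return Character vector of signatures, one per event row.
#' @export
event_signatures <- function(events, mentions) {
  if (nrow(events) == 0) {
    return(character(0))
  }
  out <- character(nrow(events))
  for (ii in split(seq_len(nrow(events)), events$doc_id)) {
    ev <- events[ii, ]
    me <- mentions[mentions$doc_id == ev$doc_id[[1]], ]
    closure <- doc_participant_closure(ev)
    part_key <- function(ids) {
      if (length(ids) == 0) {
        return("")
      }
      keys <- if ("node_key" %in% names(me)) me$node_key[match(ids, me$mention_id)] else NA
      surf <- stringi::stri_trans_tolower(me$surface[match(ids, me$mention_id)])
      paste(sort(unique(ifelse(is.na(keys), surf, keys))), collapse = ",")
    }
    for (i in seq_len(nrow(ev))) {
      theme_ids <- unique(unlist(lapply(ev$themes[[i]], expand_ref, closure, me)))
      cause_ids <- if (is.na(ev$cause[[i]])) {
        character(0)
      } else {
        expand_ref(ev$cause[[i]], closure, me)
      }
      out[ii[[i]]] <- paste0(
        ev$doc_id[[1]], "|", ev$event_type[[i]],
        "|T:", part_key(theme_ids), "|C:", part_key(cause_ids)
      )
    }
  }
  out
}

#' Score predicted events against gold annotations
#'
#' An event counts as a true positive only if the event and its arguments
#' are both correct: a predicted event must have a gold event with the same
#' type and the same normalized participant sets per role (see
#' [event_signatures()]). Unmatched predictions are false positives;
#' unmatched gold events are false negatives. When a candidate-pair table is
#' supplied, candidates covered by neither gold nor prediction (no event
#' whose participant closure contains both the pathway and the gene mention
#' surface/key) count as true negatives.
#'
#' @param gold_events,gold_mentions Gold-standard events and their mentions.
#' @param pred_events,pred_mentions Predicted events and their mentions.
#' @param candidates Optional candidate pairs from
#'   [sample_candidate_pairs()].
#' @return An [eval_counts()] row.
#' @export
score_events <- function(gold_events, gold_mentions, pred_events, pred_mentions,
                         candidates = NULL) {
  gold_sigs <- unique(event_signatures(gold_events, gold_mentions))
  pred_sigs <- unique(event_signatures(pred_events, pred_mentions))
  tp <- length(intersect(pred_sigs, gold_sigs))
  fp <- length(setdiff(pred_sigs, gold_sigs))
  fn <- length(setdiff(gold_sigs, pred_sigs))
  tn <- 0L
  if (!is.null(candidates) && nrow(candidates) > 0) {
    covered_by <- function(events, mentions) {
      vapply(seq_len(nrow(candidates)), function(i) {
        cd <- candidates[i, ]
        ev <- events[events$doc_id == cd$doc_id, ]
        if (nrow(ev) == 0) {
          return(FALSE)
        }
        me <- mentions[mentions$doc_id == cd$doc_id, ]
        closure <- doc_participant_closure(ev)
        targets <- stringi::stri_trans_tolower(c(cd$pathway_surface, cd$gene_surface))
        any(vapply(closure, function(ids) {
          surf <- stringi::stri_trans_tolower(me$surface[match(ids, me$mention_id)])
          all(targets %in% surf)
        }, logical(1)))
      }, logical(1))
    }
    covered <- covered_by(gold_events, gold_mentions) | covered_by(pred_events, pred_mentions)
    tn <- sum(!covered)
  }
  eval_counts(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Summarise confusion counts into the evaluation metrics
#'
#' @param x An [eval_counts()] row.
#' @param ... Unused.
#' @return A one-row tibble with `precision`, `pseudo_recall`, `f1` (where
#'   defined; `NA` otherwise).
#' @method glance eval_counts
#' @export
glance.eval_counts <- function(x, ...) {
  p <- tryCatch(precision(x), error = function(e) NA_real_)
  r <- tryCatch(pseudo_recall(x), error = function(e) NA_real_)
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) f1_score(p, r) else NA_real_
  tibble(precision = p, pseudo_recall = r, f1 = f1)
}
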