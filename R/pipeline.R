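# End-to-end orchestration: corpus directory in, interaction network and
# stage reports out. Per-document work is independent, so any worker count
# yields byte-identical results; documents are always combined in sorted
# doc_id order.

#' Pipeline configuration
#'
#' @param input_dir Corpus directory with `<doc_id>.txt` and standoff
#'   annotation files.
#' @param lexicon_path Gene lexicon TSV (default `gene_lexicon.tsv` in
#'   `input_dir`).
#' @param pathway_db_path Pathway dictionary TSV (default `pathway_db.tsv`
#'   in `input_dir`).
#' @param mode `"standoff"` consumes `<doc_id>.a1` entity classes as
#'   annotated (the planted-annotation path); `"detect"` runs gene lexicon
#'   scanning plus pathway recognition on the raw text, merges overlaps,
#'   disguises pathways, obtains events from `extractor` (or pre-existing
#'   `.a2` files keyed to the disguised ids), and undisguises.
#' @param match A [soft_match_config()].
#' @param filter_pathway_events Apply the regulation-only restriction for
#'   pathway-involved events?
#' @param expand_members Passed to [add_curated_edges()].
#' @param workers Number of parallel workers for the per-document stage.
#' @param output_dir Optional directory for stage outputs (`pairs.tsv`,
#'   `network.sif`, `stats.tsv`, `discards.tsv`).
#' @param extractor Optional function `(doc, a1_lines) -> character vector
#'   of .a2 lines`, the pluggable event-extractor hook used in `"detect"`
#'   mode.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir,
                            lexicon_path = file.path(input_dir, "gene_lexicon.tsv"),
                            pathway_db_path = file.path(input_dir, "pathway_db.tsv"),
                            mode = c("standoff", "detect"),
                            match = soft_match_config(),
                            filter_pathway_events = TRUE,
                            expand_members = FALSE,
                            workers = 1,
                            output_dir = NULL,
                            extractor = NULL) {
  mode <- match.arg(mode)
  if (!dir.exists(input_dir)) {
    abort(paste0("Input directory not found: ", input_dir), class = "pathevents_config_error")
  }
  for (p in c(lexicon_path, pathway_db_path)) {
    if (!file.exists(p)) {
      abort(paste0("Required table not found: ", p), class = "pathevents_config_error")
    }
  }
  if (workers < 1) {
    abort("workers must be >= 1", class = "pathevents_config_error")
  }
  structure(
    list(
      input_dir = input_dir, lexicon_path = lexicon_path,
      pathway_db_path = pathway_db_path, mode = mode, match = match,
      filter_pathway_events = filter_pathway_events,
      expand_members = expand_members, workers = as.integer(workers),
      output_dir = output_dir, extractor = extractor
    ),
    class = "pipeline_config"
  )
}

#' Run the full extraction pipeline
#'
#' Reads every document of the corpus, obtains mentions and events (from
#' standoff annotations or by recognition plus the extractor hook),
#' normalizes participants, discards events with unmappable mentions,
#' enforces the pathway event-type restriction, extracts unique undirected
#' interaction pairs, builds the merged network with curated membership
#' edges, and computes its topology statistics.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_report` list with stage `counts`, the `pairs` tibble,
#'   the `network`, its `stats`, and the `discarded` log.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lexicon <- read_gene_lexicon(cfg$lexicon_path)
  db <- read_pathway_db(cfg$pathway_db_path)
  docs <- read_corpus_documents(cfg$input_dir)
  per_doc <- if (nrow(docs) == 0) {
    list()
  } else {
    runner <- function(i) {
      doc <- docs[i, ]
      tryCatch(
        process_document(doc, cfg, lexicon, db),
        error = function(e) {
          abort(
            paste0("Failed on document ", doc$doc_id, ": ", conditionMessage(e)),
            class = "pathevents_pipeline_error"
          )
        }
      )
    }
    if (cfg$workers > 1) {
      res <- parallel::mclapply(seq_len(nrow(docs)), runner, mc.cores = cfg$workers)
      failed <- vapply(res, inherits, logical(1), "try-error")
      if (any(failed)) abort(as.character(res[[which(failed)[1]]]), class = "pathevents_pipeline_error")
      res
    } else {
      lapply(seq_len(nrow(docs)), runner)
    }
  }
  mentions <- dplyr::bind_rows(c(list(empty_mentions()), purrr::map(per_doc, "mentions")))
  events <- dplyr::bind_rows(c(list(empty_events()), purrr::map(per_doc, "events")))
  n_raw_mentions <- sum(vapply(per_doc, function(x) x$n_raw_mentions, integer(1)))

  filt <- filter_normalizable(events, mentions, lexicon, db, cfg$match)
  valid <- if (cfg$filter_pathway_events) {
    filter_valid_pathway_events(filt$kept, filt$mentions)
  } else {
    filt$kept
  }
  pairs <- extract_unique_pairs(valid, filt$mentions)
  net <- add_curated_edges(build_network(pairs), db, expand_members = cfg$expand_members)
  stats <- compute_stats(net)
  counts <- tibble(
    documents = nrow(docs),
    mentions_raw = n_raw_mentions,
    mentions_merged = nrow(mentions),
    events_read = nrow(events),
    events_discarded = nrow(filt$discarded),
    events_kept = nrow(filt$kept),
    events_valid = nrow(valid),
    unique_pairs = nrow(pairs),
    nodes = nrow(net$nodes),
    edges = nrow(net$edges)
  )
  report <- structure(
    list(
      counts = counts, pairs = pairs, network = net, stats = stats,
      discarded = filt$discarded, mentions = filt$mentions, events = valid
    ),
    class = "pipeline_report"
  )
  if (!is.null(cfg$output_dir)) {
    write_pipeline_outputs(report, cfg$output_dir)
  }
  report
}

# mentions and events for one document
process_document <- function(doc, cfg, lexicon, db) {
  base <- file.path(cfg$input_dir, doc$doc_id)
  if (cfg$mode == "standoff") {
    mentions <- read_a1(paste0(base, ".a1"), doc)
    events <- read_a2(paste0(base, ".a2"), mentions)
    return(list(mentions = mentions, events = events, n_raw_mentions = nrow(mentions)))
  }
  genes <- scan_gene_mentions(doc, lexicon)
  pathways <- detect_pathways(doc, db, cfg$match)
  merged <- merge_overlaps(genes, pathways, doc)
  dis <- disguise(merged)
  a2_lines <- if (!is.null(cfg$extractor)) {
    cfg$extractor(doc, dis$a1)
  } else if (file.exists(paste0(base, ".a2"))) {
    readLines(paste0(base, ".a2"), warn = FALSE)
  } else {
    character(0)
  }
  a2_tmp <- tempfile(fileext = ".a2")
  on.exit(unlink(a2_tmp))
  writeLines(a2_lines, a2_tmp)
  events <- read_a2(a2_tmp, dis$mentions)
  mentions <- undisguise(dis$mentions, dis$sidecar)
  list(
    mentions = mentions, events = events,
    n_raw_mentions = nrow(genes) + nrow(pathways)
  )
}

#' Scan a document for gene mentions by lexicon lookup
#'
#' Locates every lexicon surface form as a word-bounded, case-insensitive
#' match in the text; overlapping matches keep the longer span.
#'
#' @param doc One-row document tibble.
#' @param lexicon Lexicon tibble from [read_gene_lexicon()].
#' @return A tibble of `GENE` mentions.
#' @export
scan_gene_mentions <- function(doc, lexicon) {
  stopifnot(nrow(doc) == 1)
  if (nrow(lexicon) == 0) {
    return(empty_mentions())
  }
  hits <- purrr::map_dfr(lexicon$surface, function(sf) {
    pat <- paste0("(?i)\\b", regex_escape(sf), "\\b")
    loc <- stringi::stri_locate_all_regex(doc$text, pat)[[1]]
    if (nrow(loc) == 0 || anyNA(loc[, 1])) {
      return(NULL)
    }
    tibble(
      start = as.integer(loc[, 1] - 1L), end = as.integer(loc[, 2]),
      surface = stringi::stri_sub(doc$text, loc[, 1], loc[, 2])
    )
  })
  if (nrow(hits) == 0) {
    return(empty_mentions())
  }
  spans <- resolve_overlapping_spans(hits)
  tibble(
    doc_id = doc$doc_id,
    mention_id = paste0("G", seq_len(nrow(spans))),
    start = spans$start, end = spans$end, surface = spans$surface,
    entity_class = "GENE"
  )
}

regex_escape <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1")
}

write_pipeline_outputs <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch(
    {
      written <- c(written, write_pairs_tsv(report$pairs, file.path(output_dir, "pairs.tsv")))
      written <- c(written, write_sif(report$network, file.path(output_dir, "network.sif")))
      written <- c(written, write_stats_tsv(report$stats, file.path(output_dir, "stats.tsv")))
      written <- c(written, write_discard_log(
        report$discarded,
        file.path(output_dir, "discards.tsv")
      ))
    },
    error = function(e) {
      unlink(written)
      abort(paste0("Failed writing outputs: ", conditionMessage(e)),
        class = "pathevents_io_error"
      )
    }
  )
  invisible(output_dir)
}

#' Write network statistics as a flat key-value TSV
#'
#' @param stats One-row stats tibble from [compute_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  vals <- vapply(names(stats), function(nm) {
    v <- stats[[nm]]
    if (is.na(v)) "NA" else format(v, digits = 15)
  }, character(1))
  writeLines(sprintf("%s\t%s", names(stats), vals), path)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) cat("  ", format(nm, width = 18), x$counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Stage counts and network statistics of a pipeline run
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return One-row tibble: stage counts followed by topology statistics.
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$stats[, setdiff(names(x$stats), c("node_count", "edge_count"))])
}

#' Unique interaction pairs of a pipeline run
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return The pairs tibble.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$pairs
}
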