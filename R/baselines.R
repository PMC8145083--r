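#' SumBasic extractive summarization
#'
#' Word probabilities start at P(w) = c(w) / N over the whole input; each
#' round scores every unselected statement by the mean probability of its
#' words, picks — among the statements containing the currently most probable
#' word — the one with the highest mean score (earliest on ties), and squares
#' the probabilities of the selected statement's words. The squaring update
#' diversifies the summary by discounting already-covered vocabulary.
#'
#' @param statements data.frame with a `statement` column (and optionally
#'   `pair_index`), or a character vector.
#' @param n_out Number of statements to select, >= 1.
#' @return A `kias_summary` whose sentences are the selected statements in
#'   selection order; `selections` holds the selected row indices.
#' @export
sumbasic <- function(statements, n_out) {
  if (!(is.numeric(n_out) && n_out >= 1L)) kias_abort("sumbasic: n_out must be >= 1")
  stmts <- if (is.data.frame(statements)) statements$statement
           else as.character(statements)
  if (length(stmts) == 0L) {
    return(structure(list(conversation_id = "conv", selections = integer(),
                          sentences = character(), status = "ok"),
                     class = "kias_summary"))
  }
  tok_list <- lapply(stmts, tokenize_text)
  all_toks <- unlist(tok_list)
  probs <- table(all_toks) / length(all_toks)
  probs <- stats::setNames(as.numeric(probs), names(probs))
  selected <- integer()
  while (length(selected) < n_out && length(selected) < length(stmts)) {
    remaining <- setdiff(seq_along(stmts), selected)
    top_word <- names(probs)[which.max(probs)]
    scores <- vapply(remaining, function(i) mean(probs[tok_list[[i]]]),
                     numeric(1L))
    has_top <- vapply(remaining, function(i) top_word %in% tok_list[[i]],
                      logical(1L))
    pool <- if (any(has_top)) remaining[has_top] else remaining
    pool_scores <- scores[match(pool, remaining)]
    pick <- pool[which.max(pool_scores)]
    selected <- c(selected, pick)
    upd <- unique(tok_list[[pick]])
    probs[upd] <- probs[upd]^2
  }
  structure(list(conversation_id = "conv", selections = selected,
                 sentences = stmts[selected], status = "ok"),
            class = "kias_summary")
}

#' Plain abstractive summarization baseline
#'
#' Identical pipeline to [kias_summarize()] but with the Word Semantic Score
#' held at zero everywhere: a generic language model with no knowledge
#' infusion. Fed the same pruned conversation as KiAS so the two differ only
#' in the knowledge boost.
#'
#' @inheritParams kias_summarize
#' @return A `kias_summary`.
#' @export
plain_as <- function(transcript, resources, config = kias_config()) {
  kias_summarize(transcript, resources, config, use_wss = FALSE)
}

#' Abstraction over extractive summarization (AoES)
#'
#' SumBasic prefilters the statements to the top `es_fraction` before the
#' plain abstractive pipeline runs on the surviving subset (original order).
#' Low-frequency clinical phrases tend to be removed by the prefilter — the
#' failure mode knowledge infusion addresses.
#'
#' @inheritParams kias_summarize
#' @param es_fraction Fraction of statements the prefilter keeps, in (0, 1\].
#' @param on_pruned Run the prefilter on the pruned conversation (default) or
#'   the raw statements.
#' @return A `kias_summary`.
#' @export
aoes <- function(transcript, resources, config = kias_config(),
                 es_fraction = 0.5, on_pruned = TRUE) {
  if (!(is.numeric(es_fraction) && es_fraction > 0 && es_fraction <= 1)) {
    kias_abort("aoes: es_fraction must be in (0, 1]")
  }
  pruned <- if (inherits(transcript, "kias_pruned")) {
    transcript
  } else {
    stmts <- statements_from_transcript(transcript, config$completion_map)
    if (on_pruned) {
      prune_statements(stmts, resources$lexicon, resources$embeddings,
                       tau = config$tau, r = config$r,
                       conversation_id = transcript$conversation_id)
    } else {
      structure(list(conversation_id = transcript$conversation_id,
                     statements = stmts, matches = NULL,
                     kept_indices = stmts$pair_index),
                class = "kias_pruned")
    }
  }
  n <- nrow(pruned$statements)
  if (n == 0L) return(plain_as(pruned, resources, config))
  n_keep <- ceiling(es_fraction * n)
  es <- sumbasic(pruned$statements, n_out = n_keep)
  keep_rows <- sort(es$selections)
  sub <- pruned
  sub$statements <- pruned$statements[keep_rows, , drop = FALSE]
  sub$kept_indices <- pruned$kept_indices[keep_rows]
  plain_as(sub, resources, config)
}
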