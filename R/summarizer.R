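#' Combined score of a candidate path
#'
#' combined = (I + Q) / |W(p)|: length-normalizing the sum of informativeness
#' and linguistic quality gives higher weight to shorter paths, pressing the
#' summary toward concision.
#'
#' @param I Informativeness (>= 0).
#' @param Q Linguistic quality in \[0, 1\].
#' @param n_words Number of words on the path, >= 1.
#' @return Combined score.
#' @export
score_path <- function(I, Q, n_words) {
  if (!(is.numeric(n_words) && n_words >= 1L)) {
    kias_abort("score_path: n_words must be >= 1")
  }
  (I + Q) / n_words
}

#' Select one path per slice by integer linear programming
#'
#' Solves the binary program: maximize sum_i x_i * combined_i subject to
#' sum_i x_i = 1, x_i in \{0, 1\}. The one-path constraint leaves exactly K
#' feasible points, so the program is solved exactly by enumerating the
#' feasible set. Ties break toward fewer words, then earlier candidate rank.
#'
#' @param candidates List of scored candidates, each
#'   `list(words, I, Q, n_words, combined)`.
#' @return A `kias_selection`: list with `candidates`, `chosen` (index),
#'   `objective_value`; or NULL (with a warning) when no candidate exists.
#' @export
solve_slice <- function(candidates) {
  if (length(candidates) == 0L) {
    warning("solve_slice: empty candidate list, slice skipped")
    return(NULL)
  }
  K <- length(candidates)
  obj <- vapply(candidates, `[[`, numeric(1L), "combined")
  nw <- vapply(candidates, `[[`, numeric(1L), "n_words")
  # feasible set of {x : sum x = 1, x binary} = the K unit vectors
  best <- NA_integer_
  for (i in seq_len(K)) {
    x <- integer(K); x[i] <- 1L
    val <- sum(x * obj)
    if (is.na(best) || val > obj[best] ||
        (val == obj[best] && nw[i] < nw[best])) {
      best <- i
    }
  }
  structure(list(candidates = candidates, chosen = best,
                 objective_value = obj[best]),
            class = "kias_selection")
}

# internal: score the candidates of one slice (I from textrank, Q from the LM)
score_slice_candidates <- function(slice, lm, wss_lookup, config) {
  graph <- build_word_graph(slice)
  importance <- textrank(graph, d = config$d, tol = config$textrank_tol,
                         max_iter = config$textrank_max_iter)
  cands <- enumerate_paths(graph, K = config$K, min_len = config$min_len,
                           require_token = "said")
  lapply(cands, function(p) {
    I <- path_informativeness(p$node_ids, importance)
    q <- linguistic_quality(p$words, lm, wss_fn = wss_lookup)
    nw <- length(p$words)
    list(words = p$words, node_ids = p$node_ids, cost = p$cost,
         I = I, Q = q$q, n_words = nw,
         combined = score_path(I, q$q, nw))
  })
}

#' Render a selected path as a summary sentence
#'
#' Splits the fused path back into display form at the template boundary
#' ("the participant said" / "participant said"):
#' "Participant was asked: X Participant said: Y". Paths without the boundary
#' render as a single line.
#'
#' @param words Character vector, the selected path's words.
#' @return Character scalar.
#' @export
render_sentence <- function(words) {
  txt <- paste(words, collapse = " ")
  m <- regexpr("(the )?participant said ", txt)
  lead <- sub("^participant was asked ", "", substr(txt, 1L, max(0L, m - 1L)))
  if (m > 0) {
    ans <- substr(txt, m + attr(m, "match.length"), nchar(txt))
    sprintf("Participant was asked: %s Participant said: %s",
            trimws(lead), trimws(ans))
  } else {
    txt
  }
}

#' Knowledge-infused abstractive summarization (KiAS)
#'
#' End-to-end pipeline: normalize and pair the transcript, template Q&A pairs
#' into statements, prune against the depression lexicon, slice into windows
#' of at most `window` pairs, and per slice build the word graph, run
#' TextRank, enumerate fusion paths, score informativeness I and
#' WSS-modulated linguistic quality Q, and select one path by the ILP.
#' Deterministic given fixed resources.
#'
#' @param transcript A `kias_transcript`, or a precomputed `kias_pruned` (the
#'   latter skips pruning; used to feed identical pruned conversations to
#'   several summarizers).
#' @param resources List with `lexicon` (`kias_lexicon`), `embeddings`
#'   (retrofitted `kias_embeddings`), `lm` (`kias_lm`).
#' @param config A [kias_config()] list.
#' @param use_wss Logical; FALSE drops the knowledge boost (WSS = 0
#'   everywhere), which is the plain abstractive baseline.
#' @return A `kias_summary`: list with `conversation_id`, `selections`,
#'   `sentences`, `status` ("ok", "no clinical content", or "no candidates").
#' @export
kias_summarize <- function(transcript, resources, config = kias_config(),
                           use_wss = TRUE) {
  pruned <- if (inherits(transcript, "kias_pruned")) {
    transcript
  } else {
    stmts <- statements_from_transcript(transcript, config$completion_map)
    prune_statements(stmts, resources$lexicon, resources$embeddings,
                     tau = config$tau, r = config$r,
                     conversation_id = transcript$conversation_id)
  }
  if (nrow(pruned$statements) == 0L) {
    return(structure(list(conversation_id = pruned$conversation_id,
                          selections = list(), sentences = character(),
                          status = "no clinical content"),
                     class = "kias_summary"))
  }
  slices <- slice_statements(pruned, window = config$window)
  vocab_all <- unique(unlist(lapply(pruned$statements$statement, tokenize_text)))
  wss_lookup <- if (use_wss) {
    wss_table(vocab_all, resources$embeddings, resources$lexicon)
  } else {
    stats::setNames(numeric(length(vocab_all)), vocab_all)
  }
  selections <- list()
  sentences <- character()
  for (sl in slices) {
    cands <- score_slice_candidates(sl, resources$lm, wss_lookup, config)
    sel <- solve_slice(cands)
    if (is.null(sel)) next
    sel$slice_index <- sl$slice_index
    selections[[length(selections) + 1L]] <- sel
    sentences <- c(sentences,
                   render_sentence(cands[[sel$chosen]]$words))
  }
  status <- if (length(selections) == length(slices)) "ok" else "no candidates"
  structure(list(conversation_id = pruned$conversation_id,
                 selections = selections, sentences = sentences,
                 status = status),
            class = "kias_summary")
}

#' @export
print.kias_summary <- function(x, ...) {
  cat(sprintf("<kias_summary> %s (%s): %d sentence(s)\n",
              x$conversation_id, x$status, length(x$sentences)))
  for (s in x$sentences) cat(" -", s, "\n")
  invisible(x)
}

#' Summary text as a single string
#' @param summary A `kias_summary`.
#' @return Character scalar, one sentence per line.
#' @export
summary_text <- function(summary) paste(summary$sentences, collapse = "\n")
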