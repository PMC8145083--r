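#' Prune non-informative statements with the depression lexicon
#'
#' A statement is kept iff some statement within context radius `r` of it
#' (including itself) carries at least one lexicon match. Matching runs on the
#' combined templated statement, so a clinically relevant question with a
#' bland answer is retained. Pairs with an empty answer are never counted as
#' matching (no clinical evidence) but can be kept as context. The kept,
#' order-preserved subset is the "pruned conversation" — also the reference
#' summary for evaluation.
#'
#' @param statements data.frame from [statements_from_transcript()].
#' @param lexicon A `kias_lexicon`.
#' @param embeddings Optional `kias_embeddings` for semantic matching.
#' @param tau Semantic-match threshold in (0, 1\].
#' @param r Context radius (non-negative integer); default 1 keeps the
#'   immediate neighbors of every match.
#' @param conversation_id Identifier carried on the result.
#' @return A `kias_pruned`: list with `conversation_id`, `statements` (kept
#'   rows), `matches` (data.frame of PhraseMatch rows), `kept_indices`
#'   (original pair indices).
#' @export
prune_statements <- function(statements, lexicon, embeddings = NULL,
                             tau = 0.6, r = 1L, conversation_id = "conv") {
  if (!(is.numeric(r) && length(r) == 1L && r >= 0)) {
    kias_abort("prune_statements: r must be >= 0")
  }
  n <- nrow(statements)
  out_empty <- structure(list(conversation_id = conversation_id,
                              statements = statements[0, , drop = FALSE],
                              matches = NULL, kept_indices = integer()),
                         class = "kias_pruned")
  if (is.null(statements) || n == 0L) return(out_empty)
  has_answer <- if ("has_answer" %in% names(statements)) {
    statements$has_answer
  } else rep(TRUE, n)
  match_list <- lapply(seq_len(n), function(i) {
    if (!has_answer[i]) return(NULL)  # empty answers carry no clinical evidence
    m <- match_statement(statements$statement[i], lexicon, embeddings, tau,
                         pair_index = statements$pair_index[i])
    if (nrow(m) == 0L) NULL else m
  })
  matched <- !vapply(match_list, is.null, logical(1L))
  keep <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - as.integer(r)); hi <- min(n, i + as.integer(r))
    any(matched[lo:hi])
  }, logical(1L))
  matches <- do.call(rbind, match_list[matched])
  structure(list(conversation_id = conversation_id,
                 statements = statements[keep, , drop = FALSE],
                 matches = matches,
                 kept_indices = statements$pair_index[keep]),
            class = "kias_pruned")
}

#' @export
print.kias_pruned <- function(x, ...) {
  cat(sprintf("<kias_pruned> %s: %d statements kept, %d lexicon matches\n",
              x$conversation_id, nrow(x$statements),
              if (is.null(x$matches)) 0L else nrow(x$matches)))
  invisible(x)
}

#' Partition a pruned conversation into fixed-window slices
#'
#' The n kept statements are divided into k = ceiling(n / window) slices with
#' sizes as even as possible (differing by at most one, larger slices first),
#' so no slice exceeds `window` Q&A pairs. 20 pairs at window 7 yield sizes
#' 7, 7, 6. Each slice later produces one summary sentence.
#'
#' @param pruned A `kias_pruned` (or a data.frame of statements).
#' @param window Maximum slice size, >= 1; default 7 Q&A pairs.
#' @return List of `kias_slice` objects: `list(slice_index, statements)`.
#' @export
slice_statements <- function(pruned, window = 7L) {
  if (!(is.numeric(window) && length(window) == 1L && window >= 1L)) {
    kias_abort("slice_statements: window must be >= 1")
  }
  stmts <- if (inherits(pruned, "kias_pruned")) pruned$statements else pruned
  n <- nrow(stmts)
  if (n == 0L) return(list())
  k <- ceiling(n / window)
  base <- n %/% k
  rem <- n %% k
  sizes <- c(rep(base + 1L, rem), rep(base, k - rem))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(j) {
    structure(list(slice_index = j - 1L,
                   statements = stmts[starts[j]:ends[j], , drop = FALSE]),
              class = "kias_slice")
  })
}

#' Serialize a pruned conversation to JSON
#' @param pruned A `kias_pruned`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_pruned <- function(pruned, path) {
  jsonlite::write_json(
    list(conversation_id = pruned$conversation_id,
         statements = pruned$statements$statement,
         kept_indices = pruned$kept_indices,
         matches = if (is.null(pruned$matches)) list() else pruned$matches),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
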