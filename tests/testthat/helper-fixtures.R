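# Shared fixtures and independent oracles, built in code at test time.

# deterministic manual embeddings: named list word -> vector
manual_embeddings <- function(vectors) {
  mat <- do.call(rbind, vectors)
  rownames(mat) <- names(vectors)
  kias:::new_embeddings(mat)
}

# a small transcript file on disk; rows = list of c(speaker, text)
write_tsv_transcript <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(start_time = seq_along(rows), stop_time = seq_along(rows) + 1,
                   speaker = vapply(rows, `[[`, character(1L), 1L),
                   value = vapply(rows, `[[`, character(1L), 2L),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# transcript object straight from speaker/text pairs
make_transcript <- function(rows, id = "fixture") {
  utt <- data.frame(
    speaker = vapply(rows, `[[`, character(1L), 1L),
    text = vapply(rows, `[[`, character(1L), 2L),
    turn_index = seq_along(rows) - 1L, stringsAsFactors = FALSE)
  kias:::new_transcript(id, utt)
}

# independent oracle: brute-force lexicon matcher (all ngrams x all phrases)
brute_force_matches <- function(statement, lexicon, embeddings, tau) {
  toks <- tokenize_text(statement)
  tab <- kias:::lexicon_phrase_table(lexicon)
  hits <- list()
  all_ng <- unique(unlist(lapply(1:3, function(n) {
    kias:::ngrams_from_tokens(toks, n)
  })))
  exact <- intersect(tab$phrase, all_ng)
  mean_vec <- function(p) {
    ws <- strsplit(p, " ", fixed = TRUE)[[1L]]
    content <- ws[!ws %in% kias_stopwords()]
    if (length(content) == 0L) content <- ws
    hit <- content[content %in% rownames(embeddings$vectors)]
    if (length(hit) == 0L) return(NULL)
    colMeans(embeddings$vectors[hit, , drop = FALSE])
  }
  sem <- character()
  for (ng in setdiff(unique(unlist(lapply(2:3, function(n)
           kias:::ngrams_from_tokens(toks, n)))), exact)) {
    v <- mean_vec(ng)
    if (is.null(v)) next
    for (i in seq_len(nrow(tab))) {
      pv <- mean_vec(tab$phrase[i])
      if (!is.null(pv) && cosine_similarity(v, pv) >= tau) {
        sem <- c(sem, ng); break
      }
    }
  }
  list(exact = sort(exact), semantic = sort(unique(sem)))
}

# independent oracle: TextRank fixed point by dense linear solve
# Imp = (1-d) 1 + d M Imp with M[i,j] = 1/outdeg(j) for edge j -> i
textrank_solve <- function(graph, d = 0.78) {
  ids <- graph$nodes$id
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  outdeg <- table(factor(graph$edges$from, levels = ids))
  for (k in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[k]; t <- graph$edges$to[k]
    M[t, f] <- 1 / outdeg[[f]]
  }
  imp <- solve(diag(n) - d * M, rep(1 - d, n))
  names(imp) <- ids
  imp[!(ids %in% c(graph$start, graph$end))]
}

# independent oracle: all simple START->END paths by recursive DFS,
# sorted by (total 1/count cost, lexicographic words)
all_simple_paths <- function(graph, min_len = 1L) {
  adj <- split(graph$edges$to, graph$edges$from)
  cost <- stats::setNames(1 / graph$edges$count,
                          paste(graph$edges$from, graph$edges$to))
  tok <- stats::setNames(graph$nodes$token, graph$nodes$id)
  out <- list()
  walk <- function(node, path, c_acc) {
    if (node == graph$end) {
      inner <- path
      words <- unname(tok[inner])
      if (length(words) >= min_len) {
        out[[length(out) + 1L]] <<- list(words = words, node_ids = inner,
                                         cost = c_acc)
      }
      return()
    }
    for (nb in adj[[node]]) {
      if (nb %in% path) next
      walk(nb, c(path, if (nb != graph$end) nb), c_acc + cost[[paste(node, nb)]])
    }
  }
  walk(graph$start, character(), 0)
  key <- vapply(out, function(p) paste(p$words, collapse = " "), character(1L))
  out[order(vapply(out, `[[`, numeric(1L), "cost"), key)]
}

# independent oracle: direct argmax with the stated tie-breaks
argmax_selection <- function(combined, n_words) {
  best <- order(-combined, n_words, seq_along(combined))[1L]
  best
}

# standard synthetic study resources for one seed
study_resources <- function(seed, n_pairs = 58L, clinical_rate = 0.3) {
  lex <- make_toy_lexicon()
  tr <- generate_interview(gen_config(seed = seed, n_pairs = n_pairs,
                                      clinical_rate = clinical_rate), lex)
  stmts <- statements_from_transcript(tr)
  vocab <- unique(unlist(lapply(stmts$statement, tokenize_text)))
  emb <- make_embeddings(vocab, lexicon = lex, seed = seed)
  emb_r <- retrofit_embeddings(emb, build_lexicon_graph(lex))
  lm <- make_toy_lm(stmts$statement)
  pruned <- prune_statements(stmts, lex, emb,
                             conversation_id = tr$conversation_id)
  list(transcript = tr, statements = stmts, lexicon = lex,
       embeddings = emb, embeddings_retrofitted = emb_r, lm = lm,
       pruned = pruned,
       ground_truth = attr(tr, "ground_truth"),
       resources = list(lexicon = lex, embeddings = emb_r, lm = lm))
}

# does a selected path carry a planted clinical phrase?
selection_hits <- function(summary, planted_phrases) {
  vapply(summary$selections, function(sel) {
    w <- paste(sel$candidates[[sel$chosen]]$words, collapse = " ")
    any(vapply(planted_phrases, function(p) grepl(p, w, fixed = TRUE),
               logical(1L)))
  }, logical(1L))
}
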