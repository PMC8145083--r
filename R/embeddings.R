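#' Read word embeddings (word2vec text dialect)
#'
#' Each line holds a word followed by D floats; an optional `n_words dim`
#' header line is auto-detected. Lookup of an absent word is an explicit miss
#' (NULL), never a silent zero vector.
#'
#' @param path Embedding text file.
#' @return A `kias_embeddings`: list with `dimension` and `vectors` (numeric
#'   matrix, one row per word, rownames = words).
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) kias_abort(sprintf("embedding file not found: %s", path),
                                     "kias_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1L]  # count header
  }
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[[`, character(1L), 1L)
  vecs <- lapply(parts, function(p) as.numeric(p[-1L]))
  dims <- lengths(vecs)
  if (length(unique(dims)) != 1L) {
    kias_abort("embedding file has inconsistent vector dimensions",
               "kias_structure_error")
  }
  mat <- do.call(rbind, vecs)
  rownames(mat) <- words
  new_embeddings(mat)
}

new_embeddings <- function(mat) {
  structure(list(dimension = ncol(mat), vectors = mat),
            class = "kias_embeddings")
}

#' Write embeddings in word2vec text format
#' @param embeddings A `kias_embeddings`.
#' @param path Output path.
#' @param header Write the `n_words dim` count header line?
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path, header = TRUE) {
  m <- embeddings$vectors
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE,
                                   digits = 17)), collapse = " ")
  }, character(1L))
  if (header) body <- c(paste(nrow(m), ncol(m)), body)
  writeLines(body, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.kias_embeddings <- function(x, ...) {
  cat(sprintf("<kias_embeddings> %d words x %d dimensions\n",
              nrow(x$vectors), x$dimension))
  invisible(x)
}

# internal: matrix of vectors for the in-vocabulary subset of `words`
# (NULL when none are present)
embedding_lookup <- function(embeddings, words) {
  hit <- words[words %in% rownames(embeddings$vectors)]
  if (length(hit) == 0L) return(NULL)
  embeddings$vectors[hit, , drop = FALSE]
}

#' Cosine similarity of two vectors
#' @param u,v Numeric vectors of equal length; both must be nonzero.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) kias_abort("cosine: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) kias_abort("cosine: zero vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' Build the lexicon word graph used for retrofitting
#'
#' Undirected graph over lexicon words: an edge joins two distinct words that
#' co-occur in one phrase, or that are head words (first token) of phrases in
#' the same category. No self-loops.
#'
#' @param lexicon A `kias_lexicon`.
#' @return A `kias_lexicon_graph`: list with `nodes`, `edges` (two-column
#'   character matrix), and `degree` (named integer vector).
#' @export
build_lexicon_graph <- function(lexicon) {
  stopifnot(inherits(lexicon, "kias_lexicon"))
  edges <- list()
  add_clique <- function(words) {
    words <- unique(words)
    if (length(words) < 2L) return()
    cmb <- utils::combn(sort(words), 2L)
    for (k in seq_len(ncol(cmb))) {
      edges[[length(edges) + 1L]] <<- cmb[, k]
    }
  }
  for (cid in names(lexicon$categories)) {
    phrases <- lexicon$categories[[cid]]$phrases
    heads <- character()
    for (p in phrases) {
      ws <- strsplit(p, " ", fixed = TRUE)[[1L]]
      add_clique(ws)
      heads <- c(heads, ws[1L])
    }
    add_clique(heads)
  }
  nodes <- lexicon$vocabulary
  if (length(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- unique(do.call(rbind, edges))
  }
  deg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(em))) {
    deg[em[i, 1L]] <- deg[em[i, 1L]] + 1L
    deg[em[i, 2L]] <- deg[em[i, 2L]] + 1L
  }
  structure(list(nodes = nodes, edges = em, degree = deg),
            class = "kias_lexicon_graph")
}

#' Retrofit embeddings to the lexicon graph
#'
#' Synchronous (Jacobi) retrofitting: each round updates every graph word as
#' q_i <- (alpha * q_i_original + sum_j beta_ij * q_j) / (alpha + sum_j beta_ij)
#' over its graph neighbors j, pulling lexicon-linked words together while
#' alpha anchors them to their original vectors. Words outside the graph (or
#' missing from the store) are untouched. Deterministic.
#'
#' @param embeddings A `kias_embeddings`.
#' @param graph A `kias_lexicon_graph`.
#' @param alpha Attachment weight to the original vector (> 0).
#' @param beta Per-edge weight rule: "inverse_degree" (beta_ij = 1/degree(i),
#'   the standard recipe) or "uniform" (beta_ij = 1).
#' @param iterations Number of Jacobi rounds, >= 1.
#' @return Retrofitted `kias_embeddings`.
#' @export
retrofit_embeddings <- function(embeddings, graph, alpha = 1,
                                beta = c("inverse_degree", "uniform"),
                                iterations = 10L) {
  beta <- match.arg(beta)
  if (!(is.numeric(iterations) && iterations >= 1L)) {
    kias_abort("retrofit: iterations must be >= 1")
  }
  if (!(is.numeric(alpha) && alpha > 0)) kias_abort("retrofit: alpha must be > 0")
  vocab <- rownames(embeddings$vectors)
  nodes <- intersect(graph$nodes, vocab)
  missing <- setdiff(graph$nodes, vocab)
  if (length(missing) > 0L) {
    message(sprintf("retrofit: %d lexicon word(s) absent from embeddings, skipped",
                    length(missing)))
  }
  if (nrow(graph$edges) == 0L || length(nodes) == 0L) {
    warning("retrofit: empty lexicon graph, embeddings returned unchanged")
    return(embeddings)
  }
  nbrs <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges[i, 1L]; b <- graph$edges[i, 2L]
    if (a %in% nodes && b %in% nodes) {
      nbrs[[a]] <- c(nbrs[[a]], b)
      nbrs[[b]] <- c(nbrs[[b]], a)
    }
  }
  orig <- embeddings$vectors
  cur <- orig
  for (it in seq_len(iterations)) {
    nxt <- cur
    for (w in nodes) {
      nb <- nbrs[[w]]
      if (length(nb) == 0L) next
      b_w <- if (beta == "inverse_degree") 1 / length(nb) else 1
      nb_sum <- colSums(cur[nb, , drop = FALSE]) * b_w
      nxt[w, ] <- (alpha * orig[w, ] + nb_sum) / (alpha + b_w * length(nb))
    }
    cur <- nxt
  }
  new_embeddings(cur)
}

#' Word Semantic Score (WSS)
#'
#' Maximum cosine similarity of a word's vector with any word of the
#' depression lexicon, clamped to \[0, 1\]; out-of-vocabulary words score 0.
#' Computed on retrofitted embeddings, WSS quantifies how close a word is to
#' clinical depression language and multiplicatively boosts language-model
#' probabilities in the linguistic-quality score.
#'
#' @param word Character scalar.
#' @param embeddings A `kias_embeddings` (typically retrofitted).
#' @param lexicon A `kias_lexicon`.
#' @return WSS in \[0, 1\].
#' @export
wss <- function(word, embeddings, lexicon) {
  stopifnot(inherits(lexicon, "kias_lexicon"))
  if (length(lexicon$vocabulary) == 0L) kias_abort("wss: empty lexicon")
  v <- embedding_lookup(embeddings, word)
  if (is.null(v)) return(0)
  lex <- embedding_lookup(embeddings, lexicon$vocabulary)
  if (is.null(lex)) return(0)
  v <- as.numeric(v[1L, ])
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  norms <- sqrt(rowSums(lex^2))
  ok <- norms > 0
  if (!any(ok)) return(0)
  sims <- (lex[ok, , drop = FALSE] %*% v) / (norms[ok] * nv)
  max(0, min(1, max(sims)))
}

#' Vectorized WSS lookup table
#'
#' Precomputes [wss()] for a set of words (the hot path when scoring many
#' candidate paths).
#'
#' @param words Character vector.
#' @inheritParams wss
#' @return Named numeric vector of WSS values (0 for OOV words).
#' @export
wss_table <- function(words, embeddings, lexicon) {
  words <- unique(words)
  lex <- embedding_lookup(embeddings, lexicon$vocabulary)
  out <- stats::setNames(numeric(length(words)), words)
  if (is.null(lex)) return(out)
  lex_norm <- sqrt(rowSums(lex^2))
  keep <- lex_norm > 0
  lex <- lex[keep, , drop = FALSE]; lex_norm <- lex_norm[keep]
  hit <- words[words %in% rownames(embeddings$vectors)]
  if (length(hit) == 0L || nrow(lex) == 0L) return(out)
  m <- embeddings$vectors[hit, , drop = FALSE]
  m_norm <- sqrt(rowSums(m^2))
  ok <- m_norm > 0
  if (any(ok)) {
    sims <- (m[ok, , drop = FALSE] %*% t(lex)) / outer(m_norm[ok], lex_norm)
    out[hit[ok]] <- pmax(0, pmin(1, apply(sims, 1L, max)))
  }
  out
}
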