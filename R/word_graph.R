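#' Build the per-slice word graph
#'
#' Every statement of the slice is added as a chain START -> w1 -> ... -> wk
#' -> END over its tokens. Content words (non-stopwords) with the same
#' lowercase form merge into a single node, which is what lets paths fuse
#' across statements; stopword tokens merge into an existing stopword node
#' only when both its left and right neighbors already coincide with the
#' incoming context (a guard against collapsing unrelated function words).
#' Edge traversal counts accumulate.
#'
#' Template scaffold words ("participant", "asked", "said") occur in every
#' templated statement by construction and carry no content, so they are
#' merged under the same guard as stopwords; otherwise the two "participant"
#' occurrences per statement would fuse into hub nodes and open degenerate
#' START -> participant -> said -> ... shortcuts that skip the question.
#'
#' @param slice A `kias_slice`, or a character vector of statements.
#' @param stopwords Character vector of guarded-merge tokens (default
#'   [kias_stopwords()] plus the template scaffold words).
#' @return A `kias_word_graph`: list with `nodes` (data.frame id/token/
#'   is_stopword), `edges` (data.frame from/to/count), `start`, `end`.
#' @export
build_word_graph <- function(slice,
                             stopwords = c(kias_stopwords(),
                                           "participant", "asked", "said")) {
  stmts <- if (inherits(slice, "kias_slice")) slice$statements$statement
           else as.character(slice)
  if (length(stmts) == 0L) kias_abort("build_word_graph: empty slice")
  START <- "__START__"; END <- "__END__"
  tokens <- stats::setNames(c("", ""), c(START, END))
  is_stop <- stats::setNames(c(FALSE, FALSE), c(START, END))
  edges <- new.env(parent = emptyenv())
  stop_counter <- new.env(parent = emptyenv())

  ekey <- function(a, b) paste(a, b, sep = "\x1f")
  has_edge <- function(a, b) !is.null(edges[[ekey(a, b)]])
  add_edge <- function(a, b) {
    k <- ekey(a, b)
    edges[[k]] <- (edges[[k]] %||% 0L) + 1L
  }
  # does node `id` have an out-edge to some node whose token is `form`?
  out_to_form <- function(id, form) {
    for (k in ls(edges)) {
      ab <- strsplit(k, "\x1f", fixed = TRUE)[[1L]]
      if (ab[1L] == id && tokens[[ab[2L]]] == form) return(TRUE)
    }
    FALSE
  }

  for (s in stmts) {
    toks <- tokenize_text(s)
    if (length(toks) == 0L) next
    prev <- START
    used <- character()  # a statement maps at most one token to any node,
                         # so each statement stays a simple START->END walk
    for (t in seq_along(toks)) {
      tok <- toks[t]
      nxt_form <- if (t < length(toks)) toks[t + 1L] else ""
      if (!tok %in% stopwords) {
        cand <- setdiff(names(tokens)[tokens == tok & !is_stop[names(tokens)]],
                        used)
        if (length(cand) > 0L) {
          id <- cand[1L]
        } else {
          n_same <- sum(tokens == tok & !is_stop[names(tokens)])
          id <- if (n_same == 0L) tok else paste0(tok, "#rep", n_same)
          tokens[[id]] <- tok; is_stop[[id]] <- FALSE
        }
      } else {
        cand <- setdiff(names(tokens)[tokens == tok & is_stop[names(tokens)]],
                        used)
        id <- NULL
        for (c_id in cand) {
          if (has_edge(prev, c_id) && out_to_form(c_id, nxt_form)) {
            id <- c_id; break
          }
        }
        if (is.null(id)) {
          n_prev <- stop_counter[[tok]] %||% 0L
          stop_counter[[tok]] <- n_prev + 1L
          id <- paste0(tok, "#", n_prev + 1L)
          tokens[[id]] <- tok; is_stop[[id]] <- TRUE
        }
      }
      used <- c(used, id)
      add_edge(prev, id)
      prev <- id
    }
    add_edge(prev, END)
  }
  ekeys <- ls(edges)
  em <- do.call(rbind, strsplit(ekeys, "\x1f", fixed = TRUE))
  edf <- data.frame(from = em[, 1L], to = em[, 2L],
                    count = vapply(ekeys, function(k) edges[[k]], integer(1L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  ndf <- data.frame(id = names(tokens), token = unname(tokens),
                    is_stopword = unname(is_stop[names(tokens)]),
                    stringsAsFactors = FALSE)
  structure(list(nodes = ndf, edges = edf, start = START, end = END),
            class = "kias_word_graph")
}

#' @export
print.kias_word_graph <- function(x, ...) {
  cat(sprintf("<kias_word_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' TextRank word importance
#'
#' Iterates Imp(v_i) = (1 - d) + d * sum over in-neighbors v_j of
#' Imp(v_j) / outdeg(v_j), from an all-ones start, until the maximum change
#' drops below `tol` or `max_iter` rounds. Edges are unweighted inside the
#' iteration (traversal counts only rank paths). The damping factor defaults
#' to 0.78. Dummy START/END nodes take part in propagation but are excluded
#' from the returned map.
#'
#' @param graph A `kias_word_graph`.
#' @param d Damping factor in (0, 1).
#' @param tol Convergence tolerance on the max absolute change.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with a warning and `converged = FALSE` attribute.
#' @return Named numeric vector of importance scores per non-dummy node id,
#'   with attribute `converged`.
#' @export
textrank <- function(graph, d = 0.78, tol = 1e-6, max_iter = 100L) {
  if (!(is.numeric(d) && d > 0 && d < 1)) kias_abort("textrank: d must be in (0,1)")
  ids <- graph$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  # unique directed adjacency (counts ignored)
  from_i <- idx[graph$edges$from]; to_i <- idx[graph$edges$to]
  outdeg <- tabulate(from_i, nbins = n)
  in_list <- split(from_i, to_i)
  imp <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    contrib <- ifelse(outdeg > 0, imp / outdeg, 0)
    new_imp <- rep(1 - d, n)
    for (key in names(in_list)) {
      i <- as.integer(key)
      new_imp[i] <- (1 - d) + d * sum(contrib[in_list[[key]]])
    }
    delta <- max(abs(new_imp - imp))
    imp <- new_imp
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("textrank: not converged at max_iter")
  keep <- !(ids %in% c(graph$start, graph$end))
  structure(stats::setNames(imp[keep], ids[keep]), converged = converged)
}

#' Informativeness of a path
#'
#' Sum of the TextRank importance of the path's words (dummy nodes excluded).
#'
#' @param node_ids Character vector of node ids along the path (dummies
#'   allowed; they are dropped).
#' @param importance Named vector from [textrank()].
#' @return Non-negative informativeness score.
#' @export
path_informativeness <- function(node_ids, importance) {
  ids <- node_ids[!node_ids %in% c("__START__", "__END__")]
  if (length(ids) == 0L) return(0)
  if (!all(ids %in% names(importance))) {
    kias_abort("path_informativeness: unscored word on path")
  }
  sum(importance[ids])
}

#' Enumerate candidate fusion paths
#'
#' Finds up to K distinct simple START -> END paths ranked by ascending total
#' edge cost with cost(e) = 1 / traversal_count(e), so frequently traversed
#' fusions are cheap. Paths with fewer than `min_len` words are discarded.
#' Ordering is deterministic: ties in cost break lexicographically on the
#' word sequence.
#'
#' @param graph A `kias_word_graph`.
#' @param K Maximum number of paths, >= 1.
#' @param min_len Minimum path length in words (dummies excluded).
#' @param require_token Optional token that must occur on the path before its
#'   last word. The summarization pipeline passes the template verb "said" so
#'   every candidate carries an answer segment (the analog of the classic
#'   fusion constraint that a compressed sentence must contain a verb);
#'   NULL disables the filter.
#' @return List of unscored candidates: each `list(words, node_ids, cost)`.
#' @export
enumerate_paths <- function(graph, K = 100L, min_len = 8L,
                            require_token = NULL) {
  if (!(is.numeric(K) && K >= 1L)) kias_abort("enumerate_paths: K must be >= 1")
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = graph$nodes$id)
  w <- 1 / graph$edges$count
  ks <- igraph::k_shortest_paths(g, from = graph$start, to = graph$end,
                                 k = as.integer(K), weights = w)
  tok <- stats::setNames(graph$nodes$token, graph$nodes$id)
  cost_of <- function(ids) {
    key <- paste(ids[-length(ids)], ids[-1L], sep = "\x1f")
    ekey <- paste(graph$edges$from, graph$edges$to, sep = "\x1f")
    sum((1 / graph$edges$count)[match(key, ekey)])
  }
  cands <- lapply(ks$vpaths, function(vp) {
    ids <- names(vp)
    inner <- ids[!(ids %in% c(graph$start, graph$end))]
    list(words = unname(tok[inner]), node_ids = inner, cost = cost_of(ids))
  })
  cands <- Filter(function(p) length(p$words) >= min_len, cands)
  if (!is.null(require_token)) {
    cands <- Filter(function(p) {
      hit <- which(p$words == require_token)
      length(hit) > 0L && min(hit) < length(p$words)
    }, cands)
  }
  if (length(cands) == 0L) return(list())
  word_key <- vapply(cands, function(p) paste(p$words, collapse = " "),
                     character(1L))
  ord <- order(vapply(cands, `[[`, numeric(1L), "cost"), word_key)
  cands[ord]
}

#' Dump a word graph as an edge list or DOT file
#' @param graph A `kias_word_graph`.
#' @param path Output path.
#' @param format "edgelist" (tab-separated from/to/count) or "dot".
#' @return `path`, invisibly.
#' @export
write_word_graph <- function(graph, path, format = c("edgelist", "dot")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("digraph wordgraph {",
               sprintf('  "%s" -> "%s" [label=%d];',
                       graph$edges$from, graph$edges$to, graph$edges$count),
               "}")
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
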