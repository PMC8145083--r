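#' Load a PHQ-9-style depression lexicon
#'
#' The lexicon maps PHQ-9 signal categories S1..S9 (decreased pleasure,
#' feeling down, sleep disorders, loss of energy, appetite change, feeling
#' worthless, concentration problems, psychomotor change, suicidal thoughts)
#' to indicative phrases. Accepts CSV (`category,phrase`, header optional in
#' content but expected as first line) or JSON (`{"S3": ["trouble sleeping"]}`
#' or `{"S3": {"label": ..., "phrases": [...]}}`).
#'
#' @param path CSV or JSON lexicon file.
#' @return A `kias_lexicon`: list with `categories` (named list of
#'   `list(label, phrases)`) and `vocabulary` (all words in phrases).
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) kias_abort(sprintf("lexicon file not found: %s", path),
                                     "kias_io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    cats <- lapply(raw, function(x) {
      if (is.list(x) && !is.null(x$phrases)) {
        list(label = x$label %||% NA_character_,
             phrases = as.character(x$phrases))
      } else {
        list(label = NA_character_, phrases = as.character(unlist(x)))
      }
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("category", "phrase") %in% names(df))) {
      kias_abort(sprintf("lexicon CSV %s needs columns category,phrase", path),
                 "kias_structure_error")
    }
    cats <- lapply(split(df$phrase, df$category), function(p) {
      list(label = NA_character_, phrases = p)
    })
  }
  new_lexicon(cats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phq9_category_ids <- paste0("S", 1:9)

new_lexicon <- function(categories) {
  bad <- setdiff(names(categories), phq9_category_ids)
  if (length(bad) > 0L) {
    kias_abort(sprintf("unknown lexicon categories (only S1..S9 allowed): %s",
                       paste(bad, collapse = ", ")), "kias_validation_error")
  }
  categories <- lapply(categories, function(x) {
    ph <- unique(trimws(tolower(x$phrases)))
    ph <- ph[nzchar(ph)]
    list(label = x$label, phrases = ph)
  })
  if (length(categories) < 9L) {
    message(sprintf("lexicon has %d of 9 PHQ-9 categories (toy lexicon?)",
                    length(categories)))
  }
  vocab <- unique(unlist(lapply(categories,
                                function(x) unlist(strsplit(x$phrases, " ")))))
  structure(list(categories = categories, vocabulary = vocab),
            class = "kias_lexicon")
}

#' @export
print.kias_lexicon <- function(x, ...) {
  n_ph <- sum(vapply(x$categories, function(c) length(c$phrases), integer(1L)))
  cat(sprintf("<kias_lexicon> %d categories, %d phrases, %d vocabulary words\n",
              length(x$categories), n_ph, length(x$vocabulary)))
  invisible(x)
}

# internal: all (phrase, category) rows
lexicon_phrase_table <- function(lexicon) {
  rows <- lapply(names(lexicon$categories), function(cid) {
    ph <- lexicon$categories[[cid]]$phrases
    if (length(ph) == 0L) return(NULL)
    data.frame(category = cid, phrase = ph, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract contiguous n-grams
#'
#' @param text Character scalar (tokenized with the shared tokenizer).
#' @param n n-gram order, >= 1.
#' @return Character vector of space-joined n-grams in order; empty when the
#'   text has fewer than `n` tokens.
#' @export
#' @examples
#' extract_ngrams("i feel very tired", 2)
extract_ngrams <- function(text, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    kias_abort("extract_ngrams: n must be >= 1")
  }
  ngrams_from_tokens(tokenize_text(text), as.integer(n))
}

#' Normalized pointwise mutual information of an n-gram
#'
#' NPMI (Bouma) = pmi / (-log p(ngram)) with
#' pmi = log( p(ngram) / prod_i p(w_i) ), natural log. Used to rank n-gram
#' quality (the trigram-over-bigram choice for the language model). The
#' degenerate p(ngram) = 1 returns 1 by continuity.
#'
#' @param ngram Space-joined n-gram.
#' @param counts List with `unigrams` (named counts), `ngrams` (named counts of
#'   the n-gram order being scored), `n_tokens` (total tokens), `n_ngrams`
#'   (total n-gram windows).
#' @return NPMI in \[-1, 1\].
#' @export
npmi <- function(ngram, counts) {
  words <- strsplit(ngram, " ", fixed = TRUE)[[1L]]
  c_ng <- if (ngram %in% names(counts$ngrams)) counts$ngrams[[ngram]] else 0
  if (is.na(c_ng) || c_ng <= 0) {
    kias_abort(sprintf("npmi: zero-count ngram '%s'", ngram))
  }
  c_w <- vapply(words, function(w) {
    cw <- if (w %in% names(counts$unigrams)) counts$unigrams[[w]] else 0
    if (is.na(cw) || cw <= 0) {
      kias_abort(sprintf("npmi: zero-count word '%s'", w))
    }
    cw
  }, numeric(1L))
  p_ng <- c_ng / counts$n_ngrams
  p_w <- c_w / counts$n_tokens
  if (p_ng >= 1) return(1)
  pmi <- log(p_ng / prod(p_w))
  pmax(-1, pmin(1, pmi / (-log(p_ng))))
}

#' Match a statement against the depression lexicon
#'
#' Exact matches are lexicon phrases occurring as contiguous token
#' subsequences of the statement. Semantic matches are statement bigrams and
#' trigrams whose mean word vector has cosine similarity at least `tau` with
#' the mean word vector of some lexicon phrase; each matched n-gram is
#' reported once with its best-scoring lexicon phrase. Phrase vectors are
#' unweighted means over in-vocabulary words; all-OOV phrases cannot match
#' semantically.
#'
#' @param statement Character scalar (a templated statement or any text).
#' @param lexicon A `kias_lexicon`.
#' @param embeddings A `kias_embeddings` (see [read_embeddings()]), or NULL to
#'   restrict matching to exact containment.
#' @param tau Semantic threshold in (0, 1\].
#' @param pair_index Optional index recorded on the matches.
#' @return data.frame with columns `pair_index`, `matched_ngram`,
#'   `lexicon_phrase`, `category`, `kind` ("exact"/"semantic"), `score`.
#' @export
match_statement <- function(statement, lexicon, embeddings = NULL, tau = 0.6,
                            pair_index = NA_integer_) {
  stopifnot(inherits(lexicon, "kias_lexicon"))
  if (!(is.numeric(tau) && tau > 0 && tau <= 1)) {
    kias_abort("match_statement: tau must be in (0, 1]")
  }
  toks <- tokenize_text(statement)
  tab <- lexicon_phrase_table(lexicon)
  empty <- data.frame(pair_index = integer(), matched_ngram = character(),
                      lexicon_phrase = character(), category = character(),
                      kind = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(toks) == 0L || is.null(tab)) return(empty)

  out <- list()
  stmt_ng <- unlist(lapply(1:3, function(n) ngrams_from_tokens(toks, n)))
  # exact containment: phrase appears as a contiguous token window
  for (i in seq_len(nrow(tab))) {
    if (tab$phrase[i] %in% stmt_ng) {
      out[[length(out) + 1L]] <- data.frame(
        pair_index = pair_index, matched_ngram = tab$phrase[i],
        lexicon_phrase = tab$phrase[i], category = tab$category[i],
        kind = "exact", score = 1, stringsAsFactors = FALSE)
    }
  }
  exact_ngrams <- vapply(out, function(r) r$matched_ngram, character(1L))

  if (!is.null(embeddings)) {
    cand <- unique(unlist(lapply(2:3, function(n) ngrams_from_tokens(toks, n))))
    cand <- setdiff(cand, exact_ngrams)
    if (length(cand) > 0L) {
      ph_vec <- phrase_vectors(tab$phrase, embeddings)
      cd_vec <- phrase_vectors(cand, embeddings)
      ok_ph <- !vapply(ph_vec, is.null, logical(1L))
      for (j in seq_along(cand)) {
        v <- cd_vec[[j]]
        if (is.null(v)) next
        best <- -Inf; best_i <- NA_integer_
        for (i in which(ok_ph)) {
          s <- cosine_similarity(v, ph_vec[[i]])
          if (s > best) { best <- s; best_i <- i }
        }
        if (!is.na(best_i) && best >= tau) {
          out[[length(out) + 1L]] <- data.frame(
            pair_index = pair_index, matched_ngram = cand[j],
            lexicon_phrase = tab$phrase[best_i],
            category = tab$category[best_i],
            kind = "semantic", score = min(1, best), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# internal: mean in-vocabulary word vector per phrase (NULL when all OOV).
# Function words dilute short phrase vectors into noise, so the mean is taken
# over content words; all-stopword phrases fall back to the full word set.
phrase_vectors <- function(phrases, embeddings) {
  stops <- kias_stopwords()
  lapply(phrases, function(p) {
    ws <- strsplit(p, " ", fixed = TRUE)[[1L]]
    content <- ws[!ws %in% stops]
    if (length(content) == 0L) content <- ws
    vs <- embedding_lookup(embeddings, content)
    if (is.null(vs)) NULL else colMeans(vs)
  })
}
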