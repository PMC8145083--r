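#' Flesch Reading Ease
#'
#' FRE = 206.835 - 1.015 * (words / sentences) - 84.6 * (syllables / words).
#' Sentences are lines when the text is multi-line (the templated summary
#' form), otherwise runs split on `.`, `!`, `?`. Syllables come from a
#' deterministic vowel-group heuristic with a silent-e correction, so scores
#' are reproducible bit for bit.
#'
#' @param text Character scalar with at least one word.
#' @return FRE score (higher = easier to read).
#' @export
flesch_reading_ease <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  sentences <- if (length(lines) > 1L) {
    lines
  } else {
    s <- strsplit(text, "[.!?]+")[[1L]]
    s[nzchar(trimws(s))]
  }
  n_sent <- max(1L, length(sentences))
  words <- tokenize_text(text)
  if (length(words) == 0L) kias_abort("flesch_reading_ease: no words in text")
  syl <- sum(vapply(words, count_syllables, numeric(1L)))
  206.835 - 1.015 * (length(words) / n_sent) - 84.6 * (syl / length(words))
}

# internal: vowel-group syllable heuristic with silent-e correction
count_syllables <- function(word) {
  w <- gsub("[^a-z]", "", tolower(word))
  if (!nzchar(w)) return(0)
  groups <- gregexpr("[aeiouy]+", w)[[1L]]
  n <- if (groups[1L] == -1L) 0L else length(groups)
  if (n > 1L && grepl("e$", w) && !grepl("le$", w)) n <- n - 1L
  max(1L, n)
}

#' Jensen-Shannon divergence (base 2)
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2 and log base 2,
#' bounded in \[0, 1\]; 0 for identical distributions, 1 for disjoint
#' supports.
#'
#' @param p,q Probability vectors of equal length, each summing to 1
#'   (tolerance 1e-6).
#' @return JSD in \[0, 1\].
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) kias_abort("jsd: length mismatch")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    kias_abort("jsd: inputs must sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  max(0, min(1, kl(p, m) / 2 + kl(q, m) / 2))
}

#' Contextual similarity of two texts
#'
#' Cosine of the unweighted mean word vectors (bag of words; word order is
#' irrelevant). Computed on retrofitted embeddings between generated and
#' reference summaries.
#'
#' @param summary,reference Texts.
#' @param embeddings A `kias_embeddings`.
#' @return Cosine in \[-1, 1\], or NA when either text has no in-vocabulary
#'   word.
#' @export
contextual_similarity <- function(summary, reference, embeddings) {
  mv <- function(text) {
    vs <- embedding_lookup(embeddings, tokenize_text(text))
    if (is.null(vs)) NULL else colMeans(vs)
  }
  u <- mv(summary); v <- mv(reference)
  if (is.null(u) || is.null(v)) return(NA_real_)
  cosine_similarity(u, v)
}

#' ROUGE-1 / ROUGE-2 / ROUGE-L
#'
#' ROUGE-1/2 use clipped n-gram overlap; ROUGE-L uses the longest common
#' subsequence. Tokenization is the shared normalizer; no stemming or
#' stopword removal.
#'
#' @param candidate,reference Non-empty texts.
#' @param variant "1", "2", or "L".
#' @return List with `recall`, `precision`, `f1`.
#' @export
rouge <- function(candidate, reference, variant = c("1", "2", "L")) {
  variant <- match.arg(as.character(variant), c("1", "2", "L"))
  ct <- tokenize_text(candidate); rt <- tokenize_text(reference)
  if (length(rt) == 0L) kias_abort("rouge: empty reference")
  if (length(ct) == 0L) return(list(recall = 0, precision = 0, f1 = 0))
  if (variant %in% c("1", "2")) {
    n <- as.integer(variant)
    cg <- ngrams_from_tokens(ct, n); rg <- ngrams_from_tokens(rt, n)
    if (length(rg) == 0L) kias_abort("rouge: reference shorter than n")
    if (length(cg) == 0L) return(list(recall = 0, precision = 0, f1 = 0))
    ctab <- table(cg); rtab <- table(rg)
    common <- intersect(names(ctab), names(rtab))
    hits <- sum(pmin(ctab[common], rtab[common]))
    rec <- hits / length(rg); prec <- hits / length(cg)
  } else {
    l <- lcs_length(ct, rt)
    rec <- l / length(rt); prec <- l / length(ct)
  }
  f1 <- if (rec + prec == 0) 0 else 2 * rec * prec / (rec + prec)
  list(recall = rec, precision = prec, f1 = f1)
}

# internal: longest common subsequence length (dynamic programming)
lcs_length <- function(a, b) {
  na <- length(a); nb <- length(b)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' Fit an LDA topic model with coherence-based selection of k
#'
#' Fits a collapsed-Gibbs LDA per candidate number of topics and returns the
#' model with the highest C_V-style coherence (sliding-window NPMI context
#' vectors of each topic's top terms, compared by cosine). Stopwords are
#' removed before fitting. Reproducible given `seed`.
#'
#' @param reference_corpus Character vector of documents.
#' @param k_range Integer vector of candidate topic counts.
#' @param seed Integer seed.
#' @param n_iter Gibbs iterations per model.
#' @param alpha,beta Dirichlet hyperparameters.
#' @param top_n Top terms per topic used by the coherence score.
#' @param coherence_window Sliding co-occurrence window size.
#' @return A `kias_topic_model`: `n_topics`, `phi` (topics x vocab, rows sum
#'   to 1), `vocab`, `alpha`, `coherence`, `coherence_by_k`.
#' @export
fit_topic_model <- function(reference_corpus, k_range = seq(2L, 20L, by = 2L),
                            seed = 1L, n_iter = 150L, alpha = 0.1, beta = 0.01,
                            top_n = 10L, coherence_window = 10L) {
  docs <- lapply(reference_corpus, function(d) {
    t <- tokenize_text(d)
    t[!t %in% kias_stopwords()]
  })
  docs <- Filter(length, docs)
  if (length(docs) < 1L) kias_abort("fit_topic_model: empty corpus")
  if (length(unique(vapply(docs, paste, character(1L), collapse = " "))) == 1L &&
      length(docs) > 1L) {
    warning("fit_topic_model: degenerate corpus (all documents identical)")
    k_range <- min(k_range)
  }
  vocab <- sort(unique(unlist(docs)))
  widx <- stats::setNames(seq_along(vocab) - 1L, vocab)
  doc_id <- rep(seq_along(docs) - 1L, lengths(docs))
  word_id <- unname(widx[unlist(docs)])
  co <- cooccurrence_windows(docs, coherence_window)
  fits <- list()
  coh <- stats::setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    res <- gibbs_lda_cpp(doc_id, word_id, length(docs), length(vocab),
                         as.integer(k), alpha, beta, as.integer(n_iter))
    phi <- (res$nkw + beta) / (res$nk + length(vocab) * beta)
    colnames(phi) <- vocab
    coh[i] <- cv_coherence(phi, co, top_n)
    fits[[i]] <- phi
  }
  best <- which.max(coh)
  structure(list(n_topics = as.integer(k_range[best]), phi = fits[[best]],
                 vocab = vocab, alpha = alpha,
                 coherence = unname(coh[best]), coherence_by_k = coh),
            class = "kias_topic_model")
}

#' @export
print.kias_topic_model <- function(x, ...) {
  cat(sprintf("<kias_topic_model> %d topics over %d terms (coherence %.3f)\n",
              x$n_topics, length(x$vocab), x$coherence))
  invisible(x)
}

# internal: boolean word-in-window counts over sliding windows of all docs
cooccurrence_windows <- function(docs, window) {
  wins <- list()
  for (d in docs) {
    n <- length(d)
    if (n <= window) {
      wins[[length(wins) + 1L]] <- unique(d)
    } else {
      for (s in seq_len(n - window + 1L)) {
        wins[[length(wins) + 1L]] <- unique(d[s:(s + window - 1L)])
      }
    }
  }
  list(windows = wins, n = length(wins))
}

# internal: C_V-style coherence of all topics (mean over topics of the mean
# cosine between each top word's NPMI context vector and the topic's summed
# context vector)
cv_coherence <- function(phi, co, top_n) {
  eps <- 1e-12
  topic_scores <- vapply(seq_len(nrow(phi)), function(t) {
    top <- colnames(phi)[order(phi[t, ], decreasing = TRUE)][seq_len(min(top_n, ncol(phi)))]
    cnt <- vapply(top, function(w) {
      sum(vapply(co$windows, function(win) w %in% win, logical(1L)))
    }, numeric(1L))
    m <- length(top)
    npmi_mat <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) { npmi_mat[i, j] <- 1; next }
      cij <- sum(vapply(co$windows,
                        function(win) top[i] %in% win && top[j] %in% win,
                        logical(1L)))
      if (cij == 0 || cnt[i] == 0 || cnt[j] == 0) { npmi_mat[i, j] <- 0; next }
      pij <- cij / co$n; pi <- cnt[i] / co$n; pj <- cnt[j] / co$n
      npmi_mat[i, j] <- log(pij / (pi * pj) + eps) / (-log(pij + eps))
    }
    ctx_sum <- colSums(npmi_mat)
    sims <- vapply(seq_len(m), function(i) {
      ni <- sqrt(sum(npmi_mat[i, ]^2)); ns <- sqrt(sum(ctx_sum^2))
      if (ni == 0 || ns == 0) 0 else sum(npmi_mat[i, ] * ctx_sum) / (ni * ns)
    }, numeric(1L))
    mean(sims)
  }, numeric(1L))
  mean(topic_scores)
}

#' Infer a document's topic distribution
#'
#' Deterministic fixed-point (EM) fold-in against the fitted topic-word
#' matrix: responsibilities q(z = k | w) are proportional to theta_k *
#' phi_kw, and theta is re-estimated from the expected counts plus alpha.
#'
#' @param text Document text.
#' @param model A `kias_topic_model`.
#' @param iterations Fixed-point iterations.
#' @return Numeric topic-probability vector of length `n_topics`.
#' @export
infer_topics <- function(text, model, iterations = 50L) {
  toks <- tokenize_text(text)
  toks <- toks[toks %in% model$vocab]
  K <- model$n_topics
  if (length(toks) == 0L) return(rep(1 / K, K))
  counts <- table(toks)
  phi_w <- model$phi[, names(counts), drop = FALSE]
  n_w <- as.numeric(counts)
  theta <- rep(1 / K, K)
  for (it in seq_len(iterations)) {
    resp <- phi_w * theta              # K x W
    resp <- sweep(resp, 2L, pmax(colSums(resp), 1e-300), "/")
    theta_new <- as.numeric(resp %*% n_w) + model$alpha
    theta <- theta_new / sum(theta_new)
  }
  theta
}

#' Thematic overlap between a summary and its reference
#'
#' Dominant topics of each text are those with posterior probability above
#' 1 / n_topics. The overlap is |T_summary intersect T_reference| /
#' |T_reference| where T_x is the union of the `top_n` terms of x's dominant
#' topics.
#'
#' @param summary,reference Texts.
#' @param model A `kias_topic_model`.
#' @param top_n Terms per dominant topic.
#' @return Overlap in \[0, 1\], or NA when either text has no dominant topic
#'   or the reference term set is empty.
#' @export
thematic_overlap <- function(summary, reference, model, top_n = 10L) {
  term_set <- function(text) {
    theta <- infer_topics(text, model)
    dom <- which(theta > 1 / model$n_topics)
    if (length(dom) == 0L) return(NULL)
    unique(unlist(lapply(dom, function(t) {
      colnames(model$phi)[order(model$phi[t, ], decreasing = TRUE)][seq_len(
        min(top_n, ncol(model$phi)))]
    })))
  }
  ts <- term_set(summary); tr <- term_set(reference)
  if (is.null(ts) || is.null(tr) || length(tr) == 0L) return(NA_real_)
  length(intersect(ts, tr)) / length(tr)
}

#' Full evaluation report for one summary
#'
#' Computes every extrinsic metric against a reference text: FRE, topic-model
#' JSD, contextual similarity, thematic overlap, and ROUGE-1/2/L recall and
#' F1. Fields that cannot be computed (missing model or embeddings,
#' out-of-vocabulary texts) are NA.
#'
#' @param summary,reference Texts.
#' @param embeddings Optional `kias_embeddings`.
#' @param model Optional `kias_topic_model`.
#' @param top_n Terms per topic for thematic overlap.
#' @return A `kias_eval_report` list: `fre`, `jsd`, `contextual_similarity`,
#'   `thematic_overlap`, `rouge` (nested recall/f1 per variant).
#' @export
evaluate_summary <- function(summary, reference, embeddings = NULL,
                             model = NULL, top_n = 10L) {
  rep_list <- list(
    fre = if (length(tokenize_text(summary)) > 0L) flesch_reading_ease(summary)
          else NA_real_,
    jsd = if (!is.null(model)) {
      jsd(infer_topics(summary, model), infer_topics(reference, model))
    } else NA_real_,
    contextual_similarity = if (!is.null(embeddings)) {
      contextual_similarity(summary, reference, embeddings)
    } else NA_real_,
    thematic_overlap = if (!is.null(model)) {
      thematic_overlap(summary, reference, model, top_n)
    } else NA_real_,
    rouge = lapply(stats::setNames(c("1", "2", "L"), c("r1", "r2", "rL")),
                   function(v) {
                     r <- rouge(summary, reference, v)
                     list(recall = r$recall, f1 = r$f1)
                   }))
  structure(rep_list, class = "kias_eval_report")
}
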