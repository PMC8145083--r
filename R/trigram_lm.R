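#' Load a back-off trigram language model from an ARPA file
#'
#' Parses the standard ARPA format: a `\\data\\` header with n-gram counts,
#' `\\1-grams:` .. `\\3-grams:` sections (log10 probability, n-gram, optional
#' back-off weight), and a closing `\\end\\`. Section lengths must match the
#' header counts.
#'
#' @param path ARPA file.
#' @param log_floor Floor log10 probability assigned to out-of-vocabulary
#'   words (default -10).
#' @return A `kias_lm`: list with `unigrams`, `bigrams`, `trigrams` (named
#'   log10-probability vectors), `uni_bow`, `bi_bow` (named back-off weights),
#'   `vocab`, `log_floor`.
#' @export
load_arpa <- function(path, log_floor = -10) {
  if (!file.exists(path)) kias_abort(sprintf("ARPA file not found: %s", path),
                                     "kias_io_error")
  lines <- readLines(path, warn = FALSE)
  data_at <- which(trimws(lines) == "\\data\\")
  if (length(data_at) == 0L) kias_abort("ARPA parse error: missing \\data\\ header",
                                        "kias_parse_error")
  end_at <- which(trimws(lines) == "\\end\\")
  if (length(end_at) == 0L) kias_abort("ARPA parse error: missing \\end\\ marker",
                                       "kias_parse_error")
  counts <- integer(3L)
  for (i in (data_at[1L] + 1L):length(lines)) {
    l <- trimws(lines[i])
    m <- regmatches(l, regexec("^ngram ([123])=([0-9]+)$", l))[[1L]]
    if (length(m) == 3L) {
      counts[as.integer(m[2L])] <- as.integer(m[3L])
    } else if (grepl("^\\\\[123]-grams:", l)) break
  }
  parse_section <- function(order) {
    hdr <- sprintf("\\%d-grams:", order)
    at <- which(trimws(lines) == hdr)
    if (length(at) == 0L) {
      if (counts[order] == 0L) {
        return(list(lp = stats::setNames(numeric(0), character(0)),
                    bow = stats::setNames(numeric(0), character(0))))
      }
      kias_abort(sprintf("ARPA parse error: missing section %s", hdr),
                 "kias_parse_error")
    }
    lp <- numeric(); bow <- numeric(); keys <- character(); bkeys <- character()
    i <- at[1L] + 1L
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "" ) { i <- i + 1L; next }
      if (grepl("^\\\\", l)) break
      parts <- strsplit(l, "[ \t]+")[[1L]]
      if (length(parts) < order + 1L) {
        kias_abort(sprintf("ARPA parse error at line %d: '%s'", i, l),
                   "kias_parse_error")
      }
      key <- paste(parts[2:(order + 1L)], collapse = " ")
      keys <- c(keys, key)
      lp <- c(lp, as.numeric(parts[1L]))
      if (length(parts) >= order + 2L) {
        bkeys <- c(bkeys, key)
        bow <- c(bow, as.numeric(parts[order + 2L]))
      }
      i <- i + 1L
    }
    if (length(keys) != counts[order]) {
      kias_abort(sprintf(
        "ARPA parse error: section %s has %d entries, header says %d",
        hdr, length(keys), counts[order]), "kias_parse_error")
    }
    list(lp = stats::setNames(lp, keys), bow = stats::setNames(bow, bkeys))
  }
  s1 <- parse_section(1L); s2 <- parse_section(2L); s3 <- parse_section(3L)
  new_lm(s1$lp, s1$bow, s2$lp, s2$bow, s3$lp, log_floor)
}

# internal constructor: keeps the named vectors (serialization) plus O(1)
# hashed lookup environments (scoring hot path)
new_lm <- function(unigrams, uni_bow, bigrams, bi_bow, trigrams, log_floor) {
  as_env <- function(x) {
    if (length(x) == 0L) new.env(parent = emptyenv())
    else list2env(as.list(x), parent = emptyenv())
  }
  structure(list(unigrams = unigrams, uni_bow = uni_bow,
                 bigrams = bigrams, bi_bow = bi_bow, trigrams = trigrams,
                 vocab = names(unigrams), log_floor = log_floor,
                 idx = list(uni = as_env(unigrams), uni_bow = as_env(uni_bow),
                            bi = as_env(bigrams), bi_bow = as_env(bi_bow),
                            tri = as_env(trigrams))),
            class = "kias_lm")
}

#' Write a trigram model as an ARPA file
#' @param lm A `kias_lm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arpa <- function(lm, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 17)
  out <- c("\\data\\",
           sprintf("ngram 1=%d", length(lm$unigrams)),
           sprintf("ngram 2=%d", length(lm$bigrams)),
           sprintf("ngram 3=%d", length(lm$trigrams)),
           "", "\\1-grams:")
  for (k in names(lm$unigrams)) {
    has_bow <- k %in% names(lm$uni_bow)
    out <- c(out, paste(c(fmt(lm$unigrams[[k]]), k,
                          if (has_bow) fmt(lm$uni_bow[[k]])), collapse = "\t"))
  }
  out <- c(out, "", "\\2-grams:")
  for (k in names(lm$bigrams)) {
    has_bow <- k %in% names(lm$bi_bow)
    out <- c(out, paste(c(fmt(lm$bigrams[[k]]), k,
                          if (has_bow) fmt(lm$bi_bow[[k]])), collapse = "\t"))
  }
  out <- c(out, "", "\\3-grams:")
  for (k in names(lm$trigrams)) {
    out <- c(out, paste(fmt(lm$trigrams[[k]]), k, sep = "\t"))
  }
  out <- c(out, "", "\\end\\")
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.kias_lm <- function(x, ...) {
  cat(sprintf("<kias_lm> %d unigrams, %d bigrams, %d trigrams (floor %g)\n",
              length(x$unigrams), length(x$bigrams), length(x$trigrams),
              x$log_floor))
  invisible(x)
}

#' Conditional log10 probability with Katz back-off
#'
#' Returns the stored trigram log-probability when `c1 c2 w` is in the table;
#' otherwise backs off trigram -> bigram -> unigram, adding the back-off
#' weight of each context skipped (weights absent from the table count as 0).
#' A word with no unigram entry scores the floor.
#'
#' @param w Word.
#' @param context Character vector of up to 2 preceding words (earlier first).
#' @param lm A `kias_lm`.
#' @return log10 probability.
#' @export
lm_logprob <- function(w, context, lm) {
  ix <- lm$idx
  if (is.null(ix$uni[[w]])) return(lm$log_floor)  # OOV: floor, no back-off
  nctx <- length(context)
  if (nctx >= 2L) {
    c1 <- context[nctx - 1L]; c2 <- context[nctx]
    tri <- ix$tri[[paste(c1, c2, w)]]
    if (!is.null(tri)) return(tri)
    bow2 <- ix$bi_bow[[paste(c1, c2)]] %||% 0
    return(bow2 + lm_logprob(w, c2, lm))
  }
  if (nctx == 1L) {
    bi <- ix$bi[[paste(context, w)]]
    if (!is.null(bi)) return(bi)
    bow1 <- ix$uni_bow[[context]] %||% 0
    return(bow1 + lm_logprob(w, character(), lm))
  }
  ix$uni[[w]] %||% lm$log_floor
}

#' Knowledge-modulated linguistic quality of a word sequence
#'
#' Each position t is scored p_t = 10^logprob(w_t | w_(t-1), w_(t-2)) with
#' sentence-start padding, then boosted by the Word Semantic Score of w_t:
#' b_t = min(1, p_t * (1 + wss(w_t))). With L = |words| and the model's floor
#' f (log10), LL_norm = sum(log10 b_t) / (L * f) lies in \[0, 1\] and
#' Q = 1 - LL_norm. Frequent trigrams and depression-lexicon words raise Q;
#' with wss identically 0, Q is the plain length-normalized LM fluency used
#' by the knowledge-free abstractive baseline.
#'
#' @param words Character vector of tokens, length >= 1.
#' @param lm A `kias_lm`.
#' @param wss_fn Function word -> \[0, 1\] (default: no boost). A named
#'   numeric vector (e.g. from [wss_table()]) is also accepted.
#' @param boost_cap Upper cap on the boosted probability (default 1).
#' @return A `kias_quality` list: `q`, `ll_norm`, `L`.
#' @export
linguistic_quality <- function(words, lm, wss_fn = NULL, boost_cap = 1) {
  if (length(words) < 1L) kias_abort("linguistic_quality: empty word sequence")
  lookup <- if (is.null(wss_fn)) {
    function(w) 0
  } else if (is.function(wss_fn)) {
    wss_fn
  } else {
    tbl <- wss_fn
    function(w) { v <- unname(tbl[w]); if (is.na(v)) 0 else v }
  }
  padded <- c("<s>", "<s>", words)
  fl <- lm$log_floor
  lsum <- 0
  for (t in seq_along(words)) {
    ctx <- padded[(t):(t + 1L)]
    lp <- lm_logprob(words[t], ctx, lm)
    b <- min(boost_cap, (10^lp) * (1 + lookup(words[t])))
    lsum <- lsum + max(fl, log10(b))
  }
  ll_norm <- lsum / (length(words) * fl)
  ll_norm <- max(0, min(1, ll_norm))
  structure(list(q = 1 - ll_norm, ll_norm = ll_norm, L = length(words)),
            class = "kias_quality")
}
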