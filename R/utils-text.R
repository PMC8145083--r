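#' Tokenize normalized interview text
#'
#' Shared tokenizer for every module: lowercases, strips punctuation except
#' apostrophes (transcribed speech carries contractions but no sentence
#' punctuation), and splits on whitespace. Digits are kept.
#'
#' @param text Character scalar or vector.
#' @return Character vector of tokens (empty for blank input).
#' @export
#' @examples
#' tokenize_text("I'm fine, thanks!")
tokenize_text <- function(text) {
  if (length(text) == 0L) return(character())
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^a-z0-9' ]+", " ", x)
  x <- gsub("'{2,}", "'", x)
  # strip apostrophes that do not sit inside a word
  x <- gsub("(^| )'+| '+|'+( |$)", " ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' English stopword list used for word-graph node merging
#'
#' Small built-in function-word list (Snowball-style). Content words merge into
#' a single graph node by surface form; stopwords merge only under the guarded
#' neighbor test, so the list decides which tokens are "content".
#'
#' @return Character vector of lowercase stopwords.
#' @export
kias_stopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
    "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "having", "do", "does", "did", "doing",
    "a", "an", "the", "and", "but", "if", "or", "because", "as", "until",
    "while", "of", "at", "by", "for", "with", "about", "against", "between",
    "into", "through", "during", "before", "after", "above", "below", "to",
    "from", "up", "down", "in", "out", "on", "off", "over", "under", "again",
    "further", "then", "once", "here", "there", "when", "where", "why", "how",
    "all", "any", "both", "each", "few", "more", "most", "other", "some",
    "such", "no", "nor", "not", "only", "own", "same", "so", "than", "too",
    "very", "s", "t", "can", "will", "just", "don", "should", "now")
}

# internal: n-gram strings from a token vector
ngrams_from_tokens <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k < 1L) return(character())
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
         character(1L))
}

# internal: stop with a consistent contract-violation class
kias_abort <- function(msg, class = "kias_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}
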