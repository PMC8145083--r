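#' Read a DAIC-WoZ-style interview transcript
#'
#' Transcripts are tab-separated with a header; only the speaker and utterance
#' columns are used. Rows whose text is empty after trimming are skipped.
#'
#' @param path Path to a tab-separated transcript file.
#' @param dialect Named list describing the file layout:
#'   `speaker_col`, `text_col`, and `interviewer` (the speaker label, matched
#'   case-insensitively, that marks interviewer turns). Defaults mirror the
#'   DAIC-WoZ layout (`speaker`/`value` columns, interviewer "ellie").
#' @param conversation_id Identifier stored on the transcript; defaults to the
#'   file name without extension.
#' @return A `kias_transcript`: list with `conversation_id` and `utterances`,
#'   a data.frame with columns `speaker` ("interviewer"/"participant"),
#'   `text`, and `turn_index`.
#' @export
read_transcript <- function(path,
                            dialect = transcript_dialect(),
                            conversation_id = NULL) {
  if (!file.exists(path)) kias_abort(sprintf("transcript file not found: %s", path),
                                     "kias_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  if (nrow(df) == 0L) {
    kias_abort(sprintf("transcript %s has no rows", path), "kias_structure_error")
  }
  for (col in c(dialect$speaker_col, dialect$text_col)) {
    if (!col %in% names(df)) {
      kias_abort(sprintf("transcript %s lacks column '%s'", path, col),
                 "kias_structure_error")
    }
  }
  if (is.null(conversation_id)) {
    conversation_id <- sub("\\.[^.]*$", "", basename(path))
  }
  speaker_raw <- trimws(as.character(df[[dialect$speaker_col]]))
  text <- trimws(as.character(df[[dialect$text_col]]))
  keep <- nzchar(text)
  speaker <- ifelse(tolower(speaker_raw[keep]) == tolower(dialect$interviewer),
                    "interviewer", "participant")
  utt <- data.frame(speaker = speaker, text = text[keep],
                    turn_index = seq_len(sum(keep)) - 1L,
                    stringsAsFactors = FALSE)
  if (!any(utt$speaker == "interviewer")) {
    kias_abort(sprintf("transcript %s contains no interviewer turns", path),
               "kias_structure_error")
  }
  new_transcript(conversation_id, utt)
}

#' Default transcript dialect (DAIC-WoZ layout)
#' @param speaker_col,text_col Column names for speaker and utterance text.
#' @param interviewer Speaker label of the interviewer.
#' @return Named list usable as the `dialect` of [read_transcript()].
#' @export
transcript_dialect <- function(speaker_col = "speaker", text_col = "value",
                               interviewer = "ellie") {
  list(speaker_col = speaker_col, text_col = text_col, interviewer = interviewer)
}

new_transcript <- function(conversation_id, utterances) {
  stopifnot(is.data.frame(utterances),
            all(c("speaker", "text", "turn_index") %in% names(utterances)))
  structure(list(conversation_id = conversation_id, utterances = utterances),
            class = "kias_transcript")
}

#' @export
print.kias_transcript <- function(x, ...) {
  n_int <- sum(x$utterances$speaker == "interviewer")
  cat(sprintf("<kias_transcript> %s: %d turns (%d interviewer, %d participant)\n",
              x$conversation_id, nrow(x$utterances), n_int,
              nrow(x$utterances) - n_int))
  invisible(x)
}

#' Normalize an utterance
#'
#' Lowercases, collapses whitespace, completes truncated words through a
#' completion map (e.g. "peop" -> "people"), and rewrites transcriber
#' annotation tags (tokens wrapped in angle brackets, e.g. `<unintelligible>`)
#' to the literal token "xxx" used for unrecognizable speech.
#'
#' @param text Character scalar.
#' @param completion_map Named character vector mapping incomplete words to
#'   their full forms; may be empty.
#' @return Normalized character scalar (possibly empty).
#' @export
#' @examples
#' normalize_utterance("peop", c(peop = "people"))
normalize_utterance <- function(text, completion_map = character()) {
  if (length(text) != 1L || is.na(text)) return("")
  x <- tolower(text)
  x <- gsub("<[^<>]*>", " xxx ", x)
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  if (length(completion_map) > 0L && length(toks) > 0L) {
    hit <- toks %in% names(completion_map)
    toks[hit] <- unname(completion_map[toks[hit]])
  }
  paste(toks, collapse = " ")
}

#' Pair interviewer questions with participant answers
#'
#' Each interviewer turn opens a pair; all participant turns up to the next
#' interviewer turn are concatenated (single spaces) as its answer. An
#' interviewer turn with no following participant turn yields an empty answer
#' (flagged downstream, never counted as clinical evidence). Participant turns
#' before the first question have no question to attach to and are dropped
#' with a message.
#'
#' @param transcript A `kias_transcript`.
#' @param completion_map Passed to [normalize_utterance()].
#' @return data.frame with columns `pair_index`, `question`, `answer`.
#' @export
pair_qa <- function(transcript, completion_map = character()) {
  stopifnot(inherits(transcript, "kias_transcript"))
  utt <- transcript$utterances
  first_q <- match("interviewer", utt$speaker)
  if (is.na(first_q)) kias_abort("transcript has no interviewer turns",
                                 "kias_structure_error")
  if (first_q > 1L) {
    message(sprintf("pair_qa: dropped %d leading participant turn(s) with no question",
                    first_q - 1L))
    utt <- utt[first_q:nrow(utt), , drop = FALSE]
  }
  q_rows <- which(utt$speaker == "interviewer")
  pairs <- lapply(seq_along(q_rows), function(k) {
    i <- q_rows[k]
    j_end <- if (k < length(q_rows)) q_rows[k + 1L] - 1L else nrow(utt)
    ans_rows <- if (j_end > i) (i + 1L):j_end else integer()
    q <- normalize_utterance(utt$text[i], completion_map)
    a <- paste(vapply(utt$text[ans_rows], normalize_utterance, character(1L),
                      completion_map = completion_map), collapse = " ")
    data.frame(pair_index = k - 1L, question = q, answer = trimws(a),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pairs)
}

# second-person -> third-person rewrite table used in question templating;
# multi-word expansions allowed ("you're" -> "they are")
pronoun_rewrite_table <- c(
  "you" = "they", "your" = "their", "yours" = "theirs",
  "yourself" = "themselves", "you're" = "they are", "you've" = "they have"
)

#' Template a Q&A pair into a declarative statement
#'
#' Renders "participant was asked X, the participant said Y" with
#' second-person pronouns in the question rewritten to third person
#' ("how long ago were you diagnosed" becomes "how long ago were they
#' diagnosed"). The templated statement is the unit of pruning, slicing and
#' summarization.
#'
#' @param question,answer Character scalars (normalized text). `question` must
#'   be non-empty; `answer` may be empty.
#' @return Character scalar, the templated statement.
#' @export
#' @examples
#' to_statement("how long ago were you diagnosed", "a few years ago")
to_statement <- function(question, answer = "") {
  if (length(question) != 1L || is.na(question) || !nzchar(trimws(question))) {
    kias_abort("to_statement: question must be non-empty")
  }
  q_toks <- strsplit(trimws(tolower(question)), "\\s+")[[1L]]
  hit <- q_toks %in% names(pronoun_rewrite_table)
  q_toks[hit] <- unname(pronoun_rewrite_table[q_toks[hit]])
  q <- paste(q_toks, collapse = " ")
  a <- trimws(tolower(answer))
  sprintf("participant was asked %s, the participant said %s", q, a)
}

#' Build templated statements from a transcript
#'
#' Convenience wrapper: [pair_qa()] then [to_statement()] per pair.
#'
#' @inheritParams pair_qa
#' @return data.frame with columns `pair_index`, `question`, `answer`,
#'   `statement`, `has_answer`.
#' @export
statements_from_transcript <- function(transcript, completion_map = character()) {
  pairs <- pair_qa(transcript, completion_map)
  pairs$statement <- vapply(seq_len(nrow(pairs)), function(i) {
    to_statement(pairs$question[i], pairs$answer[i])
  }, character(1L))
  pairs$has_answer <- nzchar(pairs$answer)
  pairs
}

#' Write statements to disk
#'
#' Writes one statement per line (UTF-8) and, when `json_path` is given, a
#' JSON array of records `{pair_index, question, answer, statement}`.
#'
#' @param statements data.frame from [statements_from_transcript()].
#' @param path Output text file (one statement per line).
#' @param json_path Optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_statements <- function(statements, path, json_path = NULL) {
  writeLines(statements$statement, path, useBytes = TRUE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      statements[, c("pair_index", "question", "answer", "statement")],
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
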