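test_that("score_path length-normalizes the I + Q sum", {
  # printed example sentences: 14 and 10 tokens respectively
  s1 <- "participant was asked have they been diagnosed with depression participant said yeah while ago"
  s2 <- "participant was asked uh huh, then participant said pretty easy"
  expect_equal(length(tokenize_text(s1)), 14L)
  expect_equal(length(tokenize_text(s2)), 10L)
  expect_equal(score_path(0.25, 0.1, 14), 0.35 / 14)
  expect_equal(score_path(0.08, 0.04, 10), 0.12 / 10)
  expect_equal(score_path(0, 0, 5), 0)
  expect_error(score_path(1, 1, 0), ">= 1")
})

table1_candidates <- function() {
  list(
    list(words = tokenize_text(
      "participant was asked have they been diagnosed with depression participant said yeah while ago"),
      I = 0.25, Q = 0.1, n_words = 14, combined = 0.35 / 14),
    list(words = tokenize_text(
      "participant was asked uh huh, then participant said pretty easy"),
      I = 0.08, Q = 0.04, n_words = 10, combined = 0.12 / 10))
}

test_that("the ILP selects the higher-scoring printed candidate", {
  sel <- solve_slice(table1_candidates())
  expect_equal(sel$chosen, 1L)
  expect_equal(sel$objective_value, 0.35 / 14)
})

test_that("a single candidate is forced and an empty list is skipped", {
  one <- table1_candidates()[1]
  sel <- solve_slice(one)
  expect_equal(sel$chosen, 1L)
  expect_equal(sel$objective_value, one[[1L]]$combined)
  expect_warning(expect_null(solve_slice(list())), "empty")
})

test_that("the binary program agrees with the argmax oracle, ties included", {
  set.seed(101)
  for (i in 1:300) {
    K <- sample(1:20, 1)
    combined <- round(stats::runif(K), sample(1:3, 1))  # rounding forces ties
    n_words <- sample(5:30, K, replace = TRUE)
    cands <- lapply(seq_len(K), function(j) {
      list(words = rep("w", n_words[j]), I = NA, Q = NA,
           n_words = n_words[j], combined = combined[j])
    })
    sel <- solve_slice(cands)
    expect_equal(sel$chosen, argmax_selection(combined, n_words))
  }
})

test_that("selection is invariant to Q shifts and I scaling at fixed lengths", {
  set.seed(5)
  K <- 8
  I <- stats::runif(K, 0, 2); Q <- stats::runif(K)
  n <- rep(12L, K)
  mk <- function(I, Q) lapply(seq_len(K), function(j) {
    list(words = rep("w", n[j]), I = I[j], Q = Q[j], n_words = n[j],
         combined = score_path(I[j], Q[j], n[j]))
  })
  base <- solve_slice(mk(I, Q))$chosen
  expect_equal(solve_slice(mk(I, Q + 0.3))$chosen, base)
  expect_equal(solve_slice(mk(I * 10, Q * 10))$chosen, base)
})

test_that("render_sentence splits the fused path at the template boundary", {
  expect_equal(
    render_sentence(tokenize_text(
      "participant was asked do they feel down the participant said yes")),
    "Participant was asked: do they feel down Participant said: yes")
  expect_equal(render_sentence(c("no", "boundary", "here")),
               "no boundary here")
})

test_that("a 20-pair pruned conversation summarizes to exactly 3 sentences", {
  fx <- study_resources(seed = 31L, n_pairs = 40L, clinical_rate = 0.9)
  pruned <- fx$pruned
  pruned$statements <- utils::head(fx$statements, 20L)
  pruned$kept_indices <- pruned$statements$pair_index
  s <- kias_summarize(pruned, fx$resources)
  expect_equal(length(s$sentences), 3L)
  expect_equal(s$status, "ok")
})

test_that("the summary-length law holds whenever every slice yields a candidate", {
  for (seed in c(6L, 17L, 28L)) {
    fx <- study_resources(seed, n_pairs = 58L, clinical_rate = 0.3)
    s <- kias_summarize(fx$pruned, fx$resources)
    if (s$status == "ok") {
      expect_equal(length(s$sentences),
                   ceiling(nrow(fx$pruned$statements) / 7))
    }
  }
})

test_that("a transcript without clinical content yields an empty summary", {
  lex <- make_toy_lexicon()
  tr <- generate_interview(gen_config(seed = 9L, n_pairs = 12L,
                                      clinical_rate = 0), lex)
  fxv <- unique(unlist(lapply(statements_from_transcript(tr)$statement,
                              tokenize_text)))
  emb <- make_embeddings(fxv, lexicon = lex, seed = 9)
  lm <- make_toy_lm(statements_from_transcript(tr)$statement)
  s <- kias_summarize(tr, list(lexicon = lex, embeddings = emb, lm = lm))
  expect_equal(s$status, "no clinical content")
  expect_length(s$sentences, 0L)
})

test_that("the diagnosed-depression pair keeps its own answer (printed summary)", {
  lex <- make_toy_lexicon()
  rows <- list(
    c("Ellie", "what do you do when they are annoying"),
    c("Participant", "i just stop talking"),
    c("Ellie", "have you been diagnosed with depression"),
    c("Participant", "yeah i have been so depressed"),
    c("Ellie", "do you feel like therapy useful"),
    c("Participant", "oh yeah definitely"),
    c("Ellie", "what got you to seek help"),
    c("Participant", "my sister pushed me to go"),
    c("Ellie", "and do you still feel that way these days"),
    c("Participant", "yeah still feeling down lately"),
    c("Ellie", "has your family noticed"),
    c("Participant", "yeah my mom worries a lot"),
    c("Ellie", "how long ago were you diagnosed depression"),
    c("Participant", "a year ago"),
    c("Ellie", "can you tell me more about that"),
    c("Participant", "i was lying awake every night a year ago"),
    c("Ellie", "how are your nights now"),
    c("Participant", "i still keep lying awake"),
    c("Ellie", "when was the last time you felt happy"),
    c("Participant", "a while ago"))
  tr <- read_transcript(write_tsv_transcript(rows), conversation_id = "p313")
  stmts <- statements_from_transcript(tr)
  vocab <- unique(unlist(lapply(stmts$statement, tokenize_text)))
  emb <- make_embeddings(vocab, lexicon = lex, seed = 42)
  lm <- make_toy_lm(stmts$statement)
  s <- kias_summarize(tr, list(lexicon = lex, embeddings = emb, lm = lm))
  diag_sentences <- grep("how long ago were they diagnosed", s$sentences,
                         value = TRUE, fixed = TRUE)
  expect_gt(length(diag_sentences), 0L)
  expect_true(any(grepl("a year ago", diag_sentences, fixed = TRUE)))
})

test_that("summarization is deterministic given fixed resources", {
  fx <- study_resources(seed = 12L, n_pairs = 30L, clinical_rate = 0.4)
  s1 <- kias_summarize(fx$pruned, fx$resources)
  s2 <- kias_summarize(fx$pruned, fx$resources)
  expect_identical(s1$sentences, s2$sentences)
})
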