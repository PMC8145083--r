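test_that("Flesch Reading Ease matches the formula on a hand-counted sentence", {
  # 3 words, 1 sentence, 3 syllables:
  # 206.835 - 1.015 * 3 - 84.6 * 1 = 119.19
  expect_equal(flesch_reading_ease("the cat sat."), 119.19)
  # repeating the same sentence leaves the ratios unchanged
  expect_equal(flesch_reading_ease("the cat sat.\nthe cat sat."), 119.19)
  # more syllables per word strictly lowers the score
  expect_lt(flesch_reading_ease("the elephantine catastrophe."),
            flesch_reading_ease("the cat sat."))
  expect_error(flesch_reading_ease("..."), "no words")
})

test_that("the syllable heuristic counts vowel groups with silent-e handling", {
  syl <- function(w) kias:::count_syllables(w)
  expect_equal(syl("cat"), 1L)
  expect_equal(syl("table"), 2L)   # -le keeps its syllable
  expect_equal(syl("there"), 1L)   # silent e
  expect_equal(syl("beautiful"), 3L)
  expect_equal(syl("xxx"), 1L)     # floor at one
})

test_that("JSD is the base-2 Jensen-Shannon divergence", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  set.seed(3)
  for (i in 1:10) {
    a <- stats::rgamma(4, 1); a <- a / sum(a)
    b <- stats::rgamma(4, 1); b <- b / sum(b)
    expect_equal(jsd(a, b), jsd(b, a))
    expect_gte(jsd(a, b), 0); expect_lte(jsd(a, b), 1)
  }
  expect_error(jsd(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(jsd(c(0.9, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("contextual similarity is a bag-of-words cosine", {
  emb <- manual_embeddings(list(red = c(1, 0), blue = c(1, 0.2),
                                stone = c(0, 1)))
  expect_equal(contextual_similarity("red blue", "red blue", emb), 1)
  expect_equal(contextual_similarity("red", "stone", emb), 0)
  expect_equal(contextual_similarity("red blue stone", "stone blue red", emb), 1)
  expect_true(is.na(contextual_similarity("zzz", "red", emb)))
})

test_that("ROUGE variants match hand counts", {
  for (v in c("1", "2", "L")) {
    r <- rouge("the cat sat", "the cat sat", v)
    expect_equal(r$recall, 1); expect_equal(r$f1, 1)
  }
  r1 <- rouge("the cat", "the cat sat", "1")
  expect_equal(r1$recall, 2 / 3)
  expect_equal(r1$precision, 1)
  # LCS of a reversal cannot beat the unigram bag overlap
  rL <- rouge("sat cat the", "the cat sat", "L")
  r1b <- rouge("sat cat the", "the cat sat", "1")
  expect_lte(rL$recall, r1b$recall)
  expect_error(rouge("a", "", "1"), "empty reference")
})

# planted-topic corpus: `k` disjoint 10-word vocabularies
planted_corpus <- function(k, docs_per_topic = 12L, len = 40L, seed = 1L) {
  set.seed(seed)
  vocabs <- lapply(seq_len(k), function(t) sprintf("t%dword%d", t, 1:10))
  docs <- character()
  for (t in seq_len(k)) {
    for (d in seq_len(docs_per_topic)) {
      main <- sample(vocabs[[t]], len, replace = TRUE)
      docs <- c(docs, paste(main, collapse = " "))
    }
  }
  docs
}

test_that("topic-model selection recovers the planted number of topics", {
  hits <- vapply(1:5, function(seed) {
    corpus <- planted_corpus(5, seed = seed)
    m <- fit_topic_model(corpus, k_range = 2:10, seed = seed, n_iter = 80L)
    abs(m$n_topics - 5L) <= 1L
  }, logical(1L))
  expect_gte(sum(hits), 3L)  # majority across seeds
})

test_that("topic models are deterministic and honor a singleton k range", {
  corpus <- planted_corpus(3, docs_per_topic = 6L, seed = 2L)
  m1 <- fit_topic_model(corpus, k_range = 3L, seed = 7L, n_iter = 50L)
  m2 <- fit_topic_model(corpus, k_range = 3L, seed = 7L, n_iter = 50L)
  expect_equal(m1$n_topics, 3L)
  expect_identical(m1$phi, m2$phi)
  expect_equal(rowSums(m1$phi), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_warning(
    fit_topic_model(rep("same words here", 4L), k_range = c(2L, 4L),
                    seed = 1L, n_iter = 10L),
    "degenerate")
})

test_that("document-topic inference is a proper, deterministic distribution", {
  corpus <- planted_corpus(3, docs_per_topic = 6L, seed = 4L)
  m <- fit_topic_model(corpus, k_range = 3L, seed = 4L, n_iter = 50L)
  th <- infer_topics(corpus[1L], m)
  expect_equal(sum(th), 1, tolerance = 1e-9)
  expect_identical(th, infer_topics(corpus[1L], m))
  # a document of planted topic t concentrates on one topic
  expect_gt(max(th), 0.8)
})

test_that("thematic overlap is 1 on identity and 0 across planted topics", {
  corpus <- planted_corpus(3, docs_per_topic = 8L, seed = 6L)
  m <- fit_topic_model(corpus, k_range = 3L, seed = 6L, n_iter = 60L)
  doc_a <- corpus[1L]                      # topic 1 document
  doc_b <- corpus[9L]                      # topic 2 document
  expect_equal(thematic_overlap(doc_a, doc_a, m), 1)
  expect_equal(thematic_overlap(doc_a, doc_b, m), 0)
})

test_that("adding a reference-topic sentence never lowers thematic overlap", {
  corpus <- planted_corpus(3, docs_per_topic = 8L, seed = 8L)
  m <- fit_topic_model(corpus, k_range = 3L, seed = 8L, n_iter = 60L)
  reference <- corpus[1L]
  summary_far <- corpus[9L]
  before <- thematic_overlap(summary_far, reference, m)
  augmented <- paste(summary_far, paste(strsplit(reference, " ")[[1L]][1:10],
                                        collapse = " "))
  after <- thematic_overlap(augmented, reference, m)
  expect_gte(after, before)
})

test_that("evaluate_summary assembles a full report", {
  emb <- manual_embeddings(list(red = c(1, 0), stone = c(0, 1)))
  rep <- evaluate_summary("red stone", "red stone", embeddings = emb)
  expect_s3_class(rep, "kias_eval_report")
  expect_equal(rep$contextual_similarity, 1)
  expect_equal(rep$rouge$r1$recall, 1)
  expect_true(is.na(rep$jsd))          # no topic model supplied
  expect_true(is.na(rep$thematic_overlap))
})

test_that("metrics are permutation-deterministic across documents", {
  corpus <- planted_corpus(2, docs_per_topic = 5L, seed = 10L)
  m <- fit_topic_model(corpus, k_range = 2L, seed = 10L, n_iter = 40L)
  vals1 <- vapply(corpus, function(d) jsd(infer_topics(d, m),
                                          infer_topics(corpus[1L], m)),
                  numeric(1L))
  vals2 <- vapply(rev(corpus), function(d) jsd(infer_topics(d, m),
                                               infer_topics(corpus[1L], m)),
                  numeric(1L))
  expect_equal(unname(vals1), rev(unname(vals2)))
})
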