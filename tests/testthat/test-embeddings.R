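test_that("embedding files round-trip, with and without the count header", {
  emb <- manual_embeddings(list(alpha = c(0.25, -1.5, 3), beta = c(1, 2, 3)))
  p <- tempfile()
  write_embeddings(emb, p, header = TRUE)
  back <- read_embeddings(p)
  expect_equal(back$dimension, 3L)
  expect_equal(back$vectors, emb$vectors)

  write_embeddings(emb, p, header = FALSE)
  expect_equal(read_embeddings(p)$vectors, emb$vectors)

  bad <- tempfile(); writeLines(c("a 1 2", "b 1 2 3"), bad)
  expect_error(read_embeddings(bad), "inconsistent")
})

test_that("embedding lookup distinguishes misses from zero vectors", {
  emb <- manual_embeddings(list(a = c(1, 0)))
  expect_null(kias:::embedding_lookup(emb, "zzz"))
  expect_equal(nrow(kias:::embedding_lookup(emb, c("a", "zzz"))), 1L)
})

test_that("cosine similarity has the standard geometry", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
})

test_that("the lexicon graph links phrase words and same-category head words", {
  lex <- kias:::new_lexicon(list(
    S3 = list(label = NA, phrases = "trouble sleeping")))
  g <- build_lexicon_graph(lex)
  expect_equal(nrow(g$edges), 1L)
  expect_setequal(as.vector(g$edges), c("sleeping", "trouble"))

  lex1 <- kias:::new_lexicon(list(S1 = list(label = NA, phrases = "apathy")))
  g1 <- build_lexicon_graph(lex1)
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(g1$nodes, "apathy")

  # two phrases sharing "feeling" in one category: the shared word links to
  # both phrases' other words
  lex2 <- kias:::new_lexicon(list(S2 = list(
    label = NA, phrases = c("feeling hopeless", "feeling worthless"))))
  g2 <- build_lexicon_graph(lex2)
  nb <- function(w) {
    e <- g2$edges
    sort(unique(c(e[e[, 1] == w, 2], e[e[, 2] == w, 1])))
  }
  expect_setequal(nb("feeling"), c("hopeless", "worthless"))
  expect_false(any(g2$edges[, 1] == g2$edges[, 2]))
})

test_that("one synchronous retrofit step matches the hand-computed update", {
  emb <- manual_embeddings(list(a = c(1, 0), b = c(0, 1)))
  g <- structure(list(nodes = c("a", "b"),
                      edges = matrix(c("a", "b"), ncol = 2),
                      degree = c(a = 1L, b = 1L)),
                 class = "kias_lexicon_graph")
  out <- retrofit_embeddings(emb, g, alpha = 1, beta = "uniform",
                             iterations = 1L)
  expect_equal(unname(out$vectors["a", ]), c(0.5, 0.5))
  expect_equal(unname(out$vectors["b", ]), c(0.5, 0.5))
  expect_equal(cosine_similarity(out$vectors["a", ], out$vectors["b", ]), 1)

  expect_error(retrofit_embeddings(emb, g, iterations = 0), ">= 1")
})

test_that("retrofitting leaves off-graph words untouched and stays in the hull", {
  set.seed(7)
  lex <- make_toy_lexicon()
  g <- build_lexicon_graph(lex)
  words <- c(lex$vocabulary, "bystander")
  emb <- make_embeddings(words, dim = 10, lexicon = NULL, seed = 7)
  out <- retrofit_embeddings(emb, g, iterations = 3L)
  expect_equal(out$vectors["bystander", ], emb$vectors["bystander", ])

  # one-step update lies in the convex hull of {original} U neighbors:
  # coefficients are alpha and beta_ij over their sum, all positive
  one <- retrofit_embeddings(emb, g, iterations = 1L)
  w <- "lethargic"
  e <- g$edges
  nbrs <- unique(c(e[e[, 1] == w, 2], e[e[, 2] == w, 1]))
  pts <- rbind(emb$vectors[w, , drop = FALSE],
               emb$vectors[nbrs, , drop = FALSE])
  # solve for hull coefficients (least squares; must reproduce the point)
  co <- qr.solve(t(pts), one$vectors[w, ])
  expect_equal(as.numeric(t(pts) %*% co), unname(one$vectors[w, ]),
               tolerance = 1e-8)
  expect_true(all(co > -1e-8))
  expect_equal(sum(co), 1, tolerance = 1e-8)
})

test_that("retrofitting pulls linked pairs above their random-init similarity", {
  # the synchronous (Jacobi) update is not stepwise monotone — it overshoots
  # and converges in damped oscillation — but every iterate beats the
  # random initialization, which is the contraction that matters
  lex <- make_toy_lexicon()
  g <- build_lexicon_graph(lex)
  emb <- make_embeddings(lex$vocabulary, dim = 25, lexicon = NULL, seed = 13)
  linked_cos <- function(e) {
    mean(vapply(seq_len(nrow(g$edges)), function(i) {
      a <- g$edges[i, 1]; b <- g$edges[i, 2]
      cosine_similarity(e$vectors[a, ], e$vectors[b, ])
    }, numeric(1L)))
  }
  base <- linked_cos(emb)
  vals <- vapply(1:6, function(it) {
    linked_cos(retrofit_embeddings(emb, g, iterations = it))
  }, numeric(1L))
  expect_true(all(vals > base))
  # and the iteration settles (later steps change less than early ones)
  expect_lt(abs(vals[6] - vals[5]), abs(vals[2] - vals[1]))
})

test_that("wss is the clamped max cosine against lexicon words", {
  lex <- kias:::new_lexicon(list(S4 = list(label = NA,
                                           phrases = "lethargic drained")))
  emb <- manual_embeddings(list(lethargic = c(1, 0), drained = c(0, 1),
                                orthogonal = c(0, 0.0), far = c(-1, 0),
                                near = c(1, 1) / sqrt(2)))
  emb$vectors["orthogonal", ] <- c(0, 0)  # zero vector -> no similarity
  expect_equal(wss("lethargic", emb, lex), 1)
  expect_equal(wss("far", emb, lex), 0)     # negative max clamped
  expect_equal(wss("missing", emb, lex), 0) # OOV
  expect_equal(wss("near", emb, lex), cosine_similarity(c(1, 1), c(1, 0)))
})

test_that("retrofitting raises wss for graph-linked words", {
  lex <- kias:::new_lexicon(list(S4 = list(label = NA,
                                           phrases = "feeling lethargic")))
  g <- build_lexicon_graph(lex)
  emb <- manual_embeddings(list(feeling = c(1, 0, 0), lethargic = c(0, 1, 0)))
  lex_only <- kias:::new_lexicon(list(S4 = list(label = NA,
                                                phrases = "lethargic")))
  before <- wss("feeling", emb, lex_only)
  after <- wss("feeling", retrofit_embeddings(emb, g, iterations = 5L),
               lex_only)
  expect_gt(after, before)
})

test_that("wss_table agrees with scalar wss", {
  lex <- make_toy_lexicon()
  emb <- make_embeddings(c("stranger", "visitor"), lexicon = lex, seed = 3)
  words <- c("stranger", "visitor", "lethargic", "not-present")
  tab <- wss_table(words, emb, lex)
  for (w in words) expect_equal(unname(tab[w]), wss(w, emb, lex))
})
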