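test_that("a single statement becomes a START->END chain", {
  g <- build_word_graph("a b")  # both tokens are stopwords: guarded nodes
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  paths <- enumerate_paths(g, K = 10, min_len = 1)
  expect_length(paths, 1L)
  expect_equal(paths[[1L]]$words, c("a", "b"))
})

test_that("shared content words merge; repetition doubles counts only", {
  g <- build_word_graph(c("they were diagnosed recently",
                          "she was diagnosed yesterday"))
  expect_equal(sum(g$nodes$token == "diagnosed"), 1L)
  ins <- g$edges[g$edges$to == "diagnosed", ]
  expect_equal(nrow(ins), 2L)

  g2 <- build_word_graph(c("one fine day", "one fine day"))
  g1 <- build_word_graph("one fine day")
  expect_setequal(g2$nodes$id, g1$nodes$id)
  expect_equal(sort(g2$edges$count), rep(2L, nrow(g1$edges)))

  expect_error(build_word_graph(character()), "empty")
})

test_that("stopwords merge only when both neighbors coincide", {
  g <- build_word_graph(c("cats in boxes", "dogs in kennels"))
  # different contexts: two distinct "in" nodes
  expect_equal(sum(g$nodes$token == "in"), 2L)
  g2 <- build_word_graph(c("cats in boxes", "cats in boxes sleep"))
  expect_equal(sum(g2$nodes$token == "in"), 1L)
})

test_that("textrank matches the dense linear-solve oracle on a fixture bank", {
  bank <- list(
    "a b",
    c("one fine day", "one bad day"),
    c("they were diagnosed recently", "she was diagnosed yesterday"),
    c("x y z", "p q r"),
    c("alpha beta gamma", "beta gamma alpha"))
  for (stmts in bank) {
    g <- build_word_graph(stmts)
    expect_lte(nrow(g$nodes), 12L)
    got <- textrank(g, d = 0.78, tol = 1e-10, max_iter = 500)
    oracle <- textrank_solve(g, d = 0.78)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_true(all(got > 0))
    expect_true(all(got < nrow(g$nodes)))
  }
})

test_that("textrank fixed points: isolated node and symmetric 2-cycle", {
  # construct raw graphs directly
  iso <- structure(list(
    nodes = data.frame(id = c("__START__", "__END__", "lone"),
                       token = c("", "", "lone"), is_stopword = FALSE),
    edges = data.frame(from = "__START__", to = "__END__", count = 1L),
    start = "__START__", end = "__END__"), class = "kias_word_graph")
  imp <- textrank(iso, d = 0.78)
  expect_equal(unname(imp["lone"]), 0.22, tolerance = 1e-6)

  cyc <- structure(list(
    nodes = data.frame(id = c("__START__", "__END__", "a", "b"),
                       token = c("", "", "a", "b"), is_stopword = FALSE),
    edges = data.frame(from = c("a", "b"), to = c("b", "a"), count = 1L),
    start = "__START__", end = "__END__"), class = "kias_word_graph")
  imp2 <- textrank(cyc, d = 0.78)
  expect_equal(unname(imp2[c("a", "b")]), c(1, 1), tolerance = 1e-6)
})

test_that("path informativeness is the sum of word scores", {
  imp <- c(a = 0.5, b = 1.5, c = 0.25)
  expect_equal(path_informativeness(c("a", "b"), imp), 2)
  expect_equal(path_informativeness(character(), imp), 0)
  expect_equal(path_informativeness(c("__START__", "a", "__END__"), imp), 0.5)
  # additivity over concatenation
  expect_equal(path_informativeness(c("a", "b", "c"), imp),
               path_informativeness(c("a", "b"), imp) +
                 path_informativeness("c", imp))
  expect_error(path_informativeness(c("a", "zz"), imp), "unscored")
})

test_that("two disjoint statements yield exactly their two paths", {
  g <- build_word_graph(c("red house burning", "green river flowing"))
  paths <- enumerate_paths(g, K = 10, min_len = 1)
  expect_length(paths, 2L)
  expect_setequal(vapply(paths, function(p) paste(p$words, collapse = " "),
                         character(1L)),
                  c("red house burning", "green river flowing"))
})

test_that("enumeration equals the exhaustive simple-path oracle on small graphs", {
  fixtures <- list(
    c("sad song plays", "sad tune plays"),
    c("one fine day", "one bad day", "one day"),
    c("they were diagnosed recently", "she was diagnosed ago"))
  for (stmts in fixtures) {
    g <- build_word_graph(stmts)
    got <- enumerate_paths(g, K = 1000, min_len = 1)
    oracle <- all_simple_paths(g, min_len = 1)
    expect_equal(lapply(got, `[[`, "words"), lapply(oracle, `[[`, "words"))
    expect_equal(vapply(got, `[[`, numeric(1L), "cost"),
                 vapply(oracle, `[[`, numeric(1L), "cost"),
                 tolerance = 1e-9)
    # deterministic: identical on a second run
    again <- enumerate_paths(g, K = 1000, min_len = 1)
    expect_identical(lapply(again, `[[`, "words"),
                     lapply(got, `[[`, "words"))
  }
})

test_that("min_len and the require_token filter drop unusable paths", {
  g <- build_word_graph(c("short one", "a much longer statement here"))
  expect_length(enumerate_paths(g, K = 10, min_len = 3), 1L)
  g2 <- build_word_graph(c("she said yes today", "she waved goodbye"))
  with_said <- enumerate_paths(g2, K = 10, min_len = 1,
                               require_token = "said")
  expect_true(all(vapply(with_said, function(p) "said" %in% p$words,
                         logical(1L))))
  # "said" as final word does not count as carrying an answer
  g3 <- build_word_graph("she said")
  expect_length(enumerate_paths(g3, K = 10, min_len = 1,
                                require_token = "said"), 0L)
})

test_that("every input statement survives as a candidate path", {
  lex <- make_toy_lexicon()
  tr <- generate_interview(gen_config(seed = 4L, n_pairs = 14L,
                                      clinical_rate = 0.5), lex)
  stmts <- statements_from_transcript(tr)
  slices <- slice_statements(structure(
    list(statements = stmts), class = "kias_pruned"), window = 7)
  for (sl in slices) {
    g <- build_word_graph(sl)
    paths <- enumerate_paths(g, K = 10000, min_len = 1)
    keys <- vapply(paths, function(p) paste(p$words, collapse = " "),
                   character(1L))
    for (s in sl$statements$statement) {
      expect_true(paste(tokenize_text(s), collapse = " ") %in% keys)
    }
  }
})

test_that("adding a statement sharing a word never lowers its importance", {
  g1 <- build_word_graph("they were diagnosed recently")
  g2 <- build_word_graph(c("they were diagnosed recently",
                           "she was diagnosed ago"))
  i1 <- textrank(g1); i2 <- textrank(g2)
  expect_gte(i2[["diagnosed"]], i1[["diagnosed"]] - 1e-9)
})

test_that("graph dumps are written as edge lists and DOT", {
  g <- build_word_graph("red house")
  p1 <- tempfile(); p2 <- tempfile()
  write_word_graph(g, p1, "edgelist")
  expect_equal(nrow(utils::read.delim(p1)), nrow(g$edges))
  write_word_graph(g, p2, "dot")
  expect_match(readLines(p2)[1], "digraph")
})
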