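#' Built-in toy PHQ-9 depression lexicon
#'
#' Nine signal categories matching the PHQ-9 items, each with at least three
#' indicative phrases drawn from a built-in bank: decreased pleasure (S1),
#' feeling down (S2), sleep disorders (S3), loss of energy (S4), appetite
#' change (S5), feeling worthless (S6), concentration problems (S7),
#' psychomotor change (S8), suicidal thoughts (S9). A stand-in, synthetic
#' lexicon for testing; not the published PHQ-9 lexicon.
#'
#' @param seed Unused except for interface symmetry with the other
#'   generators; the bank is fixed, so the lexicon is always identical.
#' @return A `kias_lexicon`.
#' @export
make_toy_lexicon <- function(seed = 1L) {
  bank <- list(
    S1 = list(label = "decreased pleasure in most activities",
              phrases = c("lost interest", "nothing feels fun",
                          "stopped enjoying hobbies", "no interest anymore")),
    S2 = list(label = "feeling down",
              phrases = c("feeling down", "feeling hopeless", "so depressed",
                          "nobody likes me")),
    S3 = list(label = "sleep disorders",
              phrases = c("trouble sleeping", "insomnia",
                          "waking up early", "lying awake")),
    S4 = list(label = "loss of energy",
              phrases = c("feeling lethargic", "constantly tired",
                          "sick and tired", "completely drained")),
    S5 = list(label = "significant change in appetite",
              phrases = c("loss of appetite", "overeating at night",
                          "skipping meals")),
    S6 = list(label = "feeling worthless",
              phrases = c("feeling worthless", "down in guilt",
                          "constant failure")),
    S7 = list(label = "concentration problems",
              phrases = c("trouble concentrating", "mind wanders constantly",
                          "losing track")),
    S8 = list(label = "hyper or lower activity",
              phrases = c("moving very slowly", "restless for hours",
                          "fidgety and agitated")),
    S9 = list(label = "suicidal thoughts",
              phrases = c("thoughts of death", "better off dead",
                          "hurting myself")))
  new_lexicon(bank)
}

#' Synthetic word embeddings with planted lexicon structure
#'
#' Random unit vectors, except that words of the same lexicon category share
#' a latent category direction, planting pairwise within-category cosine
#' similarity of about `within_cos` (>= 0.7 at the default) independent of
#' the dimension, while unrelated pairs have expected cosine ~ 0. A
#' synthetic stand-in used so retrofitting and WSS are testable without
#' distributing real embeddings.
#'
#' @param vocab Extra (non-lexicon) words to embed.
#' @param dim Embedding dimension, >= 2 (default 300, the dimensionality of
#'   the ConceptNet Numberbatch vectors the fixture stands in for).
#' @param lexicon A `kias_lexicon` whose vocabulary is embedded with planted
#'   category structure; NULL for fully random vectors.
#' @param seed Integer seed.
#' @param within_cos Target expected cosine between two words of the same
#'   category, in (0, 1).
#' @return A `kias_embeddings`.
#' @export
make_embeddings <- function(vocab, dim = 300L, lexicon = NULL, seed = 1L,
                            within_cos = 0.9) {
  if (dim < 2L) kias_abort("make_embeddings: dim must be >= 2")
  set.seed(seed)
  unit <- function(v) v / sqrt(sum(v^2))
  words <- unique(c(vocab, if (!is.null(lexicon)) lexicon$vocabulary))
  cat_of <- character()
  if (!is.null(lexicon)) {
    # only distinctive content words carry the category direction: in real
    # embedding spaces function words and everyday vocabulary ("the", "much",
    # "time") are not close to clinical terms, even when a lexicon phrase
    # happens to contain them
    generic <- unique(c(kias_stopwords(),
                        unlist(lapply(synth_banks()[c("neutral_q", "neutral_a",
                                                      "cooldown_q", "cooldown_a")],
                                      tokenize_text))))
    for (cid in names(lexicon$categories)) {
      for (w in unlist(strsplit(lexicon$categories[[cid]]$phrases, " "))) {
        if (!w %in% names(cat_of) && !w %in% generic) cat_of[w] <- cid
      }
    }
    cat_dirs <- lapply(stats::setNames(nm = unique(cat_of)),
                       function(cid) unit(stats::rnorm(dim)))
  }
  mat <- matrix(0, nrow = length(words), ncol = dim,
                dimnames = list(words, NULL))
  for (w in words) {
    if (!is.null(lexicon) && w %in% names(cat_of)) {
      # cos(v_i, v_j) ~ within_cos for two words sharing the direction
      mat[w, ] <- unit(sqrt(within_cos) * cat_dirs[[cat_of[[w]]]] +
                         sqrt(1 - within_cos) * unit(stats::rnorm(dim)))
    } else {
      mat[w, ] <- unit(stats::rnorm(dim))
    }
  }
  new_embeddings(mat)
}

#' Generator configuration for synthetic interviews
#'
#' @param seed Integer seed.
#' @param n_pairs Number of Q&A pairs (the corpus average is ~58 statements).
#' @param clinical_rate Probability that a clinical-phase answer carries a
#'   planted lexicon phrase.
#' @param anaphora_rate Probability that a clinical-phase answer responds to
#'   a question asked two or more pairs earlier.
#' @param disfluency_rate Probability of injecting a disfluency ("uh", "um",
#'   "xxx") into an answer.
#' @param phases Proportions of the neutral / clinical / cool-down arc;
#'   must sum to 1.
#' @return A validated `kias_gen_config` list.
#' @export
gen_config <- function(seed = 1L, n_pairs = 58L, clinical_rate = 0.3,
                       anaphora_rate = 0.1, disfluency_rate = 0.15,
                       phases = c(0.25, 0.55, 0.20)) {
  if (n_pairs < 1L) kias_abort("gen_config: n_pairs must be >= 1")
  rates <- c(clinical_rate, anaphora_rate, disfluency_rate)
  if (any(rates < 0 | rates > 1)) kias_abort("gen_config: rates must be in [0,1]")
  if (abs(sum(phases) - 1) > 1e-9) kias_abort("gen_config: phases must sum to 1")
  structure(list(seed = seed, n_pairs = as.integer(n_pairs),
                 clinical_rate = clinical_rate, anaphora_rate = anaphora_rate,
                 disfluency_rate = disfluency_rate, phases = phases),
            class = c("kias_gen_config", "list"))
}

# question/answer banks; worded to avoid every toy-lexicon vocabulary word so
# that clinical_rate = 0 yields a lexicon-free transcript
synth_banks <- function() {
  list(
    neutral_q = c("okay what'd you study at school",
                  "that's good where are you from originally",
                  "how do you like l a",
                  "what do you do for work these days",
                  "do you travel much",
                  "tell me about where you grew up",
                  "what kind of music do you listen to",
                  "do you have any pets at home",
                  "what did you do this past weekend",
                  "do you follow any sports",
                  "what's your favorite food",
                  "do you cook at home",
                  "how long have you lived here",
                  "what was your first job"),
    neutral_a = c("i studied history at a community college",
                  "originally i'm from glendale california",
                  "it's okay i guess the traffic is bad",
                  "i work at a grocery store near my place",
                  "not really maybe once a year",
                  "i grew up in a small town by the coast",
                  "mostly old rock and some jazz",
                  "yeah a little dog named scout",
                  "we had a barbecue with the neighbors",
                  "basketball when the season is on",
                  "anything with noodles honestly",
                  "a couple of nights a week",
                  "about six years now",
                  "bagging groceries as a teenager"),
    clinical_q = c("have you been diagnosed with depression",
                   "how long ago were you diagnosed",
                   "are you seeing a therapist right now",
                   "what got you to seek help",
                   "is there anything you regret",
                   "have you been diagnosed with ptsd",
                   "how have things been at home lately",
                   "was that hard for you",
                   "can you tell me more about that",
                   "do you find therapy useful",
                   "how often do you see your doctor",
                   "when did you last talk to someone about this",
                   "how has work been going",
                   "do you still see your friends much",
                   "what happens when things get overwhelming",
                   "how do you handle stress",
                   "has your family noticed a change",
                   "do you take any medication for it",
                   "how has your energy been",
                   "what does a bad week look like for you",
                   "when was the last time that happened",
                   "what would make things easier for you",
                   "do you argue with people more than before",
                   "how do you get along with your coworkers",
                   "did something happen that started this",
                   "are you comfortable talking about it",
                   "what do you do when you cannot cope",
                   "how would you describe your mood this month",
                   "do you feel safe at home",
                   "what keeps you going right now"),
    clinical_neutral_a = c("yeah a while ago",
                           "a year ago",
                           "oh yeah definitely",
                           "my sister pushed me to go",
                           "hmm not really",
                           "no never",
                           "things have been complicated at home",
                           "yes it was hard",
                           "i'd rather not talk about it",
                           "oh yeah it helps a lot",
                           "about once a month",
                           "a couple of weeks back",
                           "work has been rough lately",
                           "less than i used to",
                           "i usually just shut the door",
                           "i go for long walks mostly",
                           "yeah my mom worries a lot",
                           "just what the doctor gave me",
                           "honestly pretty low these days",
                           "i stay home and cancel plans",
                           "maybe two weeks ago",
                           "fewer bills honestly",
                           "sometimes with my brother",
                           "fine mostly we keep it polite",
                           "it was after the accident",
                           "it depends on the day",
                           "i call my sister",
                           "kind of flat i guess",
                           "yes home is fine",
                           "my kids mostly"),
    clinical_templates = c("well lately i have been %s and it will not stop",
                           "honestly i am %s most days now",
                           "yeah i keep %s ever since last year",
                           "i told my doctor i am %s again",
                           "it is like %s every single week"),
    clinical_templates_emphatic = c(
      "well i have been %s i mean really %s most nights",
      "it is %s again and again just %s over and over",
      "honestly %s all week i keep %s no matter what"),
    cooldown_q = c("okay when was the last time you felt really happy",
                   "cool how would your best friend describe you",
                   "who's someone that's been a positive influence in your life",
                   "what are you looking forward to this year",
                   "is there a place you would love to visit",
                   "what's something you are proud of",
                   "any plans for the rest of the day",
                   "what helps you relax",
                   "do you have a favorite season",
                   "okay i think i have asked everything i need"),
    cooldown_a = c("probably last summer at the lake",
                   "they would say i am quiet but loyal",
                   "my grandmother she always believed in me",
                   "seeing my cousins over the holidays",
                   "i would love to see japan someday",
                   "finishing school while working",
                   "just dinner and a movie at home",
                   "music and a warm shower",
                   "autumn when it cools off",
                   "okay thank you it was nice talking"))
}

#' Generate a seeded synthetic clinical interview
#'
#' Emulates the DAIC-WoZ structure: a neutral rapport-building phase, a
#' clinical middle phase, and a cool-down phase. Each interview draws 2-3
#' presenting-symptom categories; clinical-phase answers embed a phrase from
#' those categories with probability `clinical_rate`, re-using a small
#' per-interview phrase set (interviewers re-ask rephrased questions and
#' patients repeat their symptom language, so planted phrases recur).
#' Anaphoric answers respond to a question from two or more pairs earlier;
#' disfluencies ("uh", "um", "xxx") are injected at `disfluency_rate`.
#' Consecutive participant turns are occasionally split to exercise answer
#' merging. Deterministic given the config seed.
#'
#' @param config A [gen_config()].
#' @param lexicon A `kias_lexicon`; required when `clinical_rate > 0`.
#' @return A `kias_transcript` with attribute `ground_truth`: list with
#'   `clinical_pairs`, `anaphoric_pairs` (0-based pair indices) and `planted`
#'   (data.frame pair_index/category/phrase).
#' @export
generate_interview <- function(config = gen_config(), lexicon = NULL) {
  stopifnot(inherits(config, "kias_gen_config"))
  if (config$clinical_rate > 0 && is.null(lexicon)) {
    kias_abort("generate_interview: lexicon required when clinical_rate > 0")
  }
  set.seed(config$seed)
  banks <- synth_banks()
  n <- config$n_pairs
  n_neutral <- round(config$phases[1L] * n)
  n_cool <- round(config$phases[3L] * n)
  n_clin <- n - n_neutral - n_cool
  phase <- c(rep("neutral", n_neutral), rep("clinical", n_clin),
             rep("cooldown", n_cool))

  # per-interview presenting symptoms: two categories with one or two phrases
  # each, a principal complaint the patient keeps returning to (weighted
  # draw), and a consistent personal phrasing style (2 elaboration
  # templates) — interviewers re-ask rephrased questions and patients repeat
  # their principal symptom in recurring language
  phrase_pool <- character()
  if (!is.null(lexicon) && config$clinical_rate > 0) {
    cats <- sample(names(lexicon$categories), 2L)
    phrase_pool <- unlist(lapply(cats, function(cid) {
      ph <- lexicon$categories[[cid]]$phrases
      stats::setNames(sample(ph, min(2L, length(ph))),
                      rep(cid, min(2L, length(ph))))
    }))
  }
  draw_phrase <- function() {
    if (stats::runif(1L) < 0.6 || length(phrase_pool) == 1L) 1L
    else sample(2:length(phrase_pool), 1L)
  }
  # one plain and one emphatic phrasing per patient; distressed speakers
  # often restate the complaint within a single answer
  template_pool <- c(sample(banks$clinical_templates, 1L),
                     sample(banks$clinical_templates_emphatic, 1L))

  rows <- list()
  gt_clinical <- integer(); gt_anaphoric <- integer()
  planted <- list()
  questions_asked <- character(n)
  add_row <- function(speaker, text) {
    rows[[length(rows) + 1L]] <<- data.frame(speaker = speaker, text = text,
                                             stringsAsFactors = FALSE)
  }
  disfluency <- function(text) {
    if (stats::runif(1L) < config$disfluency_rate) {
      d <- sample(c("uh", "um", "xxx"), 1L)
      if (stats::runif(1L) < 0.5) paste(d, text) else paste(text, d)
    } else text
  }
  # interviewers work through a battery of distinct questions: sample each
  # phase's bank without replacement (reshuffled recycling if exhausted)
  draw_order <- function(size, need) {
    utils::head(unlist(lapply(seq_len(ceiling(need / size)),
                              function(.) sample.int(size))), need)
  }
  phase_order <- list(
    neutral = draw_order(length(banks$neutral_q), n_neutral),
    clinical = draw_order(length(banks$clinical_q), n_clin),
    cooldown = draw_order(length(banks$cooldown_q), n_cool))
  phase_pos <- c(neutral = 0L, clinical = 0L, cooldown = 0L)
  for (i in seq_len(n)) {
    ph <- phase[i]
    # answers are index-aligned with their questions within each bank
    phase_pos[ph] <- phase_pos[ph] + 1L
    qa_idx <- phase_order[[ph]][phase_pos[ph]]
    q <- switch(ph, neutral = banks$neutral_q[qa_idx],
                clinical = banks$clinical_q[qa_idx],
                cooldown = banks$cooldown_q[qa_idx])
    questions_asked[i] <- q
    is_clinical <- ph == "clinical" && length(phrase_pool) > 0L &&
      stats::runif(1L) < config$clinical_rate
    if (is_clinical) {
      j <- draw_phrase()
      a <- gsub("%s", phrase_pool[j], sample(template_pool, 1L), fixed = TRUE)
      gt_clinical <- c(gt_clinical, i - 1L)
      planted[[length(planted) + 1L]] <- data.frame(
        pair_index = i - 1L, category = names(phrase_pool)[j],
        phrase = unname(phrase_pool[j]), stringsAsFactors = FALSE)
    } else {
      a <- switch(ph,
                  neutral = banks$neutral_a[qa_idx],
                  clinical = banks$clinical_neutral_a[qa_idx],
                  cooldown = banks$cooldown_a[qa_idx])
    }
    if (ph == "clinical" && i > 2L && stats::runif(1L) < config$anaphora_rate) {
      # answer picks up a question asked >= 2 pairs earlier
      back <- sample(seq_len(i - 2L), 1L)
      ref <- tokenize_text(questions_asked[back])
      ref <- setdiff(ref, kias_stopwords())
      if (length(ref) > 0L) {
        a <- paste(a, sprintf("like you asked before about %s",
                              paste(utils::tail(ref, 2L), collapse = " ")))
        gt_anaphoric <- c(gt_anaphoric, i - 1L)
      }
    }
    a <- disfluency(a)
    add_row("Ellie", q)
    a_toks <- strsplit(a, " ", fixed = TRUE)[[1L]]
    if (length(a_toks) > 4L && stats::runif(1L) < 0.1) {
      cut <- sample(2:(length(a_toks) - 2L), 1L)
      add_row("Participant", paste(a_toks[1:cut], collapse = " "))
      add_row("Participant", paste(a_toks[(cut + 1L):length(a_toks)],
                                   collapse = " "))
    } else {
      add_row("Participant", a)
    }
  }
  utt <- do.call(rbind, rows)
  utt$speaker <- ifelse(utt$speaker == "Ellie", "interviewer", "participant")
  utt$turn_index <- seq_len(nrow(utt)) - 1L
  tr <- new_transcript(sprintf("synth_%d", config$seed), utt)
  attr(tr, "ground_truth") <- list(
    clinical_pairs = gt_clinical, anaphoric_pairs = gt_anaphoric,
    planted = if (length(planted)) do.call(rbind, planted) else NULL)
  tr
}

#' Write a transcript in the tab-separated dialect
#'
#' Columns start_time, stop_time, speaker, value (DAIC-WoZ layout); times are
#' synthetic. When `sidecar` is given, the generator's ground truth is
#' written next to it as JSON.
#'
#' @param transcript A `kias_transcript`.
#' @param path Output TSV path.
#' @param sidecar Optional JSON path for the ground-truth annotations.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path, sidecar = NULL) {
  utt <- transcript$utterances
  df <- data.frame(start_time = sprintf("%.2f", (utt$turn_index) * 5),
                   stop_time = sprintf("%.2f", (utt$turn_index + 1L) * 5),
                   speaker = ifelse(utt$speaker == "interviewer", "Ellie",
                                    "Participant"),
                   value = utt$text, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- attr(transcript, "ground_truth")
  if (!is.null(sidecar) && !is.null(gt)) {
    jsonlite::write_json(gt, sidecar, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Train a toy add-k trigram model and its ARPA serialization
#'
#' Maximum-likelihood trigram model with add-k smoothing at every order and
#' exact back-off weights, over the closed vocabulary of the corpus plus
#' `<unk>` and the sentence markers. A synthetic stand-in for a large
#' pretrained conversational model; probabilities at each order sum to 1 over
#' the predictable vocabulary.
#'
#' @param corpus Character vector of sentences (normalized text).
#' @param smoothing_k Add-k constant (> 0).
#' @param log_floor Floor log10 probability carried by the model.
#' @return A `kias_lm`.
#' @export
make_toy_lm <- function(corpus, smoothing_k = 0.1, log_floor = -10) {
  if (length(corpus) == 0L) kias_abort("make_toy_lm: empty corpus")
  sents <- lapply(corpus, tokenize_text)
  sents <- Filter(length, sents)
  if (length(sents) == 0L) kias_abort("make_toy_lm: empty corpus")
  k <- smoothing_k
  words <- sort(unique(unlist(sents)))
  pred_vocab <- c(words, "</s>", "<unk>")   # predictable types
  V <- length(pred_vocab)

  uni <- new.env(parent = emptyenv()); bi <- new.env(parent = emptyenv())
  tri <- new.env(parent = emptyenv())
  bump <- function(env, key) env[[key]] <- (env[[key]] %||% 0L) + 1L
  n_tokens <- 0L
  for (s in sents) {
    padded <- c("<s>", "<s>", s, "</s>")
    for (t in 3:length(padded)) {
      bump(uni, padded[t]); n_tokens <- n_tokens + 1L
      bump(bi, paste(padded[t - 1L], padded[t]))
      bump(tri, paste(padded[t - 2L], padded[t - 1L], padded[t]))
    }
    bump(uni, "<s>"); bump(uni, "<s>")  # context occurrences
    bump(bi, "<s> <s>")
  }
  cnt <- function(env, key) env[[key]] %||% 0L

  # unigram distribution over predictable types (excludes <s>)
  p_uni <- stats::setNames(
    (vapply(pred_vocab, function(w) cnt(uni, w), numeric(1L)) + k) /
      (n_tokens + k * V), pred_vocab)

  p_cond_bi <- function(u, w) {
    (cnt(bi, paste(u, w)) + k) / (context_count_uni(u) + k * V)
  }
  context_count_uni <- function(u) {
    # occurrences of u as a context = sum of bigram counts starting at u
    cnt(uni, u)
  }
  p_cond_tri <- function(u, v, w) {
    (cnt(tri, paste(u, v, w)) + k) / (cnt(bi, paste(u, v)) + k * V)
  }

  bigram_keys <- ls(bi); trigram_keys <- ls(tri)
  uni_contexts <- sort(unique(vapply(strsplit(bigram_keys, " "), `[[`,
                                     character(1L), 1L)))
  uni_bow <- stats::setNames(numeric(length(uni_contexts)), uni_contexts)
  for (u in uni_contexts) {
    succ <- vapply(strsplit(bigram_keys[startsWith(bigram_keys, paste0(u, " "))],
                            " "), `[[`, character(1L), 2L)
    succ <- intersect(succ, pred_vocab)  # <s> is never predicted
    num <- 1 - sum(vapply(succ, function(w) p_cond_bi(u, w), numeric(1L)))
    den <- 1 - sum(p_uni[succ])
    uni_bow[u] <- if (den <= 0 || num <= 0) 0 else num / den
  }
  bi_bow <- stats::setNames(numeric(length(bigram_keys)), bigram_keys)
  for (uv in bigram_keys) {
    parts <- strsplit(uv, " ", fixed = TRUE)[[1L]]
    succ_keys <- trigram_keys[startsWith(trigram_keys, paste0(uv, " "))]
    succ <- vapply(strsplit(succ_keys, " "), `[[`, character(1L), 3L)
    num <- 1 - sum(vapply(succ, function(w) p_cond_tri(parts[1L], parts[2L], w),
                          numeric(1L)))
    den <- 1 - sum(vapply(succ, function(w) p_cond_bi(parts[2L], w), numeric(1L)))
    bi_bow[uv] <- if (den <= 0 || num <= 0) 0 else num / den
  }

  lg <- function(x) log10(pmax(x, 10^log_floor))
  unigrams <- lg(p_uni)
  unigrams <- c(unigrams, "<s>" = -99)
  uni_bow_log <- lg_bow(uni_bow)
  bigrams <- stats::setNames(vapply(bigram_keys, function(uv) {
    p <- strsplit(uv, " ", fixed = TRUE)[[1L]]
    lg(p_cond_bi(p[1L], p[2L]))
  }, numeric(1L)), bigram_keys)
  trigrams <- stats::setNames(vapply(trigram_keys, function(uvw) {
    p <- strsplit(uvw, " ", fixed = TRUE)[[1L]]
    lg(p_cond_tri(p[1L], p[2L], p[3L]))
  }, numeric(1L)), trigram_keys)
  new_lm(unigrams, uni_bow_log, bigrams, lg_bow(bi_bow), trigrams, log_floor)
}

# log10 of back-off weights; zero weights floored to a large negative value
lg_bow <- function(x) {
  out <- ifelse(x > 0, log10(x), -99)
  stats::setNames(out, names(x))
}
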