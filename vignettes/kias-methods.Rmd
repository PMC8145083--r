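---
title: "Knowledge-infused abstractive summarization of clinical interviews: models and methods"
author: "kias package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-infused abstractive summarization of clinical interviews: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kias)
```

## The problem

Clinical diagnostic interviews (the DAIC-WoZ corpus is the model here) are
long — around 58 question-and-answer exchanges — noisy, disfluent, and mostly
small talk: the interviewer spends much of the session building rapport before
and after a clinically substantive middle phase. A mental-health professional
reviewing such a session needs the handful of exchanges that carry diagnostic
signal. Purely frequency-driven summarizers fail here for a structural reason:
the clinically decisive utterance ("nobody likes me") may occur exactly once,
while the small talk repeats. `kias` implements an unsupervised summarizer
that injects domain knowledge — a PHQ-9 depression lexicon — at three points
in the pipeline, plus the three baselines needed to measure what that
knowledge buys.

## Pipeline and models

**Templating.** Each interviewer question is paired with the concatenation of
the participant turns that follow it, and the pair is rendered as one
declarative statement: *"participant was asked X, the participant said Y"*,
with second-person pronouns in X rewritten to third person through a fixed
six-entry table (you→they, your→their, yours→theirs, yourself→themselves,
you're→they are, you've→they have). The templated statement is the unit of
all later processing; templating lets a graph ranker see the question and its
answer as one sequence, which matters because answers in these interviews
often address a question asked several turns earlier.

**Pruning.** A statement is kept iff a statement within context radius `r`
(default 1) of it carries a lexicon match. Matches are exact (a lexicon
phrase occurs as a contiguous token window) or semantic: a statement bigram
or trigram whose phrase vector has cosine at least `tau` (default 0.6, a
recall-preferring choice) with some lexicon phrase's vector. Phrase vectors
are means of *content-word* embeddings; stopwords are excluded because in a
short phrase a function word's vector is pure noise and, empirically, lets
phrases like "sick and tired" match any text containing "and". Pairs whose
answer is empty are never counted as evidence but may be kept as context.
Matching runs on generic (non-retrofitted) embeddings; retrofitting enters
later, for scoring. The kept statements — the *pruned conversation* — also
serve as the reference summary during evaluation, since no human-written
references exist for such interviews.

**Slicing.** The pruned statements are partitioned in order into
`k = ceiling(n / window)` slices with sizes as even as possible (differing by
at most one, larger first), each at most `window = 7` pairs — 20 statements
give sizes 7, 7, 6. Seven pairs is the context a clinician judged adequate to
resolve anaphora; one summary sentence is produced per slice.

**Word graph and informativeness.** Each slice's statements are added to a
directed word graph as chains between dummy START and END nodes. Content
words with the same surface form merge into one node — this is what lets
paths fuse material from several statements — under the constraint that one
statement maps at most one token to a node (so every statement remains a
simple START→END walk). Stopwords merge only when both neighbors already
coincide. The template scaffold words *participant*, *asked*, *said* are
merged under the same guard: they occur in every statement, and merging them
freely creates hub nodes that open degenerate paths which skip the question
entirely. Node importance is TextRank with damping `d = 0.78`:

$$Imp(v_i) = (1-d) + d \sum_{v_j \in In(v_i)} \frac{Imp(v_j)}{|Out(v_j)|},$$

iterated from all-ones to tolerance 1e-6 (unweighted edges; traversal counts
are kept for path ranking only). A path's informativeness *I* is the sum of
its words' importance. Candidate paths are the `K = 100` shortest simple
START→END paths under edge cost 1/traversal-count, discarding paths shorter
than `min_len = 8` words and paths that do not pass through *said* with at
least one word after it — the analog, for templated Q&A statements, of the
classical sentence-fusion constraint that a compression must contain a verb:
a candidate must carry an answer segment.

**Knowledge-modulated linguistic quality.** Every word is scored against a
back-off trigram language model (ARPA format, Katz back-off, log floor
$f = -10$ in log10). The Word Semantic Score of a word is its maximum cosine
similarity, clamped to [0, 1], with any word of the depression lexicon,
computed on embeddings *retrofitted* to the lexicon: a synchronous Jacobi
iteration $q_i \leftarrow (\alpha \hat q_i + \sum_j \beta_{ij} q_j) /
(\alpha + \sum_j \beta_{ij})$ over a graph linking words that co-occur in a
phrase or head (first token of) phrases of the same category, with
$\alpha = 1$, $\beta_{ij} = 1/\deg(i)$, 10 iterations — the standard
retrofitting recipe. Quality of a path $p = (w_1, \dots, w_L)$ is

$$Q = 1 - \frac{\sum_t \log_{10} \min\{1,\; p_t (1 + WSS(w_t))\}}{L \cdot f},
\qquad p_t = P(w_t \mid w_{t-1}, w_{t-2}),$$

with sentence-start padding. Q lies in [0, 1], rises with trigram frequency
and with lexicon proximity, and reduces exactly to a generic fluency score
when WSS is identically zero. The displayed forms of the quality and score
equations in the source literature are not machine-readable; the boost
(multiplicative, capped at one) and the floor-normalized "1 − LL" are this
package's declared reconstruction, chosen to preserve every stated property
(boundedness, higher-is-better, lexicon words and frequent trigrams raise Q).

**Selection.** Per slice, one path is selected by the binary program
maximize $\sum_i x_i \frac{I_i + Q_i}{|W(p_i)|}$ subject to
$\sum_i x_i = 1$, $x_i \in \{0,1\}$. Length normalization presses toward
concise sentences. With the one-path constraint the feasible set is the K
unit vectors, so the program is solved exactly by enumerating it; ties break
toward fewer words, then earlier candidate rank. The selected path is
rendered back into "Participant was asked: … Participant said: …" by
splitting at the template boundary.

**Baselines.** SumBasic (extractive): word probabilities c(w)/N, sentence
weight = mean word probability, greedy selection through the highest-
probability word, squaring update after each selection. Plain abstractive
summarization: the identical pipeline with WSS ≡ 0, fed the same pruned
conversation. Abstraction-over-extraction: SumBasic keeps the top
`es_fraction` (default 0.5) of statements before the plain pipeline runs.

## Evaluation suite

Reference = pruned conversation. Metrics: Flesch Reading Ease
(206.835 − 1.015·words/sentence − 84.6·syllables/word, with a deterministic
vowel-group syllable heuristic and silent-e correction, so scores are
bit-reproducible); Jensen–Shannon divergence (base 2, bounded [0, 1])
between LDA topic distributions; cosine contextual similarity of mean word
vectors; thematic overlap (dominant topics = posterior above 1/k; overlap =
|summary's top-terms ∩ reference's top-terms| / |reference's|, top 10 terms
per dominant topic — the literature cites no formula for this score, so the
definition here is declared); ROUGE-1/2/L recall and F1 with clipped n-gram
counts and an LCS dynamic program. The LDA is a collapsed Gibbs sampler
(Rcpp) with a deterministic fixed-point fold-in for held-out documents, and
the number of topics is selected by a C_V-style coherence: sliding-window
(10 tokens) NPMI context vectors over each topic's top 10 terms, compared by
cosine. The scan range defaults to 2–20 in steps of 2 at desk scale; the
selection criterion is the point, not the scan stride.

## The synthetic-interview generator

The generator is first-class, tested code; it defines the study conditions
under which the package's claims are checked.

What it emulates: a neutral → clinical → cool-down arc with phase
proportions (0.25, 0.55, 0.20); ~58 Q&A pairs per interview; an interviewer
battery of distinct questions (each phase samples its bank without
replacement, as the DAIC-WoZ agent works through a fixed question set);
clinical-phase answers that carry a depression-lexicon phrase with
probability `clinical_rate` (default 0.3); per-interview presenting
symptoms — two lexicon categories, with a principal complaint drawn at 60%
and re-stated across answers in one plain and one emphatic per-patient
template (the emphatic form repeats the phrase within the answer, as
distressed disfluent speech does); anaphoric answers that respond to a
question at least two pairs back (rate 0.1); disfluencies "uh"/"um"/"xxx"
(rate 0.15); and occasional splitting of an answer across two participant
turns. A ground-truth sidecar records which pairs were planted.

Companion fixtures: a nine-category toy PHQ-9 lexicon (a synthetic stand-in,
not the published lexicon); 300-dimensional synthetic embeddings
(the dimensionality of ConceptNet Numberbatch) in which distinctive clinical
words of a category share a direction with pairwise cosine ≈ 0.9 while
function words and everyday vocabulary stay random — real embedding spaces
do not place "much" or "time" next to clinical terms, and at 300 dimensions
the max-cosine noise floor of a random word against ~60 lexicon words is
about 0.16, low enough that the WSS boost tracks clinical content rather
than noise; and an add-k (k = 0.1) trigram model with exact back-off
weights trained on the interview statements and serialized as valid ARPA.

What the generator does *not* emulate: real patient language (vocabulary is
bank-limited), semantic paraphrase between question variants, transcription
errors beyond the "xxx" convention, audio/video modalities, and
corpus-scale topical diversity. Tests passing on this fixture therefore
show that the machinery behaves as specified under controlled conditions —
pruning recall, selection behavior, metric directions — not that
corpus-level scores on the restricted data would be reproduced.

## Numerical choices and degenerate inputs

* TextRank: tolerance 1e-6, at most 100 iterations, all-ones start;
  non-convergence returns the last iterate with a warning.
* Path enumeration: deterministic; ties in cost break lexicographically on
  the word sequence.
* LM: log10 throughout; floor −10 for out-of-vocabulary words (the floor is
  returned directly, without adding back-off weights); `<s>` padding.
* Retrofitting: the Jacobi update is not stepwise monotone — it overshoots
  and converges in damped oscillation — so the tested contraction property
  is that every iterate exceeds the random-initialization similarity.
* NPMI: natural log, Bouma normalization, p(ngram) = 1 returns 1 by
  continuity; zero-count n-grams are errors, not zeros.
* Degenerate inputs: an empty statement list prunes to an empty conversation
  (not an error); a transcript with no lexicon match yields an empty summary
  with status `"no clinical content"`; a slice whose every candidate is
  filtered is skipped with a warning and the summary status records it.
* JSD requires inputs that sum to one (tolerance 1e-6); disjoint supports
  give exactly 1 in base 2.

## Design decisions that were genuinely open

* **Multi-question interviewer turns** are treated as one question; the
  transcripts give no marker to split on.
* **Pruning operates on the combined statement** (question + answer), so a
  clinically relevant question with a bland answer is retained.
* **"Divided evenly"** is read as ceiling(n/window) balanced slices, larger
  first — the only reading consistent with 20 → (7, 7, 6).
* **WSS is word-level** (every word of every phrase), and negative cosines
  clamp to zero so the score can multiply probabilities.
* **The ILP is solved by feasible-set enumeration.** With one path per slice
  the program is an argmax; the binary-program formulation is kept so that
  inter-slice constraints (e.g., redundancy penalties) can be added later.
* **Semantic phrase vectors use content words only** (see Pruning above);
  the all-stopword phrase falls back to the full word set.
* **ES baseline input** defaults to pruned conversations (the same input the
  abstractive systems receive), with a flag to run on raw statements.

## Known limitations

The knowledge boost moves Q by at most log10(2)/|f| per word, while
informativeness differences between candidate paths are typically an order
of magnitude larger, so KiAS and the plain abstractive baseline coincide on
most slices and differ only on near-ties; directional comparisons between
them (JSD, thematic overlap) are correspondingly small — consistent with the
single-digit relative improvements reported for this family of methods — and
the decisive knowledge effects are in pruning and in what the boost does on
ties. Fused paths can still attach an answer to a related question from the
same slice (the summaries are screening aids, not records). The package's
problem sizes (20 interviews of 58 pairs, topic scans to k = 12 or 20) are
desk-scale choices; every routine accepts larger inputs.

## A worked run

```{r, eval = FALSE}
lex <- make_toy_lexicon()
tr <- generate_interview(gen_config(seed = 1, n_pairs = 58,
                                    clinical_rate = 0.3), lex)
stmts <- statements_from_transcript(tr)
emb <- make_embeddings(unique(unlist(lapply(stmts$statement, tokenize_text))),
                       lexicon = lex, seed = 1)
emb_r <- retrofit_embeddings(emb, build_lexicon_graph(lex))
lm <- make_toy_lm(stmts$statement)
pruned <- prune_statements(stmts, lex, emb, conversation_id = "demo")
kias_summarize(pruned, list(lexicon = lex, embeddings = emb_r, lm = lm))
```
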