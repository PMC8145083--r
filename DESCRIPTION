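Package: kias
Title: Knowledge-Infused Abstractive Summarization of Clinical Diagnostic Interviews
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Unsupervised abstractive summarization of question-and-answer
    structured clinical diagnostic interviews (DAIC-WoZ-style transcripts).
    Interview turns are templated into declarative statements, pruned against a
    PHQ-9 depression lexicon, partitioned into fixed-size slices, and fused in a
    per-slice word graph. Candidate paths are scored by TextRank informativeness
    and by a trigram language-model linguistic quality in which word
    probabilities are boosted by Word Semantic Scores from lexicon-retrofitted
    embeddings; one path per slice is selected by an integer linear program.
    Ships the SumBasic extractive baseline, plain abstractive summarization,
    abstraction-over-extraction, seeded synthetic interview fixtures, and an
    evaluation suite (Flesch Reading Ease, LDA topic coherence, Jensen-Shannon
    divergence, contextual similarity, thematic overlap, ROUGE-1/2/L).
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
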