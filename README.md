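# litlinkr

Literature-based discovery (LBD) over corpora of scientific abstracts,
for researchers who want to surface candidate connections — disease to
drug, process to gene — that the literature implies but never states in
a single paper.

litlinkr implements the A–B–C co-occurrence model. An **open** search
takes a source concept A, finds intermediate concepts B that co-occur
with it unusually often, then finds target concepts C tied to those
intermediates — a hypothesis generator. A **closed** search takes A and
C and reports the intermediates B significantly linked to both — a
mechanism finder. Association between two terms is scored on their 2×2
abstract-count table with the one-sided Fisher's exact test,

p = P(X ≥ a),  X ~ Hypergeom(N, n_x, n_y),

computed in log space so p-values far below double underflow remain
exact (anything under 2.2×10⁻³⁰⁸ displays as `0`). Stage-1 A–B pairs
must pass p < 1e-5 (at most 300 survive, smallest p first); each
(A, B, C) chain is ranked by a prediction score — the fraction of the C
literature that also mentions B, gated by B–C significance. Matching is
exact, case- and punctuation-insensitive, phrase-aware (positional
inverted index), synonym-set based, and optionally restricted to
abstracts published at or before a cutoff year. Significant pairs can
be annotated with typed relations (TREATS, INHIBITS, POS_ASSOCIATION,
…) from a knowledge-graph triples file, each with evidence PMIDs.

A synthetic-corpus generator with planted co-occurrence structure makes
the whole pipeline testable without any external data.

## Worked example

Generate a corpus with a planted chain (condalpha → phenobeta →
druggamma, plus ten decoy terms), index it, and run an open search:

```r
library(litlinkr)

spec   <- corpus_spec(planted_chain = planted_chain(), seed = 42)
corpus <- generate_corpus(spec)
index  <- build_corpus_index(corpus$docs)
index
#> <corpus_index>
#>   documents: 1000
#>   distinct tokens: 1515
#>   years: 1975-2020 (1000 known)

ch      <- spec$planted_chain
a_terms <- term_list(ch$a)
b_terms <- do.call(term_list, as.list(c(ch$b, ch$decoys)))
c_terms <- do.call(term_list, as.list(c(ch$c, ch$decoys)))

hits <- open_discovery(index, a_terms, b_terms, c_terms)
tidy(hits)[1:3, c("b_label", "c_label", "ab_p_value", "bc_p_value",
                  "bc_ratio", "prediction_score", "rank")]
#> # A tibble: 3 × 7
#>   b_label   c_label     ab_p_value bc_p_value bc_ratio prediction_score  rank
#>   <chr>     <chr>            <dbl>      <dbl>    <dbl>            <dbl> <int>
#> 1 phenobeta druggamma     2.20e-47   6.69e-35    0.758            0.758     1
#> 2 phenobeta decoyterm01   2.20e-47   8.03e- 3    0.246            0         2
#> 3 phenobeta decoyterm02   2.20e-47   2.89e- 2    0.224            0         3
```

The planted chain is recovered at rank 1: the A–B link passes the 1e-5
filter (p ≈ 2e-47), the planted B–C pair is overwhelmingly significant
(p ≈ 7e-35, displayed as `7e-35` by `format_p()`), and its prediction
score of 0.758 says that 75.8% of the abstracts mentioning the target
also mention the intermediate. The decoys' B–C p-values (0.008, 0.03)
fail the significance gate, so they score 0 and rank below.

`closed_discovery(index, a, c, b_terms)` answers the inverse question;
`annotate_hits(hits, read_kg_relations("triples.tsv"))` decorates
significant pairs with typed relation labels; `autoplot()` methods draw
pair volcanoes and ranked-hit bars. A command-line interface wraps the
same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/litlink.R", package = "litlinkr"))')" \
  skim --mode open --corpus corpus.jsonl \
  --a-terms a.tsv --b-terms b.tsv --c-terms c.tsv --out results
```

Subcommands: `index`, `km` (single-stage pair search), `skim`
(`--mode open|closed`), `annotate`, `simulate` (fixture generation).
See `vignettes/discovery-methods.Rmd` for the model, parameter
defaults, numerical choices, and limitations.

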