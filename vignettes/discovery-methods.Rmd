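---
title: "Serial co-occurrence discovery: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial co-occurrence discovery: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litlinkr)
```

## The problem

Literature-based discovery (LBD) looks for implicit connections between
concepts that are each well documented but rarely discussed together. The
classic formulation is the A–B–C model: if a source concept A (say, a
disease) is repeatedly linked to intermediates B (phenotypes, processes),
and those same B terms are linked to candidate targets C (say, drugs),
then A and C may be related even if no single abstract mentions both.
litlinkr implements this model over any corpus of titled abstracts: an
*open* search takes A and ranks candidate C terms (hypothesis
generation), and a *closed* search takes A and C and reports the B terms
that connect them (mechanistic explanation).

## The statistical model

All evidence is document-level co-occurrence. For a pair of terms the
corpus is summarized by a 2×2 table of abstract counts — both terms,
each term alone, neither — and association is scored with the one-sided
Fisher's exact test. With $a$ co-occurrence documents, margins $n_x$ and
$n_y$, and $N$ eligible documents,

$$p = P(X \ge a), \qquad X \sim \mathrm{Hypergeom}(N,\, n_x,\, n_y),$$

the enrichment tail including the observed table. The exact test is used
for every pair regardless of table size because term-occurrence tables
are routinely sparse; the asymptotic chi-square test (`chi_square()`) is
provided only as a documented, non-canonical alternative and flags
zero-margin tables rather than returning an undefined statistic. No
multiple-testing correction is applied: the procedure filters on the raw
p-value at a deliberately severe threshold (below), and its output is a
ranked hypothesis list, not a family of confirmatory tests.

The serial search proceeds in two stages. Stage 1 tests A against every
B and keeps pairs with $p$ strictly below the stage-1 threshold; if more
than the cap survive, the smallest-p subset is kept. Stage 2 tests every
surviving B against every C. Each (A, B, C) chain is ranked by a
**prediction score** for its B–C pair:

$$\mathrm{score}(B, C) = \begin{cases}
  n_{BC} / n_C & p_{BC} < \text{threshold} \\
  0 & \text{otherwise,}
\end{cases}$$

i.e. the fraction of the C literature that also mentions B, gated by
significance. The two ingredients (the exact-test p-value and the
$n_{BC}/n_C$ ratio) are standard for this family of methods; the precise
combination rule is a design choice of this package, chosen because it
is scale-free, bounded in $[0,1]$, and separates "how strongly is this C
tied to an intermediate" from "is the tie statistically real". Ties are
broken by ascending B–C p-value and then by labels, so ranking is a
total deterministic order and reruns are byte-identical.

## Matching and indexing

Matching is exact, case-insensitive, and punctuation-insensitive, with
no stemming or lemmatization. One normalizer is used everywhere
(indexing, querying, knowledge-graph names): NFC-normalize, lowercase,
split on maximal runs of non-word characters (Unicode letters, digits,
underscore). A concept is a label plus a synonym set; a document matches
a concept if it contains any synonym as consecutive tokens, and counts
once however many synonyms hit.

The index is positional: token → document → positions, title tokens
first, then abstract tokens after a one-position gap so phrases cannot
match across the title/abstract boundary (whether such matches should
count is genuinely ambiguous; we chose the conservative reading). The
persisted form is a versioned JSON container; the contract is
query-result equivalence after a round trip, not bit-stable layout.

Date-restricted queries (`cutoff_year`) are inclusive and drop
documents with unknown publication year — conservative for historical
rediscovery experiments, where leaking a post-discovery abstract is a
worse error than dropping an undated one. Restricting a query with a
cutoff is exactly equivalent to querying an index built from only the
eligible documents, and this equivalence is tested.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ab_p_threshold` | 1e-5 | stage-1 significance filter (strict `<`) |
| `max_b_pairs` | 300 | cap on intermediates entering stage 2, smallest p first |
| `bc_p_threshold` | 1e-5 | significance gate inside the prediction score |
| `cutoff_year` | none | inclusive publication-year restriction |
| `association_measure` | `"fet"` | exact test; `"chi2"` as a diagnostic alternative |

The 1e-5 threshold and 300-pair cap are the method's conventional
operating point: severe enough that chance co-occurrence in a
multi-million-abstract corpus rarely passes, and a cap that keeps stage
2 tractable when A is a heavily studied concept. The cap is applied per
A term when several A terms are searched, after thresholding.

## Numerical choices

The hypergeometric tail is accumulated in log space (log-sum-exp over
`lchoose` terms), so p-values are accurate far below the smallest
normal double. The table orientation is canonicalized before summation,
making the p-value bit-invariant under transposition — which in turn
makes open and closed discovery agree bit-exactly on shared pairs. A
p-value whose magnitude is below ~1e-320 underflows to numeric 0
deterministically, and the display convention (`format_p()`) prints any
value below 2.2e-308 as `"0"`, with one-significant-figure scientific
notation otherwise. A pair in which either term matches no document is
reported with $p = 1$ and flagged, not dropped. Chains whose B and C
labels coincide are suppressed as trivial self-links.

## Knowledge-graph annotation

Co-occurrence finds *that* two terms travel together, not *why*. An
optional relation-triples file (typed entities from the closed
five-label set, typed directed relations from the closed ten-label set,
each with evidence PMIDs) is loaded into an in-memory graph and used to
decorate significant pairs with relation labels. Entity names are
normalized with the corpus normalizer, and matching is exact — fuzzy
matching would silently change the semantics of a label. Orientation is
reported for directed relations; `COREF`, `POS_ASSOCIATION`, and
`NEG_ASSOCIATION` are displayed as symmetric. Annotation is a pure
decoration: it never changes a p-value, score, or rank, and a pair
without annotations is still a valid hit.

## What the synthetic corpus emulates

Real bibliographic corpora are large and not redistributable, so the
package ships a generator (`corpus_spec()`, `generate_corpus()`) that
produces the features the engine actually consumes: a skewed background
vocabulary (Zipf weights $1/k^{1.1}$, mimicking natural token-frequency
skew), uniform publication years, and planted term structure with exact
per-document ground truth. Planted pairs land in the
both/x-only/y-only/neither categories with specified probabilities;
a planted chain adds correlated A–B and B–C occurrences plus
independent decoy terms. Default study conditions, fixed once: 1000
documents of 40–80 background tokens, joint rates 0.05 against
singleton rates 0.02, ten decoys at 0.05. Under these conditions the
planted A–B pair passes 1e-5 and the planted C is rank 1 in essentially
every seed, while the null battery (200 independent pairs in 2000
documents) keeps the fraction of $p < 0.05$ at or below nominal — the
exact test is conservative.

The generator does not emulate linguistic structure, MeSH indexing,
synonymy drift, temporal publication trends, or the heavy-tailed
document-frequency profile of real biomedical entities. Passing tests
therefore demonstrate the *engine's* correctness and calibration, not
end-to-end discovery performance on PubMed-scale data.

## Problem sizes used in the checks

The exact test is verified against direct hypergeometric summation on
all 40,920 tables with total count ≤ 29; calibration uses 200
independent pairs in 2000 documents; chain recovery uses 50 generator
seeds at the default conditions; the stage-1 cap is exercised with a
constructed corpus of 400 significant A–B pairs, of which exactly the
300 smallest by p must survive. These sizes give stable, fast, and
fully reproducible checks.

## Known limitations

* Document-level co-occurrence cannot distinguish negated, speculative,
  or incidental mentions from substantive ones; false positives are
  expected and the output is a ranked reading list, not a verdict.
* Exact matching makes recall depend entirely on synonym-set quality;
  there is no concept normalization (UMLS/MeSH) and deliberately no
  stemming.
* Ambiguous short tokens (gene symbols that are also common words)
  inflate counts; curate synonym lists accordingly.
* The chi-square alternative is unreliable at small expected counts and
  is included for comparison only.
* The prediction score is one reasonable instantiation of
  "significance-gated coverage"; other monotone combinations would
  reorder ties among strong hits.
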