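---
title: "Ranked noun phrases as citation-validated search terms: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked noun phrases as citation-validated search terms: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnav)
```

## The problem

A paper's reference list is a small, frozen slice of its related
literature. Bibliographic search engines order results by recency and a
"related articles" service returns one opaque ranked list. `litnav`
implements a transparent alternative: turn the paper's own wording into
quoted search terms, and score each term by whether its top results
recover any of the paper's author-supplied citations. A term that
independently re-finds cited work — especially work by entirely different
authors — is evidence that the rest of its results are worth a reader's
attention, and the term itself explains *why* the results are related.

## Candidate phrases

Extraction proceeds in the classical chunking style:

1. sentence splitting (regex boundaries with an abbreviation list:
   `Dr.`, `Fig.`, `e.g.`, ...);
2. word tokenisation that keeps hyphenated symbols (`XAG-2`, `hAG-2`)
   whole and emits punctuation as separate tokens, so phrases never cross
   a comma or period;
3. part-of-speech tagging through a minimal contract — any function from
   tokens to fine tags plus a map reducing fine tags to
   `NOUN`/`ADJ`/`OTHER`. The package ships a small rule-and-lexicon
   English tagger whose bias (unknown words are nouns) suits technical
   prose; taggers of this class mis-tag a noticeable fraction of tokens
   and those errors are deliberately left to flow through rather than
   patched downstream;
4. candidate selection: every single noun, every single adjective, and
   every contiguous sub-span of an adjective/noun run that ends in a noun
   (`AN`, `NN`, `ANN`, ... patterns), up to `max_phrase_len = 5` tokens
   (the longest useful printed example term has four).

Counting is per sub-span occurrence: a phrase embedded in a longer noun
run is counted at every position. Sub-span counting (rather than counting
maximal chunks only) is a deliberate choice: the printed example terms
from the worked example ("laevis cement", "laevis cement gland",
"Xenopus laevis cement gland") are nested sub-spans of one run, which
shows sub-spans must at least be *emitted*; we also *count* them per
occurrence, which keeps `doc_count` monotone under containment.

Case is folded for counting and background lookup; the original surface
form is kept for display. Single-adjective candidates are extracted but
excluded from search-term selection by default — their value as quoted
queries is undemonstrated.

## Contrastive ranking

Each distinct phrase contributes a point $(x, y)$ with
$x = \log_{10}(\mathrm{bg} + 1)$ (background/web count, +1 to admit
never-seen phrases) and $y = \log_{10}(\mathrm{doc})$ (in-document
count). A line $y = mx + c$ is fitted by quantile regression, i.e. by
minimising the pinball loss

$$\sum_i \rho_\tau(y_i - m x_i - c), \qquad
\rho_\tau(r) = r\,(\tau - \mathbf{1}[r < 0]),$$

and each phrase is scored by its residual $y' - mx - c$: how far its
document count sits *above* what its background frequency predicts. The
default $\tau = 0.5$ (median regression) is our choice — the canonical
default when no level is prescribed — and is exposed as configuration.

Numerical notes:

* An optimal line interpolates two observations with distinct $x$ (a
  basic solution of the equivalent linear program). After collapsing
  duplicate points into weights — extremely effective here, as most
  phrases have `doc_count` 1 and repeated background counts — the fitter
  enumerates all candidate pair lines exactly when at most 150 unique
  points remain; larger problems use convex coordinate descent
  (weighted-quantile updates for intercept and slope, valid for
  $x \ge 0$) followed by an active-set pair-enumeration polish around the
  incumbent. Tests hold the fitter to within $10^{-6}$ of an independent
  zoom-grid oracle.
* Ties in the score are broken by `doc_count` descending, then
  `bg_count` ascending, then lexicographic phrase order (C collation),
  so a ranking is a deterministic function of the phrase set.
* If all phrases share one background count the design is degenerate;
  ranking falls back to a constant fit ($m = 0$, $c$ = the
  $\tau$-quantile of $y$), which orders phrases by document count.

A TF-IDF-style comparator `doc_count / log10(bg_count + 10)` is provided
(+10 keeps the denominator $\ge 1$ and finite at zero background); on
generated documents its ordering correlates positively with the residual
ranking, which is the behaviour that motivates offering both.

Phrases are stratified by background count into **broad** (> 10 million),
**specific** (100 to 10 million) and **rare** (< 100). The source
description leaves the boundary membership open; both boundaries are
closed into *specific* so the three bins partition the non-negative
integers. Search terms are the top 20 specific and top 20 rare phrases
(at most 40 per paper).

## Search and citation validation

Quoted searches are exact contiguous token-sequence matches over title
plus abstract (matching remote field-restricted queries), case
insensitive, ordered by publication date descending with ties by id
descending — the recency ordering readers actually face — and truncated
to the top 20. A local inverted index serves tests and offline runs; an
E-utilities-style remote adapter with a JSON response cache serves live
runs, and published results must replay from cache.

For each term the **overlap** is the intersection of its results with
the paper's author-supplied citations; a result equal to the paper
itself is flagged a *self hit*, not an overlap. A validated term is
**CV-D** if *any* validating citation has an author set entirely
disjoint from the paper's (different-author validation takes precedence,
so D/S partitions validated terms); otherwise **CV-S** (shared-author
validators, or a self hit only). Author identity is surname plus first
initial, case-folded and diacritic-stripped — the only key reproducible
from typical citation exports. A validating citation with no author data
is conservatively counted shared-author, with a warning.

Per-paper tallies include the distinct validating citations pooled
across terms (self hits included, since the worked example labels the
paper's own record as an S validator) and the counts of validated terms
whose non-overlapping results number under 5, under 20, or over 20.
Because displayed lists truncate at 20, the non-overlap sizes use the
*untruncated* hit count minus validating citations and self hits.
Corpus summaries report percentages of papers with the stated property,
with 95% Wald (normal-approximation) intervals rounded outward to whole
percents — Wilson is available by configuration — and means with
*sample* standard deviations for the count metrics. Papers with fewer
than 5 citations are excluded before evaluation: validation is
uninformative against a near-empty reference list.

## The chance-validation null

If the top $k$ results of a search were $k$ independent uniform draws
from an $N$-document corpus, a paper with $C$ citations would be
validated with probability

$$p = 1 - (1 - C/N)^k \approx kC/N.$$

At the reference scale ($C = 100$, $N = 18{\,}000{\,}000$, $k = 20$)
this is about $1.1 \times 10^{-4}$ — under 0.02%, or less than 1 in
5000 searches — which is what makes an observed validation informative.
`random_cv_probability()` evaluates the formula (and exposes the linear
approximation); `shuffle_citations()` plus `simulate_null_cv()`
construct the matching Monte-Carlo experiment.

## What the synthetic generator emulates

Real corpora of this kind cannot be redistributed or re-crawled, so the
generator builds corpora with the structural features the method relies
on:

* **Zipf background counts.** Unigram background counts follow
  $\mathrm{count}(r) \propto r^{-s}$ with $s = 1.2$, scaled so the head
  of the vocabulary is *broad* and the bulk *specific*.
* **Rare planted signatures.** Each topic owns two-token signature
  phrases with background counts below 100 (*rare* stratum); each paper
  plants one in its body 3–6 times, mimicking a paper's own key phrase.
* **Topic-coherent citations.** Citations are drawn within-topic with
  probability 0.9, 5–8 per paper.
* **Phrase sharing.** Each topic signature enters each topic-mate's
  searchable abstract independently with probability
  `phrase_share_prob` (default 1). At 0 the text-level link between
  citing and cited papers is severed, which is the generator's null
  regime.
* Dates are uniform over a decade; every paper has its own synthetic
  author set, so cross-paper validation is different-author by
  construction. Documents are emitted as pre-tagged token streams (plus
  plain text), so extraction tests are isolated from tagger error; a
  prefix-based perfect tagger supports full-stack runs on the plain
  text.

Default sizes are 250 papers in 25 topics. The size is not arbitrary:
the per-paper chance-validation probability under the shuffled null
scales like (union of search results × C)/N, and at much smaller N the
null *saturates* (nearly every paper is chance-validated), making
signal-versus-null comparisons meaningless. 250 papers puts the
shuffled-graph rate around 60–75%, well off saturation, while a full
pipeline run stays around three seconds. Abstract filler words are drawn
uniformly rather than Zipf-weighted — abstracts carry distinctive
vocabulary — which also keeps common-word searches from flooding the
result union. The null-calibration experiment uses the fixed design
$N = 2000$, $C = 20$, $k = 20$, 10,000 searches, where the analytic rate
(≈ 18.2%) is estimated with Monte-Carlo standard error ≈ 0.4%.

What the generator does **not** emulate: linguistically real sentences,
realistic date/citation-age structure, shared authorship across papers,
tagger error (by design), and web-scale background noise. Passing the
recovery tests therefore demonstrates the pipeline's mechanics — ranking
lifts planted rare signatures, searches recover topic-mates, validation
separates a true citation graph from a shuffled one — not performance on
real prose.

## Degenerate inputs and tie-breaks

* Empty documents or documents with no noun/adjective tokens produce an
  empty phrase table and a zero-valued report with a warning, not an
  error.
* A tagger failure on one sentence skips that sentence (fault isolation)
  with a warning.
* Background lookup is total: unknown phrases count 0, which lands them
  in the *rare* bin — the correct bias for coined terms.
* Candidate lists longer than 20 are truncated with a warning;
  duplicate citation-table rows collapse with a warning.
* References without PubMed-style ids are dropped (overlap is computed
  on ids), and reference-list text never enters the extraction body, so
  cited titles cannot inflate phrase counts.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run entirely offline at desk
scale: 200 random fit instances against the grid oracle, 1000 random
tag sequences against the brute-force chunker, the fixed
$N = 2000$/10,000-search calibration, and 100 generator seeds (20 in the
script) for signal recovery at the 250-paper default. The corpus-scale
percentages reported on real literature by the method's original
evaluation (86% CV-D for search terms versus 65% for a related-citations
service, over 883 papers) depend on a live web-scale corpus and are out
of reach of an offline build; the packaged checks instead verify the
machinery those numbers rest on.

## Known limitations

* The shipped tagger is intentionally small; for serious use wrap a
  trained tagger in `make_tagger()`.
* Quoted matching is surface-exact: no stemming, no terminology-variant
  expansion (a known future direction for the method).
* Phrase pair/triple combinations (k ≥ 2 query combination) are out of
  scope; only single-phrase terms are generated.
* The display convention plots document count on the x axis and
  background count on the y axis while the regression predicts log
  document count from log background count; `plot.ranked_phrases()`
  follows the display convention and draws the fitted line transformed
  into it.
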