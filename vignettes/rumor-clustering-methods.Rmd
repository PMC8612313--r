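---
title: "Methods: clustering near-duplicate messages into rumor groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering near-duplicate messages into rumor groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumormill)
```

# The problem

Fact-checking chatbots on closed messaging platforms collect user-reported
suspicious messages. One narrative — one *rumor* — arrives as hundreds or
thousands of near-duplicate texts: forwarded copies, copies with a changed
date or a swapped authority figure, copies with added exhortations.
Propagation analysis (when does a rumor resurface? how does its wording
drift? whom does it quote?) needs those messages grouped by narrative
first. This vignette documents the models and conventions rumormill uses,
the parameters that matter, and what the package's synthetic evaluation
does and does not establish.

# Preprocessing

Pipeline order is fixed: character filter → tokenize → stop-word removal →
length filter. The character filter keeps CJK Unified Ideographs (both
simplified and traditional forms live there; no conversion between scripts
is attempted at this stage — script *detection* happens later, on the raw
text). Tokenization is pluggable because any dictionary-based Chinese
segmenter bakes its dictionary into every downstream number: the packaged
default is a forward-maximum-matching segmenter over an editable word
list, while synthetic corpora of word symbols use whitespace splitting, so
no test result depends on a segmentation dictionary.

The length filter keeps documents with at least `min_tokens = 20` tokens,
counted *after* stop-word removal. Whether the floor should apply before
or after stop-word removal is genuinely open; counting after is the
stricter reading (it guarantees 20 informative tokens) and is what the
pipeline order above implies. Token-set distances degrade on short texts —
a single shared token moves a 20-token pair by 5 percentage points but a
5-token pair by 20 — which is why the floor exists at all; the method
should not be expected to work well on short messages.

# The distance

$$d(A,B) = 1 - \frac{|tok(A)\cap tok(B)|}{\max(|tok(A)|,|tok(B)|)}$$

computed on *distinct-token sets* (binary word vectors; token order and
multiplicity are deliberately ignored — near-duplicate detection, not
topical similarity). The max-normalizer is the load-bearing choice: with
`min` in the denominator, a message wholly contained in a longer one would
be at distance 0 from it, and combined messages (two rumors concatenated)
would collapse into one of their parts. With `max`, the overlap must
dominate **both** messages. The normalizer stays configurable
(`max`/`min`/`union`) for sensitivity analysis; `union` gives plain
Jaccard. Empty token sets have no meaningful distance and raise an error.

Pairwise matrices are built by sparse binary cross-products
(`Matrix::tcrossprod` on the document-term matrix), which the test suite
pins elementwise to the naive two-set computation at 1e-12.

# Threshold HAC

Agglomerative clustering merges while the minimum inter-cluster linkage
distance is ≤ λ and stops when every remaining pair exceeds λ; cluster
count is thus data-driven. Defaults:

* **λ = 0.6.** Two messages at the threshold share 40% of the larger
  message's vocabulary. Between-group distances in near-duplicate corpora
  sit near 1 and within-group distances near 0, so results are flat over a
  wide λ band; 0.6 sits in the middle of that band.
* **Linkage = average** (configurable: complete, single). A linkage had to
  be chosen here: the common library default for agglomerative clustering
  (Ward) requires Euclidean geometry and cannot run on a precomputed set
  distance. Average linkage is the robust middle ground — single linkage
  chains through combined messages, complete linkage shatters groups with
  one outlying variant.

Implementation rides on `stats::hclust` with the tree cut at height λ.
Average-linkage merge heights are monotone in exact arithmetic but can
carry ~1e-16 floating-point jitter; decreases up to 1e-8 are clamped
(`cummax`) before cutting, and anything larger is an error rather than
silently reordered.

# Classification-based clustering

Full HAC needs the full distance matrix. The hybrid algorithm clusters
exactly only a uniform random sample of fraction `u`:

1. draw ⌊u·n⌋ documents without replacement (seeded);
2. HAC at λ on the sample;
3. relabel sample singletons to the sentinel −1;
4. train a KNN classifier on the sample *including* the −1 labels and
   predict the holdout — so holdout documents nearest to noise are
   themselves routed to noise;
5. collect everything labelled −1 and run a second HAC pass at λ on it,
   with labels offset past all first-pass labels;
6. documents still alone keep their own fresh label.

Conventions the algorithm sketch above leaves open, fixed here:

* **KNN metric** is the same token-set distance (consistency with the
  clustering geometry); votes are uniform, `k = 5`; distance ties resolve
  by sample order (stable), vote ties toward the smallest label id, with
  −1 counting as smallest — biasing ambiguous documents toward the
  second pass rather than into an arbitrary group.
* **Sampling** is uniform without replacement, but the drawn indices are
  *sorted* before use: the randomness decides membership only. This makes
  `u = 1` reduce to full HAC *exactly* — with a permuted sample, tied
  distances let `hclust`'s order-dependent tie-breaking produce a
  different (equally valid) merge order, and the reduction invariant held
  only up to ties.
* A sample with no non-singleton cluster cannot train a classifier; the
  whole corpus then goes to the second HAC pass.
* Second-pass singletons are legitimate size-1 groups, not errors; the
  sentinel −1 never appears in a final labeling.

Why the second pass cannot undo the first: when HAC stops, every pair of
remaining clusters — including singleton clusters — is separated by more
than λ, so re-running HAC on the leftovers alone cannot merge documents
that full HAC would have kept apart (at `u = 1`), and first-pass labels
are never revisited.

# Evaluation

The hybrid is scored against full HAC on the same corpus, so the gold
standard is always available by construction. rumormill uses
**pairwise co-membership** metrics: over all unordered document pairs,
precision = TP / predicted co-pairs, recall = TP / gold co-pairs, F =
harmonic mean. This is the standard clustering-comparison choice and
matches the gloss that recall measures completeness of groups and
precision the errors introduced into groups. Degenerate conventions: no
predicted co-pairs → precision 1 iff the gold also has none, else 0
(symmetrically for recall); F = 0 when P + R = 0. Alternatives (BCubed,
best-match) would give different absolute numbers, so fidelity scores
should only be compared across runs that use the same metric; the choice
is therefore documented loudly rather than hidden.

`fidelity_benchmark()` reports per-`u` means and normal-approximation 95%
intervals over repetitions with derived seeds. Wall-clock comparisons
(`runtime_benchmark()`) are hardware-dependent and intentionally produce
no headline numbers.

# Annotation conventions

* **Keyword matching** runs on the *raw* text, lowercased, as plain
  substring: the packaged 33-term lexicon contains latin terms ("covid",
  "coronavirus") that the Chinese character filter would delete, so
  tagging cannot run on filtered text. Chinese keywords have no word
  boundaries to respect; substring semantics is the only stage-robust
  option.
* **The >60% rule is strict**: a group of 10 with exactly 6 keyword
  messages is *not* a candidate. The threshold is configurable, and the
  output marks candidates as requiring manual confirmation — group-level
  COVID-relatedness is a human judgement; once confirmed, every member
  inherits it regardless of its own keywords.
* **Script-origin flagging** is one simplified-only codepoint or one
  mainland-usage phrase, on raw text. The packaged simplified↔traditional
  map and phrase list are small curated defaults (editable plain text);
  any such lexicon is debatable at the margins, which is why the 2×2
  association test takes printed cell counts as inputs rather than
  promising to reproduce someone else's lexicon from scratch.
* **Yates chi-square** from the closed form with the standard clamp at
  |ad−bc| ≤ n/2, p from χ²₁; the suite cross-checks against
  `stats::chisq.test(correct = TRUE)`. Reported to one decimal, with
  p-values below .001 rendered "<.001".
* **Percentages** round half-up to one decimal (matching how counts with
  percentages are conventionally reported; R's default `round` is
  half-even). **Quartiles** of group sizes use linear interpolation
  (`quantile` type 7).

# Temporal analytics

Days are calendar days in UTC+8 (the study region's timezone;
configurable), zero-filled between the first and last report. A **peak**
is a day with count ≥ `min_count` (default 10) that strictly exceeds
every day within ±`window` (default 3) days — invented conventions, since
resurfacing peaks are usually identified narratively; both parameters
should be reported alongside results, and flat stretches deliberately
yield no peak. Attribution counts a message toward every party whose
alias occurs as a substring (multi-party messages count multiply).
Variant timelines key on whitespace-normalized exact text: a one-character
edit is a new variant, which is the right granularity for supporting a
manually curated change log but is not edit-distance clustering.

# The synthetic generator

`generate_corpus()` emulates the statistical structure the pipeline
assumes, so every stage is testable without proprietary platform data:

* **groups** with power-law sizes (default tail exponent α = 2, sizes
  2–250) — real rumor-group sizes are strongly long-tailed;
* **near-duplicate variants**: per-group templates of distinct word
  symbols, disjoint across groups; each member edits every template token
  independently with probability `mutation_rate` (substitute / insert /
  delete, uniformly; replacements drawn from a disjoint noise pool);
* **singleton noise** messages sampled from the noise pool;
* **combined messages** concatenating two templates (ground truth
  "mixed", excluded from planted-partition scoring);
* **bursty report dates** (per-group mixtures of Gaussian-spread bursts)
  and **script markers** (simplified-only characters appended at a
  configurable rate) so temporal and script analytics have planted truth.

Under the mutation model a template token survives into a member with
probability $1 - 2m/3$, so the expected within-group distance is about
$1-(1-2m/3)^2$ (a small correction for the max in the denominator is
included in `expected_separation()`), bounded by $2m$ + tolerance; tests
verify Monte-Carlo agreement. At the default m = 0.05 the within/between
separation (~0.07 vs ~1.0) is wide, which is the regime the method
targets: near-duplicates, not paraphrases.

What the generator does **not** emulate: real token frequency
distributions (Zipfian vocabulary, shared boilerplate across groups),
paraphrase beyond token edits, gradual semantic drift, translations, or
any user/reshare structure. Passing tests therefore establish algorithmic
correctness and fidelity of the hybrid to full HAC under well-separated
near-duplicate structure — not performance on borderline paraphrased
rumors.

# Problem sizes

The fidelity experiment (`fidelity_study_spec()`) uses 10,000 messages in
300 planted groups (α = 2, sizes 2–250, capped near the scaled-down size
of the largest real group), 750 singletons (the singleton share observed
in chatbot corpora, ~7.5%), 30-token templates, mutation rate 0.05, and a
25,000-token vocabulary; the hybrid runs at u = 0.4 with 5 derived-seed
repetitions. Unit and property tests run on corpora of 6–500 documents,
with brute-force agglomeration and pair-enumeration oracles on corpora of
at most 8 documents where exhaustive naive computation is cheap.

# Limitations

* Short texts: below ~20 tokens the set distance is too coarse; such
  messages are filtered, not clustered.
* The distance ignores word order entirely; two messages using the same
  vocabulary in contradictory ways are indistinguishable.
* KNN extrapolation can absorb isolated noise documents into large groups
  when a holdout document's nearest sample neighbours all carry the same
  label; at u ≥ 0.4 on well-separated corpora this costs well under 1% of
  pairwise precision, but the effect grows as groups overlap.
* Group-level COVID tagging and fact-check status remain human
  judgements; the package only pre-screens candidates.
* The simplified-script lexicon is a heuristic for message origin; the
  association it feeds is correlational, never per-message attribution.
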