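---
title: "Methods: lexicon-driven clinical text search and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-driven clinical text search and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mednotesearch)
```

## The problem

Clinical free text expresses one concept in many surface forms: canonical
terms, specialty abbreviations ("CVA", "TIA", "HF"), synonyms, inflected
word forms, hyphenation variants and outright misspellings. A whole-word
exact search — the `string_search()` baseline in this package — retrieves
only the literal query, so a clinician looking for "stroke" must manually
enumerate "TIA", "CVA", "cerebrovascular accident", and hope the author
spelled them correctly. The NLP-enhanced search implemented here expands
the query through a medical lexicon and tolerates spelling variation, then
reports every hit as an exact character span with provenance, so a viewer
can highlight direct and semantically related hits in different colours.

## The matching model

**Normalization.** All comparisons use `normalize_term()`: lowercase,
hyphens deleted, whitespace collapsed. This makes "Anti-Coagulant" and
"anticoagulant" the same token. The tokenizer treats letters and digits as
word characters and lets internal hyphens/apostrophes join a single token,
so "anti-coagulant" is one token and "hba1c" is one token; offsets are
0-based, half-open, in Unicode code points, and interleaving gaps with
token surfaces reconstructs the text exactly. These conventions are
implementation choices made for unambiguous slicing, not claims about any
particular EHR system.

**Query expansion.** `expand_query()` is one-hop: the query reaches every
lexicon entry in which it occurs as canonical term, synonym, abbreviation
short form (indexed case-insensitively), full long form, or a whole word of
a long form. From each reached entry it collects the canonical and
synonyms (kind `synonym`) and both sides of each abbreviation pair (kind
`abbreviation`). Transitive expansion (synonym-of-synonym) is deliberately
not performed — it compounds lexicon noise and the behaviour of interest
(heart → HF, stroke → TIA/CVA) needs only one hop. Word-sense
disambiguation of ambiguous abbreviations is also out of scope: all senses
are indexed and all matches surfaced, leaving interpretation to the reader.

**Fuzzy matching.** A document token matches a target term when its
Levenshtein distance after normalization is within a length-banded budget:

| normalized target length | allowed edits |
|---|---|
| < 5 | 0 (exact only) |
| 5–8 | 1 |
| > 8 | 2 |

with `min_fuzzy_length = 5`: any non-exact match requires the target to be
at least 5 characters. The band protects short abbreviations (a 1-edit
budget on "CVA" would fire on "CBA") while catching the canonical
misspelling case ("atriall" vs "atrial": length 6, distance 1). Short
abbreviation forms are additionally exact-only as expansion terms
regardless of length. The band edges are tunable parameters of
`match_policy()`; no published threshold exists for this class of tool, so
the defaults were chosen once from the worked examples above and are not
calibrated against any outcome.

**Stemming.** Word-form matching uses a small deterministic
suffix-stripping stemmer (plural -s/-es/-ies, -ing/-ed/-er/-ly families,
final -e, undoubling of a stranded doubled consonant), applied only to
tokens of length ≥ 5. The contract is equality of stems — smoke, smokes,
smoker, smoking share "smok" — not linguistic correctness; stems never
leave the package. A plural -s is stripped only after a consonant so that
stems like "diseas" (from "disease") are fixed points of the stemmer,
which keeps stemming idempotent on the whole bundled vocabulary.

**Overlap resolution and provenance.** When expansions hit overlapping
spans (e.g. direct "heart" inside abbreviation long form "heart failure"),
the longest span wins; ties prefer direct > word_form > spelling_variant >
abbreviation > synonym, then lower edit distance, then earlier position.
One region, one colour. A hit made at nonzero edit distance is
reclassified `spelling_variant` at match time; a hit made through stem
equality is `word_form` and reports edit distance 0 (the distance concept
does not apply along the stem route). A consequence of longest-span
resolution is that the baseline's span set is guaranteed to be *covered*
(every baseline span lies inside some enhanced-search span) rather than
literally a subset: the enhanced search can legitimately return a longer
region containing a baseline hit.

**Mentions.** `mentions()` clusters matches by sentence within a document
(delimiters `.`, `!`, `?`, newline). This is the unit a reader perceives:
"No TIA or CVA" yields two matched tokens but one mention. Mention counts
are what the package reports when asked how many distinct places a concept
occurs.

## Marking and study analytics

A question carries gold evidence as a set of (document, area) units —
pieces of information are clustered per document, so three facts spread
over two documents form two markable areas. `score_answer()` gates on
answer correctness (0 marks for a wrong answer regardless of evidence
found) and otherwise awards one mark per gold area found. Free-text
answers are compared after `normalize_term()` against a set of accepted
strings; consensus human marking cannot be reproduced in code, and this is
the closest mechanical analogue. `task_accuracy()` weights questions
equally by averaging per-question mark *fractions* (marks / number of gold
areas) rather than summing raw marks; with unequal gold sizes the two
readings differ, and equal question weighting is only guaranteed by the
fraction form.

"An answer used search" is operationalized as ≥ 1 logged term for that
question — the only reading under which per-answer term means are well
defined. `validate_protocol()` excludes an evaluator entirely if any of
their records shows a functionality other than the one assigned to their
group for that task, including any logged search under a no-search arm.

**Weighted paired t-test.** Group-imbalance weights give each study group
equal total weight: an evaluator in group g of size $n_g$ gets
$w = N / (G\,n_g)$, so weights sum to the cohort size N. For paired
differences $d_i = b_i - a_i$ the test uses the weighted mean
$\bar d_w = \sum w_i d_i / \sum w_i$, the frequency-convention weighted SD
$s_w^2 = \sum w_i (d_i - \bar d_w)^2 / (\sum w_i - 1)$, and the Kish
effective sample size $n_\mathrm{eff} = (\sum w_i)^2 / \sum w_i^2$, with
$t = \bar d_w / (s_w / \sqrt{n_\mathrm{eff}})$ on $n_\mathrm{eff} - 1$
degrees of freedom, two-tailed. With equal weights this reduces exactly to
the textbook paired t-test. The weighting formula and df convention are
this package's documented choices — defensible, standard, but not the only
possibility; with the design's mild imbalance (7/13/15) the Kish df (≈ 30.4
instead of 34) changes the α = 0.10 critical value negligibly, and the
test's type-I error is verified by simulation to sit at 0.10 ± 0.02.
Percent differences are computed per pair (100·d/a) and weighted-averaged,
a config-free choice consistent with reporting a mean percentage alongside
a mean raw difference; the ratio-of-means alternative is not implemented.
Significance is strict (`p < alpha`) at the default α = 0.10, with no
multiple-testing correction across the three contrasts, matching how such
three-arm crossover comparisons are conventionally reported. Degenerate
inputs are explicit: identical pairs give t = 0, p = 1; zero variance with
nonzero mean reports the limiting p = 0 with a `degenerate` flag.

## The synthetic generator

`generate_corpus()` assembles notes from a bank of clinical-style template
sentences written for this package, each planting one lexicon term; with
configured probabilities the planted term is replaced by a one-edit
misspelling, an abbreviation short form, or a synonym, and every plant is
recorded with its exact span and variant kind. The variant kind is sampled
*before* the entry (from the sub-pool of entries supporting that kind), so
empirical injection fractions match the configured rates. Misspelling
edits are constrained to the fuzzy policy's reach for the word length
(transpositions, which cost 2 Levenshtein edits, only touch words long
enough to afford them), so every misspelled plant is recoverable by the
enhanced search by construction — and invisible to the exact baseline,
which is the qualitative separation the tool exists to produce.

Defaults mirror the evaluation-study design this machinery is built for:
3 patients × 20 documents, 10 questions per task, a cohort of 35
evaluators in groups of 7/13/15 following the cyclic functionality
rotation (none/string/nlp, string/nlp/none, nlp/none/string; the rotation
itself is this package's choice of Latin square). Cohort outcome
parameters default to plausible anchors: per-functionality evidence recall
0.838/0.837/0.881, lognormal task times with means 20.2/17.0/17.9 minutes
(lognormal for positivity and right skew; sdlog 0.35), search usage
83.7%/95.1%, and 3.51/2.05 mean terms per searched answer. Injection
rates default to 0.1 per kind — a fixture value, configurable, with no
claim about real misspelling density.

What the generator does *not* emulate: coherent clinical narrative,
negation semantics (a "No CVA" plant is still a plant — interpreting
negation is the reader's job), section structure, inter-annotator
disagreement, or evaluator learning effects across tasks. Tests passing
on synthetic data therefore demonstrate the mechanics (spans are exact,
variants are recoverable, statistics are calibrated), not clinical
performance.

## Problem sizes used by the test suite

The suite runs entirely on generated data: oracle equivalence uses ≥ 1000
random edit-distance pairs and ~100 random mini-corpora; injection-rate
checks plant > 10,000 terms; type-I calibration uses 2000 replicates of a
35-evaluator null cohort; parameter recovery uses 500 replicates of the
full generate–simulate–analyse pipeline at n = 35 with a configured
5-point recall gap between the string and NLP arms, recovering the gap
within 3 simulation standard errors. These sizes were chosen as the
smallest that make the Monte-Carlo checks sharp.

## Known limitations

* The lexicon is a flat synonym/abbreviation table; hyponym hierarchies
  are represented as synonyms, and no concept identifiers are assigned.
* Fuzzy matching is per-token; multi-word targets must match contiguously
  with no gaps, and no phonetic (Soundex-style) matching is attempted.
* No relevance ranking beyond match counts; retrieval is exhaustive by
  design, which can return many hits on common terms.
* Free-text marking by normalized string set membership is stricter than
  human consensus marking.
* The crossover analysis deliberately omits period and carryover effects;
  it implements plain weighted paired contrasts.
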