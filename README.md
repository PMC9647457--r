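# mednotesearch

Finding a fact in a patient's electronic health record is hard because
clinical free text is noisy: the same condition appears as a canonical term
("stroke"), an abbreviation ("CVA", "TIA"), a synonym ("cerebrovascular
accident"), an inflected word form ("smoker" for "smoke"), a hyphenation
variant ("anti-coagulant"), or a plain misspelling ("atriall"). A literal
whole-word search misses most of these, so clinicians burn time trying one
spelling after another.

`mednotesearch` implements, in R, an NLP-enhanced search over free-text
patient notes together with the machinery needed to evaluate such a tool in
a simulated clinical workflow. It is aimed at clinical-NLP researchers who
want a transparent, dependency-light reference implementation of
lexicon-driven query expansion and of the crossover-study analysis that
compares search functionalities.

## What the search does

Given a query *q*, the tool expands it into a set of equivalent terms
*E(q)* using a pluggable JSON lexicon of entries
(canonical term, synonyms, abbreviation short/long pairs, category):

* **direct** — the normalized query itself (lowercased, hyphens removed,
  whitespace collapsed);
* **synonym** — canonical terms and synonyms of every lexicon entry in which
  *q* appears as a surface form (including as a whole word of an
  abbreviation's long form, so "heart" reaches "HF" via "heart failure");
* **abbreviation** — both the short and long form of each abbreviation pair;
* **word form** — a stem marker enabling suffix-stripped matching
  (stem("smoker") = stem("smoke") = "smok").

Every term in *E(q)* is then located in the text as whole words (or
contiguous whole-word runs for multi-word terms). A document token *t*
matches a target *w* when the Levenshtein distance d(t, w) after
normalization is within a banded policy: 0 edits for |w| < 5, 1 edit for
5 ≤ |w| ≤ 8, 2 edits for |w| > 8, with short targets (|w| < 5, typically
abbreviations) restricted to exact matches. Each hit is reported as a
character-offset span with provenance (which expanded term fired, at what
edit distance) and a highlight class: **direct** (exact hit on the query)
or **semantic** (everything else) — the two highlight colours of an EHR
viewer. A whole-word exact `string_search()` provides the baseline, and
sentence-level `mentions()` cluster adjacent hits ("No TIA or CVA" is two
matched tokens but one mention).

## Evaluation machinery

The package also implements the study-side apparatus for comparing search
functionalities (none / string / NLP-enhanced) in a three-arm crossover
design:

* evidence-area marking: a correct answer earns one mark per gold
  (document, area) unit found; task accuracy is the equally weighted mean
  of per-question mark fractions, × 100;
* search-log metrics: percentage of answers using search, and mean (SD)
  terms per searched answer;
* protocol validation (evaluators who used the wrong functionality for a
  task are excluded);
* group-imbalance weights (each study group receives equal total weight)
  and a weighted paired two-tailed t-test with Kish effective sample size
  n_eff = (Σw)² / Σw², t = d̄_w / (sd_w / √n_eff), tested at α = 0.10;
* a deterministic synthetic generator of clinical-style notes with planted
  misspellings/abbreviations/synonyms and exact gold spans, plus a seeded
  simulator of an evaluator cohort, so the whole pipeline runs end-to-end
  with no external data.

## Worked example

```r
library(mednotesearch)
lex <- demo_lexicon()
notes <- as_corpus(c(
  note1 = "Admitted with palpitations. atriall fibrillation noted on ECG.",
  note2 = "Known HF. Coronary arteries patent on angiogram.",
  note3 = "Heart sounds normal. Plan: repeat echo in clinic."))
nlp_search("heart", notes, lex)
#> <matches: 4 hit(s) in 3 document(s)>
#>   doc_id start end  surface query     term             kind source_entry
#> 1  note1    28  35  atriall heart   atrial spelling_variant        heart
#> 2  note2     6   8       HF heart       hf     abbreviation        heart
#> 3  note2    10  18 Coronary heart coronary          synonym        heart
#> 4  note3     0   5    Heart heart    heart           direct         <NA>
#>   edit_distance highlight_class
#> 1             1        semantic
#> 2             0        semantic
#> 3             0        semantic
#> 4             0          direct

string_search("heart", notes)   # the baseline sees only the literal word
#>   doc_id start end surface
#> 1  note3     0   5   Heart
```

The enhanced search finds the misspelling "atriall" (edit distance 1 from
the expansion term "atrial"), the abbreviation "HF", and the synonym
"Coronary", none of which the whole-word baseline can see. Offsets are
0-based half-open code-point positions, so they can drive a highlighter:

```r
doc <- notes[notes$doc_id == "note1", ]
render_highlights(nlp_search("heart", notes, lex) |>
                    subset(doc_id == "note1"), doc, "text")
#> Admitted with palpitations. [[S|atriall]] fibrillation noted on ECG.
```

A command-line wrapper for searching, generating synthetic corpora,
simulating a study cohort and producing the crossover report lives at
`inst/cli/mednote-search` (run it with `Rscript`).

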