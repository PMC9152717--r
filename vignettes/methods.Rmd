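---
title: "Methods: multilingual readability analysis of a disease-article corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilingual readability analysis of a disease-article corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wikiread)
```

## The problem and the model

Patient-education guidance puts the recommended reading level of consumer
health material at about US grade 7. `wikiread` audits a multilingual
corpus of disease-related encyclopedia articles against that benchmark: it
harvests the article set from a category graph, attaches ICD-10 codes
through structured metadata and interlanguage links, scores every article
with the readability formulas defined for its language, and tests three
families of hypotheses about the scores.

All formulas are affine functions of a small set of text ratios computed by
`text_statistics()`:

* **ASL** — average sentence length, words per sentence;
* **ASW** — average syllables per word;
* **MS** — the percentage (0–100) of *complex* words, defined throughout as
  words with at least three syllables. The same definition serves as
  Gunning's "hard words" and as the polysyllable count *p* in SMOG: the
  classic FOG exemptions for proper nouns and inflected endings are *not*
  applied, keeping one complex-word rule for every metric;
* **L**, **S** — letters per 100 words and sentences per 100 words (CLI);
* characters per word and words per sentence (ARI), where a character is a
  letter or digit — punctuation never counts.

The metric sets are language-specific and dispatch is strict: English has
FRE, FKGL, FOG, SMOG, ARI, CLI; German has the Amstad FRE and the fourth
Wiener Sachtextformel; Russian has the Solovyev FRE and FKGL adaptations.
Asking for a metric outside its language raises
`wr_unsupported_metric` — there are no silent fallbacks. SMOG is used with
the standard McLaughlin constants, `3.1291 + 1.0430 * sqrt(p * 30 /
n_sentences)`: the per-30-sentence normalization is the only published
variant consistent with a polysyllable count defined on 30-sentence
samples. Scores are never clamped (a one-syllable, one-word text has an
English FRE above 121) and never rounded internally; report files round to
two decimals. FRE difficulty bands use half-open intervals with inclusive
lower edges, so a score of exactly 30.00 is "difficult", not
"very difficult".

## Counting rules and their degenerate cases

Sentences end at terminal punctuation (`.`, `!`, `?`, `…`); colons and
semicolons do not split, and per-language abbreviation lists (plain-text
config under `extdata/abbrev/`, editable data rather than code) protect
"Dr.", "z.B.", "т.е." and friends from creating false boundaries, as do
decimal numbers. Tokens are maximal runs of letters and digits; hyphenated
compounds stay one word with syllables summed across the parts. Tokens with
no letters (pure numbers) count as one word of one syllable and their
digits count toward the character total — a declared convention chosen for
determinism and language independence, not a reconstruction of any
particular reference implementation.

Syllables are estimated per language. Russian uses the exact orthographic
rule — one syllable per vowel letter (а е ё и о у ы э ю я) — which the test
suite checks against an independently coded vowel counter on random words.
English and German use vowel-group counting (adjacent vowels weigh once,
`y` is an English vowel) with English adjustments for silent final `e`,
`-es`, `-ed` (kept after `l`, sibilants, and `t`/`d`). This is a heuristic:
words like *pneumonia* or *diabetes*, where a vowel pair is actually
disyllabic, are undercounted. Both counters are validated against
hand-counted gold word lists; the known failure modes are documented there
and every count is floored at one syllable.

A text with zero sentences or zero words supports no metric. Such articles
raise `wr_degenerate_text`; the batch scorer records them as
`excluded_reason = "degenerate_text"` and reports count them — the same
exclude-and-count treatment a corpus audit applies to articles whose
metrics are technically uncomputable.

## Harvesting and annotation choices

The four filters run in a fixed order — category wildcard, given name,
geographic, stop word — and the first match wins, so per-filter exclusion
counts are order-dependent (reports note this). The given-name filter
matches on the first whitespace-separated title token, a cheap,
high-precision rule for person pages. Wildcards are case-insensitive
shell-style globs (`*`, `?`, `[...]`); an unparsable pattern raises
`wr_config_error` naming it. The geographic filter matches both title and
category titles by default, since "related to specific places" is
ambiguous between the two. Traversal of the category graph is breadth-first
with a visited set (cycles are expected), unbounded depth by default, and
insensitive to edge order. The shipped filter lists are small and
illustrative; real studies supply their own.

ICD-10 "chapter" here means the leading letter of a code (A–Z) — the label
per-chapter result tables actually use — rather than the official
Roman-numeral chapters whose ranges can span letters. A valid code is one
uppercase letter, two digits, and optionally a period plus one or two more
digits or letters; mangled codes (e.g. `0.00` where `Q0.0` was meant) are
dropped with a warning, and a manual exclusion list removes codes known to
be wrong at the source, mirroring the manual curation such metadata needs.
Codes are validated per code, then propagated as a union across
interlanguage clusters (propagated codes keep an `origin = "propagated"`
tag), and only then do articles split into groups A/B. Code conflicts
across editions are unioned, never arbitrated. An article is duplicated
into every distinct chapter letter among its codes, once per chapter.

## The statistics

* **Scenario 1** compares FRE pairwise across the three languages over all
  scored articles (groups A and B), two-tailed, with Holm adjustment across
  the family of three. Holm is applied only here — the only scenario that
  runs several tests on the same sample.
* **Scenario 2** compares each chapter's FRE against all group-A FRE values
  of the language, two-tailed. The reference deliberately includes the
  chapter's own members (the literal "mean of all the articles"); the
  induced overlap makes the test slightly conservative for large chapters,
  which reports note. Chapters enter only with n strictly greater than 25.
* **Scenario 3** tests each English chapter's FKGL against the constant
  grade 7, upper-tailed. Although the source convention calls this an
  "unpaired" test, a constant has no sample; it is implemented as a
  one-sample t test against μ₀ = 7.

All two-sample tests are Welch (unequal variances, Welch–Satterthwaite
degrees of freedom): group sizes and SDs differ widely between chapters and
languages, and the pooled-variance Student test is never safer in that
regime. The t tests and the Holm adjustment are computed by `stats::t.test`
and `stats::p.adjust`; the test suite verifies both against independently
coded textbook-formula and brute-force step-down oracles, and checks the
Welch test's empirical type-I error on simulated nulls (2,000 replicates of
two Normal(0,1) samples of 50). Descriptive SDs use the n−1 denominator and
are reported absent for single-observation groups.

## What the synthetic generator emulates

`generate_snapshot()` builds a complete snapshot — articles (JSON Lines),
category graph (node/edge TSV), interlanguage links, metadata code map,
filter lists — that is byte-identical under a fixed seed. Its articles are
pseudo-words assembled from consonant–vowel syllable templates, so the
syllable count is known exactly by construction (the letter inventory
avoids the orthographic special cases, and generated words are nudged away
from colliding with abbreviation stems). Sentence counts are lognormal;
sentence lengths are Poisson around a target ASL, corrected so the realized
ASL hits the target within rounding; syllables per word follow
`1 + Binomial(5, (ASW − 1)/5)`, a one-parameter moment match on support
1–6. Per-article FRE targets are Normal draws converted to ASW targets by
inverting the language's own FRE formula at the drawn ASL, which is also
how chapter-level FRE offsets are injected.

Default conditions echo a real disease-article corpus: group-A FRE means
and SDs of 28.69 (11.00) for English, 20.33 (9.98) for German, 38.54
(13.51) for Russian; about 70% of concept clusters carrying a code; a 15%
share of two-chapter code sets; unequal language coverage (Russian editions
exist for roughly half the clusters); and codes planted in only a strict
subset of each cluster's editions so propagation does real work. Article
counts default to desk scale (320 clusters, roughly 300/300/160 articles)
rather than the thousands of a full snapshot.

What the generator does *not* emulate: real lexical material (so passing
tests validate the counting machinery and statistics, not dictionary-level
syllabification), real category topology beyond trees with planted cycles,
and any correlation between an article's topic and its style beyond the
planted chapter offsets. Conclusions about real corpora still require real
snapshots.

## Validation set-up and problem sizes

The validation suite uses: exact recovery of construction ground truth
(sentence, word and syllable counts) on generated snapshots; exact recovery
of planted decoy counts per filter and of the planted coded-cluster
fraction after propagation; a 12-text hand-counted fixture on which all ten
formulas must agree with direct arithmetic to 1e−9; Holm equality with a
brute-force step-down on 1,000 random p-vectors; an empirical type-I error
in [0.035, 0.065] at α = .05; and a 200-replicate simulation in which
planted interlanguage FRE offsets of +8, −10 and −18 points must be covered
by the pairwise 95% CIs at least 93% of the time, with a planted −10-point
chapter-F deficit flagged significant by the full pipeline. The replicate
corpora use 40 clusters and ~9-sentence articles — CI coverage does not
depend on sample size, so small replicates are the package's choice for the
simulation — while the chapter-deficit run uses a 320-cluster snapshot with
chapter F upweighted so it clears the n > 25 inclusion rule.

## Known limitations

* English/German syllable counts are heuristic; grade-level metrics built
  on them (FKGL, SMOG, FOG, WSTF) inherit that noise. ARI and CLI, which
  count characters instead, do not.
* The wikitext stripper is minimal and regex-based: it handles templates,
  tables, reference tags, links, file links, headings and HTML comments
  best-effort, and is not a full parser for real dump markup.
* Scenario 2's overlap between chapter and reference sample is a modelling
  choice, not an oversight; with chapter shares of group A above ~20% it
  noticeably attenuates differences.
* The group split is only as good as the metadata: codes missing from every
  linked edition put an article in group B regardless of its content.
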