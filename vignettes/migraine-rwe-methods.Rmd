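---
title: "Methods: dual-arm RWE extraction and evaluation for migraine EHR studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-arm RWE extraction and evaluation for migraine EHR studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrwe)
```

## Overview

`migrwe` emulates a two-arm study design for extracting migraine-related
concepts from electronic health records. The unit of analysis is the
*encounter* — one patient seen by one physician on one date — and the object
of study is the documentation gap between structured fields and the clinical
narrative. Ten concepts are evaluated: migraine and headache, six associated
symptoms (nausea, vomiting, light sensitivity, loss of appetite, dizziness,
fatigue), and two triptans (rizatriptan, sumatriptan).

The package has four layers: corpus model and preselection filter; the two
extraction arms; the reference-standard machinery (Cohen's κ, adjudication);
and the evaluation framework (encounter-level recall/precision/F1,
chi-square arm comparison). A synthetic corpus generator with exhaustive
ground truth closes the loop, standing in for protected clinical data.

## The Traditional arm

`extract_traditional()` is deliberately simple, because that is the point:
it queries the problem list, medication list, and encounter claims through a
code map and emits one hit per mapped coded entry. Duplicate entries yield
duplicate hits; de-duplication happens only at evaluation, which preserves
the distinction between *concept occurrence* (all instances) and *encounter
occurrence* (encounters with at least one instance). The note text is never
consulted — a property the test suite enforces by randomizing notes and
asserting unchanged output.

The shipped code map does include diagnosis codes for every symptom concept
(e.g., ICD-10 R11.0 for nausea, H53.14 for photophobia). The near-zero
structured-arm recall for symptoms is a *documentation behaviour*, modelled
by the generator's `structured_prob`, not an impossibility of coding.

## The Advanced arm

`extract_advanced()` is a deterministic rule pipeline; there is no learned
component, which keeps behaviour inspectable and the package free of model
dependencies.

**Sentence segmentation** splits on sentence-final punctuation and newlines.
Clinical notes are strongly newline-structured, so rule-based segmentation
is adequate and exactly reproducible. Offsets are 0-based and half-open
throughout, and every mention's `surface` equals the corresponding slice of
the note — an invariant tested on generated corpora.

**Dictionary matching** is a case-insensitive, whole-token scan against the
lexicon, longest alternative first, with overlapping shorter matches
suppressed (so "migraine with aura" wins over "migraine", and "ha" never
fires inside "asthma"). The shipped abbreviation inventory (HA, MA, brand
names) is a plausible clinical reconstruction, flagged as such in the
lexicon documentation.

**Attribute detection** uses trigger–scope rules in the NegEx/ConText
tradition: a negation trigger (`no`, `not`, `denies`, `without`, ...)
preceding the concept within the sentence negates it unless a
scope-terminating token (`but`, `however`, `although`, `;`) intervenes;
historical triggers (`history of`, `prior`, ...) set temporality under the
same scope rule; a severity cue (`mild`, `mod`, `moderate`, `severe`)
immediately before the match sets severity. The design is the standard one
for clinical negation; the scope vocabulary is small on purpose and easy to
extend.

**Template parsing** recognizes lines consisting solely of sign-prefixed
tokens (`-headache, +nausea`). A `+` token asserts its concept. A `-` token
is only a *provisional* negative: if the same concept has an asserted
free-text mention anywhere in the encounter, the free-text assertion wins
and no negative is emitted. This encounter-level support inference is what
distinguishes the template rule from sentence-scope negation.

**Abbreviation disambiguation** scores each candidate sense of an ambiguous
surface by its summed association weight against the set of concepts
asserted anywhere in the patient's record, and resolves to the top candidate
only when its margin over the runner-up is strictly positive (the default
`margin = 0` with a strict inequality). Ties and empty contexts abstain and
the mention is dropped: silently asserting the wrong sense is worse than
missing one. Two design choices here were genuinely open:

- *Context direction.* The "longitudinal record" is taken to be the union of
  all the patient's encounters, not only prior ones; a retrospective study
  sees the whole record.
- *Association weights.* The production-scale learned-association corpus
  such a system would use is replaced by a plain, user-supplied weight table
  with defaults that encode the two canonical examples (migraine with aura
  ~ headache/photophobia; mass ~ lung cancer/tumor). This preserves the
  inference mechanism — additive evidence with margin-based abstention —
  while making it inspectable and unit-testable. Additivity and monotonicity
  (adding positively associated context never hurts a candidate) are tested
  properties.

`migraine_with_aura` is kept as a distinct sense for disambiguation but
rolled up into `migraine` for evaluation (`rollup_concepts()`, configurable).

## Reference standard

Agreement is measured by Cohen's κ on per-encounter binary concept presence,
per concept and annotator pair, then averaged without weighting; 0.8 is the
inclusive pass threshold. Presence/absence is the level at which recall is
later computed, so agreement is measured on the same surface; span
mismatches with concept agreement count as agreement. κ is computed prior to
any resolution of disagreement. Adjudication keeps agreed labels and defers
disputes to a third annotator; a dispute without a tiebreak label is an
error naming the encounters, and the adjudicated set is exactly the union of
agreed and tiebroken labels. Degenerate marginals (both annotators constant
and identical) return κ = 1 by convention.

## Evaluation

Concepts are discrete, time-specific events, so all primary metrics are
computed at the encounter level: presence is never propagated across a
patient's record, and a concept is correct only in encounters where the
reference asserts it. Only asserted labels create presence; negated mentions
never do. Precision is reported as `NA` (serialized as JSON `null`, never
0) when an arm predicts nothing; F1 is 0 when tp = 0.

The arm comparison is a Pearson chi-square on
`[[tp_trad, fn_trad], [tp_adv, fn_adv]]` without continuity correction
(counts are in the hundreds to thousands) and with no multiple-testing
adjustment, matching the reporting conventions of per-concept phenotyping
studies. An expected cell below 1 attaches a warning to the result rather
than failing. Degenerate tables (a zero row or column margin, e.g. both arms
at 100% recall) are reported as statistic 0, p = 1. The per-concept success
flag implements the protocol criterion — Advanced recall ≥ 80% *or*
absolute recall difference ≥ 25 points; where a study-level "average recall"
reading is wanted, the report's metrics table supports an across-concept
mean per arm.

## The synthetic corpus generator

`generate_corpus()` emulates the *study conditions*, not clinical language.
Per encounter it samples each concept as clinically present from its
prevalence; symptom prevalence is conditionally lifted (default ×2) in
migraine-positive encounters so the corpus exhibits the co-occurrence
structure the disambiguator exploits — the lift value is a synthetic choice,
not an estimate. Present concepts are rendered into structured codes with
probability `structured_prob` and into the narrative with probability
`narrative_prob`, using a controlled sentence bank (complaint sentences with
optional severity cues, history phrasings, medication plan sentences,
sign-prefixed review-of-systems lines, denial sentences for absent
concepts). All randomness flows through one seeded stream, so generation is
a pure function of the configuration.

The default profile ships the emulated study's dimensions: 6,032 encounters,
with `structured_prob` set to the Traditional-arm recalls the design targets
(0.666 and 0.296 for migraine and headache, a 0–0.179 band for symptoms,
~0.8 for triptans) and `narrative_prob` to the Advanced-arm recalls (0.968,
0.929, a 0.793–0.966 symptom band, ≥ 0.98 for triptans). Only the symptom
*bands* are externally fixed, not per-symptom values; the shipped per-symptom
values are placed inside the band so that every concept clears the
protocol's 80% Advanced-recall threshold with sampling headroom, and so that
the extreme recall differences reproduce the band endpoints (dizziness:
0.894 − 0.179 = 71.5 points; fatigue: 0.966 − 0.078 = 88.8 points).
Prevalence is back-calculated from target occurrence counts as
`count / (n × narrative_prob × (1 + multiplicity))`, so expected narrated
occurrences land on the published per-concept counts (migraine 2,642,
headache 6,530, and so on); this closed-form identity is itself a unit test.

Because the emulated study preselected its 6,032 encounters for relevance,
the generator guarantees every note contains at least one preselection term
(migraine, headache, rizatriptan, sumatriptan), appending a clinically
plausible denial of an absent concept when none occurs naturally. The
pipeline still runs the filter — applied identically to both arms — and it
retains the full set, keeping the occurrence calibration exact.

The generator's reference standard is its own clinical truth — an
*omniscient abstractor*. This is what makes the recall of each arm converge
to its documentation probability, which is the parameter-recovery property
the test suite checks within three binomial standard errors. It also means
passing tests demonstrate internal consistency of the machinery, **not**
performance on real clinical text: real notes have misspellings, section
structure, richer anaphora and hedging, and annotators who can only see what
is written. The generator deliberately models none of these.

## Numerical and operational choices

- Offsets 0-based half-open; dates ISO 8601; all text UTF-8; files JSON
  Lines (one record per line, order-preserving, diff-friendly).
- The preselection filter is substring-based and case-insensitive on raw
  note text by default (it enriches, it does not assert); matching
  structured codes as well is available behind a flag.
- Disambiguation abstains on ties (strict-margin rule) rather than breaking
  them arbitrarily.
- File outputs are written atomically (temp file + rename); every CLI
  command leaves a JSON run manifest beside its first output; exit codes are
  0 (success), 1 (data/validation error), 2 (usage error).
- Problem sizes used by the shipped checks, chosen to give tight binomial
  bands while remaining quick: parameter recovery runs 4,000 encounters at
  prevalence 0.5 (~2,000 clinically-present encounters per concept, so three
  standard errors of a recall near 0.9 is about two points); the full study
  emulation runs the complete 6,032-encounter profile; metric and κ oracle
  comparisons use 500 and 200 randomized replicates.

## Known limitations

- The NLP is dictionary- and rule-based: no spelling correction, section
  detection, coreference, or statistical NER; recall on real notes would be
  bounded by lexicon coverage.
- The association table must be supplied (or the small default used); the
  package does not learn weights.
- Chi-square and κ are the only inferential tools; there are no bootstrap
  intervals or ROC analyses.
- The generator's language model is a template bank; it validates the
  pipeline's mechanics and the evaluation arithmetic, not linguistic
  robustness.
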