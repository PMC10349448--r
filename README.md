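# migrwe

Dual-arm real-world-evidence (RWE) concept extraction and evaluation for
migraine studies in electronic health records.

## The problem

Observational migraine studies usually rely on *structured* EHR data —
problem lists, medication lists, and encounter-associated claims codes —
because these are trivially queryable. But clinicians document symptoms and
disease detail mainly in the free-text *narrative*, so structured-only
pipelines systematically miss concepts such as nausea, photophobia, or
dizziness, for which diagnosis codes exist but are almost never entered.
`migrwe` implements, end to end, the methodology for quantifying that gap:

- a **Traditional RWE arm**: identify concepts from structured fields only,
  through a concept/code map (ICD-9, ICD-10, normalized drug names);
- an **Advanced RWE arm**: rule-based NLP over the note text — sentence
  segmentation, dictionary matching, negation/temporality/severity detection
  within the sentence boundary, sign-prefixed template parsing
  (`-headache, +nausea`) with encounter-level support inference, and
  disambiguation of ambiguous abbreviations ("MA": migraine with aura vs.
  mass) by association scoring over the patient's longitudinal record;
- an **evaluation layer**: both arms scored at the encounter level against a
  reference standard, plus Cohen's κ machinery for building that standard
  from dual annotation with tiebreak adjudication;
- a **seeded synthetic corpus generator** with exhaustive ground truth, whose
  documentation-completeness profile emulates a 6,032-encounter tertiary-care
  migraine study, so the whole methodology can be exercised and validated
  without access to protected health data.

## The statistics

For each concept and arm, with presence reduced to the encounter level
(tp = encounters asserted by both arm and reference, fn = reference only,
fp = arm only):

    recall    = tp / (tp + fn)          (primary endpoint)
    precision = tp / (tp + fp)          (undefined when tp + fp = 0)
    F1        = 2 (precision × recall) / (precision + recall)

Arms are compared per concept by a Pearson chi-square (no continuity
correction) on the 2×2 table `[[tp_trad, fn_trad], [tp_adv, fn_adv]]` and by
the absolute recall difference in percentage points. The protocol-level
success criterion for the Advanced arm is recall ≥ 80% or an absolute recall
difference ≥ 25 points. Inter-annotator agreement is Cohen's
κ = (p_o − p_e)/(1 − p_e) on per-encounter binary concept presence, averaged
over concepts and annotator pairs, with 0.8 as the required minimum.

## Worked example

Extract from two encounters of one patient — note the severity cue, the
negation, the template support rule (the `-headache` negative is withdrawn
because headache is asserted in free text), and the longitudinal
disambiguation of "MA":

```r
library(migrwe)
x <- corpus(list(
  encounter("P07", "E0001", "D12", "2011-02-03",
    note_text = "Pt reports severe HA with photophobia. Denies vomiting.\n-headache, +nausea"),
  encounter("P07", "E0002", "D12", "2011-03-17", note_text = "pt with MA")))
extract_advanced(x)[, c("encounter_id", "concept_id", "surface", "asserted",
                        "severity", "provenance")]
#>   encounter_id         concept_id     surface asserted    severity    provenance
#> 1        E0001           headache          HA     TRUE      severe     free_text
#> 2        E0001  light_sensitivity photophobia     TRUE unspecified     free_text
#> 3        E0001           vomiting    vomiting    FALSE unspecified     free_text
#> 4        E0001             nausea      nausea     TRUE unspecified      template
#> 5        E0002 migraine_with_aura          MA     TRUE unspecified disambiguated
```

Run the full study emulation on the shipped 6,032-encounter profile
(about a minute on one CPU):

```r
study <- run_study(default_profile(seed = 1))
print(study)
#> Dual-arm RWE study emulation: 6032 encounters after preselection
#> ...
#> migraine    2713  2080 | 66.1%/100.0%/79.6% | 96.7%/100.0%/98.3% | 30.7  667.6 <2e-16
#> headache    6600  4332 | 28.4%/100.0%/44.3% | 92.9%/100.0%/96.3% | 64.5 4064.2 <2e-16
#> ...
#> Recall migraine: 66.1% (traditional) vs 96.7% (advanced); headache: 28.4% vs 92.9%
```

The Traditional arm recovers roughly two thirds of migraine diagnoses and
under a third of headache mentions, is nearly blind to the six associated
symptoms (0–18% recall, with precision unavailable where it finds nothing),
and does well only on the triptans; the Advanced arm recovers ≥ 85% of every
concept. Those recalls converge, by construction, to the per-concept
structured and narrative documentation probabilities of the generator
profile, so the run doubles as a parameter-recovery check.

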