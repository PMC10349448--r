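test_that("sentence segmentation splits on punctuation and newlines with exact offsets", {
  s <- segment_sentences("No HA today. Nausea persists.")
  expect_equal(s$start, c(0L, 13L))
  expect_equal(s$end, c(12L, 29L))
  expect_equal(s$text, c("No HA today.", "Nausea persists."))

  expect_equal(nrow(segment_sentences("")), 0L)

  one <- segment_sentences("single sentence no period")
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 0L)
  expect_equal(one$end, 25L)
})

test_that("sentence offsets always slice back to the sentence text", {
  synth <- generate_corpus(small_config(n = 30, seed = 9))
  for (e in synth$corpus$encounters) {
    s <- segment_sentences(e$note_text)
    if (nrow(s) == 0) next
    expect_equal(substr(rep(e$note_text, nrow(s)), s$start + 1, s$end), s$text)
    expect_true(all(s$start < s$end))
    expect_true(all(diff(s$start) > 0))
  }
})

test_that("dictionary matching is whole-token, case-insensitive, longest-first", {
  lex <- default_lexicon()
  m <- match_concepts("mod HA", lex)
  expect_equal(m$surface, "HA")
  expect_equal(m$concept_ids, "headache")

  m2 <- match_concepts("pt with MA", lex)
  expect_setequal(strsplit(m2$concept_ids, "|", fixed = TRUE)[[1]],
                  c("migraine_with_aura", "mass"))
  expect_true(m2$ambiguous)

  # embedded substring is blocked by the token-boundary guard
  expect_equal(nrow(match_concepts("asthma", lex)), 0L)

  # longest match wins over its prefix
  m3 <- match_concepts("migraine with aura reported", lex)
  expect_equal(m3$surface[1], "migraine with aura")
  expect_equal(m3$concept_ids[1], "migraine_with_aura")
})

test_that("negation, temporality and severity follow the trigger-scope rules", {
  lex <- default_lexicon()
  s <- segment_sentences("denies nausea or vomiting")
  m <- match_concepts(s[1, ], lex)
  expect_equal(nrow(m), 2L)
  for (j in 1:2) {
    expect_false(detect_attributes(s[1, ], m[j, ])$asserted)
  }

  s2 <- segment_sentences("mod HA")
  m2 <- match_concepts(s2[1, ], lex)
  a2 <- detect_attributes(s2[1, ], m2[1, ])
  expect_true(a2$asserted)
  expect_equal(a2$temporality, "current")
  expect_equal(a2$severity, "moderate")

  # "but" terminates the negation and history scope
  s3 <- segment_sentences("no prior migraine, but migraine today")
  m3 <- match_concepts(s3[1, ], lex)
  expect_equal(nrow(m3), 2L)
  first <- detect_attributes(s3[1, ], m3[1, ])
  second <- detect_attributes(s3[1, ], m3[2, ])
  expect_false(first$asserted)
  expect_equal(first$temporality, "historical")
  expect_true(second$asserted)
  expect_equal(second$temporality, "current")
})

test_that("template lines parse sign-prefixed tokens and skip prose", {
  t1 <- parse_templates("-headache, +nausea")
  expect_equal(t1$surface, c("headache", "nausea"))
  expect_equal(t1$sign, c("-", "+"))

  expect_equal(nrow(parse_templates("Patient is resting comfortably")), 0L)

  t3 <- parse_templates("+photophobia +phonophobia")
  expect_equal(t3$sign, c("+", "+"))
  expect_equal(t3$surface, c("photophobia", "phonophobia"))

  # offsets point at the token surfaces in the note
  note <- "Plan reviewed.\n-headache, +nausea"
  t4 <- parse_templates(note)
  expect_equal(substr(rep(note, nrow(t4)), t4$start + 1, t4$end), t4$surface)
})

test_that("template negatives are overridden by asserted free-text support", {
  lex <- default_lexicon()
  tmpl <- parse_templates("-headache")

  no_support <- resolve_template_support(tmpl, migrwe:::empty_mentions(),
                                         lex, "E1")
  expect_equal(nrow(no_support), 1L)
  expect_false(no_support$asserted)
  expect_equal(no_support$concept_id, "headache")
  expect_equal(no_support$provenance, "template")

  support <- data.frame(encounter_id = "E1", concept_id = "headache",
                        start = 0L, end = 15L, surface = "severe headache",
                        asserted = TRUE, temporality = "current",
                        severity = "severe", provenance = "free_text",
                        stringsAsFactors = FALSE)
  overridden <- resolve_template_support(tmpl, support, lex, "E1")
  expect_equal(nrow(overridden), 0L)

  pos <- resolve_template_support(parse_templates("+nausea"),
                                  migrwe:::empty_mentions(), lex, "E1")
  expect_true(pos$asserted)
  expect_equal(pos$concept_id, "nausea")
})

test_that("disambiguation follows association evidence and abstains on ties", {
  tab <- default_association_table()
  cand <- c("migraine_with_aura", "mass")
  expect_equal(disambiguate(cand, c("headache", "light_sensitivity"), tab),
               "migraine_with_aura")
  expect_equal(disambiguate(cand, c("lung_cancer", "tumor"), tab), "mass")
  expect_true(is.na(disambiguate(cand, character(), tab)))

  # adding positively associated context never decreases the winner's score
  set.seed(12)
  pool <- c("headache", "light_sensitivity", "migraine", "nausea")
  for (i in 1:20) {
    ctx <- sample(pool, sample(0:3, 1))
    extra <- sample(setdiff(pool, ctx), 1)
    s0 <- association_score("migraine_with_aura", ctx, tab)
    s1 <- association_score("migraine_with_aura", c(ctx, extra), tab)
    expect_gte(s1, s0)
  }
})

test_that("the full advanced pipeline hand-traces on a one-encounter fixture", {
  x <- corpus(list(enc("E1",
    note = "Pt reports severe HA with photophobia. Denies vomiting.")))
  m <- extract_advanced(x)
  expect_equal(nrow(m), 3L)
  ha <- m[m$concept_id == "headache", ]
  expect_true(ha$asserted)
  expect_equal(ha$severity, "severe")
  expect_true(m$asserted[m$concept_id == "light_sensitivity"])
  expect_false(m$asserted[m$concept_id == "vomiting"])

  # empty notes extract nothing; the pipeline is deterministic
  blank <- corpus(list(enc("E1"), enc("E2", date = "2011-06-02")))
  expect_equal(nrow(extract_advanced(blank)), 0L)
  expect_identical(extract_advanced(x), extract_advanced(x))
})

test_that("advanced output ignores structured fields entirely", {
  note <- "Pt c/o mod HA today. Denies nausea."
  bare <- corpus(list(enc("E1", note = note)))
  loaded <- corpus(list(enc("E1", note = note,
                            problems = codes("ICD10", "G43.909"),
                            meds = codes("DRUG", "RIZATRIPTAN"))))
  expect_identical(extract_advanced(bare), extract_advanced(loaded))
})

test_that("mention offsets round-trip into the note text on generated corpora", {
  synth <- generate_corpus(small_config(n = 50, seed = 21))
  m <- extract_advanced(synth$corpus)
  notes <- stats::setNames(
    vapply(synth$corpus$encounters, `[[`, character(1), "note_text"),
    vapply(synth$corpus$encounters, `[[`, character(1), "encounter_id"))
  expect_gt(nrow(m), 0)
  expect_equal(substr(notes[m$encounter_id], m$start + 1, m$end), m$surface,
               ignore_attr = TRUE)
})

test_that("mention files round-trip through JSON Lines", {
  x <- corpus(list(enc("E1", note = "Pt reports severe HA. -nausea")))
  m <- extract_advanced(x)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_mentions(m, path)
  expect_equal(read_mentions(path), m)
})

test_that("longitudinal context from other encounters resolves MA per patient", {
  x <- corpus(list(
    enc("E1", pid = "PA", note = "Patient reports migraine with photophobia."),
    enc("E2", pid = "PA", date = "2011-07-01", note = "pt with MA"),
    enc("E3", pid = "PB", note = "Known lung cancer. Large tumor."),
    enc("E4", pid = "PB", date = "2011-07-02", note = "pt with MA"),
    enc("E5", pid = "PC", note = "pt with MA")
  ))
  m <- extract_advanced(x)
  expect_equal(m$concept_id[m$encounter_id == "E2" & m$provenance == "disambiguated"],
               "migraine_with_aura")
  expect_equal(m$concept_id[m$encounter_id == "E4" & m$provenance == "disambiguated"],
               "mass")
  # zero-evidence patient: the ambiguous mention is dropped
  expect_false(any(m$encounter_id == "E5"))
})
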