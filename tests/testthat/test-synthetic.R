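test_that("degenerate probabilities render every migraine encounter everywhere", {
  cc <- data.frame(concept_id = "migraine", category = "diagnosis",
                   prevalence = 1, structured_prob = 1, narrative_prob = 1,
                   multiplicity = 0, stringsAsFactors = FALSE)
  cfg <- generator_config(n_encounters = 100, concepts = cc,
                          abbreviation_prob = 0, template_prob = 0,
                          negated_absent_prob = 0, distractor_prob = 0,
                          historical_prob = 0, seed = 2)
  synth <- generate_corpus(cfg)
  expect_equal(sum(synth$truth$clinically_present), 100L)
  hits <- extract_traditional(synth$corpus)
  expect_setequal(unique(hits$encounter_id),
                  migrwe:::encounter_ids(synth$corpus))
  notes <- vapply(synth$corpus$encounters, `[[`, character(1), "note_text")
  expect_true(all(grepl("migraine", tolower(notes), fixed = TRUE)))
})

test_that("generation is a pure function of the configuration and seed", {
  cfg <- small_config(n = 40, seed = 42)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$gold_mentions, s2$gold_mentions)
  expect_identical(s1$corpus$encounters, s2$corpus$encounters)
  # a different seed changes the corpus
  s3 <- generate_corpus(small_config(n = 40, seed = 43))
  expect_false(identical(s1$corpus$encounters, s3$corpus$encounters))
})

test_that("structured rendering counts follow the binomial expectation", {
  cc <- default_profile()$concepts
  cc$prevalence[] <- 0.5
  cfg <- generator_config(n_encounters = 4000, concepts = cc, seed = 13)
  synth <- generate_corpus(cfg)
  tr <- synth$truth[synth$truth$concept_id == "nausea" &
                      synth$truth$clinically_present, ]
  n_true <- nrow(tr)
  s <- cc$structured_prob[cc$concept_id == "nausea"]
  se <- sqrt(n_true * s * (1 - s))
  expect_lt(abs(sum(tr$structured_rendered) - n_true * s), 3 * se)
})

test_that("generated corpora satisfy the package's own validation with no issues", {
  synth <- generate_corpus(small_config(n = 80, seed = 4))
  expect_length(validate_corpus(synth$corpus), 0L)
})

test_that("gold mention offsets resolve into the generated notes", {
  synth <- generate_corpus(small_config(n = 60, seed = 17))
  notes <- stats::setNames(
    vapply(synth$corpus$encounters, `[[`, character(1), "note_text"),
    vapply(synth$corpus$encounters, `[[`, character(1), "encounter_id"))
  g <- synth$gold_mentions
  expect_gt(nrow(g), 0)
  expect_equal(substr(notes[g$encounter_id], g$start + 1, g$end), g$surface,
               ignore_attr = TRUE)
  # gold mentions exist only where the truth says narrative_rendered
  narr <- synth$truth[synth$truth$narrative_rendered, ]
  key_g <- unique(paste(g$encounter_id, g$concept_id))
  key_n <- paste(narr$encounter_id, narr$concept_id)
  expect_true(all(key_g %in% key_n))
  expect_true(all(key_n %in% key_g))
})

test_that("the default profile encodes the published study dimensions", {
  cfg <- default_profile()
  expect_equal(cfg$n_encounters, 6032L)
  cc <- cfg$concepts
  symptoms <- cc[cc$category == "symptom", ]
  expect_true(all(symptoms$structured_prob <= 0.179))
  expect_true(all(symptoms$narrative_prob >= 0.793 &
                    symptoms$narrative_prob <= 0.966))
  # expected narrated occurrences reproduce the published per-concept counts
  expected <- 6032 * cc$prevalence * cc$narrative_prob * (1 + cc$multiplicity)
  targets <- c(migraine = 2642, headache = 6530, nausea = 4057,
               vomiting = 3197, light_sensitivity = 243,
               loss_of_appetite = 377, dizziness = 3391, fatigue = 4088,
               rizatriptan = 102, sumatriptan = 510)
  expect_equal(stats::setNames(expected, cc$concept_id), targets,
               tolerance = 1e-6)
})

test_that("noise-free narration is fully recoverable by the advanced arm", {
  cc <- default_profile()$concepts
  cc$prevalence <- pmin(1, cc$prevalence * 2)
  cfg <- generator_config(n_encounters = 150, concepts = cc,
                          abbreviation_prob = 0, template_prob = 0,
                          negated_absent_prob = 0, distractor_prob = 0,
                          seed = 23)
  synth <- generate_corpus(cfg)
  m <- extract_advanced(synth$corpus)
  found <- unique(paste(m$encounter_id, m$concept_id)[m$asserted])
  narr <- synth$truth[synth$truth$narrative_rendered, ]
  expect_true(all(paste(narr$encounter_id, narr$concept_id) %in% found))
})

test_that("truth files round-trip through JSON Lines", {
  synth <- generate_corpus(small_config(n = 15, seed = 31))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_truth(synth, path)
  back <- read_truth(path)
  expect_equal(back$truth, synth$truth)
  gm <- synth$gold_mentions[order(synth$gold_mentions$encounter_id,
                                  synth$gold_mentions$concept_id,
                                  synth$gold_mentions$start), ]
  gb <- back$gold_mentions[order(back$gold_mentions$encounter_id,
                                 back$gold_mentions$concept_id,
                                 back$gold_mentions$start), ]
  rownames(gm) <- rownames(gb) <- NULL
  expect_equal(gb, gm[, names(gb)])
})

test_that("YAML configurations load into equivalent generator configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_encounters: 25",
    "seed: 9",
    "template_prob: 0.0",
    "concepts:",
    "  - concept_id: migraine",
    "    category: diagnosis",
    "    prevalence: 0.4",
    "    structured_prob: 0.7",
    "    narrative_prob: 0.9",
    "    multiplicity: 0.1",
    "  - concept_id: nausea",
    "    category: symptom",
    "    prevalence: 0.3",
    "    structured_prob: 0.05",
    "    narrative_prob: 0.9"), path)
  cfg <- load_generator_config(path)
  expect_s3_class(cfg, "rwe_generator_config")
  expect_equal(cfg$n_encounters, 25L)
  expect_equal(cfg$template_prob, 0)
  expect_equal(cfg$concepts$multiplicity, c(0.1, 0))
  expect_silent(generate_corpus(cfg))
})

test_that("invalid probabilities are rejected before generation", {
  cc <- default_profile()$concepts
  cc$prevalence[1] <- 1.2
  expect_error(generator_config(10, cc), "probabilities")
  cc2 <- default_profile()$concepts
  cc2$multiplicity[1] <- -1
  expect_error(generator_config(10, cc2), "multiplicity")
})
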