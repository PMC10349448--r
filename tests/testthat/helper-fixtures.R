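# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

enc <- function(eid, pid = "P1", doc = "D1", date = "2011-06-01",
                note = "", problems = NULL, meds = NULL, claims = NULL) {
  encounter(patient_id = pid, encounter_id = eid, physician_id = doc,
            date = date, problem_list = problems, medication_list = meds,
            claims = claims, note_text = note)
}

codes <- function(system, code) data.frame(code_system = system, code = code,
                                           stringsAsFactors = FALSE)

# annotation data.frame from (encounter_id, concept_id) presence pairs
ann <- function(encounter_ids, concept_id, annotator = "A",
                asserted = TRUE) {
  if (length(encounter_ids) == 0) {
    return(data.frame(encounter_id = character(), annotator_id = character(),
                      concept_id = character(), start = integer(),
                      end = integer(), asserted = logical(),
                      temporality = character(), severity = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(encounter_id = encounter_ids, annotator_id = annotator,
             concept_id = concept_id, start = NA_integer_, end = NA_integer_,
             asserted = asserted, temporality = "unspecified",
             severity = "unspecified", stringsAsFactors = FALSE)
}

# annotation frame from a logical presence vector over an encounter universe
ann_from_presence <- function(presence, encounters, concept_id,
                              annotator = "A") {
  ann(encounters[presence], concept_id, annotator)
}

# independent contingency-table kappa oracle (coded separately from the
# implementation: builds the full 2x2 table and applies the definition)
kappa_oracle <- function(a, b) {
  tab <- table(factor(a, levels = c(FALSE, TRUE)),
               factor(b, levels = c(FALSE, TRUE)))
  n <- sum(tab)
  p_o <- (tab[1, 1] + tab[2, 2]) / n
  p_e <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

# brute-force encounter-level metric oracle: double loop over the universe
metrics_oracle <- function(pred_df, ref_df, concept_id, encounters) {
  tp <- fp <- fn <- 0L
  for (e in encounters) {
    in_pred <- any(pred_df$encounter_id == e &
                     pred_df$concept_id == concept_id & pred_df$asserted)
    in_ref <- any(ref_df$encounter_id == e &
                    ref_df$concept_id == concept_id & ref_df$asserted)
    if (in_pred && in_ref) tp <- tp + 1L
    if (in_pred && !in_ref) fp <- fp + 1L
    if (!in_pred && in_ref) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# closed-form Pearson chi-square for a 2x2 table
chi2_closed_form <- function(tab) {
  tab <- matrix(as.numeric(tab), 2)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# a small generator configuration that runs fast in unit tests
small_config <- function(n = 60, seed = 1, ...) {
  cc <- default_profile()$concepts
  generator_config(n_encounters = n, concepts = cc, seed = seed, ...)
}
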