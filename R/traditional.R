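#' Traditional-arm extraction: structured fields only
#'
#' Emulates the structured-query arm of a dual-arm RWE study: every coded
#' entry on the problem list, medication list, or encounter-associated claims
#' that the code map assigns to a concept yields exactly one hit. The note
#' text is never consulted, and duplicate coded entries yield duplicate hits
#' (encounter-level de-duplication is the evaluator's job, preserving the
#' distinction between concept occurrence and encounter occurrence).
#'
#' Coded entries in a code system the map does not know are skipped with one
#' summary warning; codes that are simply unmapped within a known system are
#' silently ignored.
#'
#' @param x an `ehr_corpus` or a single `ehr_encounter`
#' @param code_map code map data.frame (see [default_code_map()])
#' @return data.frame of hits: `encounter_id`, `concept_id`, `source_field`,
#'   `code_system`, `code`
#' @export
extract_traditional <- function(x, code_map = default_code_map()) {
  if (inherits(x, "ehr_encounter")) x <- corpus(list(x))
  stopifnot(inherits(x, "ehr_corpus"))
  fields <- c("problem_list", "medication_list", "claims")
  parts <- lapply(x$encounters, function(e) {
    per_field <- lapply(fields, function(f) {
      df <- e[[f]]
      if (nrow(df) == 0) return(NULL)
      data.frame(encounter_id = e$encounter_id, source_field = f,
                 code_system = df$code_system, code = df$code,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_field)
  })
  entries <- do.call(rbind, parts)
  empty <- data.frame(encounter_id = character(), concept_id = character(),
                      source_field = character(), code_system = character(),
                      code = character(), stringsAsFactors = FALSE)
  if (is.null(entries) || nrow(entries) == 0) return(empty)
  known_systems <- unique(code_map$code_system)
  unknown <- setdiff(unique(entries$code_system), known_systems)
  if (length(unknown)) {
    warnf("skipping coded entries with unknown code system(s): %s",
          paste(unknown, collapse = ", "))
    entries <- entries[entries$code_system %in% known_systems, , drop = FALSE]
  }
  if (nrow(entries) == 0) return(empty)
  entries$concept_id <- lookup_codes(entries$code_system, entries$code, code_map)
  hits <- entries[!is.na(entries$concept_id),
                  c("encounter_id", "concept_id", "source_field",
                    "code_system", "code"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}
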