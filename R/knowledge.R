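#' The evaluated concept set
#'
#' The ten target concepts scored in the dual-arm study: two headache-family
#' conditions, six migraine-associated symptoms, and two triptan medications.
#'
#' @return data.frame with columns `concept_id`, `label`, `category`
#' @export
concept_defs <- function() {
  data.frame(
    concept_id = c("migraine", "headache", "nausea", "vomiting",
                   "light_sensitivity", "loss_of_appetite", "dizziness",
                   "fatigue", "rizatriptan", "sumatriptan"),
    label = c("Migraine", "Headache", "Nausea", "Vomiting",
              "Light sensitivity", "Loss of appetite", "Dizziness",
              "Fatigue", "Rizatriptan", "Sumatriptan"),
    category = c("diagnosis", "diagnosis", "symptom", "symptom", "symptom",
                 "symptom", "symptom", "symptom", "medication", "medication"),
    stringsAsFactors = FALSE
  )
}

target_concepts <- function() concept_defs()$concept_id

# Concepts the lexicon may reference beyond the evaluated ten: the
# migraine-with-aura child concept and the distractor concepts used by the
# abbreviation disambiguator ("MA" = migraine with aura vs. mass).
auxiliary_concepts <- function() {
  c("migraine_with_aura", "mass", "lung_cancer", "tumor")
}

known_concepts <- function() c(target_concepts(), auxiliary_concepts())

#' Load a concept lexicon from a TSV file
#'
#' Columns: `surface` (term as written), `concept_ids` (one or more concept
#' identifiers, `'|'`-separated; more than one marks the surface ambiguous),
#' `term_type` (`preferred`, `synonym`, or `abbreviation`). Surfaces are
#' stored lowercase; lookups are case-insensitive. Duplicate
#' (surface, concept set) rows are collapsed with a warning.
#'
#' @param path TSV file with a header row
#' @param known character vector of valid concept identifiers
#' @return data.frame with columns `surface`, `concept_ids`, `term_type`,
#'   `ambiguous`
#' @export
load_lexicon <- function(path, known = known_concepts()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("surface", "concept_ids", "term_type")
  if (!all(need %in% names(df))) {
    stopf("lexicon %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warnf("lexicon %s has a header but no entries", path)
    return(data.frame(surface = character(), concept_ids = character(),
                      term_type = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  df$surface <- tolower(trimws(df$surface))
  df$concept_ids <- trimws(df$concept_ids)
  bad_type <- !df$term_type %in% c("preferred", "synonym", "abbreviation")
  if (any(bad_type)) {
    stopf("lexicon %s: invalid term_type on row(s) %s", path,
          paste(which(bad_type), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    ids <- strsplit(df$concept_ids[i], "|", fixed = TRUE)[[1]]
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      stopf("lexicon %s row %d: unknown concept_id '%s'", path, i,
            paste(unknown, collapse = "', '"))
    }
  }
  key <- paste(df$surface, df$concept_ids, sep = "\r")
  if (anyDuplicated(key)) {
    warnf("lexicon %s: %d duplicate (surface, concept) row(s) collapsed",
          path, sum(duplicated(key)))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (anyDuplicated(df$surface)) {
    dup <- unique(df$surface[duplicated(df$surface)])
    stopf("lexicon %s: surface(s) listed twice with different concept sets: %s (use '|' for ambiguity)",
          path, paste(dup, collapse = ", "))
  }
  df$ambiguous <- vapply(strsplit(df$concept_ids, "|", fixed = TRUE),
                         function(x) length(x) > 1, logical(1))
  rownames(df) <- NULL
  df
}

#' The shipped default lexicon
#'
#' Terms, synonyms and abbreviations for the ten target concepts plus the
#' ambiguous abbreviation `"MA"` and its distractor senses. The abbreviation
#' inventory is a plausible clinical reconstruction, not an authoritative
#' list.
#'
#' @return lexicon data.frame (see [load_lexicon()])
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "migraine_lexicon.tsv",
                           package = "migrwe", mustWork = TRUE))
}

#' Candidate concepts for a surface string
#'
#' Case-insensitive; internal whitespace is collapsed before lookup.
#'
#' @param surface term string as matched in text
#' @param lexicon lexicon data.frame
#' @return character vector of candidate concept ids (empty when unknown)
#' @export
lexicon_candidates <- function(surface, lexicon) {
  s <- gsub("\\s+", " ", tolower(trimws(surface)))
  hit <- lexicon$concept_ids[lexicon$surface == s]
  if (length(hit) == 0) return(character())
  strsplit(hit[1], "|", fixed = TRUE)[[1]]
}

#' Load a concept code map from a TSV file
#'
#' Columns: `concept_id`, `code_system` (`ICD9`, `ICD10`, `DRUG`), `code`.
#' Codes are stored trimmed and uppercased; each (code_system, code) pair maps
#' to exactly one concept.
#'
#' @param path TSV file with a header row
#' @param known valid concept identifiers
#' @return data.frame with columns `concept_id`, `code_system`, `code`
#' @export
load_code_map <- function(path, known = known_concepts()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  need <- c("concept_id", "code_system", "code")
  if (!all(need %in% names(df))) {
    stopf("code map %s must have columns: %s", path, paste(need, collapse = ", "))
  }
  df$concept_id <- trimws(df$concept_id)
  df$code_system <- trimws(df$code_system)
  df$code <- toupper(trimws(df$code))
  unknown <- setdiff(df$concept_id, known)
  if (length(unknown)) {
    stopf("code map %s: unknown concept_id '%s'", path,
          paste(unknown, collapse = "', '"))
  }
  key <- paste(df$code_system, df$code, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stopf("code map %s: (code_system, code) mapped more than once: %s", path,
          paste(gsub("\r", " ", unique(dup)), collapse = "; "))
  }
  rownames(df) <- NULL
  df
}

#' The shipped default code map
#'
#' ICD-9/ICD-10 diagnosis codes for the headache-family and symptom concepts
#' and normalized drug-name codes (system `DRUG`) for the triptans. Symptom
#' concepts do have diagnosis codes: how rarely clinicians use them is a
#' documentation behaviour, modelled by the corpus generator, not a gap in
#' the map.
#'
#' @return code map data.frame (see [load_code_map()])
#' @export
default_code_map <- function() {
  load_code_map(system.file("extdata", "migraine_code_map.tsv",
                            package = "migrwe", mustWork = TRUE))
}

#' Look up the concept for a coded entry
#'
#' Exact string match after trimming and uppercasing the code.
#'
#' @param code_system code system identifier
#' @param code code string
#' @param code_map code map data.frame
#' @return concept id, or `NA_character_` when unmapped
#' @export
lookup_code <- function(code_system, code, code_map) {
  lookup_codes(code_system, code, code_map)
}

# vectorized code lookup
lookup_codes <- function(code_system, code, code_map) {
  key <- paste(code_system, toupper(trimws(code)), sep = "\r")
  map <- stats::setNames(code_map$concept_id,
                         paste(code_map$code_system, code_map$code, sep = "\r"))
  unname(map[key])
}

#' Load an association-weight table from a TSV file
#'
#' A plain, inspectable stand-in for a learned healthcare-association corpus:
#' symmetric non-negative weights between concept pairs, used by the
#' longitudinal abbreviation disambiguator. Missing pairs score zero.
#'
#' @param path TSV with columns `concept_a`, `concept_b`, `weight`
#' @param known valid concept identifiers
#' @return data.frame with columns `concept_a`, `concept_b`, `weight`
#' @export
load_association_table <- function(path, known = known_concepts()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = c("character", "character", "numeric"),
                          fileEncoding = "UTF-8")
  need <- c("concept_a", "concept_b", "weight")
  if (!all(need %in% names(df))) {
    stopf("association table %s must have columns: %s", path,
          paste(need, collapse = ", "))
  }
  if (any(df$weight < 0 | is.na(df$weight))) {
    stopf("association table %s: weights must be non-negative", path)
  }
  unknown <- setdiff(c(df$concept_a, df$concept_b), known)
  if (length(unknown)) {
    stopf("association table %s: unknown concept(s): %s", path,
          paste(unknown, collapse = ", "))
  }
  df
}

#' The shipped default association table
#' @return association data.frame (see [load_association_table()])
#' @export
default_association_table <- function() {
  load_association_table(system.file("extdata", "migraine_associations.tsv",
                                     package = "migrwe", mustWork = TRUE))
}

association_weight <- function(a, b, table) {
  hit <- (table$concept_a == a & table$concept_b == b) |
    (table$concept_a == b & table$concept_b == a)
  if (any(hit)) sum(table$weight[hit]) else 0
}

#' Association evidence for a candidate concept against a context
#'
#' The sum over context concepts of the (symmetric) pairwise weight with the
#' candidate. Additive over disjoint contexts; an empty context scores zero.
#'
#' @param candidate candidate concept id
#' @param context character vector (set) of context concept ids
#' @param table association table data.frame
#' @return non-negative numeric score
#' @export
association_score <- function(candidate, context, table) {
  context <- unique(context)
  if (length(context) == 0) return(0)
  sum(vapply(context, association_weight, numeric(1), a = candidate,
             table = table))
}
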