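#' Coded entry (code system + code)
#'
#' A single coded item as found on a problem list, medication list, or claim.
#'
#' @param code_system code system identifier, e.g. `"ICD9"`, `"ICD10"`, `"DRUG"`
#' @param code code string within the system
#' @return one-row data.frame with columns `code_system`, `code`
#' @export
coded_entry <- function(code_system, code) {
  stopifnot(is_string(code_system), is_string(code))
  data.frame(code_system = code_system, code = code, stringsAsFactors = FALSE)
}

normalize_coded_entries <- function(x, what, where = "") {
  if (is.null(x) || (is.list(x) && length(x) == 0)) {
    return(data.frame(code_system = character(), code = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(x)) {
    df <- x
  } else if (is.list(x)) {
    df <- do.call(rbind, lapply(x, function(e) {
      data.frame(code_system = e$code_system %||% NA_character_,
                 code = e$code %||% NA_character_, stringsAsFactors = FALSE)
    }))
  } else {
    stopf("field '%s'%s is not a list of coded entries", what, where)
  }
  if (!all(c("code_system", "code") %in% names(df))) {
    stopf("field '%s'%s: coded entries need 'code_system' and 'code'", what, where)
  }
  df <- df[, c("code_system", "code"), drop = FALSE]
  df$code_system <- as.character(df$code_system)
  df$code <- as.character(df$code)
  if (anyNA(df$code_system) || anyNA(df$code)) {
    stopf("field '%s'%s: coded entry missing code_system or code", what, where)
  }
  df
}

#' Construct a single EHR encounter
#'
#' An encounter is a single visit for a patient with a single physician on a
#' specific date. It carries the structured fields (problem list, medication
#' list, encounter-associated claims) and one free-text note.
#'
#' @param patient_id,encounter_id,physician_id opaque identifier strings
#' @param date visit date, `"YYYY-MM-DD"` (ISO 8601) or a `Date`
#' @param problem_list,medication_list,claims data.frames of coded entries
#'   (columns `code_system`, `code`), or lists coercible to one
#' @param note_text the free-text clinical note (may be empty)
#' @return an object of class `ehr_encounter`
#' @export
encounter <- function(patient_id, encounter_id, physician_id, date,
                      problem_list = NULL, medication_list = NULL,
                      claims = NULL, note_text = "") {
  if (inherits(date, "Date")) date <- format(date, "%Y-%m-%d")
  stopifnot(is_string(patient_id), is_string(encounter_id),
            is_string(physician_id), is_string(date), is_string(note_text))
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", date) || is.na(as.Date(date, "%Y-%m-%d"))) {
    stopf("invalid ISO date '%s' for encounter %s", date, encounter_id)
  }
  structure(list(
    encounter_id = encounter_id,
    patient_id = patient_id,
    physician_id = physician_id,
    date = date,
    problem_list = normalize_coded_entries(problem_list, "problem_list"),
    medication_list = normalize_coded_entries(medication_list, "medication_list"),
    claims = normalize_coded_entries(claims, "claims"),
    note_text = note_text
  ), class = "ehr_encounter")
}

#' @export
print.ehr_encounter <- function(x, ...) {
  cat(sprintf("<encounter %s: patient %s, physician %s, %s>\n",
              x$encounter_id, x$patient_id, x$physician_id, x$date))
  cat(sprintf("  problem_list: %d, medication_list: %d, claims: %d, note: %d chars\n",
              nrow(x$problem_list), nrow(x$medication_list), nrow(x$claims),
              nchar(x$note_text)))
  invisible(x)
}

#' Construct an EHR corpus
#'
#' @param encounters list of [encounter()] objects; iteration order is
#'   preserved and equals file order on round trips
#' @param source_tag free-text provenance tag
#' @return an object of class `ehr_corpus`
#' @export
corpus <- function(encounters = list(), source_tag = "") {
  stopifnot(is.list(encounters), is_string(source_tag))
  for (e in encounters) {
    if (!inherits(e, "ehr_encounter")) stop("all elements must be encounters")
  }
  ids <- vapply(encounters, `[[`, character(1), "encounter_id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("duplicate encounter_id in corpus: %s", paste(dup, collapse = ", "))
  }
  structure(list(encounters = encounters, source_tag = source_tag),
            class = "ehr_corpus")
}

#' @export
length.ehr_corpus <- function(x) length(x$encounters)

#' @export
print.ehr_corpus <- function(x, ...) {
  cat(sprintf("<ehr_corpus: %d encounters%s>\n", length(x),
              if (nzchar(x$source_tag)) paste0(", source: ", x$source_tag) else ""))
  invisible(x)
}

#' @export
`[.ehr_corpus` <- function(x, i) {
  corpus(x$encounters[i], source_tag = x$source_tag)
}

encounter_ids <- function(corpus) {
  vapply(corpus$encounters, `[[`, character(1), "encounter_id")
}

#' Validate corpus-level invariants
#'
#' Checks that (patient_id, physician_id, date) triples are unique (the visit
#' identity) and that every coded entry names a known code system.
#'
#' @param x an `ehr_corpus`
#' @param known_systems character vector of recognized code system identifiers
#' @return character vector of human-readable issues (empty when clean)
#' @export
validate_corpus <- function(x, known_systems = c("ICD9", "ICD10", "DRUG")) {
  stopifnot(inherits(x, "ehr_corpus"))
  issues <- character()
  triples <- vapply(x$encounters, function(e) {
    paste(e$patient_id, e$physician_id, e$date, sep = "\r")
  }, character(1))
  if (anyDuplicated(triples)) {
    dup <- unique(triples[duplicated(triples)])
    issues <- c(issues, sprintf(
      "duplicate (patient, physician, date) visit triple: %s",
      gsub("\r", " / ", dup)))
  }
  systems <- unique(unlist(lapply(x$encounters, function(e) {
    c(e$problem_list$code_system, e$medication_list$code_system,
      e$claims$code_system)
  })))
  unknown <- setdiff(systems, known_systems)
  if (length(unknown)) {
    issues <- c(issues, sprintf("unknown code system(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  issues
}

encounter_from_record <- function(rec, line_no) {
  req <- c("encounter_id", "patient_id", "physician_id", "date")
  missing <- req[!vapply(req, function(f) is_string(rec[[f]] %||% NA_character_),
                         logical(1))]
  if (length(missing)) {
    stopf("line %d: missing or invalid field(s): %s", line_no,
          paste(missing, collapse = ", "))
  }
  encounter(
    patient_id = rec$patient_id, encounter_id = rec$encounter_id,
    physician_id = rec$physician_id, date = rec$date,
    problem_list = rec$problem_list,
    medication_list = rec$medication_list,
    claims = rec$claims,
    note_text = rec$note_text %||% ""
  )
}

#' Read an encounter corpus from a JSON Lines file
#'
#' One encounter object per line; line order is preserved. Malformed lines are
#' reported with their line numbers; a repeated `encounter_id` is fatal and the
#' error names every line involved.
#'
#' @param path file path
#' @param source_tag provenance tag stored on the corpus (default: file name)
#' @return an `ehr_corpus`
#' @export
read_corpus <- function(path, source_tag = basename(path)) {
  recs <- read_jsonl(path)
  line_nos <- attr(recs, "line_numbers")
  encs <- vector("list", length(recs))
  errors <- character()
  for (i in seq_along(recs)) {
    encs[[i]] <- tryCatch(encounter_from_record(recs[[i]], line_nos[i]),
                          error = function(e) {
                            errors <<- c(errors, conditionMessage(e))
                            NULL
                          })
  }
  if (length(errors)) {
    stopf("malformed encounter record(s) in %s:\n  %s", path,
          paste(errors, collapse = "\n  "))
  }
  ids <- vapply(encs, `[[`, character(1), "encounter_id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- vapply(dup, function(d) {
      sprintf("encounter_id '%s' on lines %s", d,
              paste(line_nos[ids == d], collapse = ", "))
    }, character(1))
    stopf("duplicate encounter id(s) in %s: %s", path,
          paste(msg, collapse = "; "))
  }
  corpus(encs, source_tag = source_tag)
}

encounter_to_record <- function(e) {
  codes_out <- function(df) {
    if (nrow(df) == 0) list() else df
  }
  list(encounter_id = e$encounter_id, patient_id = e$patient_id,
       physician_id = e$physician_id, date = e$date,
       problem_list = codes_out(e$problem_list),
       medication_list = codes_out(e$medication_list),
       claims = codes_out(e$claims),
       note_text = e$note_text)
}

#' Write a corpus to a JSON Lines file
#'
#' `read_corpus(write_corpus(x, path))` is field-for-field identical to `x`.
#'
#' @param x an `ehr_corpus`
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "ehr_corpus"))
  write_jsonl(lapply(x$encounters, encounter_to_record), path)
  invisible(path)
}

#' Encounter preselection filter
#'
#' @param terms character vector of filter terms (stored lowercase); matching
#'   is case-insensitive
#' @param match_fields subset of `c("note_text", "structured_codes")`
#' @return a `filter_spec` object
#' @export
filter_spec <- function(terms, match_fields = "note_text") {
  stopifnot(is.character(terms), length(terms) > 0, all(nzchar(terms)))
  match_fields <- match.arg(match_fields, c("note_text", "structured_codes"),
                            several.ok = TRUE)
  structure(list(terms = tolower(terms), match_fields = match_fields),
            class = "filter_spec")
}

#' Filter a corpus to encounters mentioning at least one filter term
#'
#' Preselection enriches the data set for relevant concepts; it is applied
#' identically to both study arms. Note matching is a case-insensitive
#' substring scan of the raw note text (word boundaries are deliberately not
#' required: the filter enriches, it does not assert). Structured matching
#' retains an encounter when any coded entry maps, through the code map, to a
#' concept one of the filter terms names in the lexicon.
#'
#' @param x an `ehr_corpus`
#' @param spec a [filter_spec()]
#' @param lexicon,code_map required only when `spec` includes
#'   `"structured_codes"`; see [default_lexicon()] and [default_code_map()]
#' @return the filtered sub-corpus (possibly empty); encounters are untouched
#' @export
filter_encounters <- function(x, spec, lexicon = NULL, code_map = NULL) {
  stopifnot(inherits(x, "ehr_corpus"), inherits(spec, "filter_spec"))
  keep <- rep(FALSE, length(x))
  if ("note_text" %in% spec$match_fields) {
    notes <- tolower(vapply(x$encounters, `[[`, character(1), "note_text"))
    for (term in spec$terms) {
      keep <- keep | grepl(term, notes, fixed = TRUE)
    }
  }
  if ("structured_codes" %in% spec$match_fields) {
    if (is.null(lexicon) || is.null(code_map)) {
      stop("structured_codes matching requires a lexicon and a code map")
    }
    target <- unique(unlist(lapply(spec$terms, function(t) {
      lexicon_candidates(t, lexicon)
    })))
    keep_struct <- vapply(x$encounters, function(e) {
      codes <- rbind(e$problem_list, e$medication_list, e$claims)
      if (nrow(codes) == 0) return(FALSE)
      concepts <- lookup_codes(codes$code_system, codes$code, code_map)
      any(!is.na(concepts) & concepts %in% target)
    }, logical(1))
    keep <- keep | keep_struct
  }
  x[which(keep)]
}
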