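empty_mentions <- function() {
  data.frame(encounter_id = character(), concept_id = character(),
             start = integer(), end = integer(), surface = character(),
             asserted = logical(), temporality = character(),
             severity = character(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' Deterministic rule-based sentence segmentation
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?` followed by
#' whitespace) and on newline boundaries; clinical notes are strongly
#' newline-structured, so no statistical model is needed. Offsets are 0-based,
#' half-open, into the original note text; each sentence's text equals the
#' corresponding slice of the note.
#'
#' @param note_text the note (may be empty)
#' @return data.frame with columns `start`, `end`, `text`
#' @export
segment_sentences <- function(note_text) {
  stopifnot(is_string(note_text))
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(note_text)) return(empty)
  lm <- gregexpr("[^\n]+", note_text)[[1]]
  if (lm[1] == -1) return(empty)
  starts <- integer(); ends <- integer(); texts <- character()
  for (k in seq_along(lm)) {
    ls <- lm[k]                       # 1-based line start
    line <- substr(note_text, ls, ls + attr(lm, "match.length")[k] - 1)
    b <- gregexpr("(?<=[.!?])[ \t]+", line, perl = TRUE)[[1]]
    if (b[1] == -1) {
      p_start <- 1L
      p_end <- nchar(line)
    } else {
      blen <- attr(b, "match.length")
      p_start <- c(1L, as.integer(b) + blen)
      p_end <- c(as.integer(b) - 1L, nchar(line))
    }
    for (j in seq_along(p_start)) {
      piece <- substr(line, p_start[j], p_end[j])
      # trim, keeping offsets honest
      lead <- nchar(sub("^([ \t]*).*$", "\\1", piece))
      piece_trim <- trimws(piece)
      if (!nzchar(piece_trim)) next
      s1 <- ls + p_start[j] - 1L + lead          # 1-based in note
      starts <- c(starts, s1 - 1L)               # 0-based
      ends <- c(ends, s1 - 1L + nchar(piece_trim))
      texts <- c(texts, piece_trim)
    }
  }
  data.frame(start = starts, end = ends, text = texts, stringsAsFactors = FALSE)
}

# One alternation pattern over all lexicon surfaces, longest alternatives
# first so the leftmost match at a position is also the longest; lookaround
# guards enforce whole-token matching (blocks "ha" inside "asthma").
build_lexicon_pattern <- function(lexicon) {
  if (nrow(lexicon) == 0) return(NULL)
  surfaces <- lexicon$surface[order(-nchar(lexicon$surface))]
  esc <- gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", surfaces, perl = TRUE)
  paste0("(?<![[:alnum:]])(?:", paste(esc, collapse = "|"), ")(?![[:alnum:]])")
}

#' Dictionary concept matching within one sentence
#'
#' Case-insensitive, whole-token, longest-match-first scan of a sentence
#' against the lexicon. Overlapping shorter matches are suppressed; an
#' ambiguous surface (e.g. `"MA"`) emits all candidate concepts for
#' downstream disambiguation.
#'
#' @param sentence a one-row data.frame from [segment_sentences()], or a plain
#'   string (then offsets are sentence-relative)
#' @param lexicon lexicon data.frame (see [default_lexicon()])
#' @return data.frame with columns `surface`, `start`, `end` (note-level,
#'   0-based half-open), `concept_ids` (`'|'`-joined candidates), `ambiguous`
#' @export
match_concepts <- function(sentence, lexicon) {
  if (is.character(sentence)) {
    sentence <- data.frame(start = 0L, end = nchar(sentence), text = sentence,
                           stringsAsFactors = FALSE)
  }
  pattern <- attr(lexicon, "migrwe_pattern") %||% build_lexicon_pattern(lexicon)
  match_concepts_impl(sentence$text[1], sentence$start[1], pattern, lexicon)
}

match_concepts_impl <- function(text, sent_start0, pattern, lexicon) {
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), concept_ids = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE)
  if (is.null(pattern) || !nzchar(text)) return(empty)
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(empty)
  len <- attr(m, "match.length")
  surface <- substring(text, m, m + len - 1)
  key <- gsub("\\s+", " ", tolower(surface))
  idx <- match(key, lexicon$surface)
  ok <- !is.na(idx)
  data.frame(surface = surface[ok],
             start = sent_start0 + as.integer(m[ok]) - 1L,
             end = sent_start0 + as.integer(m[ok]) - 1L + len[ok],
             concept_ids = lexicon$concept_ids[idx[ok]],
             ambiguous = lexicon$ambiguous[idx[ok]],
             stringsAsFactors = FALSE)
}

NEGATION_TRIGGERS <- "\\b(?:no|not|denies|denied|deny|without|negative\\s+for|neg\\s+for)\\b"
SCOPE_TERMINATORS <- "\\b(?:but|however|although|except)\\b|;"
HISTORY_TRIGGERS <- "\\b(?:history\\s+of|hx\\s+of|h/o|prior|previous|previously|past)\\b"
SEVERITY_CUES <- c(mild = "mild", mod = "moderate", moderate = "moderate",
                   severe = "severe")

last_match_pos <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) -1L else max(as.integer(m))
}

#' Attribute detection within the sentence boundary
#'
#' Trigger-scope rules in the NegEx/ConText tradition: a negation trigger
#' (`no`, `denies`, `without`, ...) preceding the match within the sentence
#' with no scope-terminating conjunction (`but`, `however`, `although`, `;`)
#' in between marks the mention not asserted. Historical triggers
#' (`history of`, `prior`, ...) under the same scope rule set temporality to
#' `historical`, else `current`. A severity cue (`mild`, `mod`, `moderate`,
#' `severe`) immediately preceding the match sets severity.
#'
#' @param sentence one-row data.frame from [segment_sentences()] (or a string)
#' @param match one-row data.frame from [match_concepts()] with note-level
#'   offsets (or sentence-relative when `sentence` is a string)
#' @return list with elements `asserted` (logical), `temporality`
#'   (`current`/`historical`), `severity` (`mild`/`moderate`/`severe`/
#'   `unspecified`)
#' @export
detect_attributes <- function(sentence, match) {
  if (is.character(sentence)) {
    sentence <- data.frame(start = 0L, end = nchar(sentence), text = sentence,
                           stringsAsFactors = FALSE)
  }
  rel_start <- match$start[1] - sentence$start[1]
  stopifnot(rel_start >= 0, match$end[1] <= sentence$end[1])
  pre <- substr(sentence$text[1], 1, rel_start)
  term_pos <- last_match_pos(SCOPE_TERMINATORS, pre)
  neg_pos <- last_match_pos(NEGATION_TRIGGERS, pre)
  hist_pos <- last_match_pos(HISTORY_TRIGGERS, pre)
  asserted <- !(neg_pos > term_pos)
  temporality <- if (hist_pos > term_pos) "historical" else "current"
  last_word <- tolower(sub("^.*?([A-Za-z]+)[^A-Za-z]*$", "\\1", pre))
  severity <- if (nzchar(pre) && last_word %in% names(SEVERITY_CUES)) {
    unname(SEVERITY_CUES[[last_word]])
  } else {
    "unspecified"
  }
  list(asserted = asserted, temporality = temporality, severity = severity)
}

#' Parse sign-prefixed review-of-systems template lines
#'
#' A template line consists solely of tokens prefixed `+` or `-`, separated by
#' commas and/or whitespace, e.g. `"-headache, +nausea"`. `+` records a
#' positive assertion; `-` records a provisional negative whose fate is
#' decided by encounter-level support ([resolve_template_support()]). Prose
#' lines are ignored.
#'
#' @param note_text the note
#' @return data.frame with columns `surface`, `sign`, `start`, `end`
#'   (note-level, 0-based offsets of the surface), `line_start`, `line_end`
#' @export
parse_templates <- function(note_text) {
  stopifnot(is_string(note_text))
  empty <- data.frame(surface = character(), sign = character(),
                      start = integer(), end = integer(),
                      line_start = integer(), line_end = integer(),
                      stringsAsFactors = FALSE)
  if (!nzchar(note_text)) return(empty)
  lm <- gregexpr("[^\n]+", note_text)[[1]]
  if (lm[1] == -1) return(empty)
  out <- list()
  tok_re <- "[+-]\\s*[A-Za-z](?:[A-Za-z ]*[A-Za-z])?"
  for (k in seq_along(lm)) {
    ls <- lm[k]
    line <- substr(note_text, ls, ls + attr(lm, "match.length")[k] - 1)
    if (!grepl("^\\s*[+-]", line)) next
    tm <- gregexpr(tok_re, line, perl = TRUE)[[1]]
    if (tm[1] == -1) next
    tlen <- attr(tm, "match.length")
    # every character outside the tokens must be separator punctuation
    residual <- line
    for (j in rev(seq_along(tm))) {
      substr(residual, tm[j], tm[j] + tlen[j] - 1) <-
        paste(rep(" ", tlen[j]), collapse = "")
    }
    if (grepl("[^ \t,]", residual)) next
    toks <- substring(line, tm, tm + tlen - 1)
    sign <- substr(toks, 1, 1)
    body <- sub("^[+-]\\s*", "", toks)
    body_off <- tm + (nchar(toks) - nchar(body))   # 1-based in line
    out[[length(out) + 1]] <- data.frame(
      surface = body, sign = sign,
      start = ls - 1L + as.integer(body_off) - 1L,
      end = ls - 1L + as.integer(body_off) - 1L + nchar(body),
      line_start = ls - 1L,
      line_end = ls - 1L + nchar(line),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve template assertions against free-text support in the encounter
#'
#' A `+` record yields an asserted mention. A `-` record yields a
#' not-asserted mention *unless* the same concept already has an asserted
#' free-text mention in the encounter, in which case the free-text assertion
#' wins and no negative is emitted. Template surfaces that are unknown to the
#' lexicon, or ambiguous, are skipped.
#'
#' @param templates data.frame from [parse_templates()]
#' @param mentions free-text mention data.frame for the same encounter (may
#'   have zero rows)
#' @param lexicon lexicon data.frame
#' @param encounter_id id stamped on emitted mentions
#' @return mention data.frame rows with `provenance = "template"`
#' @export
resolve_template_support <- function(templates, mentions, lexicon,
                                     encounter_id = "") {
  out <- empty_mentions()
  if (nrow(templates) == 0) return(out)
  supported <- unique(mentions$concept_id[mentions$asserted])
  rows <- list()
  for (i in seq_len(nrow(templates))) {
    cand <- lexicon_candidates(templates$surface[i], lexicon)
    if (length(cand) != 1) next
    if (templates$sign[i] == "-" && cand %in% supported) next
    rows[[length(rows) + 1]] <- data.frame(
      encounter_id = encounter_id, concept_id = cand,
      start = templates$start[i], end = templates$end[i],
      surface = templates$surface[i],
      asserted = templates$sign[i] == "+",
      temporality = "unspecified", severity = "unspecified",
      provenance = "template", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(out)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Disambiguate an ambiguous abbreviation over the longitudinal record
#'
#' Scores every candidate sense by its summed association weight against the
#' set of concepts asserted anywhere in the patient's record, and returns the
#' top candidate only when its margin over the runner-up is strictly greater
#' than `margin` (default 0: any strictly positive difference resolves; ties
#' and all-zero contexts abstain, so the mention is dropped rather than
#' silently asserted wrong).
#'
#' @param candidates character vector of 2+ candidate concept ids
#' @param context set of concept ids from the patient's longitudinal record
#'   (excluding concepts derived from the ambiguous surface itself)
#' @param table association table (see [default_association_table()])
#' @param margin minimum score margin required to resolve
#' @return the winning concept id, or `NA_character_` when unresolvable
#' @export
disambiguate <- function(candidates, context, table, margin = 0) {
  stopifnot(length(candidates) >= 2)
  scores <- vapply(candidates, association_score, numeric(1),
                   context = context, table = table)
  ord <- order(scores, decreasing = TRUE)
  if (scores[ord[1]] - scores[ord[2]] > margin) candidates[ord[1]] else NA_character_
}

#' Advanced-arm extraction: NLP over the note text
#'
#' The full unstructured-data pipeline: sentence segmentation, dictionary
#' concept matching, sentence-scoped attribute detection, sign-prefixed
#' template parsing with encounter-level support resolution, and
#' longitudinal-record abbreviation disambiguation. Structured fields are
#' never consulted. Deterministic: the same corpus always yields the same
#' mention list.
#'
#' The longitudinal context for disambiguation is the union of concepts from
#' unambiguous asserted mentions across *all* of the patient's encounters in
#' the corpus (the whole record, as seen by a retrospective study).
#'
#' @param x an `ehr_corpus`
#' @param lexicon lexicon data.frame
#' @param assoc association table data.frame
#' @param margin disambiguation margin (see [disambiguate()])
#' @return mention data.frame: `encounter_id`, `concept_id`, `start`, `end`,
#'   `surface`, `asserted`, `temporality`, `severity`, `provenance`
#'   (`free_text`, `template`, or `disambiguated`)
#' @export
extract_advanced <- function(x, lexicon = default_lexicon(),
                             assoc = default_association_table(), margin = 0) {
  stopifnot(inherits(x, "ehr_corpus"))
  pattern <- build_lexicon_pattern(lexicon)
  resolved <- list()        # per-encounter mention frames
  pending <- list()         # ambiguous matches awaiting patient context
  patient_of <- character()
  for (e in x$encounters) {
    note <- e$note_text
    patient_of[[e$encounter_id]] <- e$patient_id
    if (!nzchar(note)) next
    templates <- parse_templates(note)
    sents <- segment_sentences(note)
    rows <- list(); amb <- list()
    for (si in seq_len(nrow(sents))) {
      s <- sents[si, , drop = FALSE]
      if (nrow(templates) > 0 &&
          any(s$start >= templates$line_start & s$start < templates$line_end)) {
        next  # template lines are handled by the template parser
      }
      matches <- match_concepts_impl(s$text, s$start, pattern, lexicon)
      for (mi in seq_len(nrow(matches))) {
        m <- matches[mi, , drop = FALSE]
        attrs <- detect_attributes(s, m)
        row <- data.frame(
          encounter_id = e$encounter_id, concept_id = m$concept_ids,
          start = m$start, end = m$end, surface = m$surface,
          asserted = attrs$asserted, temporality = attrs$temporality,
          severity = attrs$severity, provenance = "free_text",
          stringsAsFactors = FALSE)
        if (m$ambiguous) {
          amb[[length(amb) + 1]] <- row
        } else {
          rows[[length(rows) + 1]] <- row
        }
      }
    }
    free <- if (length(rows)) do.call(rbind, rows) else empty_mentions()
    tmpl <- resolve_template_support(templates, free, lexicon, e$encounter_id)
    enc_mentions <- rbind(free, tmpl)
    if (nrow(enc_mentions)) resolved[[length(resolved) + 1]] <- enc_mentions
    if (length(amb)) pending[[length(pending) + 1]] <- do.call(rbind, amb)
  }
  mentions <- if (length(resolved)) do.call(rbind, resolved) else empty_mentions()
  if (length(pending)) {
    pend <- do.call(rbind, pending)
    # longitudinal context: asserted unambiguous concepts per patient
    pat <- patient_of[mentions$encounter_id]
    ctx <- split(mentions$concept_id[mentions$asserted],
                 pat[mentions$asserted])
    extra <- list()
    for (i in seq_len(nrow(pend))) {
      cand <- strsplit(pend$concept_id[i], "|", fixed = TRUE)[[1]]
      patient <- patient_of[[pend$encounter_id[i]]]
      context <- unique(ctx[[patient]] %||% character())
      winner <- disambiguate(cand, context, assoc, margin)
      if (is.na(winner)) next
      row <- pend[i, , drop = FALSE]
      row$concept_id <- winner
      row$provenance <- "disambiguated"
      extra[[length(extra) + 1]] <- row
    }
    if (length(extra)) mentions <- rbind(mentions, do.call(rbind, extra))
  }
  if (nrow(mentions)) {
    ord <- order(match(mentions$encounter_id, encounter_ids(x)), mentions$start)
    mentions <- mentions[ord, , drop = FALSE]
    rownames(mentions) <- NULL
  }
  mentions
}

#' Read / write mention files (JSON Lines, one mention per line)
#' @param mentions mention data.frame
#' @param path file path
#' @return `path` invisibly (write) or a mention data.frame (read)
#' @export
write_mentions <- function(mentions, path) {
  write_jsonl(df_to_records(mentions), path)
  invisible(path)
}

#' @rdname write_mentions
#' @export
read_mentions <- function(path) {
  recs <- read_jsonl(path)
  if (length(recs) == 0) return(empty_mentions())
  res <- do.call(rbind, lapply(recs, function(r) {
    data.frame(encounter_id = r$encounter_id, concept_id = r$concept_id,
               start = as.integer(r$start %||% NA_integer_),
               end = as.integer(r$end %||% NA_integer_),
               surface = r$surface %||% NA_character_,
               asserted = isTRUE(r$asserted),
               temporality = r$temporality %||% "unspecified",
               severity = r$severity %||% "unspecified",
               provenance = r$provenance %||% "free_text",
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Roll child concepts up to their evaluation parent
#'
#' The default map folds `migraine_with_aura` into `migraine`: the ambiguous
#' abbreviation "MA" names a distinct clinical sense, but the study evaluates
#' it under the migraine concept.
#'
#' @param mentions mention (or hit) data.frame with a `concept_id` column
#' @param map named character vector, `names = child`, `values = parent`
#' @return the data.frame with `concept_id` rewritten
#' @export
rollup_concepts <- function(mentions,
                            map = c(migraine_with_aura = "migraine")) {
  hit <- mentions$concept_id %in% names(map)
  mentions$concept_id[hit] <- unname(map[mentions$concept_id[hit]])
  mentions
}
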