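empty_annotations <- function() {
  data.frame(encounter_id = character(), annotator_id = character(),
             concept_id = character(), start = integer(), end = integer(),
             asserted = logical(), temporality = character(),
             severity = character(), stringsAsFactors = FALSE)
}

#' Read / write annotation files (JSON Lines, one label per line)
#'
#' A label is an encounter-level (or span-level, when offsets are present)
#' concept assignment by one annotator, with the same attribute vocabulary as
#' extracted mentions.
#'
#' @param annotations annotation data.frame
#' @param path file path
#' @return `path` invisibly (write) or an annotation data.frame (read)
#' @export
write_annotations <- function(annotations, path) {
  write_jsonl(df_to_records(annotations), path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  recs <- read_jsonl(path)
  if (length(recs) == 0) return(empty_annotations())
  res <- do.call(rbind, lapply(recs, function(r) {
    data.frame(encounter_id = r$encounter_id,
               annotator_id = r$annotator_id %||% NA_character_,
               concept_id = r$concept_id,
               start = as.integer(r$start %||% NA_integer_),
               end = as.integer(r$end %||% NA_integer_),
               asserted = isTRUE(r$asserted %||% TRUE),
               temporality = r$temporality %||% "unspecified",
               severity = r$severity %||% "unspecified",
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

# per-encounter binary presence of an asserted concept
presence_vector <- function(labels, concept_id, encounters) {
  pos <- unique(labels$encounter_id[labels$concept_id == concept_id &
                                      labels$asserted])
  encounters %in% pos
}

kappa_binary <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  p_o <- mean(a == b)
  p_yes_a <- mean(a); p_yes_b <- mean(b)
  p_e <- p_yes_a * p_yes_b + (1 - p_yes_a) * (1 - p_yes_b)
  if (p_e >= 1) return(1)  # degenerate marginals; perfect agreement by convention
  (p_o - p_e) / (1 - p_e)
}

#' Cohen's kappa for one concept between two annotators
#'
#' Labels are reduced to per-encounter binary presence (the concept asserted
#' at least once in the encounter), the level at which recall is later
#' computed, and chance-corrected agreement is
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with marginal-product expected
#' agreement. Kappa is computed *prior to* any resolution of disagreement.
#' Span mismatches with concept agreement count as agreement (concepts, not
#' offsets, are evaluated).
#'
#' @param labels_a,labels_b annotation data.frames from the two annotators
#' @param concept_id concept to score
#' @param encounters the shared encounter universe; default: all encounter ids
#'   appearing in either annotation set
#' @return kappa in \[-1, 1\]
#' @export
compute_kappa <- function(labels_a, labels_b, concept_id, encounters = NULL) {
  if (is.null(encounters)) {
    encounters <- unique(c(labels_a$encounter_id, labels_b$encounter_id))
  }
  if (length(encounters) == 0) stop("empty encounter set", call. = FALSE)
  a <- presence_vector(labels_a, concept_id, encounters)
  b <- presence_vector(labels_b, concept_id, encounters)
  kappa_binary(a, b)
}

#' Average kappa across concepts and annotator pairs
#'
#' The study-level agreement figure is the unweighted mean of per-concept,
#' per-pair kappas; an average of at least `threshold` (default 0.8,
#' inclusive) is required for the reference standard to count as credible.
#'
#' @param x either a numeric vector of kappas, or a list of annotation rounds,
#'   each a list with elements `a` and `b` (annotation data.frames) and
#'   optionally `encounters`
#' @param concepts concepts to score when `x` is a list of rounds
#' @param threshold pass threshold
#' @return list with `kappas`, `mean`, and logical `pass`
#' @export
average_kappa <- function(x, concepts = target_concepts(), threshold = 0.8) {
  if (is.numeric(x)) {
    kappas <- x
  } else {
    stopifnot(is.list(x), length(x) >= 1)
    kappas <- unlist(lapply(x, function(round) {
      vapply(concepts, function(cc) {
        compute_kappa(round$a, round$b, cc, round$encounters %||% NULL)
      }, numeric(1))
    }))
  }
  if (length(kappas) == 0) stop("no kappas to average", call. = FALSE)
  m <- mean(kappas)
  list(kappas = kappas, mean = m, pass = m >= threshold)
}

#' Adjudicate dual annotations into a reference standard
#'
#' Per encounter and concept: when the two primary annotators agree on
#' presence, the shared label stands; on disagreement the third annotator's
#' (tiebreaker's) label decides. A disagreement with no tiebreak label is an
#' error naming the encounters involved. The output contains only positive
#' presence labels (absence is implicit), so the adjudicated set is exactly
#' the union of agreed labels and tiebroken labels.
#'
#' @param labels_a,labels_b primary annotators' label sets
#' @param labels_tiebreak tiebreaker's labels (may be `NULL` when the primaries
#'   agree everywhere)
#' @param concepts concepts to adjudicate
#' @param encounters encounter universe; default: ids in either primary set
#' @return annotation data.frame (`annotator_id = "adjudicated"`)
#' @export
adjudicate <- function(labels_a, labels_b, labels_tiebreak = NULL,
                       concepts = target_concepts(), encounters = NULL) {
  if (is.null(encounters)) {
    encounters <- unique(c(labels_a$encounter_id, labels_b$encounter_id))
  }
  out <- list()
  unresolved <- character()
  for (cc in concepts) {
    a <- presence_vector(labels_a, cc, encounters)
    b <- presence_vector(labels_b, cc, encounters)
    agree <- a == b
    present <- a & agree
    dis <- which(!agree)
    if (length(dis)) {
      if (is.null(labels_tiebreak)) {
        unresolved <- c(unresolved, encounters[dis])
      } else {
        t_all <- presence_vector(labels_tiebreak, cc, encounters)
        covered <- encounters[dis] %in% unique(
          labels_tiebreak$encounter_id[labels_tiebreak$concept_id == cc])
        # a tiebreak file must explicitly label every disputed encounter:
        # a positive label asserts presence, an explicit negative absence
        has_row <- encounters[dis] %in% labels_tiebreak$encounter_id[
          labels_tiebreak$concept_id == cc]
        unresolved <- c(unresolved, encounters[dis][!has_row])
        present[dis[has_row]] <- t_all[dis[has_row]]
      }
    }
    idx <- which(present)
    if (length(idx)) {
      out[[length(out) + 1]] <- data.frame(
        encounter_id = encounters[idx], annotator_id = "adjudicated",
        concept_id = cc, start = NA_integer_, end = NA_integer_,
        asserted = TRUE, temporality = "unspecified",
        severity = "unspecified", stringsAsFactors = FALSE)
    }
  }
  if (length(unresolved)) {
    stopf("disagreement without a tiebreak label for encounter(s): %s",
          paste(unique(unresolved), collapse = ", "))
  }
  if (length(out) == 0) return(empty_annotations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
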