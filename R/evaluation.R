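#' Concept and encounter occurrence counts
#'
#' Concept occurrence is the sum of all asserted instances of a concept;
#' encounter occurrence is the number of encounters with at least one.
#' Negated mentions never count.
#'
#' @param x mention or annotation data.frame (`concept_id`, `encounter_id`,
#'   `asserted` columns)
#' @param concept_id concept to count
#' @return list with `concept_id`, `concept_occurrences`,
#'   `encounter_occurrences`
#' @export
count_occurrences <- function(x, concept_id) {
  rows <- x[x$concept_id == concept_id & x$asserted, , drop = FALSE]
  list(concept_id = concept_id,
       concept_occurrences = nrow(rows),
       encounter_occurrences = length(unique(rows$encounter_id)))
}

# set of encounters where the concept is asserted, optionally requiring
# attribute agreement metadata to be carried along
presence_set <- function(x, concept_id) {
  unique(x$encounter_id[x$concept_id == concept_id & x$asserted])
}

#' F1 score (Table-style harmonic mean)
#'
#' `2 * (precision * recall) / (precision + recall)`; zero when either input
#' is zero.
#'
#' @param precision,recall values in \[0, 1\]
#' @return F1 in \[0, 1\]
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * (precision * recall) / (precision + recall)
}

#' Construct a metric result from confusion counts
#'
#' @param concept_id concept
#' @param arm `"traditional"` or `"advanced"`
#' @param tp,fp,fn confusion counts at the encounter level
#' @return object of class `rwe_metrics`: the counts plus `recall`,
#'   `precision` (`NA` when `tp + fp = 0`), and `f1` (0 when `tp = 0`)
#' @export
metric_result <- function(concept_id, arm, tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  arm <- match.arg(arm, c("traditional", "advanced"))
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (tp == 0) 0 else f1_score(precision, recall)
  structure(list(concept_id = concept_id, arm = arm, tp = tp, fp = fp,
                 fn = fn, recall = recall, precision = precision, f1 = f1),
            class = "rwe_metrics")
}

#' @export
print.rwe_metrics <- function(x, ...) {
  cat(sprintf("<%s / %s: tp=%d fp=%d fn=%d recall=%s precision=%s f1=%s>\n",
              x$concept_id, x$arm, x$tp, x$fp, x$fn,
              fmt_pct(x$recall), fmt_pct(x$precision), fmt_pct(x$f1)))
  invisible(x)
}

fmt_pct <- function(p) if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)

#' Encounter-level recall, precision and F1 against the reference standard
#'
#' Concepts are discrete, time-specific events, so they are scored at the
#' encounter level: a concept counts as correctly identified only in the
#' specific encounters where the reference asserts it — presence is never
#' propagated across the longitudinal record. Predictions and reference are
#' reduced to per-encounter asserted presence over the same (post-filter)
#' encounter universe.
#'
#' @param predictions mention/hit data.frame for one arm (hits without an
#'   `asserted` column are treated as asserted)
#' @param reference reference-standard annotation data.frame
#' @param concept_id concept to score
#' @param encounters the shared encounter universe (character vector of ids);
#'   ids outside it in either input are a fatal error
#' @param arm arm label stamped on the result
#' @return an `rwe_metrics` object (see [metric_result()])
#' @export
compute_metrics <- function(predictions, reference, concept_id, encounters,
                            arm = "advanced") {
  if (is.null(predictions$asserted)) predictions$asserted <- TRUE
  stray_p <- setdiff(unique(predictions$encounter_id), encounters)
  stray_r <- setdiff(unique(reference$encounter_id), encounters)
  if (length(stray_p) || length(stray_r)) {
    stopf("encounter universe mismatch: %d prediction and %d reference encounter id(s) outside the universe",
          length(stray_p), length(stray_r))
  }
  pred <- intersect(presence_set(predictions, concept_id), encounters)
  ref <- intersect(presence_set(reference, concept_id), encounters)
  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref, pred))
  metric_result(concept_id, arm, tp, fp, fn)
}

chi2_2x2 <- function(tab) {
  # Pearson chi-square without continuity correction; degenerate margins
  # (identical proportions are still fine) give statistic 0, p 1
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1, expected = tab * NA))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       expected = ct$expected)
}

#' Compare the two study arms on one concept
#'
#' Reports the absolute recall difference in percentage points and a Pearson
#' chi-square (no continuity correction) on the 2x2 table
#' `[[tp_trad, fn_trad], [tp_adv, fn_adv]]`. The protocol's success flag for
#' Advanced over Traditional is recall of at least 80% or an absolute recall
#' difference of at least 25 percentage points. An expected cell below 1
#' attaches a warning to the result rather than failing.
#'
#' @param metric_trad,metric_adv `rwe_metrics` for the same concept
#' @return object of class `rwe_comparison` with fields `concept_id`,
#'   `abs_recall_difference` (percentage points), `chi2_statistic`, `p_value`,
#'   `success`, `warning`
#' @export
compare_arms <- function(metric_trad, metric_adv) {
  stopifnot(inherits(metric_trad, "rwe_metrics"),
            inherits(metric_adv, "rwe_metrics"),
            identical(metric_trad$concept_id, metric_adv$concept_id))
  diff_pp <- abs(metric_adv$recall - metric_trad$recall) * 100
  tab <- matrix(c(metric_trad$tp, metric_trad$fn,
                  metric_adv$tp, metric_adv$fn),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("traditional", "advanced"),
                                c("found", "missed")))
  chi <- chi2_2x2(tab)
  warn <- if (!all(is.na(chi$expected)) && any(chi$expected < 1)) {
    "expected cell count below 1; chi-square approximation unreliable"
  } else {
    NA_character_
  }
  success <- isTRUE(metric_adv$recall >= 0.80) || isTRUE(diff_pp >= 25)
  structure(list(concept_id = metric_trad$concept_id,
                 abs_recall_difference = diff_pp,
                 chi2_statistic = chi$statistic, p_value = chi$p_value,
                 success = success, warning = warn),
            class = "rwe_comparison")
}

#' @export
print.rwe_comparison <- function(x, ...) {
  cat(sprintf("<%s: |recall diff| = %.1f pp, chi2 = %.2f, p = %s, success = %s>\n",
              x$concept_id, x$abs_recall_difference, x$chi2_statistic,
              format.pval(x$p_value, digits = 3), x$success))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Assemble the full evaluation report
#'
#' One row per concept and arm (recall, precision, F1, confusion counts), one
#' arm comparison per concept, and descriptive occurrence counts — the layout
#' of a per-concept results figure. Every target concept must be present in
#' both arms; a missing cell is fatal. Regeneration from the same inputs is
#' byte-identical.
#'
#' @param metrics list of `rwe_metrics` (both arms, all concepts)
#' @param comparisons list of `rwe_comparison` (one per concept)
#' @param occurrences list of occurrence-count lists from
#'   [count_occurrences()] (reference-standard counts)
#' @param concepts concepts the report must cover
#' @return object of class `rwe_report` holding data.frames `metrics`,
#'   `comparisons`, `occurrences`
#' @export
evaluation_report <- function(metrics, comparisons, occurrences,
                              concepts = target_concepts()) {
  mdf <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(concept_id = m$concept_id, arm = m$arm, tp = m$tp, fp = m$fp,
               fn = m$fn, recall = m$recall, precision = m$precision,
               f1 = m$f1, stringsAsFactors = FALSE)
  }))
  for (cc in concepts) {
    for (arm in c("traditional", "advanced")) {
      if (!any(mdf$concept_id == cc & mdf$arm == arm)) {
        stopf("missing metrics for concept '%s', arm '%s'", cc, arm)
      }
    }
  }
  cdf <- do.call(rbind, lapply(comparisons, function(cmp) {
    data.frame(concept_id = cmp$concept_id,
               abs_recall_difference = cmp$abs_recall_difference,
               chi2_statistic = cmp$chi2_statistic, p_value = cmp$p_value,
               success = cmp$success, warning = cmp$warning,
               stringsAsFactors = FALSE)
  }))
  missing_cmp <- setdiff(concepts, cdf$concept_id)
  if (length(missing_cmp)) {
    stopf("missing arm comparison for concept(s): %s",
          paste(missing_cmp, collapse = ", "))
  }
  odf <- do.call(rbind, lapply(occurrences, function(o) {
    data.frame(concept_id = o$concept_id,
               concept_occurrences = o$concept_occurrences,
               encounter_occurrences = o$encounter_occurrences,
               stringsAsFactors = FALSE)
  }))
  mdf <- mdf[order(match(mdf$concept_id, concepts), mdf$arm), , drop = FALSE]
  cdf <- cdf[order(match(cdf$concept_id, concepts)), , drop = FALSE]
  odf <- odf[order(match(odf$concept_id, concepts)), , drop = FALSE]
  rownames(mdf) <- rownames(cdf) <- rownames(odf) <- NULL
  structure(list(metrics = mdf, comparisons = cdf, occurrences = odf),
            class = "rwe_report")
}

#' @export
print.rwe_report <- function(x, ...) {
  cat("Dual-arm evaluation against the reference standard\n")
  cat(sprintf("%-18s %8s %8s | %-22s | %-22s | %8s %8s %s\n",
              "concept", "occ", "enc_occ", "traditional R/P/F1",
              "advanced R/P/F1", "diff_pp", "chi2", "p"))
  for (cc in unique(x$metrics$concept_id)) {
    mt <- x$metrics[x$metrics$concept_id == cc & x$metrics$arm == "traditional", ]
    ma <- x$metrics[x$metrics$concept_id == cc & x$metrics$arm == "advanced", ]
    cmp <- x$comparisons[x$comparisons$concept_id == cc, ]
    occ <- x$occurrences[x$occurrences$concept_id == cc, ]
    trio <- function(m) sprintf("%s/%s/%s", fmt_pct(m$recall),
                                fmt_pct(m$precision), fmt_pct(m$f1))
    cat(sprintf("%-18s %8s %8s | %-22s | %-22s | %8.1f %8.1f %s\n",
                cc,
                if (nrow(occ)) occ$concept_occurrences else NA,
                if (nrow(occ)) occ$encounter_occurrences else NA,
                trio(mt), trio(ma), cmp$abs_recall_difference,
                cmp$chi2_statistic,
                format.pval(cmp$p_value, digits = 3)))
  }
  invisible(x)
}

#' Write / read an evaluation report as JSON
#' @param report an `rwe_report`
#' @param path file path
#' @return `path` invisibly (write) or an `rwe_report` (read)
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "rwe_report"))
  json <- jsonlite::toJSON(unclass(report), dataframe = "rows", na = "null",
                           digits = NA, pretty = TRUE)
  atomic_write_lines(as.character(json), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(paste(read_utf8_lines(path), collapse = "\n"),
                            simplifyDataFrame = TRUE)
  structure(list(metrics = obj$metrics, comparisons = obj$comparisons,
                 occurrences = obj$occurrences), class = "rwe_report")
}
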