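# Surface realizations the note renderer draws from, per concept. Assertion
# sentences use noun-ish surfaces; denials and template tokens use the first
# (preferred) entry.
GEN_SURFACES <- list(
  migraine = c("migraine", "migraines"),
  headache = c("headache", "headaches"),
  nausea = c("nausea"),
  vomiting = c("vomiting", "emesis"),
  light_sensitivity = c("light sensitivity", "photophobia"),
  loss_of_appetite = c("loss of appetite", "decreased appetite"),
  dizziness = c("dizziness", "lightheadedness"),
  fatigue = c("fatigue", "tiredness"),
  rizatriptan = c("rizatriptan", "Maxalt"),
  sumatriptan = c("sumatriptan", "Imitrex")
)

ASSERT_TEMPLATES <- list(c("Patient reports ", "."),
                         c("Pt c/o ", " today."),
                         c("She describes ", " with gradual onset."))
MED_TEMPLATES <- list(c("Prescribed ", " for abortive therapy."),
                      c("Continue ", " as needed."),
                      c("Pt takes ", " with good relief."))
DENIAL_TEMPLATES <- list(c("Denies ", "."), c("No ", "."),
                         c("Negative for ", "."))
SEV_TOKENS <- c(mild = "mild", moderate = "moderate", mod = "moderate",
                severe = "severe")
NOISE_CODES <- data.frame(
  code_system = "ICD10",
  code = c("Z00.00", "I10", "E11.9", "J06.9", "K21.9"),
  stringsAsFactors = FALSE)

#' Configuration for the synthetic EHR corpus generator
#'
#' Per concept: `prevalence` is the per-encounter probability the concept is
#' clinically present; `structured_prob` the probability a present concept is
#' coded in a structured field (the documentation behaviour behind the
#' Traditional arm's recall); `narrative_prob` the probability it is written
#' into the note (behind the Advanced arm's recall); `multiplicity` the mean
#' number of extra narrative mentions beyond the first. Noise knobs control
#' abbreviation use, sign-prefixed review-of-systems template lines, explicit
#' denials of absent concepts, and ambiguous-abbreviation ("MA") contexts.
#' Generation is a pure function of the configuration, including its seed.
#'
#' @param n_encounters total number of encounters
#' @param concepts data.frame with columns `concept_id`, `category`,
#'   `prevalence`, `structured_prob`, `narrative_prob`, `multiplicity`
#' @param encounters_per_patient mean encounters per patient (>= 1; counts are
#'   `1 + Poisson(mean - 1)`)
#' @param abbreviation_prob probability a headache mention is written "HA"
#' @param template_prob probability a narrated concept's first mention is a
#'   review-of-systems template token rather than a sentence
#' @param negated_absent_prob probability an absent concept is explicitly
#'   denied
#' @param distractor_prob probability a migraine mention is written as the
#'   ambiguous abbreviation "MA" (resolvable only from longitudinal context)
#' @param severity_prob probability an assertion sentence carries a severity
#'   cue
#' @param historical_prob probability a mention is phrased as history
#' @param symptom_lift multiplicative lift of symptom prevalence in
#'   migraine-positive encounters (marginal prevalence is preserved)
#' @param n_physicians size of the physician pool
#' @param date_range character vector of 2 ISO dates bounding visit dates
#' @param ensure_filter_terms guarantee every note contains at least one of
#'   the preselection terms (migraine, headache, rizatriptan, sumatriptan) by
#'   appending a denial when none occurs naturally; keeps the generated set
#'   closed under the study's preselection filter
#' @param seed integer RNG seed
#' @return object of class `rwe_generator_config`
#' @export
generator_config <- function(n_encounters,
                             concepts,
                             encounters_per_patient = 3.5,
                             abbreviation_prob = 0.3,
                             template_prob = 0.15,
                             negated_absent_prob = 0.15,
                             distractor_prob = 0.05,
                             severity_prob = 0.35,
                             historical_prob = 0.08,
                             symptom_lift = 2,
                             n_physicians = 40,
                             date_range = c("2010-01-01", "2012-12-31"),
                             ensure_filter_terms = TRUE,
                             seed = 42L) {
  stopifnot(is.numeric(n_encounters), n_encounters >= 1,
            is.data.frame(concepts),
            all(c("concept_id", "category", "prevalence", "structured_prob",
                  "narrative_prob", "multiplicity") %in% names(concepts)),
            encounters_per_patient >= 1, symptom_lift >= 0,
            n_physicians >= 1)
  probs <- c(concepts$prevalence, concepts$structured_prob,
             concepts$narrative_prob, abbreviation_prob, template_prob,
             negated_absent_prob, distractor_prob, severity_prob,
             historical_prob)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(concepts$multiplicity < 0)) {
    stop("multiplicity must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(concepts$concept_id)) {
    stop("duplicate concept_id in generator concept table", call. = FALSE)
  }
  structure(list(
    n_encounters = as.integer(n_encounters), concepts = concepts,
    encounters_per_patient = encounters_per_patient,
    abbreviation_prob = abbreviation_prob, template_prob = template_prob,
    negated_absent_prob = negated_absent_prob,
    distractor_prob = distractor_prob, severity_prob = severity_prob,
    historical_prob = historical_prob, symptom_lift = symptom_lift,
    n_physicians = as.integer(n_physicians), date_range = date_range,
    ensure_filter_terms = isTRUE(ensure_filter_terms),
    seed = as.integer(seed)
  ), class = "rwe_generator_config")
}

#' The shipped study-emulation profile
#'
#' 6,032 encounters. Structured documentation probabilities mirror the
#' Traditional-arm recalls of the migraine RWE literature (66.6% and 29.6%
#' for migraine and headache, a 0-17.9% band for the six associated symptoms,
#' roughly 80% for the triptans) and narrative documentation probabilities
#' mirror the Advanced-arm recalls (96.8% and 92.9%; a 79.3-96.6% band for
#' symptoms, with per-symptom values chosen inside the band so the
#' protocol success criteria are attainable; >= 98% for the triptans).
#' Prevalence and mention multiplicity are back-calculated so expected
#' narrated concept occurrences approximate the published per-concept counts
#' (migraine 2,642; headache 6,530; nausea 4,057; vomiting 3,197; light
#' sensitivity 243; loss of appetite 377; dizziness 3,391; fatigue 4,088;
#' rizatriptan 102; sumatriptan 510).
#'
#' @param seed RNG seed stored in the configuration
#' @return an `rwe_generator_config`
#' @export
default_profile <- function(seed = 42L) {
  defs <- concept_defs()
  # expected narrated occurrences = n * prevalence * narrative_prob * (1 + multiplicity)
  calib <- data.frame(
    concept_id = defs$concept_id,
    category = defs$category,
    target_occurrences = c(2642, 6530, 4057, 3197, 243, 377, 3391, 4088,
                           102, 510),
    structured_prob = c(0.666, 0.296, 0.05, 0.03, 0.00, 0.02, 0.179, 0.078,
                        0.80, 0.81),
    narrative_prob = c(0.968, 0.929, 0.93, 0.90, 0.87, 0.86, 0.894, 0.966,
                       0.98, 0.99),
    multiplicity = c(0.3, 0.5, 0.2, 0.2, 0.0, 0.0, 0.2, 0.2, 0.0, 0.0),
    stringsAsFactors = FALSE
  )
  n <- 6032L
  calib$prevalence <- calib$target_occurrences /
    (n * calib$narrative_prob * (1 + calib$multiplicity))
  generator_config(
    n_encounters = n,
    concepts = calib[, c("concept_id", "category", "prevalence",
                         "structured_prob", "narrative_prob", "multiplicity")],
    seed = seed
  )
}

choose_surface <- function(cc, cfg) {
  if (cc == "migraine" && stats::runif(1) < cfg$distractor_prob) {
    return("MA")
  }
  if (cc == "headache" && stats::runif(1) < cfg$abbreviation_prob) {
    return("HA")
  }
  pool <- GEN_SURFACES[[cc]] %||% gsub("_", " ", cc)
  pool[sample.int(length(pool), 1)]
}

#' Generate a synthetic EHR corpus with exhaustive ground truth
#'
#' For each encounter, concepts are sampled as clinically present from their
#' prevalences (symptom prevalence conditionally lifted in migraine-positive
#' encounters, marginals preserved); present concepts are rendered into
#' structured codes with `structured_prob` and into note sentences, template
#' tokens, or abbreviations with `narrative_prob`; absent concepts are
#' explicitly denied with `negated_absent_prob`. The truth table covers every
#' encounter-by-concept cell, and every gold narrative mention carries offsets
#' that resolve into the generated note. Identical configurations (including
#' seed) give identical output.
#'
#' @param config an `rwe_generator_config`
#' @param code_map code map used to render structured codes
#' @return list of class `rwe_synth_corpus`: `corpus` (an `ehr_corpus`),
#'   `truth` (encounter-by-concept data.frame with `clinically_present`,
#'   `structured_rendered`, `narrative_rendered`), `gold_mentions` (asserted
#'   narrative mentions with offsets and attributes)
#' @export
generate_corpus <- function(config, code_map = default_code_map()) {
  stopifnot(inherits(config, "rwe_generator_config"))
  set.seed(config$seed)
  cfg <- config
  n <- cfg$n_encounters
  cdf <- cfg$concepts
  ncon <- nrow(cdf)
  cids <- cdf$concept_id

  # --- patients, physicians, dates ------------------------------------------
  sizes <- integer()
  while (sum(sizes) < n) {
    batch <- 1L + stats::rpois(256, max(cfg$encounters_per_patient - 1, 0))
    sizes <- c(sizes, batch)
  }
  cum <- cumsum(sizes)
  np <- which(cum >= n)[1]
  sizes <- sizes[seq_len(np)]
  sizes[np] <- sizes[np] - (cum[np] - n)
  patient_id <- rep(sprintf("P%05d", seq_len(np)), sizes)
  encounter_id <- sprintf("E%06d", seq_len(n))
  physician_id <- sprintf("D%03d", sample.int(cfg$n_physicians, n, replace = TRUE))
  all_dates <- seq(as.Date(cfg$date_range[1]), as.Date(cfg$date_range[2]), by = "day")
  dates <- character(n)
  pos <- 1L
  for (k in sizes) {
    dates[pos:(pos + k - 1L)] <-
      format(sort(sample(all_dates, k, replace = FALSE)), "%Y-%m-%d")
    pos <- pos + k
  }

  # --- truth sampling (vectorized) ------------------------------------------
  prev <- stats::setNames(cdf$prevalence, cids)
  pres <- matrix(FALSE, n, ncon, dimnames = list(NULL, cids))
  has_migraine <- "migraine" %in% cids
  mig <- if (has_migraine) stats::runif(n) < prev[["migraine"]] else rep(FALSE, n)
  if (has_migraine) pres[, "migraine"] <- mig
  pm <- if (has_migraine) prev[["migraine"]] else 0
  for (j in seq_len(ncon)) {
    cc <- cids[j]
    if (cc == "migraine") next
    p <- prev[[cc]]
    if (cdf$category[j] == "symptom" && has_migraine && cfg$symptom_lift != 1) {
      # solve the base rate so the marginal prevalence stays at p
      q <- p / (1 + pm * (cfg$symptom_lift - 1))
      p_cond <- pmin(1, cfg$symptom_lift * q)
      pr <- ifelse(mig, p_cond, q)
      pres[, j] <- stats::runif(n) < pr
    } else {
      pres[, j] <- stats::runif(n) < p
    }
  }
  sprob <- matrix(rep(cdf$structured_prob, each = n), n, ncon)
  uprob <- matrix(rep(cdf$narrative_prob, each = n), n, ncon)
  struct <- pres & (matrix(stats::runif(n * ncon), n, ncon) < sprob)
  narr <- pres & (matrix(stats::runif(n * ncon), n, ncon) < uprob)

  codes_by_concept <- split(code_map[, c("code_system", "code")],
                            code_map$concept_id)
  filter_terms <- c("migraine", "headache", "rizatriptan", "sumatriptan")

  encs <- vector("list", n)
  gm_enc <- list(); gm_cc <- list(); gm_start <- list(); gm_end <- list()
  gm_surf <- list(); gm_temp <- list(); gm_sev <- list(); gm_rend <- list()

  for (i in seq_len(n)) {
    lines <- character()
    # mention staging: line index, offset within line, metadata
    m_line <- integer(); m_rel <- integer(); m_surf <- character()
    m_cc <- character(); m_temp <- character(); m_sev <- character()
    m_rend <- character()
    ros <- list()  # staged review-of-systems tokens: list(sign, surface, concept)

    narrated <- cids[narr[i, ]]
    for (cc in sample(narrated)) {
      j <- match(cc, cids)
      k <- 1L + stats::rpois(1, cdf$multiplicity[j])
      for (rep_i in seq_len(k)) {
        if (rep_i == 1L && stats::runif(1) < cfg$template_prob) {
          surf <- tolower((GEN_SURFACES[[cc]] %||% gsub("_", " ", cc))[1])
          ros[[length(ros) + 1]] <- list(sign = "+", surface = surf, concept = cc)
          next
        }
        surf <- choose_surface(cc, cfg)
        hist <- stats::runif(1) < cfg$historical_prob
        if (hist) {
          prefix <- "History of "; suffix <- "."
          sev <- "unspecified"
        } else if (cdf$category[j] == "medication") {
          tpl <- MED_TEMPLATES[[sample.int(length(MED_TEMPLATES), 1)]]
          prefix <- tpl[1]; suffix <- tpl[2]
          sev <- "unspecified"
        } else {
          tpl <- ASSERT_TEMPLATES[[sample.int(length(ASSERT_TEMPLATES), 1)]]
          prefix <- tpl[1]; suffix <- tpl[2]
          if (stats::runif(1) < cfg$severity_prob) {
            tok <- names(SEV_TOKENS)[sample.int(length(SEV_TOKENS), 1)]
            prefix <- paste0(prefix, tok, " ")
            sev <- unname(SEV_TOKENS[[tok]])
          } else {
            sev <- "unspecified"
          }
        }
        lines <- c(lines, paste0(prefix, surf, suffix))
        m_line <- c(m_line, length(lines)); m_rel <- c(m_rel, nchar(prefix))
        m_surf <- c(m_surf, surf); m_cc <- c(m_cc, cc)
        m_temp <- c(m_temp, if (hist) "historical" else "current")
        m_sev <- c(m_sev, sev)
        m_rend <- c(m_rend, if (surf %in% c("MA")) "ambiguous" else "sentence")
      }
    }

    # explicit denials of absent concepts
    absent <- cids[!pres[i, ]]
    for (cc in absent) {
      if (stats::runif(1) >= cfg$negated_absent_prob) next
      surf <- (GEN_SURFACES[[cc]] %||% gsub("_", " ", cc))[1]
      if (length(ros) > 0 && stats::runif(1) < 0.5) {
        ros[[length(ros) + 1]] <- list(sign = "-", surface = tolower(surf),
                                       concept = cc)
      } else {
        tpl <- DENIAL_TEMPLATES[[sample.int(length(DENIAL_TEMPLATES), 1)]]
        lines <- c(lines, paste0(tpl[1], surf, tpl[2]))
      }
    }

    # assemble the review-of-systems template line
    if (length(ros) > 0) {
      toks <- vapply(ros, function(t) paste0(t$sign, t$surface), character(1))
      ros_line <- paste(toks, collapse = ", ")
      lines <- c(lines, ros_line)
      off <- 0L
      for (t in seq_along(ros)) {
        if (ros[[t]]$sign == "+") {
          m_line <- c(m_line, length(lines))
          m_rel <- c(m_rel, off + 1L)  # skip the sign
          m_surf <- c(m_surf, ros[[t]]$surface)
          m_cc <- c(m_cc, ros[[t]]$concept)
          m_temp <- c(m_temp, "unspecified"); m_sev <- c(m_sev, "unspecified")
          m_rend <- c(m_rend, "template")
        }
        off <- off + nchar(toks[t]) + 2L  # ", "
      }
    }

    # guarantee a preselection term so the filtered study set is the full set
    if (cfg$ensure_filter_terms) {
      note_l <- tolower(paste(lines, collapse = "\n"))
      if (!any(vapply(filter_terms, grepl, logical(1), x = note_l, fixed = TRUE))) {
        fallback <- intersect(c("headache", "migraine", "sumatriptan",
                                "rizatriptan"), cids)
        cc <- if (length(fallback)) {
          fallback[match(TRUE, !pres[i, fallback], nomatch = 1L)]
        } else {
          "headache"  # filter-term denial for a concept outside the truth set
        }
        lines <- c(lines, paste0("Denies ", (GEN_SURFACES[[cc]])[1], "."))
      }
    }

    note <- paste(lines, collapse = "\n")
    if (length(m_line) > 0) {
      line_off <- c(0L, cumsum(nchar(lines) + 1L))  # +1 for the newline
      starts <- line_off[m_line] + m_rel
      gm_enc[[i]] <- rep(encounter_id[i], length(m_line))
      gm_cc[[i]] <- m_cc
      gm_start[[i]] <- starts
      gm_end[[i]] <- starts + nchar(m_surf)
      gm_surf[[i]] <- m_surf
      gm_temp[[i]] <- m_temp
      gm_sev[[i]] <- m_sev
      gm_rend[[i]] <- m_rend
    }

    # structured fields
    pl <- list(); ml <- list(); cl <- list()
    for (cc in cids[struct[i, ]]) {
      rows <- codes_by_concept[[cc]]
      if (is.null(rows) || nrow(rows) == 0) next
      pick <- rows[sample.int(nrow(rows), 1), , drop = FALSE]
      if (pick$code_system == "DRUG") {
        ml[[length(ml) + 1]] <- pick
      } else if (stats::runif(1) < 0.5) {
        pl[[length(pl) + 1]] <- pick
      } else {
        cl[[length(cl) + 1]] <- pick
      }
    }
    n_noise <- stats::rpois(1, 0.5)
    if (n_noise > 0) {
      cl <- c(cl, lapply(sample.int(nrow(NOISE_CODES), n_noise, replace = TRUE),
                         function(r) NOISE_CODES[r, , drop = FALSE]))
    }
    bindcodes <- function(x) if (length(x)) do.call(rbind, x) else NULL
    encs[[i]] <- encounter(
      patient_id = patient_id[i], encounter_id = encounter_id[i],
      physician_id = physician_id[i], date = dates[i],
      problem_list = bindcodes(pl), medication_list = bindcodes(ml),
      claims = bindcodes(cl), note_text = note)
  }

  truth <- data.frame(
    encounter_id = rep(encounter_id, each = ncon),
    concept_id = rep(cids, times = n),
    clinically_present = as.vector(t(pres)),
    structured_rendered = as.vector(t(struct)),
    narrative_rendered = as.vector(t(narr)),
    stringsAsFactors = FALSE)

  enc_v <- unlist(gm_enc) %||% character()
  gold <- data.frame(
    encounter_id = enc_v,
    concept_id = unlist(gm_cc) %||% character(),
    start = as.integer(unlist(gm_start) %||% integer()),
    end = as.integer(unlist(gm_end) %||% integer()),
    surface = unlist(gm_surf) %||% character(),
    asserted = rep(TRUE, length(enc_v)),
    temporality = unlist(gm_temp) %||% character(),
    severity = unlist(gm_sev) %||% character(),
    rendering = unlist(gm_rend) %||% character(),
    stringsAsFactors = FALSE)

  structure(list(
    corpus = corpus(encs, source_tag = sprintf("synthetic(seed=%d)", cfg$seed)),
    truth = truth, gold_mentions = gold, config = cfg
  ), class = "rwe_synth_corpus")
}

#' @export
print.rwe_synth_corpus <- function(x, ...) {
  cat(sprintf("<synthetic EHR corpus: %d encounters, %d concepts, %d gold mentions (seed %d)>\n",
              length(x$corpus), nrow(x$config$concepts), nrow(x$gold_mentions),
              x$config$seed))
  invisible(x)
}

#' Reference-standard annotations from generator truth
#'
#' The synthetic reference standard is the generator's clinical truth: a
#' concept is annotated present in an encounter iff it was sampled as
#' clinically present there (an omniscient abstractor).
#'
#' @param truth truth data.frame from [generate_corpus()]
#' @return annotation data.frame (see [read_annotations()])
#' @export
truth_to_reference <- function(truth) {
  pos <- truth[truth$clinically_present, , drop = FALSE]
  if (nrow(pos) == 0) return(empty_annotations())
  res <- data.frame(encounter_id = pos$encounter_id, annotator_id = "truth",
                    concept_id = pos$concept_id, start = NA_integer_,
                    end = NA_integer_, asserted = TRUE,
                    temporality = "unspecified", severity = "unspecified",
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Simulate a fallible human annotator from the reference standard
#'
#' Each present concept-encounter label is missed with probability
#' `miss_prob`; each absent cell is spuriously labeled with probability
#' `add_prob`. Used to emulate dual annotation for agreement studies.
#' Draws from the current RNG stream.
#'
#' @param reference annotation data.frame (the truth labels)
#' @param encounters encounter universe
#' @param annotator_id id stamped on the labels
#' @param concepts concepts annotated
#' @param miss_prob,add_prob error rates
#' @return annotation data.frame
#' @export
simulate_annotator <- function(reference, encounters,
                               annotator_id = "A1",
                               concepts = target_concepts(),
                               miss_prob = 0.06, add_prob = 0.002) {
  out <- list()
  for (cc in concepts) {
    pos <- presence_vector(reference, cc, encounters)
    keep <- pos & (stats::runif(length(pos)) >= miss_prob)
    added <- !pos & (stats::runif(length(pos)) < add_prob)
    lab <- keep | added
    idx <- which(lab)
    if (length(idx)) {
      out[[length(out) + 1]] <- data.frame(
        encounter_id = encounters[idx], annotator_id = annotator_id,
        concept_id = cc, start = NA_integer_, end = NA_integer_,
        asserted = TRUE, temporality = "unspecified",
        severity = "unspecified", stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_annotations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read the ground-truth file (JSON Lines)
#'
#' One line per encounter-by-concept cell, with the cell's gold narrative
#' mentions nested under `mentions`.
#'
#' @param x an `rwe_synth_corpus` (write) or path (read)
#' @param path destination
#' @return `path` invisibly (write); a list with `truth` and `gold_mentions`
#'   data.frames (read)
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "rwe_synth_corpus"))
  gm <- split(x$gold_mentions, x$gold_mentions$encounter_id)
  recs <- lapply(seq_len(nrow(x$truth)), function(i) {
    row <- x$truth[i, ]
    rec <- as.list(row)
    enc_g <- gm[[row$encounter_id]]
    if (!is.null(enc_g)) {
      enc_g <- enc_g[enc_g$concept_id == row$concept_id, , drop = FALSE]
    }
    rec$mentions <- if (is.null(enc_g) || nrow(enc_g) == 0) list() else
      enc_g[, c("start", "end", "surface", "temporality", "severity",
                "rendering")]
    rec
  })
  write_jsonl(recs, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  recs <- read_jsonl(path)
  truth <- do.call(rbind, lapply(recs, function(r) {
    data.frame(encounter_id = r$encounter_id, concept_id = r$concept_id,
               clinically_present = isTRUE(r$clinically_present),
               structured_rendered = isTRUE(r$structured_rendered),
               narrative_rendered = isTRUE(r$narrative_rendered),
               stringsAsFactors = FALSE)
  }))
  gold <- do.call(rbind, lapply(recs, function(r) {
    m <- r$mentions
    if (is.null(m) || length(m) == 0 ||
        (is.data.frame(m) && nrow(m) == 0)) return(NULL)
    data.frame(encounter_id = r$encounter_id, concept_id = r$concept_id,
               start = as.integer(m$start), end = as.integer(m$end),
               surface = m$surface, asserted = TRUE,
               temporality = m$temporality, severity = m$severity,
               rendering = m$rendering, stringsAsFactors = FALSE)
  }))
  if (is.null(gold)) {
    gold <- data.frame(encounter_id = character(), concept_id = character(),
                       start = integer(), end = integer(),
                       surface = character(), asserted = logical(),
                       temporality = character(), severity = character(),
                       rendering = character(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- rownames(gold) <- NULL
  list(truth = truth, gold_mentions = gold)
}

#' Load a generator configuration from a YAML file
#'
#' Top-level keys mirror [generator_config()] arguments; `concepts` is a list
#' of per-concept mappings.
#'
#' @param path YAML file
#' @return an `rwe_generator_config`
#' @export
load_generator_config <- function(path) {
  obj <- yaml::read_yaml(path)
  concepts <- do.call(rbind, lapply(obj$concepts, function(cc) {
    data.frame(concept_id = cc$concept_id, category = cc$category,
               prevalence = cc$prevalence,
               structured_prob = cc$structured_prob,
               narrative_prob = cc$narrative_prob,
               multiplicity = cc$multiplicity %||% 0,
               stringsAsFactors = FALSE)
  }))
  args <- obj[setdiff(names(obj), "concepts")]
  do.call(generator_config, c(list(concepts = concepts), args))
}
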