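term_meta <- function(surface, category, negated = FALSE, historical = FALSE,
                      other_subject = FALSE) {
  tibble::tibble(surface = surface, category = category, negated = negated,
                 historical = historical, other_subject = other_subject)
}

#' The synthetic sentence bank
#'
#' Every sentence the synthetic grammar can emit, with hand-annotated term
#' metadata: which lexicon terms the sentence contains and with which
#' context modifiers they should be extracted. The metadata is the
#' generation-log oracle — extraction assertions on synthetic notes are
#' checked against it, never against re-running extraction on the text.
#'
#' @return Tibble: `id`, `kind` (event_cue, explicit_cue, attestation,
#'   info, distractor, filler), `intent` (NA for intent-neutral rows),
#'   `text`, `terms` (list of term-metadata tibbles).
#' @export
sentence_bank <- function() {
  tibble::tribble(
    ~id, ~kind, ~intent, ~text, ~terms,
    "ev_self", "event_cue", "self_harm",
    "Patient shot himself in the chest with a handgun.",
    dplyr::bind_rows(term_meta("shot", "shooting_verb"),
                     term_meta("handgun", "weapon_term")),
    "ev_assault", "event_cue", "assault",
    "Patient was shot by another man outside the club.",
    dplyr::bind_rows(term_meta("shot", "shooting_verb"),
                     term_meta("club", "incident_location")),
    "ev_legal", "event_cue", "legal_intervention",
    "Patient was shot by police during the arrest.",
    dplyr::bind_rows(term_meta("shot", "shooting_verb"),
                     term_meta("police", "police_actor")),
    "ev_accident", "event_cue", "accident",
    "The gun accidentally discharged while cleaning the weapon.",
    dplyr::bind_rows(term_meta("gun", "weapon_term"),
                     term_meta("accidentally", "explicit_intent_accident"),
                     term_meta("discharged", "shooting_verb")),
    "ex_accident", "explicit_cue", "accident",
    "Injury due to accidental discharge of a firearm.",
    dplyr::bind_rows(term_meta("accidental discharge",
                               "explicit_intent_accident"),
                     term_meta("firearm", "weapon_term")),
    "ex_assault", "explicit_cue", "assault",
    "Patient reports being attacked during an altercation.",
    term_meta("altercation", "explicit_intent_assault"),
    "ex_self", "explicit_cue", "self_harm",
    "Family states this was a suicide attempt.",
    term_meta("suicide attempt", "explicit_intent_self_harm"),
    "ex_legal", "explicit_cue", "legal_intervention",
    "This was an officer involved shooting.",
    term_meta("officer involved shooting", "explicit_intent_legal"),
    "att_unknown", "attestation", "unknown",
    "The circumstances remain unknown at this time.",
    term_meta("circumstances remain unknown", "no_info_attestation"),
    "info_gsw", "info", NA, "GSW to the left lower extremity.",
    term_meta("gsw", "injury_term"),
    "info_wound", "info", NA, "Single gunshot wound to the torso noted.",
    term_meta("gunshot wound", "injury_term"),
    "info_handgun", "info", NA, "A handgun was recovered at the scene.",
    term_meta("handgun", "weapon_term"),
    "info_street", "info", NA, "Patient was found on the street by EMS.",
    term_meta("street", "incident_location"),
    "info_police", "info", NA, "Police arrived on scene shortly after.",
    term_meta("police", "police_actor"),
    "info_home", "info", NA, "The incident occurred at his home.",
    term_meta("home", "incident_location"),
    "info_apartment", "info", NA, "Neighbors called from the apartment.",
    term_meta("apartment", "incident_location"),
    "info_pistol", "info", NA, "A pistol was found nearby.",
    term_meta("pistol", "weapon_term"),
    "info_rifle", "info", NA, "A rifle was secured at the scene.",
    term_meta("rifle", "weapon_term"),
    "assess_gsw", "info_assessment", NA, "GSW noted on exam.",
    term_meta("gsw", "injury_term"),
    "dx_negated", "distractor", NA, "Denies suicidal ideation.",
    term_meta("suicidal ideation", "explicit_intent_self_harm",
              negated = TRUE),
    "dx_historical", "distractor", NA, "History of GSW 10 years ago.",
    term_meta("gsw", "injury_term", historical = TRUE),
    "dx_confusion", "distractor", NA, "Per police report pt sustained GSW.",
    term_meta("gsw", "injury_term"),
    "dx_other", "distractor", NA, "His brother was shot years ago.",
    term_meta("shot", "shooting_verb", historical = TRUE,
              other_subject = TRUE),
    "fill_1", "filler", NA, "Vital signs stable on arrival.", term_meta(character(), character()),
    "fill_2", "filler", NA, "Labs within normal limits.", term_meta(character(), character()),
    "fill_3", "filler", NA, "CT of the abdomen was obtained.", term_meta(character(), character()),
    "fill_4", "filler", NA, "Pain controlled with medication.", term_meta(character(), character()),
    "fill_5", "filler", NA, "Patient resting comfortably.", term_meta(character(), character()),
    "fill_6", "filler", NA, "Plan for admission to the trauma service.", term_meta(character(), character()),
    "fill_7", "filler", NA, "Dressing applied to the site.", term_meta(character(), character()),
    "fill_8", "filler", NA, "Tetanus status updated.", term_meta(character(), character()),
    "fill_9", "filler", NA, "Patient tolerated the procedure well.", term_meta(character(), character()),
    "fill_10", "filler", NA, "Follow up arranged with the clinic.", term_meta(character(), character())
  )
}

#' Derive a row-stochastic ICD miscoding matrix from marginals
#'
#' Joint tables of ICD-coded versus adjudicated intent are rarely
#' published; what is published are the two marginal distributions. This
#' reconstructs a default joint by iterative proportional fitting from a
#' diagonal-heavy prior with extra affinity on the assault-truth to
#' ICD-accident cell (the documented accident-inflation pattern of
#' medical-record coding), then conditions on the true intent. The result
#' reproduces both marginals to `tol`.
#'
#' @param true_dist Named probabilities of adjudicated intent.
#' @param icd_dist Named probabilities of ICD-coded intent.
#' @param diagonal Prior weight on agreement cells (default 8).
#' @param inflation Extra prior weight on assault-truth/ICD-accident
#'   (default 4).
#' @param tol Convergence tolerance (default 1e-10).
#' @return 5x5 matrix, rows = true intent (summing to 1), cols = ICD intent.
#' @export
miscoding_from_marginals <- function(true_dist, icd_dist, diagonal = 8,
                                     inflation = 4, tol = 1e-10) {
  cls <- intent_levels()
  true_dist <- true_dist[cls] / sum(true_dist[cls])
  icd_dist <- icd_dist[cls] / sum(icd_dist[cls])
  prior <- matrix(1, 5, 5, dimnames = list(cls, cls))
  diag(prior) <- diagonal
  prior["assault", "accident"] <- inflation
  J <- prior
  for (iter in 1:10000) {
    J <- J * (true_dist / rowSums(J))
    J <- t(t(J) * (icd_dist / colSums(J)))
    if (max(abs(rowSums(J) - true_dist)) < tol) break
  }
  P <- J / rowSums(J)
  dimnames(P) <- list(true = cls, icd = cls)
  P
}

#' Site profiles for the synthetic generator
#'
#' A site profile fixes the study conditions a synthetic corpus emulates:
#' the adjudicated intent distribution, the ICD miscoding matrix (derived
#' from the site's published marginals), how many notes a case gets, how
#' much informative content and filler a note carries, cue emission
#' probabilities, and documentation redundancy.
#'
#' `mds_profile()` mirrors a development-site mix: assault-dominated
#' (70.8%), a sizeable unknown share (14.5%), unknown-intent cases that
#' are genuinely information-poor (density-separated), and 9% of cases
#' lacking an ICD discharge code. `evs_profile()` mirrors an external
#' validation site: more accidents and self-harm, few unknowns (3.6%),
#' and uniform documentation density (every case has information-rich
#' notes, so density rules carry no signal).
#'
#' @param name Site label used in case ids.
#' @param intent_distribution Named probabilities over the five intents.
#' @param icd_miscoding 5x5 row-stochastic matrix (true -> ICD).
#' @param icd_missing Probability a case lacks an ICD code.
#' @param cue_strength Named per-intent probability that each cue sentence
#'   of that intent is emitted.
#' @param notes_per_case Probability vector over 1..K notes.
#' @param info_sentences_known,info_sentences_unknown Candidate counts of
#'   informative sentences for known / unknown-intent cases.
#' @param distractor_prob Per-distractor-type emission probability.
#' @param filler_mean,filler_size Negative-binomial filler sentences per
#'   note (mean / dispersion).
#' @param redundancy Integer >= 1; each emitted sentence is written this
#'   many times (documentation drift: more text, no new information).
#' @return An `fi_site_profile` list.
#' @export
site_profile <- function(name = "site",
                         intent_distribution,
                         icd_miscoding,
                         icd_missing = 0,
                         cue_strength = c(accident = 0.9, assault = 0.9,
                                          legal_intervention = 0.9,
                                          self_harm = 0.9, unknown = 0.35),
                         notes_per_case = c(0.5, 0.3, 0.2),
                         info_sentences_known = 4:6,
                         info_sentences_unknown = 0:1,
                         distractor_prob = 0.3,
                         filler_mean = 6, filler_size = 8,
                         redundancy = 1L) {
  cls <- intent_levels()
  intent_distribution <- intent_distribution[cls]
  if (anyNA(intent_distribution) ||
      abs(sum(intent_distribution) - 1) > 0.02 ||
      any(intent_distribution < 0)) {
    stop("intent_distribution must be named probabilities over the 5 intents",
         call. = FALSE)
  }
  # published percentage marginals can be off by rounding; renormalise
  intent_distribution <- intent_distribution / sum(intent_distribution)
  if (!all(dim(icd_miscoding) == c(5, 5)) ||
      any(abs(rowSums(icd_miscoding) - 1) > 1e-6)) {
    stop("icd_miscoding must be a 5x5 row-stochastic matrix", call. = FALSE)
  }
  if (is.null(dimnames(icd_miscoding))) {
    dimnames(icd_miscoding) <- list(cls, cls)
  }
  stopifnot(redundancy >= 1, all(cls %in% names(cue_strength)))
  structure(list(
    name = name, intent_distribution = intent_distribution,
    icd_miscoding = icd_miscoding, icd_missing = icd_missing,
    cue_strength = cue_strength[cls],
    notes_per_case = notes_per_case / sum(notes_per_case),
    info_sentences_known = info_sentences_known,
    info_sentences_unknown = info_sentences_unknown,
    distractor_prob = distractor_prob,
    filler_mean = filler_mean, filler_size = filler_size,
    redundancy = as.integer(redundancy)),
    class = "fi_site_profile")
}

#' @rdname site_profile
#' @export
mds_profile <- function() {
  truth <- c(accident = 0.075, assault = 0.708, legal_intervention = 0.018,
             self_harm = 0.054, unknown = 0.145)
  icd <- c(accident = 0.235, assault = 0.569, legal_intervention = 0.011,
           self_harm = 0.048, unknown = 0.137)
  site_profile(name = "mds", intent_distribution = truth,
               icd_miscoding = miscoding_from_marginals(truth, icd),
               icd_missing = 0.09)
}

#' @rdname site_profile
#' @export
evs_profile <- function() {
  truth <- c(accident = 0.148, assault = 0.664, legal_intervention = 0.036,
             self_harm = 0.114, unknown = 0.036)
  icd <- c(accident = 0.339, assault = 0.482, legal_intervention = 0.030,
           self_harm = 0.111, unknown = 0.038)
  site_profile(name = "evs", intent_distribution = truth,
               icd_miscoding = miscoding_from_marginals(truth, icd),
               icd_missing = 0,
               info_sentences_unknown = 4:6)
}

#' Documentation-drift variant of a profile
#'
#' Returns the same profile with each emitted sentence duplicated
#' `redundancy_factor` times: raw mention counts grow, unique
#' term-and-context pairs do not — the drift pattern that penalises any
#' pipeline keying on raw counts.
#'
#' @param base An `fi_site_profile`.
#' @param redundancy_factor Integer multiplier >= 1.
#' @return An `fi_site_profile`.
#' @export
drifted_profile <- function(base, redundancy_factor) {
  stopifnot(inherits(base, "fi_site_profile"), redundancy_factor >= 1)
  base$redundancy <- as.integer(redundancy_factor)
  base
}

plan_case <- function(true_intent, profile, bank) {
  known <- true_intent != "unknown"
  cue <- profile$cue_strength[[true_intent]]
  planned <- character()
  if (known) {
    ev <- bank$id[bank$kind == "event_cue" & bank$intent == true_intent]
    ex <- bank$id[bank$kind == "explicit_cue" & bank$intent == true_intent]
    if (stats::runif(1) < cue) planned <- c(planned, ev)
    if (stats::runif(1) < cue) planned <- c(planned, ex)
    info_pool <- bank$id[bank$kind == "info"]
    n_info <- sample(profile$info_sentences_known, 1)
    planned <- c(planned, sample(info_pool, min(n_info, length(info_pool))))
    for (d in bank$id[bank$kind == "distractor"]) {
      if (stats::runif(1) < profile$distractor_prob) planned <- c(planned, d)
    }
    planned <- c(planned, "assess_gsw")
  } else {
    if (stats::runif(1) < cue) planned <- c(planned, "att_unknown")
    info_pool <- bank$id[bank$kind == "info"]
    n_info <- sample(profile$info_sentences_unknown, 1)
    if (n_info > 0) {
      planned <- c(planned, sample(info_pool, min(n_info, length(info_pool))))
    }
    if (identical(max(profile$info_sentences_unknown),
                  max(profile$info_sentences_known))) {
      planned <- c(planned, "assess_gsw")
    } else if (stats::runif(1) < profile$distractor_prob) {
      # information-poor unknowns: at most one distractor, no echo
      planned <- c(planned, sample(bank$id[bank$kind == "distractor"], 1))
    }
  }
  planned
}

planned_pairs <- function(planned_ids, bank) {
  # oracle pair count from bank metadata: the assessment echo renders in
  # ASSESSMENT, everything else in HPI
  rows <- bank[match(planned_ids, bank$id), ]
  sigs <- purrr::map2(rows$terms, rows$kind, function(tm, kind) {
    if (nrow(tm) == 0) return(character())
    section <- if (kind == "info_assessment") "ASSESSMENT" else "HPI"
    paste(tm$surface, tm$category, section, tm$negated, tm$historical,
          tm$other_subject, sep = "\x1f")
  })
  length(unique(unlist(sigs)))
}

render_case_notes <- function(planned_ids, profile, bank, case_id,
                              base_date = as.Date("2019-01-01")) {
  n_notes <- sample(seq_along(profile$notes_per_case), 1,
                    prob = profile$notes_per_case)
  fillers <- bank$id[bank$kind == "filler"]
  text_of <- function(ids) {
    txt <- bank$text[match(ids, bank$id)]
    rep(txt, each = profile$redundancy)
  }
  notes <- purrr::map_dfr(seq_len(n_notes), function(j) {
    ids <- if (j == 1) planned_ids else {
      # later notes repeat a subset of the first note's content
      keep <- planned_ids[stats::runif(length(planned_ids)) < 0.6]
      keep
    }
    assess <- ids[ids == "assess_gsw"]
    hpi <- setdiff(ids, assess)
    n_fill <- stats::rnbinom(1, mu = profile$filler_mean,
                             size = profile$filler_size)
    course <- sample(fillers, min(max(n_fill, 1), length(fillers)))
    text <- paste0(
      "HPI: ", paste(text_of(hpi), collapse = " "),
      if (length(hpi) == 0) "Seen in the emergency department. " else " ",
      "ED COURSE: ", paste(text_of(course), collapse = " "), " ",
      "ASSESSMENT: ",
      if (length(assess) > 0) paste(text_of(assess), collapse = " ")
      else "Gunshot injury, disposition as above.")
    tibble::tibble(
      case_id = case_id,
      note_type = if (j == 1) "ED note" else "progress note",
      date = as.character(base_date + j - 1),
      text = text)
  })
  notes
}

#' Generate a labelled synthetic corpus
#'
#' Draws `n` cases: a true intent from the profile's distribution, an ICD
#' label from the miscoding row of the true intent (or NA with the
#' profile's missing-code probability), and one or more rendered notes per
#' case from the template grammar. Deterministic given `seed`. The
#' returned object carries a generation log sufficient to check every
#' downstream extraction and rule assertion without re-reading the text.
#'
#' @param n Number of cases (>= 1).
#' @param profile An `fi_site_profile`.
#' @param seed Integer seed.
#' @return A tibble (class `fi_corpus`) with one row per case: `case_id`,
#'   `true_intent`, `icd_intent` (NA when uncoded), `notes` (list of note
#'   tibbles), and log columns `planned_ids` (list), `planned_pairs`,
#'   `cue_event`, `cue_explicit`, `attestation`.
#' @export
generate_corpus <- function(n, profile = mds_profile(), seed = 1L) {
  if (!inherits(profile, "fi_site_profile")) {
    stop("profile must be an fi_site_profile", call. = FALSE)
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  bank <- sentence_bank()
  cls <- intent_levels()
  withr::with_seed(seed, {
    truth <- sample(cls, n, replace = TRUE,
                    prob = profile$intent_distribution)
    rows <- purrr::map(seq_len(n), function(i) {
      case_id <- sprintf("%s%05d", profile$name, i)
      icd <- if (stats::runif(1) < profile$icd_missing) NA_character_
        else sample(cls, 1, prob = profile$icd_miscoding[truth[i], ])
      planned <- plan_case(truth[i], profile, bank)
      notes <- render_case_notes(planned, profile, bank, case_id)
      tibble::tibble(
        case_id = case_id, true_intent = truth[i], icd_intent = icd,
        notes = list(notes), planned_ids = list(planned),
        planned_pairs = planned_pairs(planned, bank),
        cue_event = any(bank$kind[match(planned, bank$id)] == "event_cue"),
        cue_explicit = any(bank$kind[match(planned, bank$id)] == "explicit_cue"),
        attestation = "att_unknown" %in% planned)
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("fi_corpus", class(out))
    out
  })
}

#' Flatten a corpus to the notes / labels files the real-data path uses
#'
#' @param corpus An `fi_corpus`.
#' @return `corpus_notes()`: long tibble of notes; `corpus_labels()`:
#'   tibble `case_id`, `adjudicated`, `icd`.
#' @export
corpus_notes <- function(corpus) {
  dplyr::bind_rows(corpus$notes)
}

#' @rdname corpus_notes
#' @export
corpus_labels <- function(corpus) {
  tibble::tibble(case_id = corpus$case_id,
                 adjudicated = corpus$true_intent,
                 icd = corpus$icd_intent)
}
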