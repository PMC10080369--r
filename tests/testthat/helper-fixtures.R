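# shared fixtures, built in code

tiny_lexicon <- function() {
  new_lexicon(tibble::tribble(
    ~surface, ~category, ~tags,
    "shot", "shooting_verb", "-",
    "gsw", "injury_term", "-",
    "suicidal ideation", "explicit_intent_self_harm", "-",
    "si", "explicit_intent_self_harm", "-",
    "suicide attempt", "explicit_intent_self_harm", "-",
    "self inflicted gunshot", "explicit_intent_self_harm", "-",
    "gunshot", "injury_term", "-",
    "police", "police_actor", "-",
    "police report", "confusion_term", "-",
    "home", "incident_location", "location=inside",
    "street", "incident_location", "location=outside",
    "altercation", "explicit_intent_assault", "-",
    "accidental discharge", "explicit_intent_accident", "-",
    "circumstances remain unknown", "no_info_attestation", "-"
  ))
}

make_note <- function(text, case_id = "c1", note_type = "ED note",
                      date = "2019-01-01") {
  list(case_id = case_id, note_type = note_type, date = date, text = text)
}

# build an fi_case directly from mention/event specs, bypassing text, so
# rule logic is tested in isolation
make_case <- function(case_id = "c1", mentions = NULL, events = NULL,
                      n_notes = 1L) {
  empty_m <- tibble::tibble(
    surface = character(), category = character(), tags = list(),
    sentence = integer(), section = character(), negated = logical(),
    historical = logical(), other_subject = logical(),
    start = integer(), end = integer(), note_index = integer())
  if (is.null(mentions)) mentions <- empty_m
  mentions <- dplyr::bind_rows(empty_m, mentions)
  mentions$tags[vapply(mentions$tags, is.null, logical(1))] <- list(list())
  empty_e <- tibble::tibble(
    verb = character(), shooter = character(), shot_person = character(),
    circumstances = list(), passive = logical(), self_directed = logical(),
    note_index = integer(), sentence = integer())
  if (is.null(events)) events <- empty_e
  events <- dplyr::bind_rows(empty_e, events)
  structure(list(case_id = case_id, mentions = mentions, events = events,
                 n_notes = n_notes), class = "fi_case")
}

mention_row <- function(surface, category, section = "HPI", negated = FALSE,
                        historical = FALSE, other_subject = FALSE,
                        note_index = 1L, sentence = 1L, tags = list()) {
  tibble::tibble(surface = surface, category = category, tags = list(tags),
                 sentence = sentence, section = section, negated = negated,
                 historical = historical, other_subject = other_subject,
                 start = 0L, end = 1L, note_index = note_index)
}

event_row <- function(verb = "shot", shooter = NA_character_,
                      shot_person = NA_character_, passive = FALSE,
                      self_directed = FALSE, note_index = 1L) {
  tibble::tibble(verb = verb, shooter = shooter, shot_person = shot_person,
                 circumstances = list(character()), passive = passive,
                 self_directed = self_directed, note_index = note_index,
                 sentence = 1L)
}

# brute-force reference matcher: enumerate every matching subspan, then
# repeatedly select by (earliest start, longest, category-registry order)
# among spans not overlapping an already-selected span
brute_force_match <- function(tokens, lexicon) {
  cats <- attr(lexicon, "categories")
  spans <- list()
  for (r in seq_len(nrow(lexicon))) {
    len <- lexicon$n_tokens[r]
    if (len > length(tokens)) next
    for (i in seq_len(length(tokens) - len + 1)) {
      if (identical(paste(tokens[i:(i + len - 1)], collapse = " "),
                    lexicon$surface[r])) {
        spans[[length(spans) + 1]] <- list(
          row = r, start = i - 1L, end = i - 1L + len,
          rank = match(lexicon$category[r], cats))
      }
    }
  }
  chosen <- list()
  while (length(spans) > 0) {
    ord <- order(vapply(spans, `[[`, integer(1), "start"),
                 -vapply(spans, function(s) s$end - s$start, integer(1)),
                 vapply(spans, `[[`, integer(1), "rank"))
    pick <- spans[[ord[1]]]
    chosen[[length(chosen) + 1]] <- pick
    spans <- purrr::keep(spans, function(s)
      s$end <= pick$start || s$start >= pick$end)
  }
  out <- purrr::map_dfr(chosen, function(s)
    tibble::tibble(surface = lexicon$surface[s$row],
                   category = lexicon$category[s$row],
                   start = s$start, end = s$end))
  if (nrow(out) == 0) {
    out <- tibble::tibble(surface = character(), category = character(),
                          start = integer(), end = integer())
  }
  out
}

# exhaustive-threshold reference for one-vs-rest ROC / PR areas
brute_force_areas <- function(scores, truth) {
  if (sum(truth) == 0) return(list(auroc = NA_real_, auprc = NA_real_))
  ths <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(ths, function(t) {
    pred <- scores >= t
    tibble::tibble(tpr = sum(pred & truth) / sum(truth),
                   fpr = if (sum(!truth) == 0) NA_real_
                         else sum(pred & !truth) / sum(!truth),
                   prec = sum(pred & truth) / sum(pred))
  })
  fpr <- c(0, pts$fpr); tpr <- c(0, pts$tpr)
  auroc <- if (anyNA(fpr)) NA_real_ else
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  auprc <- sum(diff(c(0, pts$tpr)) * pts$prec)
  list(auroc = auroc, auprc = auprc)
}

random_confusion <- function() {
  m <- matrix(rpois(25, 8), 5, 5,
              dimnames = list(predicted = intent_levels(),
                              adjudicated = intent_levels()))
  storage.mode(m) <- "integer"
  structure(m, class = c("fi_confusion", "matrix", "array"))
}

mds_table4_matrix <- function() {
  read_confusion_csv(system.file("extdata", "confusion_mds.csv",
                                 package = "firearmintent"))
}

evs_table4_matrix <- function() {
  read_confusion_csv(system.file("extdata", "confusion_evs.csv",
                                 package = "firearmintent"))
}

# small fully separable feature set: one indicator feature per class
separable_features <- function(n_per_class = 6) {
  cls <- intent_levels()
  labels <- rep(cls, each = n_per_class)
  feats <- purrr::map_dfc(cls, function(c)
    tibble::tibble(!!paste0("is_", c) := as.integer(labels == c)))
  list(features = feats, labels = labels)
}

loc <- function(where) list(location = where)

# 15 hand-built cases and their expected feature vectors
rule_fixture_suite <- function() {
  list(
    # 1: affirmed self-harm cue
    list(case = make_case("f01", mention_row("suicide attempt",
                                             "explicit_intent_self_harm")),
         expect = c(explicit_self_harm = 1, no_explicit_intent = 0,
                    low_info_case = 1, high_info_note = 0)),
    # 2: negated self-harm cue does not fire the explicit rule
    list(case = make_case("f02", mention_row("suicide attempt",
                                             "explicit_intent_self_harm",
                                             negated = TRUE)),
         expect = c(explicit_self_harm = 0, no_explicit_intent = 1)),
    # 3: historical cue does not fire
    list(case = make_case("f03", mention_row("altercation",
                                             "explicit_intent_assault",
                                             historical = TRUE)),
         expect = c(explicit_assault = 0, no_explicit_intent = 1)),
    # 4: affirmed assault cue
    list(case = make_case("f04", mention_row("altercation",
                                             "explicit_intent_assault")),
         expect = c(explicit_assault = 1, conflicting_intent = 0)),
    # 5: two different explicit intents -> conflict
    list(case = make_case("f05", dplyr::bind_rows(
      mention_row("altercation", "explicit_intent_assault"),
      mention_row("suicide attempt", "explicit_intent_self_harm",
                  sentence = 2L))),
      expect = c(explicit_assault = 1, explicit_self_harm = 1,
                 conflicting_intent = 1, no_explicit_intent = 0)),
    # 6: two cues of the same intent corroborate, no conflict
    list(case = make_case("f06", dplyr::bind_rows(
      mention_row("altercation", "explicit_intent_assault"),
      mention_row("assault", "explicit_intent_assault", sentence = 2L))),
      expect = c(explicit_assault = 1, conflicting_intent = 0)),
    # 7: no mentions at all
    list(case = make_case("f07"),
         expect = c(no_explicit_intent = 1, low_info_case = 1,
                    high_info_note = 0, explicit_assault = 0)),
    # 8: third-party shooter event
    list(case = make_case("f08", events = event_row(shooter = "another man",
                                                    shot_person = "patient",
                                                    passive = TRUE)),
         expect = c(assault_shooter = 1, legal_shooter = 0,
                    self_directed_shooting = 0)),
    # 9: police shooter event
    list(case = make_case("f09", events = event_row(shooter = "police",
                                                    shot_person = "he",
                                                    passive = TRUE)),
         expect = c(legal_shooter = 1, assault_shooter = 0)),
    # 10: reflexive event
    list(case = make_case("f10", events = event_row(shooter = "patient",
                                                    shot_person = "himself",
                                                    self_directed = TRUE)),
         expect = c(self_directed_shooting = 1, assault_shooter = 0)),
    # 11: weapon subject is no assault shooter
    list(case = make_case("f11", events = event_row(shooter = "the gun")),
         expect = c(assault_shooter = 0, legal_shooter = 0)),
    # 12: location tags
    list(case = make_case("f12", mention_row("home", "incident_location",
                                             tags = loc("inside"))),
         expect = c(location_inside = 1, location_outside = 0)),
    # 13: negated location does not fire
    list(case = make_case("f13", mention_row("street", "incident_location",
                                             negated = TRUE,
                                             tags = loc("outside"))),
         expect = c(location_outside = 0, location_inside = 0)),
    # 14: attestation of no information
    list(case = make_case("f14", mention_row("circumstances remain unknown",
                                             "no_info_attestation")),
         expect = c(no_info_attested = 1, no_explicit_intent = 0)),
    # 15: info-dense case crosses the high threshold
    list(case = make_case("f15", dplyr::bind_rows(purrr::map2(
      c("gsw", "shot", "home", "altercation", "suicide attempt"),
      c("injury_term", "shooting_verb", "incident_location",
        "explicit_intent_assault", "explicit_intent_self_harm"),
      ~ mention_row(.x, .y, sentence = 1L)))),
      expect = c(high_info_note = 1, low_info_case = 0,
                 conflicting_intent = 1))
  )
}

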