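#' Rule-engine thresholds
#'
#' Thresholds for the information-density rules: `high_info_note` fires
#' when a case has at least one note whose unique term-and-context pair
#' count reaches `high_info_threshold` (boundary inclusive); `low_info_case`
#' fires when the case-wide pair count falls below `low_info_threshold`.
#' These are the knobs tuned to capture unknown-intent cases, which are
#' defined by their lack of information.
#'
#' @param high_info_threshold Positive integer, per-note pair count at or
#'   above which a note is "high information".
#' @param low_info_threshold Positive integer, per-case pair count below
#'   which a case is "low information". Must be `<= high_info_threshold`.
#' @return An `fi_rule_config` list.
#' @export
rule_config <- function(high_info_threshold = 5, low_info_threshold = 3) {
  stopifnot(high_info_threshold >= 1, low_info_threshold >= 1)
  if (low_info_threshold > high_info_threshold) {
    stop("low_info_threshold must not exceed high_info_threshold",
         call. = FALSE)
  }
  structure(list(high_info_threshold = as.integer(high_info_threshold),
                 low_info_threshold = as.integer(low_info_threshold)),
            class = "fi_rule_config")
}

rule_kinds <- function() {
  c("explicit_intent", "role", "location", "info_density", "meta")
}

parse_clauses <- function(clauses, id) {
  if (is.na(clauses) || clauses %in% c("", "-")) return(list())
  parts <- stringr::str_trim(stringr::str_split(clauses, ";")[[1]])
  purrr::map(parts[parts != ""], function(p) {
    kv <- stringr::str_match(p, "^([a-z_]+)\\s*=\\s*(.+)$")
    if (anyNA(kv)) stop("rule '", id, "': malformed clause '", p, "'",
                        call. = FALSE)
    key <- kv[2]; val <- stringr::str_trim(kv[3])
    switch(
      key,
      require_category = list(type = "require_category", category = val),
      require_tag = {
        m <- stringr::str_match(val, "^([a-z_]+):([a-z_]+)=([A-Za-z0-9_\\-]+)$")
        if (anyNA(m)) stop("rule '", id, "': malformed require_tag '", val,
                           "'", call. = FALSE)
        list(type = "require_tag", category = m[2], key = m[3], value = m[4])
      },
      forbid_modifier = list(
        type = "forbid_modifier",
        modifiers = stringr::str_trim(stringr::str_split(val, ",")[[1]])),
      event_role = list(type = "event_role", role = val),
      pair_count_cmp = {
        m <- stringr::str_match(val, "^(per_note_max|per_case)\\s+(ge|gt|le|lt)\\s+(high|low|[0-9]+)$")
        if (anyNA(m)) stop("rule '", id, "': malformed pair_count_cmp '", val,
                           "'", call. = FALSE)
        list(type = "pair_count_cmp", scope = m[2], op = m[3], ref = m[4])
      },
      count_explicit = {
        m <- stringr::str_match(val, "^(eq|ge|le)\\s+([0-9]+)$")
        if (anyNA(m)) stop("rule '", id, "': malformed count_explicit", call. = FALSE)
        list(type = "count_explicit", op = m[2], k = as.integer(m[3]))
      },
      distinct_intents = {
        m <- stringr::str_match(val, "^(eq|ge|le)\\s+([0-9]+)$")
        if (anyNA(m)) stop("rule '", id, "': malformed distinct_intents", call. = FALSE)
        list(type = "distinct_intents", op = m[2], k = as.integer(m[3]))
      },
      stop("rule '", id, "': unknown clause type '", key, "'", call. = FALSE)
    )
  })
}

#' Construct a validated ruleset
#'
#' Rules are declared as data, one row per rule, with a small clause
#' mini-language so a revised rule inventory can be loaded without code
#' changes. Clause types: `require_category=<cat>`,
#' `require_tag=<cat>:<key>=<value>`, `forbid_modifier=<mod>,<mod>`
#' (mention-level clauses combine: one mention must satisfy all of them),
#' `event_role=<self_directed|other_shooter|police_shooter>`,
#' `pair_count_cmp=<per_note_max|per_case> <ge|gt|le|lt> <high|low|n>`,
#' and for meta rules `count_explicit=<op> <n>` /
#' `distinct_intents=<op> <n>` (these may reference only the
#' explicit-intent rules, so no cycles are possible).
#'
#' @param df Data frame with columns `id`, `kind`, `intent`, `clauses`.
#' @return An `fi_ruleset` tibble with a parsed `predicate` list column.
#' @export
new_ruleset <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("id", "kind", "clauses") %in% names(df)))
  if (!"intent" %in% names(df)) df$intent <- NA_character_
  df$intent[df$intent %in% c("-", "")] <- NA_character_
  if (anyDuplicated(df$id)) stop("duplicate rule ids", call. = FALSE)
  bad <- setdiff(unique(df$kind), rule_kinds())
  if (length(bad) > 0) {
    stop("unknown rule kind: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$predicate <- purrr::map2(df$clauses, df$id, parse_clauses)
  for (i in seq_len(nrow(df))) {
    types <- vapply(df$predicate[[i]], `[[`, character(1), "type")
    meta_types <- c("count_explicit", "distinct_intents")
    if (df$kind[i] == "meta" && !all(types %in% meta_types)) {
      stop("meta rule '", df$id[i],
           "' may only count explicit-intent rules", call. = FALSE)
    }
    if (df$kind[i] != "meta" && any(types %in% meta_types)) {
      stop("rule '", df$id[i], "' of kind ", df$kind[i],
           " cannot reference other rules", call. = FALSE)
    }
  }
  structure(df[, c("id", "kind", "intent", "clauses", "predicate")],
            class = c("fi_ruleset", class(tibble::tibble())))
}

#' The default rule inventory
#'
#' One explicit-intent rule per class (affirmed, non-historical mention of
#' the class's cue category), a no-information attestation rule, three
#' dependency-role rules (self-directed shooting, assault shooter, legal
#' shooter), two location rules reading the inside/outside attribute tag,
#' the two information-density rules, and the two meta rules over the
#' explicit-intent rules.
#'
#' @return An `fi_ruleset`.
#' @export
default_ruleset <- function() {
  new_ruleset(tibble::tribble(
    ~id, ~kind, ~intent, ~clauses,
    "explicit_accident", "explicit_intent", "accident",
    "require_category=explicit_intent_accident;forbid_modifier=negated,historical",
    "explicit_assault", "explicit_intent", "assault",
    "require_category=explicit_intent_assault;forbid_modifier=negated,historical",
    "explicit_self_harm", "explicit_intent", "self_harm",
    "require_category=explicit_intent_self_harm;forbid_modifier=negated,historical",
    "explicit_legal", "explicit_intent", "legal_intervention",
    "require_category=explicit_intent_legal;forbid_modifier=negated,historical",
    "no_info_attested", "explicit_intent", "unknown",
    "require_category=no_info_attestation;forbid_modifier=negated,historical",
    "self_directed_shooting", "role", "self_harm", "event_role=self_directed",
    "assault_shooter", "role", "assault", "event_role=other_shooter",
    "legal_shooter", "role", "legal_intervention", "event_role=police_shooter",
    "location_inside", "location", NA,
    "require_tag=incident_location:location=inside;forbid_modifier=negated,historical",
    "location_outside", "location", NA,
    "require_tag=incident_location:location=outside;forbid_modifier=negated,historical",
    "high_info_note", "info_density", NA, "pair_count_cmp=per_note_max ge high",
    "low_info_case", "info_density", NA, "pair_count_cmp=per_case lt low",
    "no_explicit_intent", "meta", NA, "count_explicit=eq 0",
    "conflicting_intent", "meta", NA, "distinct_intents=ge 2"
  ))
}

#' Load / write a ruleset file (TSV: id, kind, intent, clauses)
#'
#' @param path File path.
#' @return `load_ruleset()` an `fi_ruleset`; `write_ruleset()` the path,
#'   invisibly.
#' @export
load_ruleset <- function(path) {
  if (!file.exists(path)) stop("ruleset file not found: ", path, call. = FALSE)
  new_ruleset(readr::read_tsv(
    path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE))
}

#' @rdname load_ruleset
#' @param ruleset An `fi_ruleset`.
#' @export
write_ruleset <- function(ruleset, path) {
  df <- ruleset[, c("id", "kind", "intent", "clauses")]
  df$intent[is.na(df$intent)] <- "-"
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Stable identifier of a ruleset's feature space
#'
#' @param ruleset An `fi_ruleset`.
#' @return A short hash of the ordered rule ids, stored in model files so a
#'   saved model refuses features from a different ruleset.
#' @export
ruleset_hash <- function(ruleset) string_hash(ruleset$id)

default_police_surfaces <- function() {
  c("police", "officer", "officers", "cop", "cops", "law enforcement",
    "trooper", "swat", "sheriff", "deputy")
}

self_words <- function() {
  c("patient", "pt", "himself", "herself", "themselves", "self", "he",
    "she", "they")
}

weapon_words <- function() {
  c("gun", "handgun", "rifle", "pistol", "firearm", "weapon", "shotgun")
}

eval_mention_clauses <- function(mentions, clauses) {
  # clauses jointly restrict one mention
  ok <- rep(TRUE, nrow(mentions))
  for (cl in clauses) {
    if (cl$type == "require_category") {
      ok <- ok & mentions$category == cl$category
    } else if (cl$type == "require_tag") {
      ok <- ok & mentions$category == cl$category &
        vapply(mentions$tags, function(tg)
          identical(tg[[cl$key]], cl$value), logical(1))
    } else if (cl$type == "forbid_modifier") {
      for (mod in cl$modifiers) ok <- ok & !mentions[[mod]]
    }
  }
  any(ok)
}

eval_event_clause <- function(events, role, police_surfaces) {
  if (nrow(events) == 0) return(FALSE)
  shooter_tokens <- purrr::map(events$shooter, function(s)
    if (is.na(s)) character() else tokenize1(s))
  police_tok <- unlist(tokenize(police_surfaces))
  is_police <- vapply(shooter_tokens, function(tk)
    length(tk) > 0 && any(tk %in% police_tok), logical(1))
  is_self <- vapply(shooter_tokens, function(tk)
    length(tk) > 0 && utils::tail(tk[is_word_token(tk)], 1) %in% self_words(),
    logical(1))
  is_weapon <- vapply(shooter_tokens, function(tk)
    length(tk) > 0 && utils::tail(tk[is_word_token(tk)], 1) %in% weapon_words(),
    logical(1))
  switch(role,
    self_directed = any(events$self_directed),
    police_shooter = any(is_police & !is.na(events$shooter)),
    other_shooter = any(!is.na(events$shooter) & !is_police & !is_self &
                          !is_weapon & !events$self_directed),
    stop("unknown event role: ", role, call. = FALSE))
}

cmp_op <- function(a, op, b) {
  switch(op, ge = a >= b, gt = a > b, le = a <= b, lt = a < b, eq = a == b)
}

#' Evaluate the rule set over one case
#'
#' A pure function of the case extraction and configuration: every rule is
#' evaluated to 0/1 in declaration order; meta rules see the explicit-intent
#' rule outcomes. Explicit-intent rules fire only on affirmed,
#' non-historical mentions, so "denies suicide attempt" never fires the
#' self-harm rule. Because the information-density rules count unique
#' term-and-context pairs, duplicating a note verbatim changes no feature.
#'
#' @param x An `fi_case`.
#' @param ruleset An `fi_ruleset` (default [default_ruleset()]).
#' @param cfg An `fi_rule_config`.
#' @param police_surfaces Surfaces treated as law-enforcement shooters by
#'   the `police_shooter` event role (defaults to a built-in list; pass the
#'   lexicon's `police_actor` surfaces to keep lexicon and rules in step).
#' @return A one-row tibble: `case_id` then one 0/1 column per rule id.
#' @export
evaluate_rules <- function(x, ruleset = default_ruleset(), cfg = rule_config(),
                           police_surfaces = default_police_surfaces()) {
  stopifnot(inherits(x, "fi_case"), inherits(ruleset, "fi_ruleset"))
  mentions <- x$mentions
  events <- x$events
  per_case <- count_unique_term_context_pairs(x, "per_case")
  per_note <- count_unique_term_context_pairs(x, "per_note")
  per_note_max <- if (length(per_note) == 0) 0L else max(per_note)

  vals <- stats::setNames(integer(nrow(ruleset)), ruleset$id)
  non_meta <- which(ruleset$kind != "meta")
  for (i in non_meta) {
    clauses <- ruleset$predicate[[i]]
    types <- vapply(clauses, `[[`, character(1), "type")
    fired <- TRUE
    mcl <- clauses[types %in% c("require_category", "require_tag",
                                "forbid_modifier")]
    if (length(mcl) > 0) fired <- fired && eval_mention_clauses(mentions, mcl)
    for (cl in clauses[types == "event_role"]) {
      fired <- fired && eval_event_clause(events, cl$role, police_surfaces)
    }
    for (cl in clauses[types == "pair_count_cmp"]) {
      val <- if (cl$scope == "per_case") per_case else per_note_max
      ref <- switch(cl$ref, high = cfg$high_info_threshold,
                    low = cfg$low_info_threshold, as.integer(cl$ref))
      fired <- fired && cmp_op(val, cl$op, ref)
    }
    vals[i] <- as.integer(fired)
  }
  explicit <- ruleset$kind == "explicit_intent"
  n_explicit <- sum(vals[explicit])
  n_intents <- length(unique(ruleset$intent[explicit & vals == 1L &
                                              !is.na(ruleset$intent)]))
  for (i in which(ruleset$kind == "meta")) {
    fired <- TRUE
    for (cl in ruleset$predicate[[i]]) {
      fired <- fired && switch(cl$type,
        count_explicit = cmp_op(n_explicit, cl$op, cl$k),
        distinct_intents = cmp_op(n_intents, cl$op, cl$k))
    }
    vals[i] <- as.integer(fired)
  }
  out <- tibble::as_tibble(as.list(vals))
  dplyr::bind_cols(tibble::tibble(case_id = x$case_id), out)
}

#' Feature matrix for a list of cases
#'
#' @param cases List of `fi_case` objects.
#' @inheritParams evaluate_rules
#' @return Tibble: `case_id` plus one 0/1 column per rule, constant width.
#' @export
build_feature_matrix <- function(cases, ruleset = default_ruleset(),
                                 cfg = rule_config(),
                                 police_surfaces = default_police_surfaces()) {
  purrr::map_dfr(cases, evaluate_rules, ruleset = ruleset, cfg = cfg,
                 police_surfaces = police_surfaces)
}

#' High-info-note and low-info-case rules
#'
#' Convenience accessors for the two information-density rules.
#' `rule_high_info_note()` is true when the maximum per-note unique
#' pair count reaches the high threshold (boundary `>=`);
#' `rule_low_info_case()` is true when the per-case unique pair count is
#' strictly below the low threshold.
#'
#' @param x An `fi_case`.
#' @param cfg An `fi_rule_config`.
#' @return Logical scalar.
#' @export
rule_high_info_note <- function(x, cfg = rule_config()) {
  per_note <- count_unique_term_context_pairs(x, "per_note")
  length(per_note) > 0 && max(per_note) >= cfg$high_info_threshold
}

#' @rdname rule_high_info_note
#' @export
rule_low_info_case <- function(x, cfg = rule_config()) {
  count_unique_term_context_pairs(x, "per_case") < cfg$low_info_threshold
}

#' Meta rules over explicit-intent outcomes
#'
#' @param features A one-row feature tibble (or named 0/1 vector) for the
#'   explicit-intent rules.
#' @param ruleset The ruleset declaring which rules are explicit-intent.
#' @return Logical scalar.
#' @export
rule_no_explicit_intent <- function(features, ruleset = default_ruleset()) {
  ids <- ruleset$id[ruleset$kind == "explicit_intent"]
  sum(unlist(features[ids])) == 0
}

#' @rdname rule_no_explicit_intent
#' @export
rule_conflicting_intent <- function(features, ruleset = default_ruleset()) {
  sub <- ruleset[ruleset$kind == "explicit_intent" & !is.na(ruleset$intent), ]
  fired <- unlist(features[sub$id]) == 1
  length(unique(sub$intent[fired])) >= 2
}

#' Tune the information-density threshold
#'
#' Sweeps a grid of threshold values; at each value the information-density
#' features are recomputed (both thresholds set to the grid value), the
#' supplied classifier specification is fitted on the tuning cases, and the
#' unknown-class F-score of its resubstitution predictions is measured. The
#' grid value with the best unknown-class F wins; ties go to the smallest
#' threshold.
#'
#' @param cases List of `fi_case` tuning cases.
#' @param labels Adjudicated intent labels aligned with `cases`; must
#'   contain unknown-intent cases.
#' @param ruleset An `fi_ruleset`.
#' @param spec Classifier specification: list with `algorithm`,
#'   `hyperparameters` (list), `seed`.
#' @param grid Integer candidate thresholds.
#' @param police_surfaces See [evaluate_rules()].
#' @return An `fi_rule_config` with both thresholds at the selected value.
#' @export
tune_info_threshold <- function(cases, labels, ruleset = default_ruleset(),
                                spec = list(algorithm = "gbm",
                                            hyperparameters = list(),
                                            seed = 1L),
                                grid = 1:15,
                                police_surfaces = default_police_surfaces()) {
  labels <- assert_intents(labels)
  if (!any(labels == "unknown")) {
    stop("tuning data contains no unknown-intent cases", call. = FALSE)
  }
  stopifnot(length(cases) == length(labels), length(grid) >= 1)
  grid <- sort(unique(as.integer(grid)))
  base <- build_feature_matrix(cases, ruleset, rule_config(grid[1], grid[1]),
                               police_surfaces)
  per_case <- vapply(cases, count_unique_term_context_pairs, integer(1),
                     scope = "per_case")
  per_note_max <- vapply(cases, function(x) {
    pn <- count_unique_term_context_pairs(x, "per_note")
    if (length(pn) == 0) 0L else as.integer(max(pn))
  }, integer(1))
  info_ids <- ruleset$id[ruleset$kind == "info_density"]
  best_f <- -1
  best_t <- grid[1]
  for (t in grid) {
    feats <- base
    for (rid in info_ids) {
      cl <- ruleset$predicate[[which(ruleset$id == rid)]][[1]]
      val <- if (cl$scope == "per_case") per_case else per_note_max
      feats[[rid]] <- as.integer(cmp_op(val, cl$op, t))
    }
    model <- train_intent_model(feats, labels,
                                algorithm = spec$algorithm %||% "gbm",
                                hyperparameters = spec$hyperparameters %||% list(),
                                seed = spec$seed %||% 1L)
    pred <- predict_intent(model, feats)$label
    cm <- confusion_matrix(pred, labels)
    f_unknown <- per_class_metrics(cm)$f_score[
      per_class_metrics(cm)$class == "unknown"]
    if (f_unknown > best_f + 1e-12) { best_f <- f_unknown; best_t <- t }
  }
  rule_config(best_t, best_t)
}
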