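#' Packaged starter lexicon and ruleset
#'
#' The starter lexicon covers every term category the rule inventory
#' consumes (shooting verbs, weapons, injuries, tagged incident locations,
#' police actors, one explicit-intent cue set per class, no-information
#' attestations, confusion terms); it is a working seed, not a site-tuned
#' inventory — deployments extend it via [score_candidate_terms()] and
#' error review.
#'
#' @return `default_lexicon()` an `fi_lexicon`; `packaged_ruleset()` an
#'   `fi_ruleset` identical to [default_ruleset()] but read from the
#'   shipped TSV.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "lexicon.tsv",
                           package = "firearmintent"),
               version = "starter-1")
}

#' @rdname default_lexicon
#' @export
packaged_ruleset <- function() {
  load_ruleset(system.file("extdata", "ruleset.tsv",
                           package = "firearmintent"))
}

#' Run extraction over a notes table, one case at a time
#'
#' @param notes Tibble of notes (`case_id`, `note_type`, `date`, `text`),
#'   e.g. from [read_notes()] or [corpus_notes()].
#' @param lexicon An `fi_lexicon`.
#' @param context Context-trigger configuration.
#' @param parser Dependency-parse provider.
#' @return Named list of `fi_case` objects, one per case id, in first-seen
#'   order.
#' @export
extract_corpus <- function(notes, lexicon = default_lexicon(),
                           context = default_context_config(),
                           parser = fixture_parser) {
  notes <- tibble::as_tibble(notes)
  ids <- unique(notes$case_id)
  analyzer <- case_analyzer(lexicon, context, parser)
  out <- purrr::map(ids, function(id)
    aggregate_case(notes[notes$case_id == id, ], lexicon, context, parser,
                   analyzer = analyzer))
  stats::setNames(out, ids)
}

#' Extraction audit table
#'
#' Per-case trace of why features fired: mention and event counts and the
#' unique pair counts the information-density rules consume. Written next
#' to every feature matrix by the command-line tools so flagged cases can
#' be reviewed by hand.
#'
#' @param cases Named list of `fi_case` (from [extract_corpus()]).
#' @return Tibble: `case_id`, `n_mentions`, `n_events`, `pairs_per_case`,
#'   `pairs_per_note_max`.
#' @export
extraction_audit <- function(cases) {
  purrr::map_dfr(cases, function(x) {
    pn <- count_unique_term_context_pairs(x, "per_note")
    tibble::tibble(
      case_id = x$case_id,
      n_mentions = nrow(x$mentions),
      n_events = nrow(x$events),
      pairs_per_case = count_unique_term_context_pairs(x, "per_case"),
      pairs_per_note_max = if (length(pn) == 0) 0L else as.integer(max(pn)))
  })
}
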