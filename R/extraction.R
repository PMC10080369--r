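#' Default clinical section headers
#'
#' Headers recognised by [segment_note()], matched case-insensitively when
#' followed by a colon. Text before the first header lands in a section
#' labelled `"preamble"`.
#'
#' @return Character vector of header labels.
#' @export
default_section_headers <- function() {
  c("HPI", "ED COURSE", "PMH", "PSH", "SOCIAL HISTORY", "ASSESSMENT",
    "PLAN", "DISCHARGE", "PHYSICAL EXAM", "IMPRESSION")
}

# words before a period that do not end a sentence
sentence_abbreviations <- function() {
  c("dr", "mr", "mrs", "ms", "st", "vs", "approx", "pt", "no")
}

locate_sentences <- function(text, abbrev = sentence_abbreviations()) {
  n <- nchar(text)
  if (n == 0) return(tibble::tibble(start = integer(), end = integer()))
  # boundary: ., ! or ? followed by whitespace then a capital letter
  m <- stringr::str_locate_all(text, "[.!?](?=\\s+[A-Z])")[[1]]
  cuts <- integer()
  for (k in seq_len(nrow(m))) {
    pos <- m[k, 1]
    before <- stringr::str_sub(text, max(1, pos - 12), pos - 1)
    last_word <- stringr::str_to_lower(
      stringr::str_extract(before, "[A-Za-z']+$"))
    if (stringr::str_sub(text, pos, pos) == "." &&
        !is.na(last_word) && last_word %in% abbrev) next
    cuts <- c(cuts, pos)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  tibble::tibble(start = starts - 1L, end = ends)  # 0-based half-open
}

#' Segment a clinical note into sections and sentences
#'
#' Sections tile the note text without overlap: each configured header
#' (matched as `HEADER:`) starts a section running to the next header or
#' the end of the note; text before the first header becomes the
#' `"preamble"` section. Sentences are split at `.`, `!` or `?` followed by
#' whitespace and a capital letter, with a small abbreviation guard list,
#' and never cross a section boundary.
#'
#' @param note A list or one-row data frame with at least `text`, and
#'   optionally `case_id`, `note_type`, `date`.
#' @param section_headers Recognised header labels.
#' @return An `fi_note` list with `$text`, `$sections` (tibble `header`,
#'   `start`, `end`; 0-based half-open character offsets) and `$sentences`
#'   (tibble `sentence`, `section`, `start`, `end`, `text`, `tokens`).
#' @export
segment_note <- function(note, section_headers = default_section_headers()) {
  if (is.data.frame(note)) note <- as.list(note[1, ])
  text <- note$text
  stopifnot(is.character(text), length(text) == 1, nchar(text) > 0)
  pat <- paste0("(?i)(", paste(stringr::str_replace_all(
    section_headers, "([^A-Za-z0-9 ])", "\\\\\\1"), collapse = "|"),
    ")\\s*:")
  loc <- stringr::str_locate_all(text, pat)[[1]]
  if (nrow(loc) == 0) {
    sections <- tibble::tibble(header = "preamble", start = 0L,
                               end = nchar(text))
  } else {
    hdr <- stringr::str_to_upper(stringr::str_remove(
      stringr::str_sub(text, loc[, 1], loc[, 2]), "\\s*:$"))
    starts <- loc[, 1] - 1L
    sections <- tibble::tibble(
      header = hdr, start = as.integer(starts),
      end = as.integer(c(starts[-1], nchar(text))))
    if (starts[1] > 0) {
      sections <- dplyr::bind_rows(
        tibble::tibble(header = "preamble", start = 0L,
                       end = as.integer(starts[1])), sections)
    }
  }
  sent <- purrr::pmap_dfr(sections, function(header, start, end) {
    seg <- stringr::str_sub(text, start + 1, end)
    s <- locate_sentences(seg)
    if (nrow(s) == 0) return(NULL)
    s$start <- s$start + start
    s$end <- s$end + start
    s$section <- header
    s
  })
  if (nrow(sent) > 0) {
    sent$text <- stringr::str_trim(
      stringr::str_sub(note$text, sent$start + 1, sent$end))
    sent <- sent[nchar(sent$text) > 0, ]
    sent$tokens <- tokenize(sent$text)
    sent$sentence <- seq_len(nrow(sent))
    sent <- sent[, c("sentence", "section", "start", "end", "text", "tokens")]
  } else {
    sent <- tibble::tibble(sentence = integer(), section = character(),
                           start = integer(), end = integer(),
                           text = character(), tokens = list())
  }
  structure(list(case_id = note$case_id %||% NA_character_,
                 note_type = note$note_type %||% NA_character_,
                 date = note$date %||% NA_character_,
                 text = text, sections = sections, sentences = sent),
            class = "fi_note")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default context-trigger configuration
#'
#' Trigger phrases for the clinical context modifiers, in the same lexicon
#' dialect as the intent lexicon: `negation_trigger` (scoped strictly before
#' the term), `history_trigger` and `other_subject_trigger` (scoped before
#' or after), and `scope_terminator` ("but", ";") which blocks a trigger
#' from reaching across it. Scopes never cross sentence boundaries.
#'
#' @param window Scope window in tokens (default 6).
#' @param triggers Optional `fi_lexicon` of triggers to use instead of the
#'   built-in list.
#' @return A list with `$triggers` and `$window`.
#' @export
default_context_config <- function(window = 6, triggers = NULL) {
  if (is.null(triggers)) {
    df <- tibble::tribble(
      ~surface, ~category,
      "denies", "negation_trigger",
      "denied", "negation_trigger",
      "no", "negation_trigger",
      "not", "negation_trigger",
      "negative for", "negation_trigger",
      "without", "negation_trigger",
      "history of", "history_trigger",
      "h/o", "history_trigger",
      "hx of", "history_trigger",
      "years ago", "history_trigger",
      "year ago", "history_trigger",
      "prior", "history_trigger",
      "remote", "history_trigger",
      "old", "history_trigger",
      "brother", "other_subject_trigger",
      "sister", "other_subject_trigger",
      "father", "other_subject_trigger",
      "mother", "other_subject_trigger",
      "friend", "other_subject_trigger",
      "family member", "other_subject_trigger",
      "cousin", "other_subject_trigger",
      "neighbor", "other_subject_trigger",
      "but", "scope_terminator",
      ";", "scope_terminator"
    )
    triggers <- new_lexicon(df, categories = context_categories())
  }
  list(triggers = triggers, window = window)
}

#' @rdname default_context_config
#' @export
context_categories <- function() {
  c("negation_trigger", "history_trigger", "other_subject_trigger",
    "scope_terminator")
}

#' Load context triggers from a lexicon-dialect TSV
#'
#' @param path TSV with columns surface, category, tags; categories from
#'   [context_categories()].
#' @param window Scope window in tokens.
#' @return A context configuration list.
#' @export
load_context_config <- function(path, window = 6) {
  default_context_config(
    window = window,
    triggers = load_lexicon(path, categories = context_categories()))
}

# is there a trigger of `cat` in scope of [mstart, mend)? spans 0-based.
in_scope <- function(trig, cat, mstart, mend, window, bidirectional) {
  rows <- trig[trig$category == cat, , drop = FALSE]
  if (nrow(rows) == 0) return(FALSE)
  term_rows <- trig[trig$category == "scope_terminator", , drop = FALSE]
  blocked <- function(lo, hi) {
    # any terminator whose span lies strictly between lo and hi
    nrow(term_rows) > 0 && any(term_rows$start >= lo & term_rows$end <= hi)
  }
  before <- rows$end <= mstart & (mstart - rows$end) <= window
  for (i in which(before)) {
    if (!blocked(rows$end[i], mstart)) return(TRUE)
  }
  if (!bidirectional) return(FALSE)
  after <- rows$start >= mend & (rows$start - mend) <= window
  for (i in which(after)) {
    if (!blocked(mend, rows$start[i])) return(TRUE)
  }
  FALSE
}

# context-annotated matches for one token sequence (no section attached)
analyze_sentence <- function(toks, lexicon, context) {
  m <- match_terms(toks, lexicon)
  m <- m[!m$confusion, , drop = FALSE]
  has_shooting <- any(m$category == "shooting_verb")
  if (nrow(m) > 0) {
    trig <- match_terms(toks, context$triggers)
    W <- context$window
    m$negated <- vapply(seq_len(nrow(m)), function(i)
      in_scope(trig, "negation_trigger", m$start[i], m$end[i],
               W, bidirectional = FALSE), logical(1))
    m$historical <- vapply(seq_len(nrow(m)), function(i)
      in_scope(trig, "history_trigger", m$start[i], m$end[i],
               W, bidirectional = TRUE), logical(1))
    m$other_subject <- vapply(seq_len(nrow(m)), function(i)
      in_scope(trig, "other_subject_trigger", m$start[i],
               m$end[i], W, bidirectional = TRUE), logical(1))
  }
  list(mentions = m, has_shooting = has_shooting)
}

# closure with a per-sentence-text memo shared across a corpus: clinical
# notes repeat sentences heavily, so analysis is cached by sentence text
case_analyzer <- function(lexicon, context = default_context_config(),
                          parser = fixture_parser) {
  memo <- new.env(parent = emptyenv())
  shooting_surfaces <- lexicon$surface[lexicon$category == "shooting_verb"]
  function(text, toks) {
    hit <- get0(text, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    res <- analyze_sentence(toks, lexicon, context)
    res$events <- if (res$has_shooting && !is.null(parser)) {
      parsed <- tryCatch(parser(toks), error = function(e) {
        warning("parse provider failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(parsed)) NULL else extract_events(parsed, shooting_surfaces)
    }
    assign(text, res, envir = memo)
    res
  }
}

#' Extract term mentions with clinical context from a segmented note
#'
#' Matches the lexicon in every sentence and attaches the three modifier
#' flags. `negated` requires a negation trigger within `window` tokens
#' before the match in the same sentence with no scope terminator between;
#' `historical` and `other_subject` triggers may sit on either side of the
#' match (clinical phrasing puts "years ago" after and "history of"
#' before). Confusion-term matches suppress contained informative matches
#' during matching and are not emitted as mentions.
#'
#' @param note An `fi_note` from [segment_note()].
#' @param lexicon A `fi_lexicon`.
#' @param context A context configuration from [default_context_config()].
#' @param analyzer Optional shared sentence analyzer (a memoising closure
#'   built internally); supplied by [extract_corpus()] so repeated
#'   sentences across a corpus are analysed once.
#' @return Tibble of mentions: `surface`, `category`, `tags`, `sentence`,
#'   `section`, `negated`, `historical`, `other_subject`, `start`, `end`.
#' @export
extract_mentions <- function(note, lexicon, context = default_context_config(),
                             analyzer = NULL) {
  stopifnot(inherits(note, "fi_note"))
  if (is.null(analyzer)) analyzer <- case_analyzer(lexicon, context,
                                                   parser = NULL)
  sent <- note$sentences
  out <- purrr::pmap_dfr(
    list(sent$sentence, sent$section, sent$text, sent$tokens),
    function(sid, section, text, toks) {
      m <- analyzer(text, toks)$mentions
      if (nrow(m) == 0) return(NULL)
      m$sentence <- sid
      m$section <- section
      m
    })
  if (nrow(out) == 0) {
    return(tibble::tibble(surface = character(), category = character(),
                          tags = list(), sentence = integer(),
                          section = character(), negated = logical(),
                          historical = logical(), other_subject = logical(),
                          start = integer(), end = integer()))
  }
  out[, c("surface", "category", "tags", "sentence", "section",
          "negated", "historical", "other_subject", "start", "end")]
}

#' Aggregate a case's notes into one extraction
#'
#' Unions mentions from all of a case's notes (in chronological order when
#' dates are present) and extracts shooting events from every sentence that
#' contains a shooting-verb mention, via the supplied dependency parser.
#' Duplicate sentences across notes are kept as distinct mentions;
#' deduplication happens only in pair counting.
#'
#' @param notes A list of notes (raw lists/rows or `fi_note`s) sharing one
#'   `case_id`, or a data frame of notes.
#' @param lexicon A `fi_lexicon`.
#' @param context Context configuration.
#' @param parser A parse provider, `function(tokens) -> fi_parse`
#'   (default [fixture_parser()]).
#' @inheritParams extract_mentions
#' @return An `fi_case` list: `$case_id`, `$mentions` (tibble with
#'   `note_index` column), `$events` (tibble from [extract_events()]),
#'   `$n_notes`.
#' @export
aggregate_case <- function(notes, lexicon, context = default_context_config(),
                           parser = fixture_parser, analyzer = NULL) {
  if (is.data.frame(notes)) {
    notes <- purrr::map(seq_len(nrow(notes)), ~ as.list(notes[.x, ]))
  }
  if (length(notes) == 0) stop("a case needs at least one note", call. = FALSE)
  notes <- purrr::map(notes, function(n)
    if (inherits(n, "fi_note")) n else segment_note(n))
  ids <- unique(vapply(notes, function(n) as.character(n$case_id), character(1)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    stop("notes with mixed case_ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  dates <- vapply(notes, function(n) as.character(n$date %||% NA_character_),
                  character(1))
  if (!anyNA(dates)) notes <- notes[order(dates)]
  if (is.null(analyzer)) analyzer <- case_analyzer(lexicon, context, parser)
  per_note <- purrr::imap(notes, function(n, i) {
    sent <- n$sentences
    res <- purrr::pmap(list(sent$sentence, sent$section, sent$text,
                            sent$tokens),
                       function(sid, section, text, toks) {
      a <- analyzer(text, toks)
      m <- a$mentions
      if (nrow(m) > 0) { m$sentence <- sid; m$section <- section }
      ev <- a$events
      if (!is.null(ev) && nrow(ev) > 0) ev$sentence <- sid
      list(m = m, ev = ev)
    })
    m <- dplyr::bind_rows(purrr::map(res, "m"))
    if (nrow(m) > 0) m$note_index <- i
    ev <- dplyr::bind_rows(purrr::compact(purrr::map(res, "ev")))
    if (nrow(ev) > 0) ev$note_index <- i
    list(m = m, ev = ev)
  })
  mentions <- dplyr::bind_rows(purrr::map(per_note, "m"))
  events <- dplyr::bind_rows(purrr::map(per_note, "ev"))
  if (nrow(mentions) > 0) {
    mentions <- mentions[, c("surface", "category", "tags", "sentence",
                             "section", "negated", "historical",
                             "other_subject", "start", "end", "note_index")]
  }
  if (nrow(mentions) == 0) {
    mentions <- tibble::tibble(
      surface = character(), category = character(), tags = list(),
      sentence = integer(), section = character(), negated = logical(),
      historical = logical(), other_subject = logical(),
      start = integer(), end = integer(), note_index = integer())
  }
  if (nrow(events) == 0) events <- empty_events()
  structure(list(case_id = if (length(ids)) ids else NA_character_,
                 mentions = mentions, events = events,
                 n_notes = length(notes)),
            class = "fi_case")
}

pair_signatures <- function(mentions) {
  if (nrow(mentions) == 0) return(character())
  paste(mentions$surface, mentions$category, mentions$section,
        mentions$negated, mentions$historical, mentions$other_subject,
        sep = "\x1f")
}

#' Count unique term-and-context pairs
#'
#' A pair is a term (surface + category) together with its context
#' signature (section, negated, historical, other_subject). Repeats of the
#' same term in the same context — including verbatim duplicate notes —
#' add nothing; the same term negated in one sentence and affirmed in
#' another counts twice. These counts drive the information-density rules.
#'
#' @param x An `fi_case`.
#' @param scope `"per_case"` (one count over all notes) or `"per_note"`
#'   (a named integer vector, one count per note index).
#' @return Integer count, or named integer vector for `"per_note"`.
#' @export
count_unique_term_context_pairs <- function(x, scope = c("per_case", "per_note")) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "fi_case"))
  m <- x$mentions
  if (scope == "per_case") {
    return(length(unique(pair_signatures(m))))
  }
  counts <- stats::setNames(integer(x$n_notes), seq_len(x$n_notes))
  if (nrow(m) > 0) {
    by_note <- split(pair_signatures(m), m$note_index)
    counts[names(by_note)] <- vapply(by_note, function(s)
      length(unique(s)), integer(1))
  }
  counts
}

#' Read clinical notes from a JSON-lines file
#'
#' One JSON object per line with fields `case_id`, `note_type`, `date`,
#' `text`. A malformed line is an error naming the line number.
#'
#' @param path File path.
#' @return Tibble of notes.
#' @export
read_notes <- function(path) {
  if (!file.exists(path)) stop("notes file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  lines_keep <- which(nchar(stringr::str_trim(lines)) > 0)
  recs <- purrr::map(lines_keep, function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) stop(sprintf(
               "malformed JSON at line %d of %s: %s", i, path,
               conditionMessage(e)), call. = FALSE))
  })
  purrr::map_dfr(recs, function(r) tibble::tibble(
    case_id = as.character(r$case_id),
    note_type = as.character(r$note_type %||% NA_character_),
    date = as.character(r$date %||% NA_character_),
    text = as.character(r$text)))
}

#' Write clinical notes to a JSON-lines file
#'
#' @param notes Tibble with `case_id`, `note_type`, `date`, `text`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path) {
  lines <- vapply(seq_len(nrow(notes)), function(i)
    jsonlite::toJSON(as.list(notes[i, c("case_id", "note_type", "date", "text")]),
                     auto_unbox = TRUE), character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
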