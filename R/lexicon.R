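#' Default lexicon category registry
#'
#' The closed set of term categories a lexicon may use, in priority order.
#' Order matters: when two terms of equal length match at the same position,
#' the category earlier in the registry wins, which keeps matching
#' deterministic. `confusion_term` is first so that uninformative phrases
#' ("police report") out-compete the informative terms they contain
#' ("police") whenever lengths tie.
#'
#' @return Character vector of category labels.
#' @export
lexicon_categories <- function() {
  c("confusion_term",
    "explicit_intent_accident",
    "explicit_intent_assault",
    "explicit_intent_self_harm",
    "explicit_intent_legal",
    "no_info_attestation",
    "shooting_verb",
    "police_actor",
    "incident_location",
    "weapon_term",
    "injury_term")
}

parse_tags <- function(x, line = NA_integer_) {
  if (is.na(x) || x == "-" || x == "") return(list())
  parts <- stringr::str_split(x, ";")[[1]]
  kv <- stringr::str_match(parts, "^\\s*([A-Za-z0-9_]+)=([A-Za-z0-9_\\-]+)\\s*$")
  if (anyNA(kv[, 1])) {
    stop(sprintf("malformed tag syntax%s: '%s'",
                 if (is.na(line)) "" else sprintf(" at line %d", line), x),
         call. = FALSE)
  }
  stats::setNames(as.list(kv[, 3]), kv[, 2])
}

format_tags <- function(tags) {
  if (length(tags) == 0) return("-")
  paste(sprintf("%s=%s", names(tags), unlist(tags)), collapse = ";")
}

#' Construct a lexicon from a data frame
#'
#' @param terms A data frame with columns `surface` (1-5 token phrase),
#'   `category`, and `tags` (either a list column of named lists or a
#'   character column in `key=value;key=value` / `-` syntax).
#' @param categories Category registry (closed set); terms with categories
#'   outside it are rejected.
#' @param version Version string carried with the lexicon.
#' @return A `fi_lexicon` tibble with columns `surface`, `category`, `tags`
#'   (list), `tokens` (list), `n_tokens`, `confusion` (logical).
#' @export
new_lexicon <- function(terms, categories = lexicon_categories(), version = "0") {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("surface", "category") %in% names(terms)))
  if (!"tags" %in% names(terms)) terms$tags <- rep(list(list()), nrow(terms))
  if (is.character(terms$tags)) {
    terms$tags <- purrr::imap(terms$tags, ~ parse_tags(.x, .y))
  }
  terms$surface <- vapply(tokenize(terms$surface),
                          paste, character(1), collapse = " ")
  bad_cat <- setdiff(unique(terms$category), categories)
  if (length(bad_cat) > 0) {
    stop("unknown lexicon categories: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  toks <- tokenize(terms$surface)
  n_tok <- lengths(toks)
  if (any(n_tok < 1 | n_tok > 5)) {
    bad <- terms$surface[n_tok < 1 | n_tok > 5]
    stop("lexicon surfaces must be 1-5 tokens: ",
         paste(utils::head(bad, 3), collapse = "; "), call. = FALSE)
  }
  dup <- duplicated(terms[, c("surface", "category")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (surface, category) rows collapsed",
            call. = FALSE)
    terms <- terms[!dup, ]
    toks <- toks[!dup]
    n_tok <- n_tok[!dup]
  }
  out <- tibble::tibble(
    surface = terms$surface,
    category = terms$category,
    tags = terms$tags,
    tokens = toks,
    n_tokens = n_tok,
    confusion = terms$category == "confusion_term"
  )
  out <- dplyr::arrange(out, .data$surface, .data$category)
  structure(out,
            class = c("fi_lexicon", class(tibble::tibble())),
            categories = categories, version = version,
            index = split(seq_len(nrow(out)), out$surface))
}

#' Load a lexicon from a TSV or CSV file
#'
#' Expected columns: `surface`, `category`, `tags` (semicolon-separated
#' `key=value` pairs, `-` for none). Duplicate (surface, category) rows are
#' collapsed with a warning; unknown categories and malformed tags are load
#' errors (the tag error names the offending line).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param categories Category registry to validate against.
#' @param version Version string to attach.
#' @return A `fi_lexicon`.
#' @export
load_lexicon <- function(path, format = c("tsv", "csv"),
                         categories = lexicon_categories(), version = "0") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  need <- c("surface", "category", "tags")
  if (!all(need %in% names(raw))) {
    stop("lexicon header must name columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$tags <- purrr::map2(raw$tags, seq_len(nrow(raw)) + 1L, parse_tags)
  new_lexicon(raw, categories = categories, version = version)
}

#' Write a lexicon in canonical order
#'
#' Rows are sorted by (surface, category) so that a load/save cycle is
#' byte-stable modulo the original row order.
#'
#' @param lexicon A `fi_lexicon`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  df <- tibble::tibble(
    surface = lexicon$surface,
    category = lexicon$category,
    tags = vapply(lexicon$tags, format_tags, character(1))
  )
  df <- dplyr::arrange(df, .data$surface, .data$category)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# n-gram dictionary: named list keyed by the space-joined surface
lexicon_index <- function(lexicon) {
  idx <- attr(lexicon, "index")
  if (!is.null(idx)) return(idx)
  split(seq_len(nrow(lexicon)), lexicon$surface)
}

#' Match lexicon terms in a token sequence
#'
#' Greedy longest-match, left to right: at each position the longest
#' matching surface wins; at equal length the category earlier in the
#' registry wins; the scan then resumes after the match. Spans are 0-based
#' half-open token indices. Any non-confusion match whose span falls fully
#' inside a matched confusion-term span is suppressed (with greedy matching
#' this is enforced by construction); confusion matches themselves are
#' returned flagged `confusion = TRUE` for audit and carry no intent signal
#' downstream.
#'
#' @param tokens Character vector of case-folded tokens (from [tokenize()]).
#' @param lexicon A `fi_lexicon`.
#' @return Tibble with columns `surface`, `category`, `tags` (list),
#'   `start`, `end` (0-based, half-open), `confusion`.
#' @export
match_terms <- function(tokens, lexicon) {
  empty <- tibble::tibble(surface = character(), category = character(),
                          tags = list(), start = integer(), end = integer(),
                          confusion = logical())
  n <- length(tokens)
  if (n == 0 || nrow(lexicon) == 0) return(empty)
  idx <- lexicon_index(lexicon)
  cat_rank <- match(lexicon$category, attr(lexicon, "categories"))
  max_len <- min(5L, max(lexicon$n_tokens))
  hits <- list()
  i <- 1L
  while (i <= n) {
    found <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      rows <- idx[[key]]
      if (!is.null(rows)) {
        found <- rows[which.min(cat_rank[rows])]
        break
      }
    }
    if (found > 0L) {
      hits[[length(hits) + 1L]] <-
        list(row = found, start = i - 1L, end = i - 1L + lexicon$n_tokens[found])
      i <- i + lexicon$n_tokens[found]
    } else {
      i <- i + 1L
    }
  }
  if (length(hits) == 0) return(empty)
  rows <- vapply(hits, `[[`, integer(1), "row")
  tibble::tibble(
    surface = lexicon$surface[rows],
    category = lexicon$category[rows],
    tags = lexicon$tags[rows],
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    confusion = lexicon$confusion[rows]
  )
}

#' Score candidate lexicon terms by intent-specific frequency ratio
#'
#' For each term (token n-gram up to `max_len` long) and each intent class,
#' the score is the relative frequency of the term among cases of that
#' intent divided by its relative frequency across all cases — a
#' tf-idf-style ratio. Case-level presence (not raw counts) is used, so a
#' term mentioned five times in one case counts once. Terms occurring in
#' fewer than `min_cases` cases are dropped as noise.
#'
#' @param corpus Data frame with columns `case_id`, `intent`, `text` (one or
#'   more rows per case; texts of a case are concatenated).
#' @param max_len Longest n-gram to consider (default 5).
#' @param min_cases Minimum number of distinct cases a term must appear in
#'   (default 3).
#' @return Tibble `(surface, intent, score)` sorted by descending score.
#' @export
score_candidate_terms <- function(corpus, max_len = 5, min_cases = 3) {
  corpus <- tibble::as_tibble(corpus)
  stopifnot(all(c("case_id", "intent", "text") %in% names(corpus)))
  cases <- corpus |>
    dplyr::group_by(.data$case_id, .data$intent) |>
    dplyr::summarise(text = paste(.data$text, collapse = " "), .groups = "drop")
  if (dplyr::n_distinct(cases$intent) < 2) {
    stop("candidate scoring needs at least 2 intent classes", call. = FALSE)
  }
  ngrams_of <- function(text) {
    tok <- tokenize1(text)
    tok <- tok[is_word_token(tok)]
    if (length(tok) == 0) return(character())
    out <- lapply(seq_len(min(max_len, length(tok))), function(len) {
      if (length(tok) < len) return(character())
      vapply(seq_len(length(tok) - len + 1L), function(i)
        paste(tok[i:(i + len - 1L)], collapse = " "), character(1))
    })
    unique(unlist(out))
  }
  presence <- tibble::tibble(
    intent = rep(cases$intent, times = 0L),
    surface = character()
  )
  per_case <- purrr::map(cases$text, ngrams_of)
  presence <- tibble::tibble(
    intent = rep(cases$intent, lengths(per_case)),
    surface = unlist(per_case)
  )
  n_total <- nrow(cases)
  class_n <- table(cases$intent)
  term_n <- presence |> dplyr::count(.data$surface, name = "n_all")
  keep <- term_n$surface[term_n$n_all >= min_cases]
  if (length(keep) == 0) {
    return(tibble::tibble(surface = character(), intent = character(),
                          score = numeric()))
  }
  presence <- presence[presence$surface %in% keep, ]
  counts <- presence |> dplyr::count(.data$surface, .data$intent, name = "n_in")
  grid <- tidyr::expand_grid(surface = keep,
                             intent = names(class_n)) |>
    dplyr::left_join(counts, by = c("surface", "intent")) |>
    dplyr::left_join(term_n, by = "surface") |>
    dplyr::mutate(
      n_in = tidyr::replace_na(.data$n_in, 0L),
      score = (.data$n_in / as.numeric(class_n[.data$intent])) /
        (.data$n_all / n_total)
    ) |>
    dplyr::select("surface", "intent", "score") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$surface, .data$intent)
  grid
}
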