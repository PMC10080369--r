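test_that("sections tile the note and sentences respect boundaries", {
  n <- segment_note(make_note(
    "Presenting complaint. HPI: Pt shot in L leg. Denies SI. ASSESSMENT: Stable."))
  expect_equal(n$sections$header, c("preamble", "HPI", "ASSESSMENT"))
  # tiling: contiguous, non-overlapping, covers all characters
  expect_equal(n$sections$start[-1], head(n$sections$end, -1))
  expect_equal(n$sections$start[1], 0L)
  expect_equal(dplyr::last(n$sections$end), nchar(n$text))

  # no headers -> single preamble
  n2 <- segment_note(make_note("Pt shot in L leg. Denies SI."))
  expect_equal(n2$sections$header, "preamble")
  expect_equal(n2$sentences$text, c("Pt shot in L leg.", "Denies SI."))

  # boundary requires whitespace + capital; abbreviation guard holds
  n3 <- segment_note(make_note("Seen by Dr. Smith today. Plan follows."))
  expect_equal(nrow(n3$sentences), 2)
  expect_match(n3$sentences$text[1], "Dr. Smith")
})

test_that("mention extraction attaches context modifiers per the oracle table", {
  lex <- tiny_lexicon()
  ctx <- default_context_config()
  # hand-built oracle: sentence, term surface, negated, historical, other
  oracle <- tibble::tribble(
    ~text, ~surface, ~negated, ~historical, ~other_subject,
    "Denies suicidal ideation.", "suicidal ideation", TRUE, FALSE, FALSE,
    "History of GSW 10 years ago.", "gsw", FALSE, TRUE, FALSE,
    "No SI today.", "si", TRUE, FALSE, FALSE,
    "SI reported.", "si", FALSE, FALSE, FALSE,
    "Negative for SI.", "si", TRUE, FALSE, FALSE,
    "Not a suicide attempt.", "suicide attempt", TRUE, FALSE, FALSE,
    "His brother reported a GSW.", "gsw", FALSE, FALSE, TRUE,
    "GSW to the chest.", "gsw", FALSE, FALSE, FALSE,
    "Old GSW on imaging.", "gsw", FALSE, TRUE, FALSE,
    "Prior GSW to the arm.", "gsw", FALSE, TRUE, FALSE,
    "Pt was shot near home.", "shot", FALSE, FALSE, FALSE,
    "Pt was shot near home.", "home", FALSE, FALSE, FALSE,
    "Friend states pt was shot.", "shot", FALSE, FALSE, TRUE,
    "Per police report pt was shot.", "shot", FALSE, FALSE, FALSE,
    "No injury but GSW documented.", "gsw", FALSE, FALSE, FALSE,
    "Without obvious SI.", "si", TRUE, FALSE, FALSE,
    "Denied suicide attempt last night.", "suicide attempt", TRUE, FALSE, FALSE,
    "GSW one year ago.", "gsw", FALSE, TRUE, FALSE,
    "Shot by police.", "shot", FALSE, FALSE, FALSE,
    "Altercation denied.", "altercation", FALSE, FALSE, FALSE
  )
  for (tx in unique(oracle$text)) {
    note <- segment_note(make_note(tx))
    m <- extract_mentions(note, lex, ctx)
    want <- oracle[oracle$text == tx, ]
    got <- m[m$surface %in% want$surface,
             c("surface", "negated", "historical", "other_subject")]
    got <- got[match(want$surface, got$surface), ]
    expect_equal(got$negated, want$negated, info = tx)
    expect_equal(got$historical, want$historical, info = tx)
    expect_equal(got$other_subject, want$other_subject, info = tx)
  }
})

test_that("scope terminators block negation ('no SI but shot by brother')", {
  m <- extract_mentions(segment_note(make_note("No SI but shot by brother.")),
                        tiny_lexicon(), default_context_config())
  si <- m[m$surface == "si", ]
  shot <- m[m$surface == "shot", ]
  expect_true(si$negated)
  expect_false(shot$negated)       # "but" terminates the negation scope
  expect_true(shot$other_subject)  # brother follows within the window
})

test_that("negation scope is bounded by the token window", {
  ctx <- default_context_config(window = 6)
  txt <- "Denies one two three four five six seven SI."
  m <- extract_mentions(segment_note(make_note(txt)), tiny_lexicon(), ctx)
  expect_false(m$negated[m$surface == "si"])  # 8 tokens away, window 6
})

test_that("case aggregation unions notes and counts unique pairs", {
  lex <- tiny_lexicon()
  notes <- list(
    make_note("GSW to chest. Denies SI. Shot near home.", date = "2019-01-01"),
    make_note("GSW to chest. Follow up.", note_type = "progress note",
              date = "2019-01-02"))
  case <- aggregate_case(notes, lex)
  # note 1: gsw, si, shot, home = 4 mentions; note 2: gsw = 1
  expect_equal(nrow(case$mentions), 5)
  expect_equal(case$case_id, "c1")

  # duplicate sentences are retained as distinct mentions...
  expect_equal(sum(case$mentions$surface == "gsw"), 2)
  # ...but deduplicated in pair counting
  expect_equal(count_unique_term_context_pairs(case, "per_case"), 4)
  expect_equal(unname(count_unique_term_context_pairs(case, "per_note")),
               c(4L, 1L))

  expect_error(aggregate_case(list(), lex), "at least one note")
  expect_error(aggregate_case(list(make_note("GSW.", case_id = "a"),
                                   make_note("GSW.", case_id = "b")), lex),
               "mixed case_ids")
})

test_that("pair counts equal a set-based reference on generated cases", {
  lex <- tiny_lexicon()
  withr::with_seed(5, {
    sentences <- c("GSW to chest.", "Denies SI.", "Shot near home.",
                   "History of GSW 10 years ago.", "SI reported.",
                   "Per police report pt was shot.", "Shot on the street.")
    for (i in 1:10) {
      texts <- sample(sentences, sample(3:7, 1), replace = TRUE)
      case <- aggregate_case(list(make_note(paste(texts, collapse = " "))),
                             lex)
      m <- case$mentions
      ref <- nrow(dplyr::distinct(
        tibble::tibble(s = m$surface, c = m$category, sec = m$section,
                       n = m$negated, h = m$historical, o = m$other_subject)))
      expect_equal(count_unique_term_context_pairs(case, "per_case"), ref)
      expect_lte(ref, nrow(m))
    }
  })
})

test_that("verbatim duplicate notes change no pair count and no feature", {
  lex <- tiny_lexicon()
  base_notes <- list(make_note("GSW to chest. Denies SI. Shot near home."))
  dup_notes <- c(base_notes, base_notes, base_notes)
  c1 <- aggregate_case(base_notes, lex)
  c3 <- aggregate_case(dup_notes, lex)
  expect_gt(nrow(c3$mentions), nrow(c1$mentions))
  expect_equal(count_unique_term_context_pairs(c1, "per_case"),
               count_unique_term_context_pairs(c3, "per_case"))
  f1 <- evaluate_rules(c1)
  f3 <- evaluate_rules(c3)
  expect_identical(f1[-1], f3[-1])
})

test_that("pair counting is invariant to note order", {
  lex <- tiny_lexicon()
  notes <- list(make_note("GSW to chest.", date = "2019-01-01"),
                make_note("Denies SI. Shot near home.", date = "2019-01-02"))
  a <- aggregate_case(notes, lex)
  b <- aggregate_case(rev(notes), lex)
  expect_equal(count_unique_term_context_pairs(a, "per_case"),
               count_unique_term_context_pairs(b, "per_case"))
})

test_that("JSON-lines notes round-trip and malformed lines are located", {
  notes <- tibble::tibble(case_id = c("a", "a", "b"),
                          note_type = "ED note",
                          date = "2019-01-01",
                          text = c("GSW.", "SI.", "Shot."))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_notes(notes, path)
  expect_equal(read_notes(path), notes)

  lines <- readLines(path)
  writeLines(c(lines[1], "{broken json", lines[3]), path)
  expect_error(read_notes(path), "line 2")
  expect_error(read_notes(tempfile()), "not found")
})
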