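test_that("tokenizer case-folds, splits punctuation, ignores trailing space", {
  expect_equal(tokenize1("Per police report, pt was SHOT."),
               c("per", "police", "report", ",", "pt", "was", "shot", "."))
  expect_equal(tokenize1("  GSW to chest   "), c("gsw", "to", "chest"))
  expect_equal(tokenize1("h/o GSW"), c("h", "/", "o", "gsw"))
  expect_equal(tokenize("A; b")[[1]], c("a", ";", "b"))
})

test_that("lexicon load validates, collapses duplicates, round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("surface\tcategory\ttags",
               "Police Report\tconfusion_term\t-",
               "police report\tconfusion_term\t-",
               "home\tincident_location\tlocation=inside"), path)
  expect_warning(lex <- load_lexicon(path), "duplicate")
  expect_equal(nrow(lex), 2)
  expect_true("police report" %in% lex$surface)
  expect_equal(lex$tags[[which(lex$surface == "home")]]$location, "inside")

  # canonical save -> load -> save is byte-stable
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, p1)
  write_lexicon(load_lexicon(p1), p2)
  expect_identical(readLines(p1), readLines(p2))

  # empty file with a valid header is an empty lexicon
  writeLines("surface\tcategory\ttags", path)
  expect_equal(nrow(load_lexicon(path)), 0)
})

test_that("lexicon load rejects bad input with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("surface\tcategory\ttags",
               "one two three four five six\tshooting_verb\t-"), path)
  expect_error(load_lexicon(path), "1-5 tokens")

  writeLines(c("surface\tcategory\ttags",
               "shot\tnot_a_category\t-"), path)
  expect_error(load_lexicon(path), "unknown lexicon categories")

  writeLines(c("surface\tcategory\ttags",
               "home\tincident_location\tlocation"), path)
  expect_error(load_lexicon(path), "line 2")

  writeLines("surface\twrong\tcols", path)
  expect_error(load_lexicon(path), "header")

  expect_error(load_lexicon(tempfile()), "not found")
})

test_that("candidate term scoring equals the hand-computed frequency ratio", {
  # 10 cases: 1 self-harm, 5 assault, 4 accident
  corpus <- tibble::tibble(
    case_id = sprintf("c%02d", 1:10),
    intent = c("self_harm", rep("assault", 5), rep("accident", 4)),
    text = c("ligature marks noted gsw chest",
             rep("assailant fled the scene gsw chest", 5),
             rep("cleaning weapon gsw chest", 4)))
  sc <- score_candidate_terms(corpus, min_cases = 1)

  # term only in self-harm cases (10% of corpus): 1/0.1 = 10
  lig <- sc[sc$surface == "ligature", ]
  expect_equal(lig$score[lig$intent == "self_harm"], 10)
  expect_equal(lig$score[lig$intent == "assault"], 0)

  # term in every case scores 1 for every class
  gsw <- sc[sc$surface == "gsw", ]
  expect_equal(gsw$score, rep(1, 3))

  # assailant: 5/5 assault vs 5/10 overall -> 2 for assault
  assailant <- sc[sc$surface == "assailant", ]
  expect_equal(assailant$score[assailant$intent == "assault"], 2)

  # sorted by descending score
  expect_true(!is.unsorted(rev(sc$score)))

  # min support excludes rare terms
  sc3 <- score_candidate_terms(corpus, min_cases = 3)
  expect_false("ligature" %in% sc3$surface)

  # single-class corpus is degenerate
  expect_error(score_candidate_terms(corpus[2:6, ]), "2 intent classes")
})

test_that("case-count-weighted mean of per-class scores is 1", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- 20
      intents <- sample(c("assault", "self_harm", "unknown"), n, TRUE)
      words <- c("alpha", "beta", "gamma", "delta", "epsilon")
      corpus <- tibble::tibble(
        case_id = sprintf("c%d", 1:n), intent = intents,
        text = vapply(1:n, function(i)
          paste(sample(words, sample(2:4, 1)), collapse = " "), character(1)))
      sc <- score_candidate_terms(corpus, min_cases = 1)
      w <- as.numeric(table(intents)[sc$intent]) / n
      agg <- tapply(sc$score * w, sc$surface, sum)
      expect_true(all(abs(agg - 1) < 1e-9))
    }
  })
})

test_that("matching suppresses terms inside confusion phrases", {
  lex <- tiny_lexicon()
  m <- match_terms(tokenize1("per police report pt was shot"), lex)
  expect_equal(m$surface, c("police report", "shot"))
  expect_equal(m$confusion, c(TRUE, FALSE))
  expect_false("police" %in% m$surface)

  # spans are 0-based half-open
  expect_equal(m$start, c(1L, 5L))
  expect_equal(m$end, c(3L, 6L))

  expect_equal(nrow(match_terms(tokenize1("nothing to see here"), lex)), 0)
  expect_equal(nrow(match_terms(character(), lex)), 0)
})

test_that("greedy longest match equals the brute-force reference", {
  lex <- tiny_lexicon()
  m <- match_terms(tokenize1("self inflicted gunshot wound"), lex)
  expect_equal(m$surface, "self inflicted gunshot")

  vocab <- c("self", "inflicted", "gunshot", "si", "police", "report",
             "shot", "gsw", "home", "street", "the", "was", "remain",
             "circumstances", "unknown", "suicidal", "ideation")
  withr::with_seed(99, {
    for (i in 1:50) {
      toks <- sample(vocab, sample(3:12, 1), replace = TRUE)
      got <- match_terms(toks, lex)
      want <- brute_force_match(toks, lex)
      expect_equal(got[, c("surface", "category", "start", "end")], want,
                   info = paste(toks, collapse = " "))
    }
  })
})

test_that("adding a confusion term never adds non-confusion matches", {
  lex <- tiny_lexicon()
  lex_plus <- new_lexicon(dplyr::bind_rows(
    tibble::tibble(surface = lex$surface, category = lex$category,
                   tags = lex$tags),
    tibble::tibble(surface = "gsw home", category = "confusion_term",
                   tags = list(list()))))
  vocab <- c("gsw", "home", "police", "report", "shot", "street", "si")
  withr::with_seed(7, {
    for (i in 1:30) {
      toks <- sample(vocab, sample(2:10, 1), replace = TRUE)
      n_base <- sum(!match_terms(toks, lex)$confusion)
      n_plus <- sum(!match_terms(toks, lex_plus)$confusion)
      expect_lte(n_plus, n_base)
    }
  })
})

test_that("matching is deterministic and case/whitespace invariant", {
  lex <- tiny_lexicon()
  a <- match_terms(tokenize1("Pt WAS shot  near home.  "), lex)
  b <- match_terms(tokenize1("pt was shot near home."), lex)
  expect_identical(a, b)
  expect_identical(a, match_terms(tokenize1("Pt WAS shot  near home.  "), lex))
})
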