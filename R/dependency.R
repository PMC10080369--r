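#' Dependency-relation inventory
#'
#' Relation labels accepted in a parse. Synonymous labels from different
#' annotation schemes are normalised on input: `nsubj:pass` to `nsubjpass`,
#' `dobj` to `obj`, `obl:agent` to `agent`, `obl` to `prep`. Structural
#' fillers (`aux`, `det`, `dep`, `root`) carry no role information.
#'
#' @return Character vector of relation labels.
#' @export
relation_inventory <- function() {
  c("root", "nsubj", "nsubjpass", "obj", "agent", "advmod", "prep", "pobj",
    "aux", "auxpass", "det", "dep")
}

normalise_relation <- function(rel) {
  map <- c("nsubj:pass" = "nsubjpass", "dobj" = "obj",
           "obl:agent" = "agent", "obl" = "prep")
  ifelse(rel %in% names(map), map[rel], rel)
}

#' Construct a validated parsed sentence
#'
#' @param tokens Character vector of tokens (1-based positions).
#' @param arcs Data frame with columns `dep` (dependent token index), `head`
#'   (head token index, 0 for the root), `rel` (relation label).
#' @return An `fi_parse` list with `$tokens` and `$arcs`.
#' @details Validation enforces the parse invariants: every token has
#'   exactly one head, exactly one token is the root (head 0), the arcs are
#'   acyclic, and relation labels come from [relation_inventory()].
#' @export
new_parse <- function(tokens, arcs) {
  stopifnot(length(tokens) >= 1)
  arcs <- tibble::as_tibble(arcs)
  stopifnot(all(c("dep", "head", "rel") %in% names(arcs)))
  arcs$rel <- unname(normalise_relation(as.character(arcs$rel)))
  bad <- setdiff(unique(arcs$rel), relation_inventory())
  if (length(bad) > 0) {
    stop("relation labels outside the inventory: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(tokens)
  if (nrow(arcs) != n || !setequal(arcs$dep, seq_len(n))) {
    stop("every token needs exactly one head arc", call. = FALSE)
  }
  if (sum(arcs$head == 0) != 1) {
    stop("a parse must have exactly one root", call. = FALSE)
  }
  # acyclicity: walk each token to the root
  head_of <- integer(n)
  head_of[arcs$dep] <- arcs$head
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (j != 0) {
      if (seen[j]) stop("cyclic arcs in parse", call. = FALSE)
      seen[j] <- TRUE
      j <- head_of[j]
    }
  }
  structure(list(tokens = tokens, arcs = arcs), class = "fi_parse")
}

#' Read a gold parse from JSON
#'
#' Fixture format: `{"tokens": [...], "arcs": [[dep, head, rel], ...]}`.
#'
#' @param x A file path or a JSON string.
#' @return An `fi_parse`.
#' @export
read_parse_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  arcs <- purrr::map_dfr(obj$arcs, function(a)
    tibble::tibble(dep = as.integer(a[[1]]), head = as.integer(a[[2]]),
                   rel = as.character(a[[3]])))
  new_parse(unlist(obj$tokens), arcs)
}

shooting_verb_forms <- function() {
  c("shot", "shoot", "shoots", "shooting", "fired", "fires", "fire",
    "discharged", "discharges")
}

#' Deterministic heuristic parse provider
#'
#' A small rule-based dependency parser for the simple declarative
#' sentences the synthetic grammar and the test fixtures use. It finds the
#' (first) shooting-type verb, detects passive voice from a be/get
#' auxiliary before the verb, attaches the nearest preceding nominal as
#' subject (`nsubj` or `nsubjpass`), the first nominal after an active verb
#' as `obj`, a by-phrase nominal as `agent`, `-ly` adverbs as `advmod`, and
#' preposition + object chains as `prep`/`pobj`. Everything else hangs off
#' the root as `dep`. It is not a general parser; real deployments inject a
#' trained parser through the same provider contract.
#'
#' @param tokens Character vector of case-folded tokens.
#' @return An `fi_parse`.
#' @export
fixture_parser <- function(tokens) {
  if (length(tokens) == 0) stop("cannot parse an empty sentence", call. = FALSE)
  n <- length(tokens)
  preps <- c("in", "at", "on", "near", "during", "inside", "outside",
             "into", "with", "from", "to", "of", "while", "after", "by")
  aux_forms <- c("was", "were", "is", "are", "been", "be", "got", "gets")
  dets <- c("the", "a", "an", "his", "her", "their")
  word <- is_word_token(tokens)

  verb <- which(tokens %in% shooting_verb_forms())[1]
  if (is.na(verb)) {
    # no shooting verb: first word token becomes the root
    root <- which(word)[1]
    if (is.na(root)) root <- 1L
    arcs <- tibble::tibble(dep = seq_len(n),
                           head = ifelse(seq_len(n) == root, 0L, root),
                           rel = ifelse(seq_len(n) == root, "root", "dep"))
    return(new_parse(tokens, arcs))
  }

  head_of <- rep(verb, n)
  rel_of <- rep("dep", n)
  head_of[verb] <- 0L
  rel_of[verb] <- "root"

  aux_idx <- which(seq_len(n) < verb & tokens %in% aux_forms &
                     (verb - seq_len(n)) <= 3)
  passive <- length(aux_idx) > 0
  for (a in aux_idx) rel_of[a] <- "auxpass"

  # subject: nearest word token before the verb/aux block
  lo <- if (passive) min(aux_idx) else verb
  subj_cand <- which(word & seq_len(n) < lo &
                       !(tokens %in% c(dets, preps, aux_forms)) &
                       !(grepl("ly$", tokens) & nchar(tokens) > 3))
  if (length(subj_cand) > 0) {
    s <- max(subj_cand)
    rel_of[s] <- if (passive) "nsubjpass" else "nsubj"
    # determiners before the subject attach to it
    d <- s - 1L
    while (d >= 1 && tokens[d] %in% dets) {
      head_of[d] <- s; rel_of[d] <- "det"; d <- d - 1L
    }
  }

  i <- verb + 1L
  while (i <= n) {
    tok <- tokens[i]
    if (!word[i]) { i <- i + 1L; next }
    if (grepl("ly$", tok) && nchar(tok) > 3) {
      rel_of[i] <- "advmod"; i <- i + 1L; next
    }
    if (tok %in% preps) {
      p <- i
      rel_of[p] <- "prep"
      # object of the preposition: last word token of the chunk before the
      # next preposition/punctuation
      j <- p + 1L
      last_word <- NA_integer_
      while (j <= n && !(tokens[j] %in% preps) && word[j]) {
        if (!(tokens[j] %in% dets)) last_word <- j
        j <- j + 1L
      }
      if (!is.na(last_word)) {
        rel_of[last_word] <- "pobj"
        head_of[last_word] <- p
        if (tok == "by" && passive) rel_of[p] <- "agent"
        for (k in seq(p + 1L, j - 1L)) {
          if (k != last_word && word[k]) { head_of[k] <- last_word; rel_of[k] <- "det" }
        }
      }
      i <- j
      next
    }
    if (!passive && rel_of[i] == "dep" &&
        !any(rel_of == "obj") && !(tok %in% aux_forms)) {
      if (tok %in% dets) {
        # determiner of the upcoming object
        i <- i + 1L
        if (i <= n && word[i] && !(tokens[i] %in% preps)) {
          rel_of[i] <- "obj"
          head_of[i - 1L] <- i
          rel_of[i - 1L] <- "det"
        }
        i <- i + 1L
        next
      }
      rel_of[i] <- "obj"
      i <- i + 1L
      next
    }
    i <- i + 1L
  }

  # adverbs directly before the verb ("accidentally discharged")
  if (verb > 1) {
    b <- verb - 1L
    if (word[b] && grepl("ly$", tokens[b]) && nchar(tokens[b]) > 3 &&
        rel_of[b] == "dep") {
      rel_of[b] <- "advmod"
    }
  }

  new_parse(tokens, tibble::tibble(dep = seq_len(n), head = head_of,
                                   rel = rel_of))
}

subtree_tokens <- function(parsed, root_idx, cap = 8) {
  n <- length(parsed$tokens)
  head_of <- integer(n)
  head_of[parsed$arcs$dep] <- parsed$arcs$head
  inside <- logical(n)
  inside[root_idx] <- TRUE
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!inside[i] && head_of[i] != 0 && inside[head_of[i]]) {
        inside[i] <- TRUE; changed <- TRUE
      }
    }
  }
  idx <- which(inside)
  idx <- idx[seq_len(min(length(idx), cap))]
  paste(parsed$tokens[sort(idx)], collapse = " ")
}

empty_events <- function() {
  tibble::tibble(verb = character(), shooter = character(),
                 shot_person = character(), circumstances = list(),
                 passive = logical(), self_directed = logical(),
                 note_index = integer(), sentence = integer())
}

#' Extract shooting events from a parsed sentence
#'
#' For each token matching a shooting-verb surface: in active voice the
#' `nsubj` child is the shooter and the `obj` child the person shot; in
#' passive voice (an `nsubjpass` child present) the `nsubjpass` child is
#' the person shot and the agent/by-phrase object the shooter. `advmod`
#' children and prepositional subtrees (capped at 8 tokens) become
#' circumstance phrases. A reflexive person shot ("himself", "herself",
#' "themselves") with a shooter present flags the event `self_directed`.
#' A verb with no subject, object or modifier children emits no event.
#'
#' @param parsed An `fi_parse`.
#' @param shooting_verbs Character vector of shooting-verb surfaces (the
#'   lexicon's `shooting_verb` category).
#' @return Tibble of events: `verb`, `shooter`, `shot_person`,
#'   `circumstances` (list of character), `passive`, `self_directed`.
#' @export
extract_events <- function(parsed, shooting_verbs) {
  stopifnot(inherits(parsed, "fi_parse"))
  toks <- parsed$tokens
  arcs <- parsed$arcs
  verbs <- which(toks %in% shooting_verbs)
  reflexives <- c("himself", "herself", "themselves", "self", "myself")
  out <- purrr::map_dfr(verbs, function(v) {
    kids <- arcs[arcs$head == v, , drop = FALSE]
    passive <- any(kids$rel == "nsubjpass")
    phrase_of <- function(idx) {
      if (length(idx) == 0) return(NA_character_)
      # head token plus its determiners, in surface order
      det_kids <- arcs$dep[arcs$head == idx[1] & arcs$rel == "det"]
      paste(toks[sort(c(idx[1], det_kids))], collapse = " ")
    }
    shooter <- NA_character_
    shot <- NA_character_
    if (passive) {
      shot <- phrase_of(kids$dep[kids$rel == "nsubjpass"])
      ag <- kids$dep[kids$rel == "agent"]
      if (length(ag) > 0) {
        pobj <- arcs$dep[arcs$head == ag[1] & arcs$rel == "pobj"]
        shooter <- if (length(pobj) > 0) phrase_of(pobj) else phrase_of(ag)
        if (!is.na(shooter) && toks[ag[1]] == "by" &&
            length(pobj) == 0) shooter <- NA_character_
      }
    } else {
      shooter <- phrase_of(kids$dep[kids$rel == "nsubj"])
      shot <- phrase_of(kids$dep[kids$rel == "obj"])
    }
    circ_idx <- kids$dep[kids$rel %in% c("advmod", "prep")]
    circumstances <- purrr::map_chr(circ_idx, function(ci) {
      if (arcs$rel[arcs$dep == ci] == "advmod") toks[ci]
      else subtree_tokens(parsed, ci, cap = 8)
    })
    if (is.na(shooter) && is.na(shot) && length(circumstances) == 0) {
      return(NULL)
    }
    shot_head <- if (!is.na(shot))
      utils::tail(strsplit(shot, " ")[[1]], 1) else NA_character_
    tibble::tibble(
      verb = toks[v], shooter = shooter, shot_person = shot,
      circumstances = list(circumstances), passive = passive,
      self_directed = !is.na(shot_head) && shot_head %in% reflexives &&
        !is.na(shooter))
  })
  if (nrow(out) == 0) {
    return(empty_events()[, c("verb", "shooter", "shot_person",
                              "circumstances", "passive", "self_directed")])
  }
  out
}
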