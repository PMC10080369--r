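#' Shared clinical tokenizer
#'
#' Case-folds and splits text on whitespace and punctuation. Word characters
#' (letters, digits, apostrophes) form tokens; each punctuation mark becomes
#' its own token so that scope terminators (";") and sentence punctuation
#' survive as positions. Every stage of the pipeline (lexicon matching,
#' candidate scoring, context triggers, the dependency stage) uses this same
#' tokenizer so matching semantics are identical throughout.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element; tokens are
#'   lower-case.
#' @examples
#' tokenize("Per police report, pt was shot.")
#' @export
tokenize <- function(text) {
  stringr::str_extract_all(stringr::str_to_lower(text), "[a-z0-9']+|[^\\sa-z0-9']")
}

#' @rdname tokenize
#' @param x A single string.
#' @return `tokenize1()` returns a single character vector of tokens.
#' @export
tokenize1 <- function(x) {
  stopifnot(length(x) == 1)
  tokenize(x)[[1]]
}

# tokens that are words (not punctuation); used where windows are counted
is_word_token <- function(tok) grepl("^[a-z0-9']", tok)
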