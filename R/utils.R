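#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in the reported metric tables (base `round()` uses
#' banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' The five intent classes, in fixed report order
#'
#' @return Character vector of the closed intent label set.
#' @export
intent_levels <- function() {
  c("accident", "assault", "legal_intervention", "self_harm", "unknown")
}

assert_intents <- function(x, arg = "labels") {
  bad <- setdiff(unique(as.character(x)), intent_levels())
  if (length(bad) > 0) {
    stop(sprintf("%s contains labels outside the intent set: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  factor(as.character(x), levels = intent_levels())
}

# stable digest for feature-space compatibility checks (djb2 over a string;
# no dependency on a hashing package)
string_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
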