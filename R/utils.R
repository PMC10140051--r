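# Shared internal helpers.

#' Percentage with one-decimal round-half-up formatting
#'
#' Published summary tables round percentages to one decimal with halves
#' rounded up; base `round()` rounds half to even, so reproduction of printed
#' ratios needs an explicit convention.
#'
#' @param num Numerator (count).
#' @param den Denominator (count).
#' @param digits Decimal places kept (default 1).
#' @return A numeric percentage, e.g. `pct_round(7174, 10453)` is 68.6.
#' @export
pct_round <- function(num, den, digits = 1) {
  if (any(den == 0)) abort("denominator is zero")
  f <- 10^digits
  floor(100 * num / den * f + 0.5) / f
}

AA_ALPHABET20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

NT_ALPHABET <- c("A", "C", "G", "T")

random_aa <- function(n, first_m = FALSE) {
  s <- sample(AA_ALPHABET20, n, replace = TRUE)
  if (first_m) s[1] <- "M"
  paste(s, collapse = "")
}

random_nt <- function(n) {
  paste(sample(NT_ALPHABET, n, replace = TRUE), collapse = "")
}

# Substitute each position independently with probability p, drawing the new
# state uniformly from the other `alphabet` members. Position 1 can be held
# fixed (used to preserve the initiator methionine).
mutate_seq <- function(seq, p, alphabet = AA_ALPHABET20, fix_first = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < p
  if (fix_first && length(hit)) hit[1] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    chars[i] <- sample(setdiff(alphabet, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

seq_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}
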