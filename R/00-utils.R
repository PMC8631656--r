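## Low-level sequence helpers shared across modules. Sequences are held as
## plain uppercase character scalars over the alphabet {A,C,G,T,N}; Biostrings
## objects are constructed only at the boundaries (file IO, alignment, motif
## search) where that machinery pays off.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Encode A/C/G/T as 1..4; anything else (N, gap) becomes NA.
seq_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], BASES)
}

int_to_seq <- function(v) {
  out <- BASES[v]
  out[is.na(v)] <- "N"
  paste(out, collapse = "")
}

## Random uniform A/C/G/T string of length n (uses the current RNG stream).
random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ssuscan_format_error", "error")))
}

stop_consistency <- function(...) {
  stop(errorCondition(sprintf(...),
                      class = c("ssuscan_consistency_error", "error")))
}

stop_lookup <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ssuscan_lookup_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(sprintf(...), class = c("ssuscan_config_error", "error")))
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## Derive a per-stage 31-bit sub-seed from a master seed; keeps every stage's
## stream independent while everything remains a pure function of (seed, tag).
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}
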