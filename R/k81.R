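## Kimura (1981) three-substitution-type distance and the pairwise global
## alignment used to compare orthologous gene sequences.

## Site-pair classification table: 0 identical, 1 transition (A<->G, C<->T),
## 2 A<->T / G<->C transversion, 3 A<->C / G<->T transversion.
K81_TYPE <- matrix(c(0L, 3L, 1L, 2L,
                     3L, 0L, 2L, 1L,
                     1L, 2L, 0L, 3L,
                     2L, 1L, 3L, 0L), 4L, 4L, byrow = TRUE,
                   dimnames = list(BASES, BASES))

#' Kimura three-substitution-type (K81) distance between aligned sequences
#'
#' With P the proportion of comparable sites differing by a transition, Q by
#' an A/T or G/C transversion and R by an A/C or G/T transversion, the
#' distance is
#' `d = -(1/4) * (log(1-2P-2Q) + log(1-2P-2R) + log(1-2Q-2R))`
#' substitutions per site. Sites containing a gap or N in either sequence are
#' excluded. When any logarithm argument is non-positive the distance is
#' saturated: `distance` is `NA` and `saturated` is `TRUE`.
#'
#' @param seqA,seqB aligned nucleotide strings of equal length.
#' @return list with `distance`, `P`, `Q`, `R`, `n_sites` (comparable sites),
#'   `mismatches` (raw count) and `saturated`.
#' @export
k81_distance <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stop_format("aligned sequences must have equal length")
  a <- seq_to_int(toupper(seqA))
  b <- seq_to_int(toupper(seqB))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) stop_format("no comparable sites (all gaps or N)")
  type <- K81_TYPE[cbind(a[ok], b[ok])]
  counts <- tabulate(type + 1L, nbins = 4L)
  P <- counts[2L] / n; Q <- counts[3L] / n; R <- counts[4L] / n
  w1 <- 1 - 2 * P - 2 * Q
  w2 <- 1 - 2 * P - 2 * R
  w3 <- 1 - 2 * Q - 2 * R
  saturated <- w1 <= 0 || w2 <= 0 || w3 <= 0
  d <- if (saturated) NA_real_ else -0.25 * (log(w1) + log(w2) + log(w3))
  list(distance = d, P = P, Q = Q, R = R, n_sites = n,
       mismatches = sum(type != 0L), saturated = saturated)
}

#' Global pairwise alignment of two gene sequences
#'
#' End-to-end Needleman-Wunsch alignment (match +1, mismatch -1, gap open -4,
#' gap extend -1). Equal-length sequences are returned unchanged: with
#' substitution-only divergence the identity alignment is already global and
#' gap-free. Gap columns are excluded downstream by [k81_distance()].
#'
#' @param seqA,seqB nucleotide strings.
#' @return list of two aligned strings of equal length.
#' @export
align_pair <- function(seqA, seqB) {
  if (nchar(seqA) == nchar(seqB)) return(list(seqA, seqB))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(seqA, seqB, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 4, gapExtension = 1)
  list(as.character(Biostrings::alignedPattern(aln)),
       as.character(Biostrings::alignedSubject(aln)))
}
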