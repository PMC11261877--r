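#' Ends-free global pairwise alignment
#'
#' Aligns two nucleotide sequences with a Needleman-Wunsch dynamic programme
#' in which terminal gaps are free (overlap alignment), the convention used
#' by greedy dereplication tools: a sequence fully contained in another at
#' high identity scores as (near-)identical. Scoring is linear-gap with
#' defaults match = +2, mismatch = -3, gap = -5.
#'
#' For long sequences the programme is banded around the corridor between
#' the end diagonals; the default band comfortably covers the small indel
#' counts expected between sequences near a high identity threshold. Set
#' `band = Inf` to force the full (exact) programme.
#'
#' @param a,b Nucleotide sequences (single strings, uppercase).
#' @param match,mismatch,gap Integer alignment scores (gap is per gapped
#'   column; terminal gaps are free).
#' @param band Half-width of the alignment band, `Inf` for unbanded, or
#'   `NULL` (default) to choose automatically: unbanded for sequences up to
#'   512 nt, otherwise `max(64, length difference + 64)`.
#' @return A list with `a_aln` and `b_aln` (the aligned core, `-` for gaps;
#'   free terminal gaps are not included), `score`, `matches`, `columns`,
#'   `identity` (percent, matches / columns) and the 0-based core start
#'   offsets `a_start`, `b_start`.
#' @export
align_pair <- function(a, b, match = 2L, mismatch = -3L, gap = -5L,
                       band = NULL) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1) {
    stop("`a` and `b` must be single strings", call. = FALSE)
  }
  if (!nzchar(a) || !nzchar(b)) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  n <- nchar(a); m <- nchar(b)
  if (is.null(band)) {
    band <- if (max(n, m) <= 512L) -1L else max(64L, abs(n - m) + 64L)
  }
  if (is.infinite(band)) band <- -1L
  align_overlap_cpp(a, b, as.integer(match), as.integer(mismatch),
                    as.integer(gap), as.integer(band))
}

#' Percent identity of two sequences
#'
#' Identity of the optimal ends-free global alignment, defined as matching
#' columns over alignment columns with terminal-gap columns excluded (the
#' usual dereplication-tool semantics). Symmetric in its arguments.
#'
#' @inheritParams align_pair
#' @return Percent identity in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, band = NULL) {
  align_pair(a, b, band = band)$identity
}

#' Pairwise distance in SNVs per 100 comparable sites
#'
#' Distance between two sequences counted over the columns of their global
#' alignment in which both sequences carry an unambiguous base (A, C, G or
#' T): `100 * mismatching columns / comparable columns`. Gap columns and
#' columns containing `N` or other ambiguity codes are excluded from both
#' numerator and denominator.
#'
#' @inheritParams align_pair
#' @param aligned If `TRUE`, `a` and `b` are already aligned strings of
#'   equal length (possibly containing `-`) and are compared column-wise
#'   without re-alignment.
#' @return Distance in SNVs per 100 comparable nucleotides.
#' @seealso [identity_from_distance()]
#' @export
pairwise_distance <- function(a, b, aligned = FALSE, band = NULL) {
  if (aligned) {
    if (nchar(a) != nchar(b)) {
      stop("aligned sequences must have equal length", call. = FALSE)
    }
    aa <- a; bb <- b
  } else {
    aln <- align_pair(a, b, band = band)
    aa <- aln$a_aln; bb <- aln$b_aln
  }
  va <- strsplit(aa, "", fixed = TRUE)[[1]]
  vb <- strsplit(bb, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  comparable <- va %in% bases & vb %in% bases
  ncomp <- sum(comparable)
  if (ncomp == 0) {
    stop("no comparable (gap-free, unambiguous) alignment columns",
         call. = FALSE)
  }
  100 * sum(va[comparable] != vb[comparable]) / ncomp
}

#' Convert a distance to a percent identity
#'
#' Distances are expressed as SNVs per 100 comparable nucleotides, so the
#' corresponding identity is simply `100 - distance`.
#'
#' @param d Numeric vector of distances.
#' @return `100 - d`.
#' @export
identity_from_distance <- function(d) {
  100 - d
}

#' Approximate SNV count from identity and a mean sequence length
#'
#' Converts a percent identity into an approximate count of single-
#' nucleotide variants over a sequence of given (mean) length:
#' `round(mean_length * (100 - identity) / 100)`.
#'
#' @param identity Percent identity in \[0, 100\].
#' @param mean_length Mean sequence length in nucleotides.
#' @return Rounded SNV count.
#' @export
snv_estimate <- function(identity, mean_length) {
  if (any(identity < 0 | identity > 100)) {
    stop("identity must be in [0, 100]", call. = FALSE)
  }
  round(mean_length * (100 - identity) / 100)
}
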