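#' Per-column residue conservation
#'
#' Mean pairwise residue similarity (see [aa_similarity()]) over the
#' non-gap residues of a column, down-weighted by the gap fraction:
#' `cons = mean_pair_sim * (1 - gap_fraction)`. Columns with fewer than two
#' residues score 0. `X` counts as a gap.
#'
#' @param column character vector of residues (with gaps), length >= 2.
#' @return conservation in `[0, 1]`.
#' @export
#' @examples
#' conservation_score(c("E", "E", "A", "A")) # 5/9
conservation_score <- function(column) {
  if (length(column) == 0L) stop_kinfam("empty column")
  if (length(column) < 2L) stop_kinfam("conservation needs >= 2 sequences")
  m <- matrix(toupper(column), ncol = 1L)
  column_conservation(m)[1L]
}

# vectorised conservation over all columns of an alignment matrix
column_conservation <- function(m) {
  cnt <- aa_counts(m)
  gapfrac <- 1 - colSums(cnt) / nrow(m)
  w <- within_similarity(cnt)
  ifelse(is.na(w), 0, w * (1 - gapfrac))
}

#' Diversity-of-positions (DOPs) score of an alignment
#'
#' Summarises how varied the per-column conservation values of an alignment
#' are: `100 * (#distinct conservation scores, rounded to 4 decimals) /
#' (#columns)`. An alignment of identical sequences has a single repeated
#' score and a low DOPs; a score above 70 indicates high sequence diversity
#' and is used as the gate for conservation-based analyses.
#'
#' @param alignment named character vector of gapped rows (>= 2 sequences)
#'   or a character matrix.
#' @return DOPs score in `[0, 100]`.
#' @export
dops <- function(alignment) {
  m <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  if (nrow(m) < 2L)
    stop_kinfam("DOPs undefined for a single-sequence alignment")
  if (ncol(m) < 1L) stop_kinfam("alignment has no columns")
  cons <- round(column_conservation(m), 4L)
  100 * length(unique(cons)) / ncol(m)
}
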