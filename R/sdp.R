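# 20 x ncols residue count matrix of an alignment matrix (gaps/X excluded)
aa_counts <- function(m) {
  aa <- aa_alphabet()
  out <- matrix(0, nrow = 20L, ncol = ncol(m), dimnames = list(aa, NULL))
  for (a in aa) out[a, ] <- colSums(m == a)
  out
}

# vectorised within-group mean pair similarity per column; NA where a
# column has fewer than 2 residues
within_similarity <- function(counts) {
  s <- similarity_matrix()
  n <- colSums(counts)
  q <- colSums(counts * (s %*% counts))
  out <- ifelse(n >= 2, (q - n) / (n * (n - 1)), NA_real_)
  out
}

# vectorised between-group mean pair similarity per column
between_similarity <- function(counts_a, counts_b) {
  s <- similarity_matrix()
  na <- colSums(counts_a)
  nb <- colSums(counts_b)
  q <- colSums(counts_a * (s %*% counts_b))
  ifelse(na >= 1 & nb >= 1, q / (na * nb), NA_real_)
}

#' Differential-conservation scores for one alignment column
#'
#' GroupSim-style column statistic between two sequence groups sharing a
#' joint alignment coordinate system: `cons_a` and `cons_b` are the mean
#' pairwise residue similarities within each group (gaps and `X` excluded),
#' `between` the mean similarity over cross-group pairs, and
#' `groupsim = min(cons_a, cons_b) - between`. A column is a
#' specificity-determining position (SDP) when both groups are conserved
#' (`cons >= tau_cons`), the differential signal is strong
#' (`groupsim >= tau_gs`) and neither group is mostly gapped
#' (gap fraction <= 0.5).
#'
#' @param col_a,col_b character vectors: the residues of each group at the
#'   column (each group needs at least 2 sequences).
#' @param tau_cons within-group conservation threshold (default 0.8).
#' @param tau_gs groupsim threshold (default 0.4).
#' @return one-row data frame: `cons_a`, `cons_b`, `between`, `groupsim`,
#'   `gapfrac_a`, `gapfrac_b`, `is_sdp`. Conservation values are `NA` when
#'   a group has fewer than 2 residues at the column (such columns are
#'   never SDPs).
#' @export
#' @examples
#' group_column_scores(rep("E", 4), rep("A", 4)) # groupsim 2/3, SDP
group_column_scores <- function(col_a, col_b, tau_cons = 0.8,
                                tau_gs = 0.4) {
  if (length(col_a) < 2L || length(col_b) < 2L)
    stop_kinfam("group too small: need at least 2 sequences per group")
  ma <- matrix(toupper(col_a), ncol = 1L)
  mb <- matrix(toupper(col_b), ncol = 1L)
  out <- column_scores_table(ma, mb, tau_cons, tau_gs)
  out$position <- NULL
  out
}

# shared engine: per-column score table for two row-groups of a joint
# alignment (matrices with equal column counts)
column_scores_table <- function(ma, mb, tau_cons = 0.8, tau_gs = 0.4) {
  ca <- aa_counts(ma)
  cb <- aa_counts(mb)
  cons_a <- within_similarity(ca)
  cons_b <- within_similarity(cb)
  between <- between_similarity(ca, cb)
  groupsim <- pmin(cons_a, cons_b) - between
  gapfrac_a <- 1 - colSums(ca) / nrow(ma)
  gapfrac_b <- 1 - colSums(cb) / nrow(mb)
  is_sdp <- !is.na(groupsim) &
    !is.na(cons_a) & !is.na(cons_b) &
    cons_a >= tau_cons & cons_b >= tau_cons &
    groupsim >= tau_gs &
    gapfrac_a <= 0.5 & gapfrac_b <= 0.5
  data.frame(position = seq_len(ncol(ma)),
             cons_a = cons_a, cons_b = cons_b, between = between,
             groupsim = groupsim,
             gapfrac_a = gapfrac_a, gapfrac_b = gapfrac_b,
             is_sdp = is_sdp)
}

#' Detect specificity-determining positions between two groups
#'
#' Applies [group_column_scores()] to every column of two alignments that
#' share a joint coordinate system and returns the full ranked table,
#' sorted by `groupsim` descending (columns whose conservation is undefined
#' sort last). SDP columns are flagged in `is_sdp`.
#'
#' @param aln_a,aln_b named character vectors of gapped rows with equal
#'   column counts (each with at least 2 sequences).
#' @inheritParams group_column_scores
#' @return data frame as in [group_column_scores()], plus `position`
#'   (1-based column index in the joint alignment).
#' @export
detect_sdps <- function(aln_a, aln_b, tau_cons = 0.8, tau_gs = 0.4) {
  ma <- aln_matrix(aln_a)
  mb <- aln_matrix(aln_b)
  if (ncol(ma) != ncol(mb))
    stop_kinfam("alignments have different column counts (",
                ncol(ma), " vs ", ncol(mb), ")")
  if (nrow(ma) < 2L || nrow(mb) < 2L)
    stop_kinfam("group too small: need at least 2 sequences per group")
  tab <- column_scores_table(ma, mb, tau_cons, tau_gs)
  tab[order(-tab$groupsim, tab$position, na.last = TRUE), , drop = FALSE]
}
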