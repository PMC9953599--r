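#' Position-based sequence weights (Henikoff & Henikoff)
#'
#' Each alignment column distributes one unit of weight: a sequence carrying
#' residue r in a column with k distinct residues, r occurring c times,
#' receives 1/(k*c). Weights are rescaled to sum to the number of sequences
#' (so a uniform alignment gives every sequence weight 1). Gaps and `X`
#' contribute nothing.
#'
#' @param alignment named character vector of gapped rows, or a character
#'   matrix.
#' @return numeric vector of weights, one per sequence.
#' @export
position_weights <- function(alignment) {
  m <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  n <- nrow(m)
  code <- matrix(match(m, aa_alphabet()), nrow = n) # NA for gaps/X
  w <- numeric(n)
  for (j in seq_len(ncol(code))) {
    col <- code[, j]
    ok <- !is.na(col)
    if (!any(ok)) next
    cnt <- tabulate(col[ok], nbins = 20L)
    k <- sum(cnt > 0L)
    w[ok] <- w[ok] + 1 / (k * cnt[col[ok]])
  }
  if (sum(w) > 0) w <- w * n / sum(w) else w[] <- 1
  names(w) <- rownames(m)
  w
}

#' Build a frequency profile from a cluster alignment
#'
#' Per-column residue probabilities with position-based sequence weights and
#' background-frequency pseudocounts:
#' `p(a) = (weighted count of a + w_pc * bg(a)) / (weighted non-gap total + w_pc)`.
#' Columns with no residues (all gaps) are set to the background. Profiles
#' stand in for the per-cluster HMMs of the classification protocol: they
#' carry no insert/delete states, which is sufficient here because profile
#' comparisons only drive the merge order of the agglomerative tree.
#'
#' @param cluster a `seq_cluster` (uses its `$alignment`) or an alignment
#'   (named character vector of gapped rows).
#' @param pseudocount_weight non-negative pseudocount mass (default 1).
#' @return object of class `profile_model`: list with `mat` (ncols x 20
#'   probability matrix, rows summing to 1), `ncols`, `pseudocount_weight`.
#' @export
build_profile <- function(cluster, pseudocount_weight = 1.0) {
  alignment <- if (inherits(cluster, "seq_cluster")) cluster$alignment
               else cluster
  m <- aln_matrix(alignment)
  aa <- aa_alphabet()
  bg <- aa_background()
  w <- position_weights(m)
  ncols <- ncol(m)
  # weighted residue counts per column: one pass per letter
  cnt <- matrix(0, nrow = ncols, ncol = 20L, dimnames = list(NULL, aa))
  for (a in aa) cnt[, a] <- colSums((m == a) * w)
  tot <- rowSums(cnt)
  prof <- (cnt + pseudocount_weight * rep(bg, each = ncols)) /
    (tot + pseudocount_weight)
  empty <- tot == 0
  if (any(empty)) prof[empty, ] <- rep(bg, each = sum(empty))
  structure(list(mat = prof, ncols = ncols,
                 pseudocount_weight = pseudocount_weight),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("Frequency profile:", x$ncols, "columns, pseudocount weight",
      x$pseudocount_weight, "\n")
  invisible(x)
}

#' Majority-rule consensus of an alignment
#'
#' The most frequent non-gap residue per column (ties broken
#' alphabetically); all-gap columns are dropped.
#'
#' @param alignment named character vector of gapped rows or a `funfam`.
#' @return a single residue string.
#' @export
consensus_sequence <- function(alignment) {
  if (inherits(alignment, "funfam")) alignment <- alignment$alignment
  m <- aln_matrix(alignment)
  cnt <- aa_counts(m)
  keep <- colSums(cnt) > 0
  paste(rownames(cnt)[apply(cnt[, keep, drop = FALSE], 2L, which.max)],
        collapse = "")
}

# profile for a single ungapped sequence (delta columns when pc = 0)
sequence_profile <- function(seq, pseudocount_weight = 0) {
  build_profile(setNames(seq, "s"), pseudocount_weight)
}

# column-score matrix between two profiles under BLOSUM62
profile_score_matrix <- function(p, q) {
  b <- blosum62()
  p$mat %*% b %*% t(q$mat)
}

#' Profile-profile alignment score
#'
#' Global dynamic-programming alignment of two frequency profiles with
#' column score `s(i, j) = sum_ab p_i(a) q_j(b) B62(a, b)` and affine gap
#' penalties (open -10, extend -1). The total score is normalised by the
#' number of columns of the shorter profile, making the score symmetric and
#' roughly length-independent.
#'
#' @param p,q `profile_model` objects.
#' @return normalised alignment score (numeric scalar).
#' @seealso [align_profiles()] for the alignment path.
#' @export
score_profiles <- function(p, q) {
  align_profiles(p, q)$score
}

#' @rdname score_profiles
#' @return `align_profiles()` returns a list with `score` (normalised),
#'   `raw_score`, and the aligned column path `path_i`, `path_j` (0 marks a
#'   gap in the respective profile).
#' @export
align_profiles <- function(p, q) {
  stopifnot(inherits(p, "profile_model"), inherits(q, "profile_model"))
  S <- profile_score_matrix(p, q)
  al <- gotoh_align(S, gap_open = -10, gap_extend = -1)
  list(score = al$score / min(p$ncols, q$ncols), raw_score = al$score,
       path_i = al$path_i, path_j = al$path_j)
}

# merge two alignments along a profile-profile path: aligned columns are
# stacked, gap steps insert all-gap columns for the other block
merge_alignments <- function(aln_a, aln_b, path_i, path_j) {
  ma <- aln_matrix(aln_a)
  mb <- aln_matrix(aln_b)
  ia <- ifelse(path_i > 0L, path_i, NA_integer_)
  ib <- ifelse(path_j > 0L, path_j, NA_integer_)
  pick <- function(m, idx) {
    out <- matrix("-", nrow = nrow(m), ncol = length(idx),
                  dimnames = list(rownames(m), NULL))
    ok <- !is.na(idx)
    out[, ok] <- m[, idx[ok], drop = FALSE]
    out
  }
  matrix_aln(rbind(pick(ma, ia), pick(mb, ib)))
}
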