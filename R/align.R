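#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap
#' penalties (open -10, extend -0.5); identity is the number of identical
#' aligned residue pairs divided by the length of the shorter sequence.
#'
#' @param a,b residue strings (non-empty).
#' @return identity in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDF") # 0.75
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop_kinfam("empty sequence")
  identity_to_refs(a, c(ref = b))[[1L]]
}

# identity of one sequence against many references (single alignment call)
identity_to_refs <- function(seq, refs) {
  if (!nzchar(seq) || any(!nzchar(refs))) stop_kinfam("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(refs),
    subject = Biostrings::AAString(seq),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  # PID3: identities / length of shorter sequence
  setNames(Biostrings::pid(pa, type = "PID3") / 100, names(refs))
}

#' Star alignment of near-identical sequences to a representative
#'
#' Aligns every member to the representative (global BLOSUM62 alignment,
#' affine -10/-0.5) and merges the pairwise alignments on the
#' representative's coordinates, inserting shared gap columns where members
#' carry insertions. Intended for identity pre-clusters whose members are
#' close to the representative, where the star approximation is benign.
#'
#' @param seqs named character vector of sequences.
#' @param rep_id name of the representative (default: first element).
#' @return named character vector of gapped rows (the alignment), same
#'   order as `seqs`.
#' @export
star_align <- function(seqs, rep_id = names(seqs)[1L]) {
  stopifnot(!is.null(names(seqs)), rep_id %in% names(seqs))
  if (length(seqs) == 1L) return(seqs)
  rep_seq <- seqs[[rep_id]]
  L <- nchar(rep_seq)
  others <- seqs[setdiff(names(seqs), rep_id)]
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(others)),
    subject = Biostrings::AAString(rep_seq),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))

  # insertions of each member after each representative position (0 = before
  # the first residue)
  ins <- matrix(0L, nrow = length(others), ncol = L + 1L)
  member_cols <- vector("list", length(others))
  for (k in seq_along(others)) {
    pc <- strsplit(pat[k], "", fixed = TRUE)[[1L]]
    sc <- strsplit(sub[k], "", fixed = TRUE)[[1L]]
    p <- 0L
    for (t in seq_along(sc)) {
      if (sc[t] == "-") ins[k, p + 1L] <- ins[k, p + 1L] + 1L else p <- p + 1L
    }
    member_cols[[k]] <- list(pc = pc, sc = sc)
  }
  maxins <- apply(ins, 2L, max)
  width <- L + sum(maxins)
  # column index of representative position p
  pos_col <- cumsum(maxins[seq_len(L)]) + seq_len(L)

  rows <- matrix("-", nrow = length(seqs), ncol = width,
                 dimnames = list(names(seqs), NULL))
  rows[rep_id, pos_col] <- strsplit(rep_seq, "", fixed = TRUE)[[1L]]
  for (k in seq_along(others)) {
    pc <- member_cols[[k]]$pc
    sc <- member_cols[[k]]$sc
    p <- 0L       # representative position
    slot_used <- 0L
    for (t in seq_along(sc)) {
      if (sc[t] == "-") {
        # insertion in slot after position p, left-justified
        base <- if (p == 0L) 0L else pos_col[p]
        slot_used <- slot_used + 1L
        rows[names(others)[k], base + slot_used] <- pc[t]
      } else {
        p <- p + 1L
        slot_used <- 0L
        rows[names(others)[k], pos_col[p]] <- pc[t]
      }
    }
  }
  matrix_aln(rows)[names(seqs)]
}
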