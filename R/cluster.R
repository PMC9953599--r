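#' Greedy identity pre-clustering (S90)
#'
#' CD-HIT-style greedy clustering: sequences are visited longest first (ties
#' by id), each either joins the first existing cluster whose representative
#' it matches at `threshold` identity or founds a new cluster. Cluster
#' alignments are star alignments of members to the representative. With
#' the default threshold of 0.90 this produces the S90 seed clusters of the
#' classification protocol.
#'
#' @param units named character vector of (unit) sequences, or a data frame
#'   with `unit_id` and `unit_seq` columns.
#' @param threshold identity threshold in (0, 1]; default 0.90.
#' @param annotated_ids ids of sequences carrying an experimental functional
#'   annotation; a cluster is `annotated` if it contains at least one.
#' @return list of `seq_cluster` objects: `id`, `members`, `representative`,
#'   `alignment`, `annotated`.
#' @export
greedy_cluster <- function(units, threshold = 0.90,
                           annotated_ids = character()) {
  if (is.data.frame(units))
    units <- setNames(units$unit_seq, units$unit_id)
  stopifnot(length(units) > 0L, !is.null(names(units)))
  if (threshold <= 0 || threshold > 1)
    stop_kinfam("threshold must be in (0, 1]")
  o <- order(-nchar(units), names(units))
  units <- units[o]
  reps <- character(0)        # representative ids, in creation order
  membership <- character(length(units))
  names(membership) <- names(units)
  for (id in names(units)) {
    assigned <- NA_character_
    if (length(reps)) {
      idn <- identity_to_refs(units[[id]], setNames(units[reps], reps))
      hit <- which(idn >= threshold)
      if (length(hit)) assigned <- reps[hit[1L]]
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    membership[id] <- assigned
  }
  lapply(reps, function(r) {
    members <- names(membership)[membership == r]
    seqs <- units[members]
    aln <- star_align(seqs, rep_id = r)
    new_seq_cluster(id = paste0("S90:", r), members = members,
                    representative = r, alignment = aln,
                    annotated = any(members %in% annotated_ids))
  })
}

new_seq_cluster <- function(id, members, alignment, annotated = FALSE,
                            representative = NULL) {
  structure(list(id = id, members = members,
                 representative = representative,
                 alignment = alignment, annotated = annotated),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat("Cluster ", x$id, ": ", length(x$members), " member(s), ",
      nchar(x$alignment[[1L]]), " alignment column(s)",
      if (x$annotated) ", annotated" else "", "\n", sep = "")
  invisible(x)
}
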