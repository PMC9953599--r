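#' Agglomerative merge tree over seed clusters
#'
#' GeMMA-style agglomerative clustering: all pairwise profile-profile scores
#' are computed, the best-scoring pair is merged (its alignments combined
#' along the profile alignment path, a new profile built), and scores
#' against the new node are recomputed, until a single root remains. Score
#' ties are broken by the lexicographically smallest sorted pair of node
#' ids, so the tree is independent of input order.
#'
#' @param clusters list of `seq_cluster` objects (at least one).
#' @param pseudocount_weight pseudocount mass for node profiles.
#' @return object of class `merge_tree`: a recursive node list. Leaves hold
#'   a cluster; internal nodes hold `left`, `right`, the merged `alignment`
#'   and `profile`, `merge_score` and `merge_order`.
#' @export
build_merge_tree <- function(clusters, pseudocount_weight = 1.0) {
  if (length(clusters) == 0L) stop_kinfam("no clusters to merge")
  stopifnot(all(vapply(clusters, inherits, logical(1), "seq_cluster")))
  make_leaf <- function(cl) {
    structure(list(id = cl$id, leaf = TRUE, cluster = cl,
                   members = cl$members, alignment = cl$alignment,
                   profile = build_profile(cl$alignment, pseudocount_weight)),
              class = "merge_node")
  }
  active <- lapply(clusters, make_leaf)
  names(active) <- vapply(active, `[[`, character(1), "id")
  if (anyDuplicated(names(active))) stop_kinfam("duplicate cluster ids")

  n <- length(active)
  if (n == 1L) {
    root <- active[[1L]]
    class(root) <- c("merge_tree", class(root))
    return(root)
  }
  # pairwise score cache
  scores <- matrix(NA_real_, n, n, dimnames = list(names(active),
                                                   names(active)))
  ids <- names(active)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    scores[i, j] <- scores[j, i] <-
      score_profiles(active[[i]]$profile, active[[j]]$profile)
  }
  order_counter <- 0L
  while (length(active) > 1L) {
    ids <- names(active)
    sc <- scores[ids, ids, drop = FALSE]
    best <- max(sc, na.rm = TRUE)
    cand <- which(sc == best, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # tie-break: smallest sorted (id, id) pair
    pair_lo <- pmin(ids[cand[, 1L]], ids[cand[, 2L]])
    pair_hi <- pmax(ids[cand[, 1L]], ids[cand[, 2L]])
    k <- order(pair_lo, pair_hi)[1L]
    a <- active[[ids[cand[k, 1L]]]]
    b <- active[[ids[cand[k, 2L]]]]
    if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }

    al <- align_profiles(a$profile, b$profile)
    merged_aln <- merge_alignments(a$alignment, b$alignment,
                                   al$path_i, al$path_j)
    order_counter <- order_counter + 1L
    node <- structure(
      list(id = min(a$id, b$id), leaf = FALSE, left = a, right = b,
           members = c(a$members, b$members), alignment = merged_aln,
           profile = build_profile(merged_aln, pseudocount_weight),
           merge_score = al$score, merge_order = order_counter),
      class = "merge_node")

    keep <- setdiff(names(active), c(a$id, b$id))
    active[[a$id]] <- NULL
    active[[b$id]] <- NULL
    active[[node$id]] <- node
    new_scores <- vapply(keep, function(k)
      score_profiles(active[[k]]$profile, node$profile), numeric(1))
    # grow the cache for the new node id (reuse slot of the smaller id)
    scores[node$id, keep] <- new_scores
    scores[keep, node$id] <- new_scores
  }
  root <- active[[1L]]
  class(root) <- c("merge_tree", class(root))
  root
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("Merge tree: ", n_leaves(x), " leaves, ",
      length(x$members), " sequences\n", sep = "")
  invisible(x)
}

#' Count the leaves of a merge tree
#' @param node a `merge_tree` / `merge_node`.
#' @return integer.
#' @export
n_leaves <- function(node) {
  if (node$leaf) 1L else n_leaves(node$left) + n_leaves(node$right)
}

#' Serialise a merge tree as Newick
#'
#' Internal nodes are labelled `'merge_order:merge_score'` (quoted, since
#' the label contains a colon).
#'
#' @param tree a `merge_tree`.
#' @param path optional file; if omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_merge_tree <- function(tree, path = NULL) {
  rec <- function(node) {
    if (node$leaf) return(gsub("[(),:;]", "_", node$id))
    sprintf("(%s,%s)'%d:%.6g'", rec(node$left), rec(node$right),
            node$merge_order, node$merge_score)
  }
  nwk <- paste0(rec(tree), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
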