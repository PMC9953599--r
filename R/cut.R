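#' Decide whether a merge-tree node separates two functional families
#'
#' A node keeps its two children as separate families when (a) both
#' children have at least `n_min` members, (b) both children pass the
#' information gate, and (c) at least `k_min` specificity-determining
#' positions separate the children in the node's joint alignment.
#'
#' The information gate asks whether a child's conservation values can be
#' trusted: a child passes if its alignment has DOPs >= `dops_min`, or if
#' it has at least `n_reliable` members. The member-count escape reflects
#' the empirical observation that low-DOPs alignments are unreliable
#' precisely when they hold very few sequences; a large low-diversity
#' (redundant) alignment still yields well-determined conservation.
#'
#' @param node an internal `merge_node` (leaf input is an error).
#' @param n_min minimum child size for a split (default 3).
#' @param k_min minimum number of SDP columns (default 2).
#' @param dops_min DOPs gate for small children (default 70).
#' @param n_reliable child size at which the DOPs gate is waived
#'   (default 6).
#' @param tau_cons,tau_gs SDP thresholds, see [group_column_scores()].
#' @return `TRUE` to keep the children separate, `FALSE` to merge them.
#' @export
decide_cut <- function(node, n_min = 3L, k_min = 2L, dops_min = 70,
                       n_reliable = 6L, tau_cons = 0.8, tau_gs = 0.4) {
  stopifnot(inherits(node, "merge_node"))
  if (node$leaf) stop_kinfam("decide_cut() needs an internal node")
  a <- node$left$members
  b <- node$right$members
  if (length(a) < n_min || length(b) < n_min) return(FALSE)
  info_ok <- function(child) {
    if (length(child$members) >= n_reliable) return(TRUE)
    if (length(child$alignment) < 2L) return(FALSE)
    dops(child$alignment) >= dops_min
  }
  if (!info_ok(node$left) || !info_ok(node$right)) return(FALSE)
  sdps <- node_sdps(node, tau_cons, tau_gs)
  if (is.null(sdps)) return(FALSE)
  sum(sdps$is_sdp) >= k_min
}

# SDP table between the two children of a node, in the node's joint
# alignment coordinates; NULL when a child is a singleton (differential
# conservation cannot be established)
node_sdps <- function(node, tau_cons = 0.8, tau_gs = 0.4) {
  if (length(node$left$members) < 2L || length(node$right$members) < 2L)
    return(NULL)
  aln <- node$alignment
  detect_sdps(aln[node$left$members], aln[node$right$members],
              tau_cons, tau_gs)
}

#' Cut a merge tree into functional families
#'
#' Post-order traversal of the merge tree: at every internal node the two
#' child groups are merged unless [decide_cut()] keeps them apart or a cut
#' anywhere below has already split a child (a cut propagates: ancestors of
#' a cut node never merge across it). The result is a partition of the
#' tree's leaf members into functional families (FunFams).
#'
#' @param tree a `merge_tree`.
#' @param params parameter list from [kinfam_params()] (only the cut
#'   parameters are used).
#' @return list of `funfam` objects (id, members, alignment, profile,
#'   `sdps_vs_sibling`, `mda_set`), a partition of the leaf members.
#' @export
cut_tree <- function(tree, params = kinfam_params()) {
  stopifnot(inherits(tree, "merge_node"))
  rec <- function(node) {
    if (node$leaf)
      return(list(list(members = node$members, alignment = node$alignment,
                       sdps = NULL)))
    ga <- rec(node$left)
    gb <- rec(node$right)
    if (length(ga) == 1L && length(gb) == 1L &&
        !decide_cut(node, params$n_min, params$k_min, params$dops_min,
                    params$n_reliable, params$tau_cons, params$tau_gs)) {
      return(list(list(members = node$members, alignment = node$alignment,
                       sdps = NULL)))
    }
    # the node is a family boundary: attach the sibling SDP table to
    # groups that do not yet carry one from a deeper cut
    sdps <- node_sdps(node, params$tau_cons, params$tau_gs)
    ann <- function(g) {
      if (is.null(g$sdps)) g$sdps <- sdps
      g
    }
    c(lapply(ga, ann), lapply(gb, ann))
  }
  groups <- rec(tree)
  groups_to_funfams(groups, params)
}

groups_to_funfams <- function(groups, params) {
  # deterministic ids: order by size descending, then smallest member id
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  firsts <- vapply(groups, function(g) min(g$members), character(1))
  o <- order(-sizes, firsts)
  groups <- groups[o]
  out <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    aln <- drop_gap_columns(g$alignment)
    structure(list(id = sprintf("FF%03d", k), members = g$members,
                   alignment = aln,
                   profile = build_profile(aln, params$pseudocount_weight),
                   sdps_vs_sibling = g$sdps, mda_set = character(0)),
              class = "funfam")
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

# drop columns that are all-gap (arise when a family is carved out of a
# larger merged alignment)
drop_gap_columns <- function(alignment) {
  m <- aln_matrix(alignment)
  keep <- colSums(m != "-" & m != ".") > 0L
  if (!any(keep)) return(alignment)
  matrix_aln(m[, keep, drop = FALSE])
}

#' @export
print.funfam <- function(x, ...) {
  cat("FunFam ", x$id, ": ", length(x$members), " member(s), ",
      nchar(x$alignment[[1L]]), " columns",
      if (length(x$mda_set)) paste0(", MDAs: ",
                                    paste(x$mda_set, collapse = " ")) else "",
      "\n", sep = "")
  invisible(x)
}
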