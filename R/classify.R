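#' Parameters of the classification pipeline
#'
#' Collects every tunable threshold in one place. Defaults follow the
#' protocol: 20-residue linker bound, S90 identity pre-clustering,
#' unit-mass pseudocounts, and the cut rule of [decide_cut()].
#'
#' @param linker_max maximum inter-lobe linker length (residues).
#' @param s90_threshold identity threshold of the pre-clustering step.
#' @param pseudocount_weight pseudocount mass for profiles.
#' @param n_min,k_min,dops_min,n_reliable,tau_cons,tau_gs cut parameters,
#'   see [decide_cut()] and [group_column_scores()].
#' @return list of class `kinfam_params`.
#' @export
kinfam_params <- function(linker_max = 20L, s90_threshold = 0.90,
                          pseudocount_weight = 0, n_min = 3L,
                          k_min = 2L, dops_min = 70, n_reliable = 6L,
                          tau_cons = 0.8, tau_gs = 0.4) {
  structure(list(linker_max = linker_max, s90_threshold = s90_threshold,
                 pseudocount_weight = pseudocount_weight, n_min = n_min,
                 k_min = k_min, dops_min = dops_min,
                 n_reliable = n_reliable, tau_cons = tau_cons,
                 tau_gs = tau_gs),
            class = "kinfam_params")
}

#' Classify a two-lobe superfamily into functional families
#'
#' Full pipeline driver. The sequences are resolved into multi-domain
#' architectures, functional units are built and partitioned by MDA key;
#' within each partition the units are pre-clustered at S90, clusters
#' without an experimental annotation are held aside, and the annotated
#' clusters are merged into a tree and cut into families. The per-MDA
#' families are then pooled and a final merge-tree/cut iteration is run
#' over all of them, so that families split across architectures can
#' re-join. Held-aside (unannotated) clusters are finally scanned against
#' the family profiles for an advisory assignment.
#'
#' @param sequences named character vector of protein sequences.
#' @param hits domain-hit data frame (`seq_id family_id start stop score`).
#' @param annotations annotation data frame (`seq_id ec4 experimental`);
#'   a sequence is annotated when it has a row with `experimental` TRUE/1.
#' @param n_family,c_family N- and C-lobe domain family ids.
#' @param params a [kinfam_params()] list.
#' @return object of class `kinfam_classification`: list with `funfams`
#'   (named list of `funfam`), `assignments` (data frame `funfam_id`,
#'   `unit_id`, `seq_id`, `mda_key`), `unassigned` (advisory table for
#'   held-aside clusters), `units`, `mda`, `held_aside`, `params`.
#' @export
classify_superfamily <- function(sequences, hits, annotations,
                                 n_family = "3.30.200.20",
                                 c_family = "1.10.510.10",
                                 params = kinfam_params()) {
  res <- resolve_dataset(sequences, hits, n_family, c_family,
                         params$linker_max)
  units <- res$units
  if (nrow(units) == 0L)
    stop_kinfam("no functional units could be built")
  ann_flag <- annotations$experimental %in% TRUE
  annotated_seqs <- unique(annotations$seq_id[ann_flag])
  annotated_units <- units$unit_id[units$seq_id %in% annotated_seqs]

  held <- list()
  pooled <- list()
  for (key in sort(unique(units$mda_key))) {
    u <- units[units$mda_key == key, , drop = FALSE]
    clusters <- greedy_cluster(setNames(u$unit_seq, u$unit_id),
                               threshold = params$s90_threshold,
                               annotated_ids = annotated_units)
    ann <- Filter(function(cl) cl$annotated, clusters)
    held <- c(held, Filter(function(cl) !cl$annotated, clusters))
    if (!length(ann)) next
    tree <- build_merge_tree(ann, params$pseudocount_weight)
    fams <- cut_tree(tree, params)
    pooled <- c(pooled, fams)
  }
  if (!length(pooled))
    stop_kinfam("no annotated clusters: nothing to classify")

  # final iteration over the pooled per-MDA families
  seed_clusters <- lapply(pooled, function(ff)
    new_seq_cluster(id = paste0("FF:", min(ff$members)),
                    members = ff$members, alignment = ff$alignment,
                    annotated = TRUE))
  if (length(seed_clusters) > 1L) {
    tree <- build_merge_tree(seed_clusters, params$pseudocount_weight)
    funfams <- cut_tree(tree, params)
  } else {
    funfams <- groups_to_funfams(
      list(list(members = seed_clusters[[1L]]$members,
                alignment = seed_clusters[[1L]]$alignment, sdps = NULL)),
      params)
  }

  unit_mda <- setNames(units$mda_key, units$unit_id)
  unit_seqid <- setNames(units$seq_id, units$unit_id)
  funfams <- lapply(funfams, function(ff) {
    ff$mda_set <- sort(unique(unit_mda[ff$members]))
    ff
  })
  assignments <- do.call(rbind, lapply(funfams, function(ff)
    data.frame(funfam_id = ff$id, unit_id = ff$members,
               seq_id = unname(unit_seqid[ff$members]),
               mda_key = unname(unit_mda[ff$members]))))
  rownames(assignments) <- NULL

  unassigned <- assign_unannotated(held, funfams)
  structure(list(funfams = funfams, assignments = assignments,
                 unassigned = unassigned, units = units, mda = res$mda,
                 held_aside = held, params = params),
            class = "kinfam_classification")
}

#' Advisory assignment of unannotated clusters to families
#'
#' Scores each held-aside (unannotated) cluster profile against every
#' family profile and reports the best-scoring family. The assignment is
#' advisory: members are not added to the family.
#'
#' @param clusters list of `seq_cluster` (may be empty).
#' @param funfams named list of `funfam` objects with profiles.
#' @return data frame `cluster_id`, `funfam_id`, `score`.
#' @export
assign_unannotated <- function(clusters, funfams) {
  if (!length(clusters))
    return(data.frame(cluster_id = character(), funfam_id = character(),
                      score = numeric()))
  rows <- lapply(clusters, function(cl) {
    prof <- build_profile(cl$alignment)
    sc <- vapply(funfams, function(ff) score_profiles(prof, ff$profile),
                 numeric(1))
    best <- which.max(sc)
    data.frame(cluster_id = cl$id, funfam_id = names(funfams)[best],
               score = unname(sc[best]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.kinfam_classification <- function(x, ...) {
  cat("Functional-family classification\n")
  cat("  ", length(x$funfams), " FunFams over ",
      nrow(x$assignments), " functional units (",
      length(unique(x$assignments$seq_id)), " sequences)\n", sep = "")
  cat("  ", length(unique(x$units$mda_key)), " multi-domain architectures; ",
      length(x$held_aside), " unannotated cluster(s) held aside\n", sep = "")
  invisible(x)
}

#' @export
summary.kinfam_classification <- function(object, ...) {
  sizes <- vapply(object$funfams, function(ff) length(ff$members),
                  integer(1))
  out <- list(n_funfams = length(object$funfams),
              n_units = nrow(object$assignments),
              n_mdas = length(unique(object$units$mda_key)),
              family_sizes = sizes,
              n_held_aside = length(object$held_aside))
  class(out) <- "summary.kinfam_classification"
  out
}

#' @export
print.summary.kinfam_classification <- function(x, ...) {
  cat("FunFams:", x$n_funfams, " units:", x$n_units,
      " MDAs:", x$n_mdas, " held aside:", x$n_held_aside, "\n")
  cat("family sizes:\n")
  print(x$family_sizes)
  invisible(x)
}
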