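#' Filter drug records to approved, potent kinase-inhibitor activities
#'
#' Keeps ChEMBL-style records that pass every gate of the druggability
#' protocol: approved drug (`max_phase >= 4`), direct single-protein
#' binding assay (`assay_type == "B"`), potency `pchembl >= 6`, activity
#' concentration stronger than 1 mM (`activity_nM < 1e6`), and an ATC code
#' in the antineoplastic protein-kinase-inhibitor class (prefix `"L01E"`).
#' The filter is order-preserving and idempotent.
#'
#' @param records drug-record data frame (see [read_drug_records()]).
#' @param phase_min,assay,pchembl_min,activity_max_nM,atc_prefix the gates.
#' @return the qualifying rows of `records`.
#' @export
filter_drug_records <- function(records, phase_min = 4L, assay = "B",
                                pchembl_min = 6.0,
                                activity_max_nM = 1e6,
                                atc_prefix = "L01E") {
  keep <- records$max_phase >= phase_min &
    records$assay_type == assay &
    records$pchembl >= pchembl_min &
    records$activity_nM < activity_max_nM &
    startsWith(as.character(records$atc_code), atc_prefix)
  out <- records[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric drug-target enrichment per family
#'
#' For each family, tests over-representation of drug targets among its
#' members with the exact hypergeometric upper tail
#' `p = P(X >= k | N, K, n)` where `N` is the universe size, `K` the
#' number of targets in the universe, `n` the family size and `k` the
#' number of targets in the family. Benjamini-Hochberg q-values are
#' attached and families with `q < alpha` flagged druggable.
#'
#' @param funfams a `kinfam_classification`, named list of `funfam`, or
#'   membership data frame (`funfam_id`, `seq_id`).
#' @param target_ids sequence ids that are drug targets (subset of the
#'   universe).
#' @param universe_ids the enrichment universe (all classified sequences
#'   under analysis).
#' @param alpha FDR level for the druggable flag (default 0.05).
#' @return data frame of class `enrichment_result`: `funfam_id`,
#'   `n_members`, `n_targets`, `universe_n`, `universe_targets`,
#'   `p_value`, `q_value`, `druggable`.
#' @export
family_enrichment <- function(funfams, target_ids, universe_ids,
                              alpha = 0.05) {
  membership <- as_membership(funfams)
  target_ids <- unique(target_ids)
  universe_ids <- unique(universe_ids)
  extra_t <- setdiff(target_ids, universe_ids)
  if (length(extra_t))
    stop_kinfam("targets outside the universe: ",
                paste(extra_t, collapse = ", "))
  extra_m <- setdiff(unique(membership$seq_id), universe_ids)
  if (length(extra_m))
    stop_kinfam("family members outside the universe: ",
                paste(extra_m, collapse = ", "))
  N <- length(universe_ids)
  K <- length(target_ids)
  fams <- split(unique(membership[c("funfam_id", "seq_id")])$seq_id,
                unique(membership[c("funfam_id", "seq_id")])$funfam_id)
  out <- do.call(rbind, lapply(names(fams), function(f) {
    n <- length(fams[[f]])
    k <- sum(fams[[f]] %in% target_ids)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(funfam_id = f, n_members = n, n_targets = k,
               universe_n = N, universe_targets = K, p_value = p)
  }))
  out$q_value <- bh_fdr(out$p_value)
  out$druggable <- out$q_value < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH adjustment (`q_i = min_{p_(j) >= p_(i)} m p_(j) / j`),
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop_kinfam("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Families enriched in drug targets
#'
#' @param results an `enrichment_result` from [family_enrichment()].
#' @param alpha FDR level (default 0.05).
#' @return character vector of family ids with `q < alpha`, sorted by
#'   q-value then id.
#' @export
druggable_families <- function(results, alpha = 0.05) {
  hit <- results[results$q_value < alpha, , drop = FALSE]
  hit$funfam_id[order(hit$q_value, hit$funfam_id)]
}
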