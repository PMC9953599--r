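#' Enzyme Commission purity of functional families
#'
#' Counts, per family, the distinct EC codes among EC-annotated members at
#' the 4-field (EC4) and 3-field (EC3, first three fields of EC4) levels.
#' The summary fractions (families with exactly one EC3 / one EC4) are
#' computed over families with at least one EC-annotated member.
#'
#' @param funfams a `kinfam_classification`, a named list of `funfam`
#'   objects, or a membership data frame with `funfam_id` and `seq_id`.
#' @param annotations data frame with `seq_id` and `ec4` (NA allowed).
#' @return object of class `purity_report`: list with `per_family` (data
#'   frame `funfam_id`, `n_seqs_with_ec`, `unique_ec3`, `unique_ec4`) and
#'   `summary` (`n_families`, `n_families_with_ec`, `frac_one_ec3`,
#'   `frac_one_ec4`).
#' @export
ec_purity <- function(funfams, annotations) {
  membership <- as_membership(funfams)
  ecs <- annotations[!is.na(annotations$ec4), c("seq_id", "ec4")]
  if (nrow(ecs)) {
    parts <- strsplit(ecs$ec4, ".", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 4L
    if (any(bad))
      stop_kinfam("malformed EC number '", ecs$ec4[bad][1L],
                  "' for sequence ", ecs$seq_id[bad][1L])
    ecs$ec3 <- vapply(parts, function(p) paste(p[1:3], collapse = "."),
                      character(1))
  } else {
    ecs$ec3 <- character(0)
  }
  fams <- split(membership$seq_id, membership$funfam_id)
  per <- do.call(rbind, lapply(names(fams), function(f) {
    e <- ecs[ecs$seq_id %in% fams[[f]], , drop = FALSE]
    data.frame(funfam_id = f,
               n_seqs_with_ec = length(unique(e$seq_id)),
               unique_ec3 = length(unique(e$ec3)),
               unique_ec4 = length(unique(e$ec4)))
  }))
  rownames(per) <- NULL
  with_ec <- per[per$n_seqs_with_ec > 0L, , drop = FALSE]
  summ <- list(n_families = nrow(per),
               n_families_with_ec = nrow(with_ec),
               frac_one_ec3 = if (nrow(with_ec))
                 mean(with_ec$unique_ec3 == 1L) else NA_real_,
               frac_one_ec4 = if (nrow(with_ec))
                 mean(with_ec$unique_ec4 == 1L) else NA_real_)
  structure(list(per_family = per, summary = summ),
            class = "purity_report")
}

#' @export
print.purity_report <- function(x, ...) {
  s <- x$summary
  cat("EC purity over ", s$n_families_with_ec, "/", s$n_families,
      " families with EC annotations\n", sep = "")
  cat(sprintf("  single EC3: %.1f%%   single EC4: %.1f%%\n",
              100 * s$frac_one_ec3, 100 * s$frac_one_ec4))
  invisible(x)
}

# normalise the various family containers to (funfam_id, seq_id)
as_membership <- function(funfams) {
  if (inherits(funfams, "kinfam_classification"))
    return(funfams$assignments[, c("funfam_id", "seq_id")])
  if (is.data.frame(funfams)) {
    stopifnot(all(c("funfam_id", "seq_id") %in% names(funfams)))
    return(funfams[, c("funfam_id", "seq_id")])
  }
  if (is.list(funfams)) {
    rows <- lapply(funfams, function(ff) {
      if (inherits(ff, "funfam"))
        data.frame(funfam_id = ff$id, seq_id = ff$members)
      else stop_kinfam("cannot interpret family container")
    })
    return(do.call(rbind, rows))
  }
  stop_kinfam("cannot interpret family container")
}

#' Map a reference family classification onto a test classification
#'
#' Assigns every sequence to its test family (from the test partition,
#' falling back to `scan_hits` for sequences absent from it) and labels
#' each reference family: `one-to-one` (all members in a single test family
#' that holds no other reference family), `split` (members spread over
#' several test families), `merged` (single test family shared with another
#' reference family) or `unmapped` (no member mapped).
#'
#' @param reference_partition,test_partition data frames with `family_id`
#'   and `seq_id` (or named lists of member vectors).
#' @param scan_hits optional data frame with `seq_id` and `funfam_id`
#'   (e.g. from [scan_sequences()]) used for sequences missing from the
#'   test partition.
#' @return object of class `mapping_report`: `per_family` data frame
#'   (`family_id`, `n_members`, `n_mapped`, `n_test_families`,
#'   `test_families`, `relation`) and `counts` (named integer vector over
#'   the four relations).
#' @export
map_families <- function(reference_partition, test_partition,
                         scan_hits = NULL) {
  ref <- as_partition(reference_partition)
  tst <- as_partition(test_partition)
  assign <- setNames(tst$family_id, tst$seq_id)
  if (!is.null(scan_hits) && nrow(scan_hits)) {
    extra <- scan_hits[!(scan_hits$seq_id %in% names(assign)), ,
                       drop = FALSE]
    assign <- c(assign, setNames(extra$funfam_id, extra$seq_id))
  }
  fams <- split(ref$seq_id, ref$family_id)
  test_of_ref <- lapply(fams, function(m)
    sort(unique(assign[m][!is.na(assign[m])])))
  # test families containing members of >= 2 reference families
  pair <- unique(data.frame(
    ref = rep(names(test_of_ref),
              vapply(test_of_ref, length, integer(1))),
    tst = unlist(test_of_ref, use.names = FALSE)))
  shared <- names(which(table(pair$tst) >= 2L))
  per <- do.call(rbind, lapply(names(fams), function(f) {
    tset <- test_of_ref[[f]]
    rel <- if (length(tset) == 0L) "unmapped"
           else if (length(tset) > 1L) "split"
           else if (tset %in% shared) "merged"
           else "one-to-one"
    data.frame(family_id = f, n_members = length(fams[[f]]),
               n_mapped = sum(!is.na(assign[fams[[f]]])),
               n_test_families = length(tset),
               test_families = paste(tset, collapse = ","),
               relation = rel)
  }))
  rownames(per) <- NULL
  counts <- table(factor(per$relation,
                         levels = c("one-to-one", "split", "merged",
                                    "unmapped")))
  structure(list(per_family = per, counts = c(counts)),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("Family mapping:",
      paste(names(x$counts), x$counts, sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("family_id", "seq_id") %in% names(x)))
      return(x[, c("family_id", "seq_id")])
    if (all(c("funfam_id", "seq_id") %in% names(x)))
      return(data.frame(family_id = x$funfam_id, seq_id = x$seq_id))
    stop_kinfam("partition needs family_id/seq_id columns")
  }
  if (inherits(x, "kinfam_classification"))
    return(data.frame(family_id = x$assignments$funfam_id,
                      seq_id = x$assignments$seq_id))
  if (is.list(x) && !is.null(names(x)))
    return(data.frame(
      family_id = rep(names(x), vapply(x, length, integer(1))),
      seq_id = unlist(x, use.names = FALSE)))
  stop_kinfam("cannot interpret partition")
}
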