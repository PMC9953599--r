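#' Resolve domain hits into a non-overlapping architecture
#'
#' Exact weighted-interval scheduling over the scored hits of one sequence:
#' returns the subset of hits with maximal total score such that no two hits
#' share a residue (intervals are closed, 1-based inclusive). Score ties are
#' broken in favour of the solution with more hits, then the
#' lexicographically smallest sorted list of `(start, family_id)` pairs, so
#' the result is a deterministic function of the hit set (input order never
#' matters).
#'
#' @param hits data frame with columns `seq_id`, `family_id`, `start`,
#'   `stop`, `score`, all for a single sequence.
#' @return an object of class `resolved_architecture`: list with `seq_id`,
#'   `hits` (selected rows, ordered by start) and `total_score`.
#' @export
#' @examples
#' h <- data.frame(seq_id = "s", family_id = c("A", "B", "C"),
#'                 start = c(1, 50, 120), stop = c(100, 150, 200),
#'                 score = c(10, 12, 5))
#' resolve_hits(h) # keeps A and C, total score 15
resolve_hits <- function(hits) {
  cols <- c("seq_id", "family_id", "start", "stop", "score")
  if (is.null(hits) || nrow(hits) == 0L) {
    arch <- list(seq_id = NA_character_,
                 hits = data.frame(seq_id = character(),
                                   family_id = character(),
                                   start = integer(), stop = integer(),
                                   score = numeric()),
                 total_score = 0)
    class(arch) <- "resolved_architecture"
    return(arch)
  }
  if (!all(cols %in% names(hits)))
    stop_kinfam("hits must have columns: ", paste(cols, collapse = ", "))
  hits <- hits[cols]
  if (length(unique(hits$seq_id)) != 1L)
    stop_kinfam("resolve_hits() takes hits of a single sequence; got ids: ",
                paste(unique(hits$seq_id), collapse = ", "))
  validate_hits(hits)
  hits$start <- as.integer(hits$start)
  hits$stop <- as.integer(hits$stop)

  # sort by stop (then start, family) so prefixes are well-defined
  o <- order(hits$stop, hits$start, hits$family_id)
  h <- hits[o, , drop = FALSE]
  n <- nrow(h)
  # p[i]: number of intervals (in sorted order) ending strictly before
  # start[i] (closed intervals: compatible iff stop < start)
  p <- findInterval(h$start - 1L, h$stop)

  # solution value: list(score, nhits, sel = integer indices into h)
  sol_key <- function(sel) {
    if (length(sel) == 0L) return(character())
    k <- sprintf("%012d|%s", h$start[sel], h$family_id[sel])
    sort(k)
  }
  better <- function(a, b) {
    # is solution a strictly better than b?
    if (a$score != b$score) return(a$score > b$score)
    if (length(a$sel) != length(b$sel)) return(length(a$sel) > length(b$sel))
    ka <- sol_key(a$sel); kb <- sol_key(b$sel)
    m <- min(length(ka), length(kb))
    if (m > 0L) {
      d <- which(ka[seq_len(m)] != kb[seq_len(m)])
      if (length(d)) return(ka[d[1L]] < kb[d[1L]])
    }
    FALSE
  }

  best <- vector("list", n + 1L)
  best[[1L]] <- list(score = 0, sel = integer())
  for (i in seq_len(n)) {
    skip <- best[[i]]
    take <- list(score = best[[p[i] + 1L]]$score + h$score[i],
                 sel = c(best[[p[i] + 1L]]$sel, i))
    best[[i + 1L]] <- if (better(take, skip)) take else skip
  }
  sel <- best[[n + 1L]]$sel
  out <- h[sel, , drop = FALSE]
  out <- out[order(out$start, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  arch <- list(seq_id = hits$seq_id[1L], hits = out,
               total_score = sum(out$score))
  class(arch) <- "resolved_architecture"
  arch
}

#' @export
print.resolved_architecture <- function(x, ...) {
  cat("Resolved architecture for ", x$seq_id %||% "<empty>",
      ": ", nrow(x$hits), " domain(s), total score ",
      format(x$total_score), "\n", sep = "")
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

#' Build kinase functional units from a resolved architecture
#'
#' Pairs each N-lobe hit with the nearest following C-lobe hit, provided no
#' other domain lies between them and the inter-lobe gap (the linker) is at
#' most `linker_max` residues. Each pairing yields one functional unit
#' spanning the N-lobe start to the C-lobe stop, linker included; lobes that
#' cannot be paired yield no unit. A sequence may contain several units
#' (tandem kinases).
#'
#' @param arch a `resolved_architecture`.
#' @param n_family,c_family domain family ids of the N- and C-lobe.
#' @param linker_max maximum linker length (residues) between lobes.
#' @param sequence optional residue string of the sequence, used to fill
#'   `unit_seq`.
#' @return data frame with one row per unit: `unit_id`, `seq_id`,
#'   `n_start`, `n_stop`, `c_start`, `c_stop`, `linker_len`, `unit_seq`.
#' @export
build_functional_units <- function(arch, n_family, c_family,
                                   linker_max = 20L, sequence = NULL) {
  stopifnot(inherits(arch, "resolved_architecture"))
  if (identical(n_family, c_family))
    stop_kinfam("n_family and c_family must differ")
  h <- arch$hits
  empty <- data.frame(unit_id = character(), seq_id = character(),
                      n_start = integer(), n_stop = integer(),
                      c_start = integer(), c_stop = integer(),
                      linker_len = integer(), unit_seq = character())
  if (nrow(h) < 2L) return(empty)
  h <- h[order(h$start), , drop = FALSE]
  used <- logical(nrow(h))
  units <- list()
  for (i in seq_len(nrow(h) - 1L)) {
    if (used[i] || h$family_id[i] != n_family) next
    j <- i + 1L # nearest following hit; anything else has a hit in between
    if (used[j] || h$family_id[j] != c_family) next
    gap <- h$start[j] - h$stop[i] - 1L
    if (gap < 0L || gap > linker_max) next
    used[i] <- used[j] <- TRUE
    units[[length(units) + 1L]] <-
      data.frame(seq_id = arch$seq_id,
                 n_start = h$start[i], n_stop = h$stop[i],
                 c_start = h$start[j], c_stop = h$stop[j],
                 linker_len = gap)
  }
  if (!length(units)) return(empty)
  out <- do.call(rbind, units)
  out$unit_id <- if (nrow(out) == 1L) out$seq_id else
    paste0(out$seq_id, "_u", seq_len(nrow(out)))
  out$unit_seq <- NA_character_
  if (!is.null(sequence)) {
    if (max(out$c_stop) > nchar(sequence))
      stop_kinfam("unit extends beyond sequence length for ", arch$seq_id)
    out$unit_seq <- substr(rep(sequence, nrow(out)), out$n_start, out$c_stop)
  }
  out[c("unit_id", "seq_id", "n_start", "n_stop", "c_start", "c_stop",
        "linker_len", "unit_seq")]
}

#' Multi-domain architecture key of a resolved sequence
#'
#' Emits the domain tokens of a resolved architecture in start order, with
#' the two lobes of each functional unit collapsed into a single token
#' `FU:<n_family>-<c_family>` placed at the N-lobe start. Unpaired lobes
#' keep their own family token.
#'
#' @param arch a `resolved_architecture` with at least one hit.
#' @param units data frame from [build_functional_units()] (possibly empty).
#' @return character vector of tokens (the MDA). Use [mda_key()] to collapse
#'   it into a single partition key.
#' @export
assign_mda <- function(arch, units) {
  stopifnot(inherits(arch, "resolved_architecture"))
  h <- arch$hits
  if (nrow(h) == 0L) stop_kinfam("no domains: cannot assign an MDA")
  h <- h[order(h$start), , drop = FALSE]
  token <- h$family_id
  drop <- logical(nrow(h))
  if (!is.null(units) && nrow(units)) {
    for (k in seq_len(nrow(units))) {
      i <- which(h$start == units$n_start[k] & h$stop == units$n_stop[k])
      j <- which(h$start == units$c_start[k] & h$stop == units$c_stop[k])
      if (length(i) != 1L || length(j) != 1L)
        stop_kinfam("unit lobes not found in architecture of ", arch$seq_id)
      token[i] <- paste0("FU:", h$family_id[i], "-", h$family_id[j])
      drop[j] <- TRUE
    }
  }
  token[!drop]
}

#' @rdname assign_mda
#' @param tokens character vector of MDA tokens.
#' @export
mda_key <- function(tokens) paste(tokens, collapse = "|")

#' Resolve a full hit table into architectures, units and MDA keys
#'
#' Driver over [resolve_hits()], [build_functional_units()] and
#' [assign_mda()] for a whole dataset.
#'
#' @param sequences named character vector of protein sequences.
#' @param hits domain-hit data frame (all sequences).
#' @inheritParams build_functional_units
#' @return list with `architectures` (named list), `units` (data frame with
#'   an `mda_key` column) and `mda` (named character vector per sequence).
#' @export
resolve_dataset <- function(sequences, hits, n_family, c_family,
                            linker_max = 20L) {
  ids <- names(sequences)
  archs <- list()
  units <- list()
  mda <- character(0)
  byseq <- split(hits, hits$seq_id)
  for (id in ids) {
    h <- byseq[[id]]
    if (is.null(h) || nrow(h) == 0L) next
    a <- resolve_hits(h)
    u <- build_functional_units(a, n_family, c_family, linker_max,
                                sequence = sequences[[id]])
    archs[[id]] <- a
    key <- mda_key(assign_mda(a, u))
    mda[id] <- key
    if (nrow(u)) {
      u$mda_key <- key
      units[[id]] <- u
    }
  }
  units <- if (length(units)) do.call(rbind, units) else
    data.frame(unit_id = character(), seq_id = character(),
               n_start = integer(), n_stop = integer(),
               c_start = integer(), c_stop = integer(),
               linker_len = integer(), unit_seq = character(),
               mda_key = character())
  rownames(units) <- NULL
  list(architectures = archs, units = units, mda = mda)
}
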