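#' Read and write protein sequences (FASTA)
#'
#' Thin wrappers around Biostrings. Sequences are handled package-wide as
#' named uppercase character vectors; alignments may contain `-` gaps.
#'
#' @param path file path.
#' @param seqs named character vector of (possibly gapped) sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(out)))
    stop_kinfam("duplicate sequence ids in ", path)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a domain-hit table
#'
#' Tab-separated with columns `seq_id family_id start stop score`; `#`
#' lines are comments. Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return data frame with the five columns, types checked.
#' @export
read_domain_hits <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("seq_id", "family_id", "start", "stop", "score")
  if (!all(need %in% names(df)))
    stop_kinfam("domain-hit table must have columns: ",
                paste(need, collapse = ", "))
  df <- df[need]
  df$start <- as.integer(df$start)
  df$stop <- as.integer(df$stop)
  df$score <- as.numeric(df$score)
  validate_hits(df)
  df
}

#' @rdname read_domain_hits
#' @param hits a domain-hit data frame.
#' @export
write_domain_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a functional-annotation table
#'
#' Tab-separated with columns `seq_id ec4 experimental` (0/1). `ec4` may be
#' empty/NA for sequences without an EC assignment.
#'
#' @param path file path.
#' @return data frame with columns `seq_id`, `ec4`, `experimental` (logical).
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("seq_id", "ec4", "experimental")
  if (!all(need %in% names(df)))
    stop_kinfam("annotation table must have columns: ",
                paste(need, collapse = ", "))
  df <- df[need]
  df$experimental <- as.logical(as.integer(df$experimental))
  df
}

#' Read a drug-record table
#'
#' Tab-separated with the columns of a ChEMBL-style activity record:
#' `drug_id target_seq_id max_phase assay_type pchembl activity_nM atc_code`.
#'
#' @param path file path.
#' @return data frame with typed columns.
#' @export
read_drug_records <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("drug_id", "target_seq_id", "max_phase", "assay_type",
            "pchembl", "activity_nM", "atc_code")
  if (!all(need %in% names(df)))
    stop_kinfam("drug-record table must have columns: ",
                paste(need, collapse = ", "))
  df <- df[need]
  df$max_phase <- as.integer(df$max_phase)
  df$pchembl <- as.numeric(df$pchembl)
  df$activity_nM <- as.numeric(df$activity_nM)
  df
}

#' Write classification output tables
#'
#' `write_funfam_table()` writes `funfam_id seq_id mda_key` (one row per
#' classified functional unit); `write_sdp_report()` writes per-column SDP
#' scores for each family-vs-sibling comparison.
#'
#' @param classification a `kinfam_classification` object.
#' @param path output file.
#' @export
write_funfam_table <- function(classification, path) {
  write.table(classification$assignments[, c("funfam_id", "seq_id", "mda_key")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_funfam_table
#' @export
write_sdp_report <- function(classification, path) {
  rows <- lapply(classification$funfams, function(ff) {
    if (is.null(ff$sdps_vs_sibling) || nrow(ff$sdps_vs_sibling) == 0L)
      return(NULL)
    cbind(funfam_pair = paste0(ff$id, "|sibling"), ff$sdps_vs_sibling)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows))
    rows <- data.frame(funfam_pair = character(), position = integer(),
                       cons_a = numeric(), cons_b = numeric(),
                       between = numeric(), groupsim = numeric(),
                       gapfrac_a = numeric(), gapfrac_b = numeric(),
                       is_sdp = logical())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(invisible(hits))
  bad <- hits$start < 1L | hits$stop < hits$start
  if (any(bad))
    stop_kinfam("invalid hit coordinates for: ",
                paste(unique(hits$seq_id[bad]), collapse = ", "))
  if (any(hits$score < 0))
    stop_kinfam("negative hit scores for: ",
                paste(unique(hits$seq_id[hits$score < 0]), collapse = ", "))
  invisible(hits)
}
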