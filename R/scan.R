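#' Calibrate E-values for a profile by decoy scoring
#'
#' Scores the profile against `n_decoys` random sequences drawn i.i.d.
#' from the background amino-acid frequencies (length-matched to the
#' profile) and fits a Gumbel extreme-value law by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - 0.5772/lambda`. The
#' E-value of a score s against a database of `n_db` sequences is then
#' `E(s) = n_db * (1 - exp(-exp(-lambda (s - mu))))`.
#'
#' @param profile a `profile_model`.
#' @param n_decoys number of decoys (>= 50).
#' @param seed RNG seed (calibration is deterministic given the seed).
#' @return object of class `evalue_calibration`: `lambda`, `mu`,
#'   `n_decoys`, `decoy_scores`.
#' @export
calibrate_evalues <- function(profile, n_decoys = 200L, seed = 1L) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_decoys < 50L) stop_kinfam("need at least 50 decoys")
  bg <- aa_background()
  scores <- with_seed(seed, {
    vapply(seq_len(n_decoys), function(k) {
      d <- paste(sample(aa_alphabet(), profile$ncols, replace = TRUE,
                        prob = bg), collapse = "")
      score_profiles(sequence_profile(d), profile)
    }, numeric(1))
  })
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-12)
    stop_kinfam("degenerate decoy score variance")
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  structure(list(lambda = lambda, mu = mu, n_decoys = n_decoys,
                 decoy_scores = scores),
            class = "evalue_calibration")
}

#' @rdname calibrate_evalues
#' @param score bit-score-like profile alignment score(s).
#' @param calibration an `evalue_calibration`.
#' @param n_db number of sequences in the scanned database.
#' @return `evalue()` returns the E-value(s), positive and decreasing in
#'   the score.
#' @export
evalue <- function(score, calibration, n_db) {
  stopifnot(inherits(calibration, "evalue_calibration"))
  x <- calibration$lambda * (score - calibration$mu)
  # tail probability of the Gumbel: 1 - exp(-exp(-x)), stable for large x
  p <- -expm1(-exp(-x))
  n_db * p
}

#' Scan sequences against a family profile library
#'
#' Scores every sequence against every family profile (global
#' profile-profile alignment) and reports, per sequence, the best-scoring
#' family whose calibrated E-value is at most `evalue_max` (default
#' 1e-18, the match threshold of the protocol). Sequences with no
#' qualifying family are omitted. The E-value database size `n_db` is the
#' number of scanned sequences.
#'
#' @param seqs named character vector of sequences.
#' @param funfams named list of `funfam` objects.
#' @param evalue_max E-value cutoff (default 1e-18).
#' @param calibrations optional named list of `evalue_calibration`, one
#'   per family; computed with [calibrate_evalues()] when missing.
#' @param n_decoys,seed calibration settings when `calibrations` is NULL.
#' @return data frame of class `scan_hits`: `seq_id`, `funfam_id`,
#'   `bit_score`, `evalue`; attribute `n_db`.
#' @export
scan_sequences <- function(seqs, funfams, evalue_max = 1e-18,
                           calibrations = NULL, n_decoys = 200L,
                           seed = 1L) {
  stopifnot(length(funfams) > 0L)
  if (is.null(calibrations)) {
    calibrations <- lapply(seq_along(funfams), function(k)
      calibrate_evalues(funfams[[k]]$profile, n_decoys, seed + k))
    names(calibrations) <- names(funfams)
  }
  n_db <- length(seqs)
  rows <- lapply(names(seqs), function(id) {
    sp <- sequence_profile(seqs[[id]])
    sc <- vapply(funfams, function(ff) score_profiles(sp, ff$profile),
                 numeric(1))
    ev <- vapply(names(funfams), function(f)
      evalue(sc[[f]], calibrations[[f]], n_db), numeric(1))
    ok <- which(ev <= evalue_max)
    if (!length(ok)) return(NULL)
    best <- ok[which.max(sc[ok])]
    data.frame(seq_id = id, funfam_id = names(funfams)[best],
               bit_score = unname(sc[best]), evalue = unname(ev[best]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), funfam_id = character(),
               bit_score = numeric(), evalue = numeric())
  rownames(out) <- NULL
  attr(out, "n_db") <- n_db
  class(out) <- c("scan_hits", class(out))
  out
}
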