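#' Amino-acid alphabet and background frequencies
#'
#' The 20 standard residues in the order used by all profile matrices in the
#' package, and the fixed background frequency table used for profile
#' pseudocounts, decoy generation and E-value calibration. The frequencies
#' are a standard average amino-acid composition of globular proteins; they
#' sum to 1 exactly.
#'
#' @return `aa_alphabet()` a character vector of length 20;
#'   `aa_background()` a named numeric vector summing to 1.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname aa_alphabet
#' @export
aa_background <- function() {
  c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
    Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
    L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
    S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
}

# BLOSUM62 restricted to the 20-letter alphabet, cached
blosum62 <- function() {
  if (is.null(.kinfamr$b62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    aa <- aa_alphabet()
    .kinfamr$b62 <- e$BLOSUM62[aa, aa]
  }
  .kinfamr$b62
}

# 20 x 20 matrix of the normalised similarity kernel, cached
similarity_matrix <- function() {
  if (is.null(.kinfamr$sim)) {
    b <- blosum62()
    d <- diag(b)
    den <- outer(d, d, pmax) + 4
    s <- (b + 4) / den
    s[s < 0] <- 0
    diag(s) <- 1
    .kinfamr$sim <- s
  }
  .kinfamr$sim
}

#' Substitution-matrix similarity kernel between two residues
#'
#' Maps BLOSUM62 scores into `[0, 1]`:
#' `sim(x, y) = max(0, (B62(x, y) + 4) / (max(B62(x, x), B62(y, y)) + 4))`,
#' so that `sim(x, x) = 1` for every residue. Used for per-column
#' conservation and differential-conservation (SDP) scoring.
#'
#' @param x,y character vectors of single amino-acid letters (recycled).
#' @return numeric vector in `[0, 1]`; `NA` where either letter is not one
#'   of the 20 standard residues (such positions are excluded from column
#'   statistics, like gaps).
#' @export
#' @examples
#' aa_similarity("E", "E") # 1
#' aa_similarity("E", "A") # 1/3
aa_similarity <- function(x, y) {
  s <- similarity_matrix()
  n <- max(length(x), length(y))
  x <- rep_len(toupper(x), n)
  y <- rep_len(toupper(y), n)
  out <- rep(NA_real_, n)
  ok <- x %in% rownames(s) & y %in% rownames(s)
  out[ok] <- s[cbind(x[ok], y[ok])]
  out
}
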