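`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_kinfam <- function(...) stop(..., call. = FALSE)

# split alignment (named character vector of gapped strings) into a
# character matrix, rows = sequences
aln_matrix <- function(alignment) {
  if (length(alignment) == 0L) stop_kinfam("empty alignment")
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop_kinfam("alignment rows have unequal lengths")
  m <- matrix(unlist(strsplit(alignment, "", fixed = TRUE), use.names = FALSE),
              nrow = length(alignment), ncol = w, byrow = TRUE)
  rownames(m) <- names(alignment)
  m
}

# collapse a character matrix back to gapped strings
matrix_aln <- function(m) {
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

degap <- function(x) gsub("[-.]", "", x)

is_gap_char <- function(x) x %in% c("-", ".", "X")
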