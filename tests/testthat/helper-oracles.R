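# Independent oracles and small fixture builders shared across tests.

# brute-force weighted-interval scheduling: enumerate every subset, keep
# the best by (total score desc, #hits desc, lexicographically smallest
# sorted (start, family_id) key)
oracle_resolve <- function(hits) {
  n <- nrow(hits)
  if (n == 0L) return(hits[0L, ])
  conflict <- outer(seq_len(n), seq_len(n), function(i, j)
    hits$start[i] <= hits$stop[j] & hits$start[j] <= hits$stop[i])
  diag(conflict) <- FALSE
  key_of <- function(sel)
    paste(sort(sprintf("%012d|%s", hits$start[sel], hits$family_id[sel])),
          collapse = ";")
  best_sel <- integer(0); best_score <- 0; best_key <- ""
  for (mask in 0:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) > 1L && any(conflict[sel, sel])) next
    sc <- sum(hits$score[sel])
    better <- sc > best_score ||
      (sc == best_score && length(sel) > length(best_sel)) ||
      (sc == best_score && length(sel) == length(best_sel) &&
         key_of(sel) < best_key)
    if (better || mask == 0L) {
      best_sel <- sel; best_score <- sc; best_key <- key_of(sel)
    }
  }
  out <- hits[best_sel, , drop = FALSE]
  out <- out[order(out$start, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_hit_instance <- function(n, seq_len_max = 300L) {
  if (n == 0L)
    return(data.frame(seq_id = character(), family_id = character(),
                      start = integer(), stop = integer(),
                      score = numeric()))
  data.frame(seq_id = "s",
             family_id = sample(LETTERS[1:4], n, replace = TRUE),
             start = st <- sample.int(seq_len_max - 30L, n, replace = TRUE),
             stop = st + sample.int(60L, n, replace = TRUE),
             score = round(sample.int(20L, n, replace = TRUE) / 2, 1))
}

# plain-R global affine-gap alignment score over arbitrary column scores
# (first gap residue costs open + extend); independent of the C++ kernel
oracle_affine_score <- function(S, open, extend) {
  n <- nrow(S); m <- ncol(S); NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- open + i * extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- open + j * extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1L, j + 1L] <- S[i, j] + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1L, j + 1L] <- max(M[i, j + 1L] + open + extend,
                             X[i, j + 1L] + extend,
                             Y[i, j + 1L] + open + extend)
    Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + open + extend,
                             Y[i + 1L, j] + extend,
                             X[i + 1L, j] + open + extend)
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

b62_score_matrix <- function(a, b) {
  B <- kinfamr:::blosum62()
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  outer(ac, bc, function(x, y) B[cbind(x, y)])
}

random_aa_seq <- function(n) {
  paste(sample(aa_alphabet(), n, replace = TRUE, prob = aa_background()),
        collapse = "")
}

# two-group alignment with known SDP columns: both groups share a
# consensus except at `sdp_at`, where group A carries `res_a` and group B
# `res_b`; other columns optionally noised
planted_sdp_alignment <- function(n_per_group = 6L, ncols = 40L,
                                  sdp_at = c(5L, 12L, 20L, 28L, 35L),
                                  res_a = "E", res_b = "W", noise = 0) {
  cons <- strsplit(random_aa_seq(ncols), "")[[1]]
  mk <- function(res, prefix) {
    rows <- vapply(seq_len(n_per_group), function(k) {
      x <- cons
      x[sdp_at] <- res
      if (noise > 0) {
        mut <- which(runif(ncols) < noise)
        mut <- setdiff(mut, sdp_at)
        x[mut] <- vapply(x[mut], function(c)
          sample(setdiff(aa_alphabet(), c), 1L), character(1))
      }
      paste(x, collapse = "")
    }, character(1))
    setNames(rows, paste0(prefix, seq_len(n_per_group)))
  }
  list(a = mk(res_a, "a"), b = mk(res_b, "b"), sdp_at = sdp_at)
}

# small fixture config used where full scale is unnecessary
small_fixture <- function(seed = 1L, n_families = 2L,
                          mda_layouts = list(c("FU"))) {
  fixture_config(n_families = n_families, seqs_per_family = c(8L, 8L),
                 unit_length = 120L, mda_layouts = mda_layouts,
                 seed = seed)
}
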