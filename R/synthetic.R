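#' Configuration of a synthetic superfamily fixture
#'
#' Describes a planted-truth superfamily: families drawn from one root
#' consensus, conserved within and differentially conserved between
#' families at a set of planted SDP columns, wrapped as N-lobe + linker +
#' C-lobe functional units and embedded in multi-domain architectures with
#' toy accessory domains. Defaults give 6 families over 3 architectures
#' (about 120 sequences), 5 SDP columns, and a 5% within-family mutation
#' rate.
#'
#' @param n_families number of planted families.
#' @param seqs_per_family integer range (min, max) of family sizes.
#' @param unit_length total lobe length of the functional unit (residues,
#'   excluding the linker).
#' @param n_sdp_columns number of planted SDP columns; every family pair
#'   differs at exactly these columns.
#' @param within_family_mutation_rate per-residue mutation probability.
#' @param between_family_divergence per-column probability that a family
#'   carries a neutral drift substitution at a drift-eligible column.
#'   Neutral drift uses conservative replacements (similarity >= 0.75
#'   under the package kernel, e.g. I/V, L/I), so it separates families
#'   in sequence identity without creating differential conservation:
#'   planted SDP columns remain the only SDPs.
#' @param mda_layouts list of domain layouts (tokens `"FU"`,
#'   `"ACC1"`..`"ACC5"`); families are assigned to layouts round-robin.
#' @param linker_length_range integer range for the inter-lobe linker; one
#'   length is drawn per bundle (indels are disabled by default so that
#'   alignment columns correspond exactly to unit coordinates).
#' @param ec_map character vector of EC4 codes, one per family.
#' @param target_fraction fraction of sequences that are drug targets.
#' @param unannotated_fraction fraction of sequences left without an
#'   experimental annotation.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_families = 6L,
                           seqs_per_family = c(18L, 22L),
                           unit_length = 280L,
                           n_sdp_columns = 5L,
                           within_family_mutation_rate = 0.05,
                           between_family_divergence = 0.3,
                           mda_layouts = list(c("FU"),
                                              c("ACC1", "FU"),
                                              c("FU", "ACC2")),
                           linker_length_range = c(5L, 15L),
                           ec_map = NULL,
                           target_fraction = 0.15,
                           unannotated_fraction = 0.10,
                           seed = 1L) {
  if (n_families < 1L) stop_kinfam("need at least one family")
  if (n_families > 10L)
    stop_kinfam("at most 10 families (size of the SDP residue panel)")
  if (within_family_mutation_rate < 0 || within_family_mutation_rate > 1)
    stop_kinfam("mutation rate must be in [0, 1]")
  if (n_sdp_columns < 0L) stop_kinfam("n_sdp_columns must be >= 0")
  for (lay in mda_layouts) {
    bad <- !(lay %in% c("FU", paste0("ACC", 1:5)))
    if (any(bad))
      stop_kinfam("unknown layout token(s): ",
                  paste(lay[bad], collapse = ", "))
    if (!any(lay == "FU"))
      stop_kinfam("every layout needs at least one FU token")
  }
  if (is.null(ec_map))
    ec_map <- paste0("2.7.", 10L + (seq_len(n_families) - 1L) %% 4L, ".",
                     seq_len(n_families))
  if (length(ec_map) != n_families)
    stop_kinfam("ec_map must have one EC per family")
  structure(list(n_families = as.integer(n_families),
                 seqs_per_family = as.integer(seqs_per_family),
                 unit_length = as.integer(unit_length),
                 n_sdp_columns = as.integer(n_sdp_columns),
                 within_family_mutation_rate = within_family_mutation_rate,
                 between_family_divergence = between_family_divergence,
                 mda_layouts = mda_layouts,
                 linker_length_range = as.integer(linker_length_range),
                 ec_map = ec_map,
                 target_fraction = target_fraction,
                 unannotated_fraction = unannotated_fraction,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# residues with mutually low similarity under the package kernel (greedy
# max-dissimilar selection, max pairwise similarity 0.42); ordered so that
# the rotation used by the generator pairs residues of similarity <= 0.24
# for family offsets up to 5, keeping planted SDPs far from the groupsim
# threshold
sdp_residue_panel <- function() {
  c("H", "P", "I", "W", "C", "G", "N", "E", "T", "F")
}

# conservative-replacement map for neutral family drift: for each residue
# the most similar partner, kept only when similarity >= 0.75 so that a
# drift column never looks differentially conserved
conservative_partner <- function() {
  s <- similarity_matrix()
  diag(s) <- 0
  best <- apply(s, 1L, which.max)
  sim <- s[cbind(seq_len(nrow(s)), best)]
  out <- colnames(s)[best]
  names(out) <- rownames(s)
  out[sim >= 0.75]
}

#' Generate a synthetic superfamily with planted ground truth
#'
#' Draws one root consensus, plants family-specific residues at the SDP
#' columns (mutually dissimilar between families, conserved within),
#' mutates every position i.i.d. at the configured rate, wraps each unit
#' with a linker and accessory domains according to the family's layout,
#' and emits sequences, domain hits (with weak spurious hits overlapping
#' the C-lobe on every fifth sequence), EC annotations and a drug-record
#' table whose targets are concentrated in the first family.
#'
#' @param config a [fixture_config()].
#' @return list of class `fixture_bundle`: `sequences` (named character
#'   vector), `domain_hits`, `annotations`, `drug_records` (data frames),
#'   `truth` (list: `family`, `mda`, `sdp_columns` in unit coordinates,
#'   `linker_len`, `targets`, `unannotated`), and `config`.
#' @export
generate_superfamily <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, generate_superfamily_impl(config))
}

generate_superfamily_impl <- function(cfg) {
  aa <- aa_alphabet()
  bg <- aa_background()
  panel <- sdp_residue_panel()
  n_len <- round(0.4 * cfg$unit_length)
  c_len <- cfg$unit_length - n_len
  rand_seq <- function(n) sample(aa, n, replace = TRUE, prob = bg)
  # accepted point mutations are conservative: mutant residues are drawn
  # with probability proportional to bg(a) * 2^(B62(c, a) / 2)
  mut_weights <- local({
    b <- blosum62()
    w <- t(2^(b / 2) * bg)    # rows: current residue c, cols: mutant a
    diag(w) <- 0
    w / rowSums(w)
  })
  mutate <- function(res, rate) {
    hit <- which(runif(length(res)) < rate)
    for (i in hit) res[i] <- sample(aa, 1L, prob = mut_weights[res[i], ])
    res
  }

  consensus <- rand_seq(cfg$unit_length)
  sdp_cols <- sort(sample.int(cfg$unit_length, cfg$n_sdp_columns))
  partner <- conservative_partner()
  drift_eligible <- setdiff(which(consensus %in% names(partner)), sdp_cols)
  # family f gets panel[(f + j) mod] at the j-th SDP column: residues are
  # distinct across families at every column
  fam_residue <- function(f, j)
    panel[((f - 1L + j - 1L) %% length(panel)) + 1L]
  linker_len <- if (cfg$linker_length_range[1] == cfg$linker_length_range[2])
    cfg$linker_length_range[1] else
    sample(seq(cfg$linker_length_range[1], cfg$linker_length_range[2]), 1L)
  # the linker (hinge) is part of the superfamily consensus: conserved
  # across families, mutated per sequence like any other position
  linker_consensus <- rand_seq(linker_len)
  acc_len <- 60L
  acc_tokens <- unique(unlist(cfg$mda_layouts))
  acc_tokens <- acc_tokens[acc_tokens != "FU"]
  acc_consensus <- lapply(setNames(acc_tokens, acc_tokens),
                          function(t) rand_seq(acc_len))
  spacer_len <- 30L # > linker_max, so accessories never join a unit

  seqs <- character(0)
  hits <- list()
  fam_of <- character(0)
  n_dom <- c("3.30.200.20")
  c_dom <- c("1.10.510.10")
  seq_counter <- 0L
  for (f in seq_len(cfg$n_families)) {
    layout <- cfg$mda_layouts[[((f - 1L) %% length(cfg$mda_layouts)) + 1L]]
    fam_cons <- consensus
    for (j in seq_along(sdp_cols)) fam_cons[sdp_cols[j]] <- fam_residue(f, j)
    drift <- drift_eligible[runif(length(drift_eligible)) <
                              cfg$between_family_divergence]
    fam_cons[drift] <- partner[fam_cons[drift]]
    n_f <- if (cfg$seqs_per_family[1] == cfg$seqs_per_family[2])
      cfg$seqs_per_family[1] else
      sample(seq(cfg$seqs_per_family[1], cfg$seqs_per_family[2]), 1L)
    for (k in seq_len(n_f)) {
      seq_counter <- seq_counter + 1L
      id <- sprintf("f%02ds%03d", f, k)
      unit <- mutate(fam_cons, cfg$within_family_mutation_rate)
      res <- character(0)
      seq_hits <- list()
      for (tok in layout) {
        if (length(res)) res <- c(res, rand_seq(spacer_len))
        if (tok == "FU") {
          n_start <- length(res) + 1L
          res <- c(res, unit[seq_len(n_len)])
          n_stop <- length(res)
          res <- c(res, mutate(linker_consensus,
                               cfg$within_family_mutation_rate))
          c_start <- length(res) + 1L
          res <- c(res, unit[(n_len + 1L):cfg$unit_length])
          c_stop <- length(res)
          seq_hits[[length(seq_hits) + 1L]] <- data.frame(
            seq_id = id, family_id = c(n_dom, c_dom),
            start = c(n_start, c_start), stop = c(n_stop, c_stop),
            score = 2 * c(n_len, c_len))
        } else {
          a_start <- length(res) + 1L
          res <- c(res, mutate(acc_consensus[[tok]],
                               cfg$within_family_mutation_rate))
          a_stop <- length(res)
          seq_hits[[length(seq_hits) + 1L]] <- data.frame(
            seq_id = id, family_id = tok,
            start = a_start, stop = a_stop, score = 2 * acc_len)
        }
      }
      if (seq_counter %% 5L == 0L) {
        # weak spurious hit overlapping the (first) C-lobe: resolution
        # must discard it
        h <- do.call(rbind, seq_hits)
        ci <- which(h$family_id == c_dom)[1L]
        seq_hits[[length(seq_hits) + 1L]] <- data.frame(
          seq_id = id, family_id = "DECOY",
          start = h$start[ci] + 5L,
          stop = min(h$start[ci] + 45L, h$stop[ci]),
          score = 0.2 * c_len)
      }
      seqs[id] <- paste(res, collapse = "")
      fam_of[id] <- paste0("fam", f)
      hits[[id]] <- do.call(rbind, seq_hits)
    }
  }
  hits <- do.call(rbind, hits)
  rownames(hits) <- NULL

  ids <- names(seqs)
  n_seqs <- length(ids)
  unannotated <- sort(sample(ids, round(cfg$unannotated_fraction * n_seqs)))
  annotated <- setdiff(ids, unannotated)
  fam_index <- as.integer(sub("fam", "", fam_of))
  annotations <- data.frame(seq_id = annotated,
                            ec4 = cfg$ec_map[fam_index[match(annotated,
                                                             ids)]],
                            experimental = 1L)

  n_targets <- max(1L, round(cfg$target_fraction * n_seqs))
  fam1 <- ids[fam_of == "fam1"]
  n_fam1 <- min(length(fam1), round(0.8 * n_targets))
  targets <- c(sample(fam1, n_fam1),
               sample(setdiff(ids, fam1), n_targets - n_fam1))
  targets <- sort(unique(targets))
  qualifying <- data.frame(
    drug_id = sprintf("D%03d", seq_along(targets)),
    target_seq_id = targets, max_phase = 4L, assay_type = "B",
    pchembl = 7.2, activity_nM = 120, atc_code = "L01EA01")
  failing <- data.frame(
    drug_id = sprintf("D9%02d", 1:4),
    target_seq_id = sample(ids, 4L),
    max_phase = c(3L, 4L, 4L, 4L),
    assay_type = c("B", "F", "B", "B"),
    pchembl = c(7.0, 7.0, 5.2, 7.0),
    activity_nM = c(100, 100, 100, 2e6),
    atc_code = c("L01EA01", "L01EA01", "L01EA01", "C07AB01"))
  drug_records <- rbind(qualifying, failing)

  # unit coordinates of the planted SDP columns (linker inserted after the
  # N-lobe shifts C-lobe positions)
  sdp_unit <- ifelse(sdp_cols <= n_len, sdp_cols, sdp_cols + linker_len)
  truth <- list(family = fam_of,
                mda = vapply(split(hits, hits$seq_id), function(h) {
                  a <- resolve_hits(h)
                  u <- build_functional_units(a, n_dom, c_dom, 20L)
                  mda_key(assign_mda(a, u))
                }, character(1))[ids],
                sdp_columns = sdp_unit,
                sdp_consensus_columns = sdp_cols,
                linker_len = linker_len,
                n_len = n_len,
                targets = targets,
                unannotated = unannotated)
  structure(list(sequences = seqs, domain_hits = hits,
                 annotations = annotations, drug_records = drug_records,
                 truth = truth, config = cfg),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Synthetic superfamily: ", length(x$sequences), " sequences, ",
      x$config$n_families, " families, ",
      length(unique(x$truth$mda)), " MDAs, ",
      length(x$truth$sdp_columns), " SDP columns\n", sep = "")
  invisible(x)
}

#' Write a fixture bundle to plain-text files
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$sequences, file.path(dir, "sequences.fasta"))
  write_domain_hits(bundle$domain_hits, file.path(dir, "hits.tsv"))
  write.table(bundle$annotations, file.path(dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$drug_records, file.path(dir, "drugs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(family_id = unname(bundle$truth$family),
                      seq_id = names(bundle$truth$family),
                      mda = unname(bundle$truth$mda[names(bundle$truth$family)]))
  write.table(truth, file.path(dir, "truth_families.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(unit_column = bundle$truth$sdp_columns),
              file.path(dir, "truth_sdp_columns.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' High-diversity alignment fixture
#'
#' Generates an ungapped alignment whose per-column mutation rates are
#' drawn continuously (uniform on `[0, max_rate]`), giving nearly every
#' column a distinct conservation value. Used to exercise the high end of
#' the DOPs scale; the planted-family generator, by contrast, produces
#' low-diversity (within-family conserved) alignments.
#'
#' @param n_seqs,ncols alignment dimensions.
#' @param max_rate upper bound of the per-column mutation rate.
#' @param seed RNG seed.
#' @return named character vector of aligned rows.
#' @export
simulate_diverse_alignment <- function(n_seqs = 30L, ncols = 200L,
                                       max_rate = 0.6, seed = 1L) {
  aa <- aa_alphabet()
  with_seed(seed, {
    cons <- sample(aa, ncols, replace = TRUE, prob = aa_background())
    m <- matrix(rep(cons, each = n_seqs), nrow = n_seqs)
    for (j in seq_len(ncols)) {
      r <- runif(1, 0, max_rate)
      mut <- runif(n_seqs) < r
      if (any(mut))
        m[mut, j] <- sample(setdiff(aa, cons[j]), sum(mut), replace = TRUE)
    }
    rownames(m) <- sprintf("div%03d", seq_len(n_seqs))
    matrix_aln(m)
  })
}

#' Length-matched shuffled decoy sequences
#'
#' Draws sequences i.i.d. from the empirical residue frequencies of a
#' bundle (or sequence set), with lengths resampled from the source
#' lengths. Used to test E-value calibration tails.
#'
#' @param x a `fixture_bundle` or named character vector of sequences.
#' @param n number of decoys (>= 1).
#' @param seed RNG seed.
#' @return named character vector of decoy sequences.
#' @export
shuffle_decoys <- function(x, n, seed = 1L) {
  if (inherits(x, "fixture_bundle")) x <- x$sequences
  stopifnot(n >= 1L, length(x) > 0L)
  res <- unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
  res <- res[res %in% aa_alphabet()]
  freq <- table(factor(res, levels = aa_alphabet()))
  freq <- as.numeric(freq) / sum(freq)
  lens <- nchar(x)
  with_seed(seed, {
    out <- vapply(seq_len(n), function(k)
      paste(sample(aa_alphabet(), sample(lens, 1L), replace = TRUE,
                   prob = freq), collapse = ""), character(1))
    setNames(out, sprintf("decoy%04d", seq_len(n)))
  })
}
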