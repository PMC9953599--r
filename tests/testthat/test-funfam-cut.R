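test_that("similarity kernel matches hand-derived values", {
  expect_equal(aa_similarity("E", "E"), 1)
  expect_equal(aa_similarity("E", "A"), 1 / 3)
  expect_equal(aa_similarity("W", "G"), 2 / 15)
  expect_true(all(aa_similarity(aa_alphabet(), aa_alphabet()) == 1))
  expect_true(is.na(aa_similarity("X", "A")))
})

test_that("column scores quantify differential conservation", {
  s <- group_column_scores(rep("E", 4), rep("A", 4))
  expect_equal(s$cons_a, 1)
  expect_equal(s$cons_b, 1)
  expect_equal(s$between, 1 / 3)
  expect_equal(s$groupsim, 2 / 3)
  expect_true(s$is_sdp)

  # identical conserved columns cannot be specificity-determining
  s2 <- group_column_scores(rep("K", 3), rep("K", 3))
  expect_equal(s2$groupsim, 0)
  expect_false(s2$is_sdp)

  # unconserved group blocks the SDP flag regardless of groupsim
  s3 <- group_column_scores(rep("E", 4), c("A", "D", "K", "W"))
  expect_lt(s3$cons_b, 0.8)
  expect_false(s3$is_sdp)
  # brute-force mean over the 6 unordered B pairs
  pairs <- combn(c("A", "D", "K", "W"), 2)
  expect_equal(s3$cons_b, mean(aa_similarity(pairs[1, ], pairs[2, ])))

  expect_error(group_column_scores("E", rep("A", 3)), "too small")
})

test_that("gap-dominated columns are never SDPs", {
  s <- group_column_scores(c("E", "E", "-", "-", "-", "-"), rep("A", 6))
  expect_gt(s$gapfrac_a, 0.5)
  expect_false(s$is_sdp)
  # X behaves like a gap
  s2 <- group_column_scores(c("E", "E", "X", "X", "X", "X"), rep("A", 6))
  expect_false(s2$is_sdp)
})

test_that("detect_sdps recovers exactly the planted columns", {
  set.seed(301)
  fx <- planted_sdp_alignment(noise = 0.03)
  sd <- detect_sdps(fx$a, fx$b)
  expect_setequal(sd$position[sd$is_sdp], fx$sdp_at)
  # ranked by groupsim: planted columns come first
  expect_setequal(sd$position[seq_along(fx$sdp_at)], fx$sdp_at)

  # identical alignments: no SDPs
  sd2 <- detect_sdps(fx$a, fx$a)
  expect_equal(sum(sd2$is_sdp), 0L)

  expect_error(detect_sdps(fx$a, substr(fx$b, 1, 10)), "column counts")
})

test_that("catalytic-motif columns rank among the top SDPs", {
  # JAK-like encoding: catalytic group carries H-R-D and D-F-G, the
  # pseudokinase group G-N at the RD columns and D-P-G at the DFG motif
  set.seed(302)
  cons <- strsplit(random_aa_seq(50), "")[[1]]
  mk <- function(motif, at, prefix) {
    rows <- vapply(1:6, function(k) {
      x <- cons; x[at] <- motif
      mut <- sample(setdiff(seq_along(x), at), 2)
      x[mut] <- vapply(x[mut], function(c)
        sample(setdiff(aa_alphabet(), c), 1), character(1))
      paste(x, collapse = "")
    }, character(1))
    setNames(rows, paste0(prefix, 1:6))
  }
  at <- c(10, 11, 12, 30, 31, 32)
  cat_grp <- mk(c("H", "R", "D", "D", "F", "G"), at, "cat")
  psi_grp <- mk(c("H", "G", "N", "D", "P", "G"), at, "psi")
  sd <- detect_sdps(cat_grp, psi_grp)
  # the substituted motif columns (R->G, D->N, F->P) lead the ranking
  expect_true(all(c(11, 12, 31) %in% sd$position[1:4]))
  expect_true(all(sd$is_sdp[sd$position %in% c(11, 12, 31)]))
})

test_that("cut decisions respect size, information and SDP-count gates", {
  b <- generate_superfamily(small_fixture(seed = 9L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  fam <- b$truth$family
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  mk <- function(id, members) kinfamr:::new_seq_cluster(
    id, members, star_align(units[members]), annotated = TRUE)
  f1 <- names(units)[fam[res$units$seq_id] == "fam1"]
  f2 <- names(units)[fam[res$units$seq_id] == "fam2"]
  tree <- build_merge_tree(list(mk("A", f1), mk("B", f2)))
  expect_true(decide_cut(tree))

  # singleton child: cannot establish differential conservation
  tree2 <- build_merge_tree(list(mk("A", f1), mk("B", f2[1])))
  expect_false(decide_cut(tree2))

  # identical children: nothing to cut
  tree3 <- build_merge_tree(list(mk("A", f1[1:4]), mk("B", f1[5:8])))
  expect_false(decide_cut(tree3))

  expect_error(decide_cut(build_merge_tree(list(mk("A", f1)))), "internal")
})

test_that("cut_tree partitions leaves and recovers planted families", {
  b <- generate_superfamily(fixture_config(
    n_families = 4L, seqs_per_family = c(8L, 8L), unit_length = 150L,
    mda_layouts = list(c("FU")), seed = 11L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90, annotated_ids = names(units))
  params <- kinfam_params()
  tree <- build_merge_tree(cl, params$pseudocount_weight)
  fams <- cut_tree(tree, params)
  members <- unlist(lapply(fams, `[[`, "members"))
  expect_setequal(members, names(units))
  expect_equal(anyDuplicated(members), 0L)
  pred <- rep(names(fams), vapply(fams, function(f) length(f$members),
                                  integer(1)))
  names(pred) <- members
  truth <- b$truth$family[res$units$seq_id[match(members,
                                                 res$units$unit_id)]]
  expect_gte(mclust::adjustedRandIndex(pred, truth), 0.99)
})

test_that("a tree with no qualifying node collapses to one family", {
  b <- generate_superfamily(small_fixture(seed = 12L, n_families = 1L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90, annotated_ids = names(units))
  fams <- cut_tree(build_merge_tree(cl), kinfam_params())
  expect_length(fams, 1L)
})

test_that("families differing below k_min SDP columns merge", {
  set.seed(303)
  fx <- planted_sdp_alignment(n_per_group = 8L, ncols = 60L,
                              sdp_at = 17L, noise = 0.03)
  mk <- function(id, aln) kinfamr:::new_seq_cluster(id, names(aln), aln,
                                                    annotated = TRUE)
  tree <- build_merge_tree(list(mk("A", fx$a), mk("B", fx$b)))
  expect_length(cut_tree(tree, kinfam_params()), 1L)
  # with k_min = 1 the same tree splits
  expect_length(cut_tree(tree, kinfam_params(k_min = 1L)), 2L)
})

test_that("raising k_min or tau_gs never increases the family count", {
  b <- generate_superfamily(fixture_config(
    n_families = 3L, seqs_per_family = c(8L, 8L), unit_length = 150L,
    mda_layouts = list(c("FU")), seed = 13L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90, annotated_ids = names(units))
  tree <- build_merge_tree(cl, 0)
  for (tau in c(0.2, 0.4, 0.6)) {
    n_prev <- Inf
    for (k in c(1L, 2L, 4L, 8L)) {
      n <- length(cut_tree(tree, kinfam_params(k_min = k, tau_gs = tau)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
  for (k in c(1L, 2L, 4L)) {
    n_prev <- Inf
    for (tau in c(0.1, 0.3, 0.5, 0.7)) {
      n <- length(cut_tree(tree, kinfam_params(k_min = k, tau_gs = tau)))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("the pipeline driver classifies a single family into one FunFam", {
  b <- generate_superfamily(small_fixture(seed = 14L, n_families = 1L))
  cl <- classify_superfamily(b$sequences, b$domain_hits, b$annotations)
  expect_length(cl$funfams, 1L)
  expect_s3_class(cl, "kinfam_classification")
  expect_output(print(cl), "FunFams")
})

test_that("MDA pooling rejoins a family split across architectures", {
  # one family, two architectures: halves share all conserved columns, so
  # the final pooled iteration must merge them into a single FunFam
  b <- generate_superfamily(fixture_config(
    n_families = 1L, seqs_per_family = c(16L, 16L), unit_length = 150L,
    mda_layouts = list(c("FU")), seed = 15L))
  hits <- b$domain_hits
  # move half the sequences into a second architecture by appending an
  # accessory domain hit beyond the unit
  ids <- names(b$sequences)
  half <- ids[seq(1L, length(ids), by = 2L)]
  seqs <- b$sequences
  extra <- list()
  for (id in half) {
    L <- nchar(seqs[[id]])
    seqs[id] <- paste0(seqs[[id]], paste(rep("G", 40L), collapse = ""))
    extra[[id]] <- data.frame(seq_id = id, family_id = "ACC1",
                              start = L + 1L, stop = L + 40L, score = 80)
  }
  hits <- rbind(hits, do.call(rbind, extra))
  cl <- classify_superfamily(seqs, hits, b$annotations)
  expect_equal(length(unique(cl$assignments$mda_key)), 2L)
  expect_length(cl$funfams, 1L)
})

test_that("unannotated clusters are assigned to their nearest family", {
  b <- generate_superfamily(small_fixture(seed = 16L))
  cl <- classify_superfamily(b$sequences, b$domain_hits, b$annotations)
  if (nrow(cl$unassigned)) {
    held <- cl$held_aside
    names(held) <- vapply(held, `[[`, character(1), "id")
    fam <- b$truth$family
    for (i in seq_len(nrow(cl$unassigned))) {
      cluster <- held[[cl$unassigned$cluster_id[i]]]
      member_fams <- unique(fam[sub("_u.*", "", cluster$members)])
      ff <- cl$funfams[[cl$unassigned$funfam_id[i]]]
      ff_fams <- unique(fam[sub("_u.*", "", ff$members)])
      expect_true(any(member_fams %in% ff_fams))
    }
  }
  expect_equal(nrow(assign_unannotated(list(), cl$funfams)), 0L)
})
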