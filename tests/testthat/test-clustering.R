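test_that("pairwise identity matches hand-checked cases", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  # shorter-sequence denominator: 4 matches / min(4, 8)
  expect_equal(pairwise_identity("AAAA", "AAAAAAAA"), 1.0)
  expect_error(pairwise_identity("", "ACD"), "empty")
})

test_that("pairwise identity is symmetric on random sequences", {
  set.seed(201)
  for (rep in 1:10) {
    a <- random_aa_seq(60); b <- random_aa_seq(75)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-12)
  }
})

test_that("greedy clustering groups identical sequences and splits distant ones", {
  ident <- setNames(rep(random_aa_seq(80), 5), paste0("s", 1:5))
  cl <- greedy_cluster(ident)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, names(ident))

  set.seed(202)
  g1 <- random_aa_seq(100)
  g2 <- random_aa_seq(100)
  expect_lt(pairwise_identity(g1, g2), 0.5)
  seqs <- c(a1 = g1, a2 = g1, b1 = g2, b2 = g2)
  cl2 <- greedy_cluster(seqs)
  expect_length(cl2, 2L)

  expect_error(greedy_cluster(seqs, threshold = 0), "threshold")
})

test_that("greedy clustering output is a partition with representative identity above threshold", {
  b <- generate_superfamily(small_fixture(seed = 3L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90)
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, names(units))
  expect_equal(anyDuplicated(all_members), 0L)
  for (c in cl) {
    for (m in c$members)
      expect_gte(pairwise_identity(units[[m]], units[[c$representative]]),
                 0.90)
    # de-gapped alignment rows reproduce the member sequences
    expect_equal(kinfamr:::degap(c$alignment[c$members]),
                 setNames(units[c$members], c$members))
  }
})

test_that("profiles are normalised probability tables", {
  # single sequence without pseudocounts: delta columns
  p0 <- build_profile(c(s = "ACDE"), pseudocount_weight = 0)
  expect_equal(unname(p0$mat[1, "A"]), 1)
  expect_equal(unname(p0$mat[3, "D"]), 1)
  expect_true(all(abs(rowSums(p0$mat) - 1) < 1e-9))

  # hand computation: column of four A, pseudocount mass 1
  p1 <- build_profile(setNames(rep("A", 4), paste0("s", 1:4)), 1.0)
  expect_equal(unname(p1$mat[1, "A"]), (4 + 0.074) / 5, tolerance = 1e-12)

  # all-gap column falls back to the background
  p2 <- build_profile(c(a = "A-C", b = "A-C"), 1.0)
  expect_equal(unname(p2$mat[2, ]), unname(aa_background()))
  expect_true(all(abs(rowSums(p2$mat) - 1) < 1e-9))
  expect_true(all(p2$mat > 0))
})

test_that("position-based weights follow the Henikoff scheme", {
  # one column AABC: A gets 1/(3*2), B and C get 1/3 each, rescaled to n
  w <- position_weights(c(s1 = "A", s2 = "A", s3 = "R", s4 = "C"))
  expect_equal(unname(w), c(1 / 6, 1 / 6, 1 / 3, 1 / 3) * 4)
  # uniform alignment: everyone weight 1
  expect_equal(unname(position_weights(c(a = "KK", b = "KK"))), c(1, 1))
})

test_that("profile-profile scores are symmetric and discriminative", {
  set.seed(203)
  mk <- function(s) build_profile(setNames(s, "x"), 0.1)
  for (rep in 1:100) {
    p <- mk(random_aa_seq(40))
    q <- mk(random_aa_seq(40))
    spq <- score_profiles(p, q)
    expect_equal(spq, score_profiles(q, p), tolerance = 1e-9)
    expect_gte(score_profiles(p, p), spq)
  }
})

test_that("single-sequence profile alignment equals a plain sequence DP", {
  set.seed(204)
  for (rep in 1:10) {
    a <- random_aa_seq(30); b <- random_aa_seq(35)
    p <- build_profile(setNames(a, "a"), 0)
    q <- build_profile(setNames(b, "b"), 0)
    got <- score_profiles(p, q) * min(nchar(a), nchar(b))
    exp <- oracle_affine_score(b62_score_matrix(a, b), -10, -1)
    expect_equal(got, exp, tolerance = 1e-6)
  }
})

test_that("merge tree has n-1 internal nodes and recovers planted topology", {
  b <- generate_superfamily(small_fixture(seed = 5L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  fam <- b$truth$family
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  # three leaf clusters: A, B from family 1; C from family 2
  f1 <- names(units)[fam[res$units$seq_id] == "fam1"]
  f2 <- names(units)[fam[res$units$seq_id] == "fam2"]
  mk <- function(id, members) {
    aln <- star_align(units[members])
    kinfamr:::new_seq_cluster(id, members, aln, annotated = TRUE)
  }
  A <- mk("A", f1[1:4]); B <- mk("B", f1[5:8]); C <- mk("C", f2[1:4])
  tree <- build_merge_tree(list(A, B, C))
  expect_equal(n_leaves(tree), 3L)
  # first merge joins the two same-family clusters
  first <- if (tree$left$leaf) tree$right else tree$left
  expect_setequal(first$members, c(A$members, B$members))

  expect_error(build_merge_tree(list()), "no clusters")
  single <- build_merge_tree(list(A))
  expect_true(single$leaf)
})

test_that("merge tree is invariant to input cluster order", {
  b <- generate_superfamily(small_fixture(seed = 6L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90)
  t1 <- build_merge_tree(cl)
  t2 <- build_merge_tree(rev(cl))
  expect_equal(write_merge_tree(t1), write_merge_tree(t2))
})

test_that("merged alignments de-gap back to the original sequences", {
  b <- generate_superfamily(small_fixture(seed = 7L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90)
  tree <- build_merge_tree(cl)
  aln <- tree$alignment
  expect_length(unique(nchar(aln)), 1L)
  expect_equal(sort(names(aln)), sort(names(units)))
  expect_equal(kinfamr:::degap(aln)[names(units)], units)
})

test_that("newick export is parseable and labels internal nodes", {
  b <- generate_superfamily(small_fixture(seed = 8L))
  res <- resolve_dataset(b$sequences, b$domain_hits,
                         "3.30.200.20", "1.10.510.10")
  units <- setNames(res$units$unit_seq, res$units$unit_id)
  cl <- greedy_cluster(units, 0.90)
  tree <- build_merge_tree(cl)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_merge_tree(tree, f)
  ph <- ape::read.tree(f)
  expect_equal(length(ph$tip.label), length(cl))
  expect_true(all(grepl(":", ph$node.label)))
})
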