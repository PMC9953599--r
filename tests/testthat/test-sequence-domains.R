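test_that("resolve_hits handles empty and single-hit inputs", {
  empty <- resolve_hits(data.frame(seq_id = character(),
                                   family_id = character(),
                                   start = integer(), stop = integer(),
                                   score = numeric()))
  expect_equal(nrow(empty$hits), 0L)
  expect_equal(empty$total_score, 0)

  one <- resolve_hits(data.frame(seq_id = "s", family_id = "A",
                                 start = 1L, stop = 100L, score = 10))
  expect_equal(one$hits$family_id, "A")
  expect_equal(one$total_score, 10)
})

test_that("resolve_hits picks the maximum-score non-overlapping subset", {
  h <- data.frame(seq_id = "s", family_id = c("A", "B", "C"),
                  start = c(1L, 50L, 120L), stop = c(100L, 150L, 200L),
                  score = c(10, 12, 5))
  r <- resolve_hits(h)
  expect_equal(r$hits$family_id, c("A", "C"))
  expect_equal(r$total_score, 15)
  expect_identical(r$hits, oracle_resolve(h))
})

test_that("resolve_hits rejects mixed sequences and bad coordinates", {
  expect_error(resolve_hits(data.frame(seq_id = c("a", "b"),
                                       family_id = "A", start = 1L,
                                       stop = 5L, score = 1)),
               "single sequence")
  expect_error(resolve_hits(data.frame(seq_id = "a", family_id = "A",
                                       start = 10L, stop = 5L, score = 1)),
               "coordinates")
  expect_error(resolve_hits(data.frame(seq_id = "a", family_id = "A",
                                       start = 1L, stop = 5L, score = -1)),
               "negative")
})

test_that("resolve_hits matches exhaustive enumeration on random instances", {
  set.seed(101)
  for (rep in 1:150) {
    h <- random_hit_instance(sample(0:8, 1L))
    got <- resolve_hits(h)
    exp <- oracle_resolve(h)
    expect_equal(got$hits$start, exp$start)
    expect_equal(got$hits$family_id, exp$family_id)
    expect_equal(got$total_score, sum(exp$score))
  }
})

test_that("resolve_hits is invariant to input hit order", {
  set.seed(102)
  for (rep in 1:25) {
    h <- random_hit_instance(7L)
    a <- resolve_hits(h)
    b <- resolve_hits(h[sample.int(nrow(h)), , drop = FALSE])
    expect_identical(a$hits, b$hits)
  }
})

test_that("functional units pair lobes across a bounded linker", {
  arch <- resolve_hits(data.frame(
    seq_id = "s", family_id = c("N", "C"),
    start = c(10L, 100L), stop = c(90L, 250L), score = c(50, 80)))
  u <- build_functional_units(arch, "N", "C")
  expect_equal(nrow(u), 1L)
  expect_equal(u$n_start, 10L)
  expect_equal(u$c_stop, 250L)
  expect_equal(u$linker_len, 9L)

  # gap of 29 exceeds the 20-residue linker bound: no unit
  arch2 <- resolve_hits(data.frame(
    seq_id = "s", family_id = c("N", "C"),
    start = c(10L, 120L), stop = c(90L, 250L), score = c(50, 80)))
  expect_equal(nrow(build_functional_units(arch2, "N", "C")), 0L)

  # exactly at the bound: allowed
  arch3 <- resolve_hits(data.frame(
    seq_id = "s", family_id = c("N", "C"),
    start = c(10L, 111L), stop = c(90L, 250L), score = c(50, 80)))
  expect_equal(build_functional_units(arch3, "N", "C")$linker_len, 20L)
})

test_that("tandem kinases yield two units in sequence order", {
  arch <- resolve_hits(data.frame(
    seq_id = "jak", family_id = c("N", "C", "N", "C"),
    start = c(583L, 700L, 875L, 1000L),
    stop = c(690L, 855L, 990L, 1153L),
    score = c(50, 80, 50, 80)))
  u <- build_functional_units(arch, "N", "C")
  expect_equal(nrow(u), 2L)
  expect_true(all(diff(u$n_start) > 0))
  expect_equal(u$unit_id, c("jak_u1", "jak_u2"))
})

test_that("unit count never exceeds the smaller lobe count", {
  set.seed(103)
  for (rep in 1:30) {
    h <- random_hit_instance(sample(2:8, 1L))
    h$family_id <- sample(c("N", "C"), nrow(h), replace = TRUE)
    arch <- resolve_hits(h)
    u <- build_functional_units(arch, "N", "C")
    nn <- sum(arch$hits$family_id == "N")
    nc <- sum(arch$hits$family_id == "C")
    expect_lte(nrow(u), min(nn, nc))
    if (nrow(u)) expect_true(all(u$linker_len <= 20L))
  }
})

test_that("MDA tokens collapse paired lobes and preserve order", {
  mk_arch <- function(fams, starts, stops)
    resolve_hits(data.frame(seq_id = "s", family_id = fams, start = starts,
                            stop = stops, score = 10))
  a1 <- mk_arch(c("3.30.200.20", "1.10.510.10"), c(1L, 120L),
                c(100L, 300L))
  u1 <- build_functional_units(a1, "3.30.200.20", "1.10.510.10")
  expect_equal(assign_mda(a1, u1), "FU:3.30.200.20-1.10.510.10")

  a2 <- mk_arch(c("X", "3.30.200.20", "1.10.510.10"),
                c(1L, 210L, 330L), c(200L, 320L, 500L))
  u2 <- build_functional_units(a2, "3.30.200.20", "1.10.510.10")
  expect_equal(assign_mda(a2, u2),
               c("X", "FU:3.30.200.20-1.10.510.10"))

  # two units with an accessory between them
  a3 <- mk_arch(c("N", "C", "X", "N", "C"),
                c(1L, 110L, 320L, 530L, 650L),
                c(100L, 300L, 500L, 640L, 800L))
  u3 <- build_functional_units(a3, "N", "C")
  expect_equal(assign_mda(a3, u3), c("FU:N-C", "X", "FU:N-C"))

  # unpaired lobes keep their own family token
  a4 <- mk_arch("3.30.200.20", 1L, 100L)
  expect_equal(assign_mda(a4, build_functional_units(
    a4, "3.30.200.20", "1.10.510.10")), "3.30.200.20")

  expect_error(assign_mda(resolve_hits(NULL), NULL), "no domains")
})

test_that("domain-hit tables round-trip through files", {
  h <- data.frame(seq_id = c("a", "a", "b"), family_id = c("N", "C", "N"),
                  start = c(1L, 120L, 5L), stop = c(100L, 300L, 90L),
                  score = c(10.5, 20, 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_domain_hits(h, f)
  expect_equal(read_domain_hits(f), h)
})
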