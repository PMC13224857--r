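test_that("assign_by_score picks the higher score, ties unassigned", {
  expect_equal(assign_by_score(60, 55), "129")
  expect_equal(assign_by_score(55, 60), "CAST")
  expect_equal(assign_by_score(50, 50), "unassigned")
  # partition property
  set.seed(8)
  a <- sample(0:80, 500, replace = TRUE)
  b <- sample(0:80, 500, replace = TRUE)
  asg <- assign_by_score(a, b)
  expect_equal(sum(asg == "129") + sum(asg == "CAST") +
                 sum(asg == "unassigned"), 500L)
})

test_that("allelic_proportion normalizes by size factors", {
  expect_equal(allelic_proportion(84, 16), 0.84)
  expect_equal(allelic_proportion(7, 7), 0.5)
  expect_equal(allelic_proportion(30, 10, size_factors = c(2, 1)), 0.6)
  # complement symmetry under equal size factors
  set.seed(1)
  n <- sample(1:100, 20); m <- sample(1:100, 20)
  expect_equal(allelic_proportion(n, m) + allelic_proportion(m, n),
               rep(1, 20))
  expect_error(allelic_proportion(0, 0), "zero denominator")
})

test_that("unassigned_size_factors have geometric mean one", {
  sf <- unassigned_size_factors(c(1000, 2000, 4000))
  expect_equal(exp(mean(log(sf))), 1)
  expect_equal(sf[2] / sf[1], 2)
})

test_that("imbalance_test is symmetric and exact on balanced tables", {
  tb <- data.frame(condition = rep(c("A", "B"), each = 3),
                   replicate = rep(1:3, 2),
                   n_129 = rep(50L, 6), n_CAST = rep(50L, 6))
  res <- imbalance_test(tb)
  expect_equal(res$estimate, 0)
  expect_lt(abs(res$p.value - 1), 1e-6)

  # swapping allele labels negates the estimate, p unchanged
  tb2 <- simulate_allelic_counts(features = "f", seed = 77)
  r1 <- imbalance_test(tb2)
  tb2_sw <- tb2
  tb2_sw$n_129 <- tb2$n_CAST; tb2_sw$n_CAST <- tb2$n_129
  r2 <- imbalance_test(tb2_sw)
  expect_equal(r1$estimate, -r2$estimate, tolerance = 1e-8)
  expect_equal(r1$p.value, r2$p.value, tolerance = 1e-8)
})

test_that("imbalance_test rejects degenerate designs", {
  tb <- data.frame(condition = rep(c("A", "B", "C"), each = 2),
                   replicate = rep(1:2, 3), n_129 = 1L, n_CAST = 1L)
  expect_error(imbalance_test(tb), "exactly 2 conditions")
  tb2 <- data.frame(condition = rep(c("A", "B"), each = 2),
                    replicate = rep(1:2, 2),
                    n_129 = c(5L, 6L, 0L, 0L), n_CAST = c(4L, 5L, 0L, 0L))
  expect_error(imbalance_test(tb2), "all-zero")
  tb3 <- data.frame(condition = c("A", "B"), replicate = c(1L, 1L),
                    n_129 = c(5L, 6L), n_CAST = c(4L, 5L))
  expect_error(imbalance_test(tb3), "2 replicates")
})

test_that("imbalance_test detects a strong planted ratio shift", {
  set.seed(21)
  p <- replicate(40, {
    ratio <- matrix(c(0.5, 0.8), 1, 2,
                    dimnames = list("f", c("c1", "c2")))
    tb <- simulate_allelic_counts(features = "f",
                                  conditions = c("c1", "c2"),
                                  ratio = ratio,
                                  seed = sample.int(2^31 - 1, 1))
    imbalance_test(tb)$p.value
  })
  expect_gt(mean(p < 0.05), 0.8)
})

test_that("score-based assignment is near-perfect at realistic settings", {
  loc <- shared_locus()
  set.seed(13)
  n <- 2000L; len <- 75L
  starts <- sample.int(loc$config$length - len, n) - 1L
  allele <- sample(c("129", "CAST"), n, TRUE)
  hap <- c("129" = loc$hap129$seq, "CAST" = loc$hapCAST$seq)
  reads <- alleloop:::.add_seq_errors(
    substr(hap[allele], starts + 1L, starts + len), 0.001)
  sc <- dual_alignment_scores(reads, starts, loc$hap129, loc$hapCAST)
  asg <- assign_by_score(sc$score_129, sc$score_CAST)
  ov <- vapply(seq_len(n), function(i)
    any(loc$snvs$pos >= starts[i] & loc$snvs$pos < starts[i] + len),
    logical(1))
  # reads with no SNV under them must be unassigned (equal scores)
  expect_true(all(asg[!ov] == "unassigned" |
                    reads[!ov] != substr(hap[allele[!ov]], starts[!ov] + 1L,
                                         starts[!ov] + len)))
  expect_gt(mean(asg[ov] == allele[ov]), 0.99)
})

test_that("methylation_fractions tallies C/(C+T) per CpG and allele", {
  # amplicon layout: CpG cytosines at 2 and 8; SNVs at 5 (A/G) and 11 (C/T)
  snps <- data.frame(pos = c(5L, 11L), base129 = c("A", "C"),
                     baseCAST = c("G", "T"))
  r129 <- function(c1, c2) paste0("GG", c1, "TTATT", c2, "AACAA")
  rCAST <- function(c1, c2) paste0("GG", c1, "TTGTT", c2, "AATAA")
  reads <- data.frame(
    start = 0L,
    seq = c(r129("C", "C"), r129("C", "T"), r129("T", "C"),
            rCAST("T", "T"), rCAST("C", "T")))
  mc <- methylation_fractions(reads, cpg_positions = c(2L, 8L), snps)
  g <- function(p, a) mc$fraction[mc$pos == p & mc$allele == a]
  expect_equal(g(2L, "129"), 2 / 3)
  expect_equal(g(8L, "129"), 2 / 3)
  expect_equal(g(2L, "CAST"), 1 / 2)
  expect_equal(g(8L, "CAST"), 0)
  expect_equal(attr(mc, "n_unassigned_reads"), 0L)
})

test_that("methylation allele votes: ties and uninformative reads excluded", {
  snps <- data.frame(pos = c(1L, 3L), base129 = c("A", "A"),
                     baseCAST = c("G", "G"))
  reads <- data.frame(start = 0L,
                      seq = c("CACAC",   # both votes 129
                              "CGCGC",   # both votes CAST
                              "CACGC",   # tie -> excluded
                              "CTCTC"))  # no informative SNV -> excluded
  mc <- methylation_fractions(reads, cpg_positions = 0L, snps)
  expect_equal(attr(mc, "n_unassigned_reads"), 2L)
  expect_equal(sum(mc$n_C + mc$n_T), 2L)
})
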