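test_that("generators are pure functions of their seed", {
  cfg <- locus_config(length = 20000L, min_valid_fragments = 30L)
  l1 <- make_diploid_locus(cfg, seed = 4)
  l2 <- make_diploid_locus(cfg, seed = 4)
  expect_identical(l1$hap129$seq, l2$hap129$seq)
  expect_identical(l1$hapCAST$seq, l2$hapCAST$seq)
  expect_identical(l1$snvs, l2$snvs)
  expect_false(identical(make_diploid_locus(cfg, seed = 5)$hap129$seq,
                         l1$hap129$seq))

  t1 <- simulate_allelic_counts(seed = 8)
  t2 <- simulate_allelic_counts(seed = 8)
  expect_identical(t1, t2)
  expect_identical(simulate_qpcr(seed = 8), simulate_qpcr(seed = 8))

  f1 <- simulate_smfish_stack(n_cells = 1L, dim = c(5L, 56L, 56L),
                              n_cyto = 3L, seed = 8)
  f2 <- simulate_smfish_stack(n_cells = 1L, dim = c(5L, 56L, 56L),
                              n_cyto = 3L, seed = 8)
  expect_identical(f1$fish, f2$fish)

  # generators restore the caller's RNG stream
  set.seed(99); before <- .Random.seed
  invisible(simulate_allelic_counts(seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("SNV placement follows the configured Poisson density", {
  loc <- make_diploid_locus(locus_config(length = 135000L,
                                         snv_spacing = 135), seed = 17)
  n <- nrow(loc$snvs)
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  # every SNV differs between haplotypes and matches the table
  c129 <- substring(loc$hap129$seq, loc$snvs$pos + 1L, loc$snvs$pos + 1L)
  cCAST <- substring(loc$hapCAST$seq, loc$snvs$pos + 1L, loc$snvs$pos + 1L)
  expect_identical(c129, loc$snvs$base129)
  expect_identical(cCAST, loc$snvs$baseCAST)
  expect_true(all(c129 != cCAST))
  # outside SNVs the haplotypes agree (fragment maps shared by construction)
  expect_equal(sum(charToRaw(loc$hap129$seq) != charToRaw(loc$hapCAST$seq)),
               nrow(loc$snvs))
})

test_that("locus constraints are enforced", {
  expect_error(locus_config(length = 1000L), ">= 5 kb")
  expect_error(make_diploid_locus(locus_config(length = 5000L,
                                               min_valid_fragments = 1000L),
                                  seed = 1), "unsatisfiable")
})

test_that("contact probabilities normalize and concentrate per the model", {
  loc <- shared_locus()
  pr <- contact_probabilities(loc, contact_model())
  expect_equal(sum(pr$p_129), 1)
  expect_equal(sum(pr$p_CAST), 1)
  vp <- loc$viewpoint$viewpoint_fragment
  expect_equal(pr$p_129[vp + 1L], 0)  # viewpoint not capturable
  # 4-fold loop on 129 inside the target region
  fr <- loc$fmap$fragments
  mid <- (fr$start + fr$end) / 2
  int <- mid >= loc$target$start & mid < loc$target$end
  ratio <- sum(pr$p_129[int]) / sum(pr$p_CAST[int])
  expect_gt(ratio, 1)
})

test_that("the empirical decay slope recovers the exponent", {
  loc <- shared_locus()
  model <- contact_model(lambda_129 = 1, lambda_CAST = 1,
                         n_reads = 1000000L, error_rate = 0)
  lib <- simulate_4c_library(loc, model, seed = 55)
  fr <- loc$fmap$fragments
  cnt <- tabulate(lib$truth$fragment + 1L, nbins = nrow(fr))
  mid <- (fr$start + fr$end) / 2
  vp_mid <- mid[loc$viewpoint$viewpoint_fragment + 1L]
  d <- abs(mid - vp_mid)
  sel <- fr$valid & d > 500 & cnt > 20
  fit <- lm(log(cnt[sel]) ~ log(d[sel]), weights = cnt[sel])
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.1)
})

test_that("an empty 4C library is empty but well-formed", {
  loc <- shared_locus()
  lib <- simulate_4c_library(loc, contact_model(n_reads = 0L), seed = 1)
  expect_length(lib$read1, 0)
  expect_equal(nrow(lib$truth), 0L)
  expect_equal(sum(lib$prob$p_129), 1)
})

test_that("simulated 4C reads demultiplex and place at the true fragment", {
  loc <- shared_locus()
  lib <- simulate_4c_library(loc, contact_model(n_reads = 2000L,
                                                error_rate = 0), seed = 5)
  dm <- demux_reads(lib$read1, lib$read2, list(loc$viewpoint),
                    loc$config$enzymes)
  expect_equal(attr(dm, "qc")[["matched"]], 2000L)
  # allele split agrees with the simulation truth (no sequencing errors)
  expect_identical(dm$allele, lib$truth$allele)
  aln <- naive_align(dm$trimmed_seq, loc)
  placed <- fragment_of(loc$fmap, aln$start[aln$is_unique])
  expect_identical(placed, lib$truth$fragment[aln$is_unique])
})

test_that("allelic count tables have the configured moments", {
  tb <- simulate_allelic_counts(features = "f", conditions = "c",
                                replicates = 40L, total = 1e5,
                                dispersion = 0, seed = 12)
  expect_lt(abs(mean(tb$n_129) - 5e4) / 5e4, 0.01)
  expect_lt(abs(mean(tb$n_CAST) - 5e4) / 5e4, 0.01)
  expect_true(all(tb$n_unassigned > 0))
})

test_that("noise-free qPCR tables give exact unit fold changes", {
  ct <- simulate_qpcr(replicate_sd = 0, residual_sd = 0, seed = 3)
  fc <- fold_change_table(delta_ct_table(ct), "untreated")
  expect_equal(fc$fold_change, rep(1, nrow(fc)))
})

test_that("a one-cycle effect halves expression on average", {
  set.seed(14)
  eff <- matrix(c(0, 0, 1, 0), 2, 2,
                dimnames = list(c("gene", "enhancer"),
                                c("untreated", "depleted")))
  fcs <- replicate(40, {
    ct <- simulate_qpcr(effects = eff, seed = sample.int(2^31 - 1, 1))
    fc <- fold_change_table(delta_ct_table(ct), "untreated")
    mean(fc$fold_change[fc$target == "gene" & fc$condition == "depleted"])
  })
  expect_gt(mean(fcs), 0.45)
  expect_lt(mean(fcs), 0.55)
})

test_that("smFISH field generator respects capacity and emptiness", {
  expect_error(simulate_smfish_stack(n_cells = 50L,
                                     dim = c(5L, 64L, 64L), seed = 1),
               "do not fit")
  f <- simulate_smfish_stack(n_cells = 0L, dim = c(5L, 48L, 48L), seed = 1)
  expect_equal(nrow(f$truth$spots), 0L)
  expect_true(all(f$truth$cells == 0L))
  # blank up to noise and the camera offset
  expect_lt(max(abs(f$fish - 100)), 40)
})
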