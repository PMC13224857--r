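vp_fixture <- function(primer = "ACGTACGTACGTACGTGATC", name = "vpA",
                       max_mismatch = 2L)
  viewpoint_spec(name, primer, viewpoint_fragment = 0L,
                 max_mismatch = max_mismatch)

test_that("match_viewpoint applies the anchored mismatch rule", {
  vp <- vp_fixture()
  read <- paste0(vp$primer_seq, "AAAACCCC")
  expect_equal(match_viewpoint(read, list(vp))$status, "matched")

  two_mm <- read
  substr(two_mm, 1, 1) <- "T"; substr(two_mm, 5, 5) <- "T"
  expect_equal(match_viewpoint(two_mm, list(vp))$name, "vpA")

  three_mm <- two_mm
  substr(three_mm, 9, 9) <- "C"  # position 9 is A in the primer
  expect_equal(match_viewpoint(three_mm, list(vp))$status, "none")

  # two qualifying viewpoints: ambiguous
  vp2 <- viewpoint_spec("vpB", substr(vp$primer_seq, 1, 18))
  res <- match_viewpoint(read, list(vp, vp2))
  expect_equal(res$status, "ambiguous")
  expect_true(is.na(res$name))
})

test_that("trim_to_primary_site returns the suffix from the motif", {
  # primer ends in the motif: trimmed read = motif + downstream
  vp <- vp_fixture()
  read <- paste0(vp$primer_seq, "TTTTGGGG")
  tr <- trim_to_primary_site(read, nchar(vp$primer_seq), "GATC")
  expect_equal(tr, "GATCTTTTGGGG")

  # no motif anywhere downstream
  expect_true(is.na(trim_to_primary_site("ACGTACGTACGTACGTAAAAAAA", 20L,
                                         "GATC")))

  # leftmost occurrence wins when the motif appears twice
  read2 <- "AAAAAAAAAAAAAAAAAAAAAAGATCTTGATCCC"
  tr2 <- trim_to_primary_site(read2, 20L, "GATC")
  expect_equal(tr2, "GATCTTGATCCC")
})

test_that("split_allele reads the discriminating base", {
  snv <- list(offset = 3L, base129 = "A", baseCAST = "G")
  expect_equal(split_allele("CCCA", snv), "129")
  expect_equal(split_allele("CCCG", snv), "CAST")
  expect_equal(split_allele("CCCT", snv), "unassigned")
  expect_equal(split_allele("CCCN", snv), "unassigned")
  expect_equal(split_allele("CC", snv), "unassigned")  # offset out of range
  expect_equal(split_allele("CCCA", NULL), "unassigned")
})

test_that("demux conserves reads exactly across QC categories", {
  loc <- shared_locus()
  lib <- shared_library()
  dm <- demux_reads(lib$read1, lib$read2, list(loc$viewpoint),
                    loc$config$enzymes)
  qc <- attr(dm, "qc")
  expect_identical(sum(qc), length(lib$read1))
  expect_identical(qc[["matched"]], nrow(dm))
  expect_gt(qc[["matched"]] / sum(qc), 0.99)
})

test_that("count_fragments follows the exact-boundary rule", {
  loc <- shared_locus()
  fm <- loc$fmap
  fr <- fm$fragments
  # start match counts, interior read does not
  aln <- data.frame(start = c(fr$start[10], fr$start[10] + 20L),
                    end = c(fr$start[10] + 50L, fr$start[10] + 60L),
                    is_paired = TRUE, is_unique = TRUE)
  cnt <- count_fragments(aln, fm)
  expect_equal(cnt[10], 1L)
  expect_equal(sum(cnt), 1L)

  # a read matching both boundaries of one fragment counts once
  aln2 <- data.frame(start = fr$start[5], end = fr$end[5])
  expect_equal(sum(count_fragments(aln2, fm)), 1L)

  # a read matching boundaries of two different fragments is discarded
  aln3 <- data.frame(start = fr$start[5], end = fr$end[6])
  cnt3 <- count_fragments(aln3, fm)
  expect_equal(sum(cnt3), 0L)
  expect_equal(attr(cnt3, "discarded"), 1L)
})

test_that("count_fragments matches the per-read brute force", {
  loc <- shared_locus()
  fm <- loc$fmap
  fr <- fm$fragments
  set.seed(9)
  n <- 1000L
  starts <- ifelse(runif(n) < 0.5,
                   sample(fr$start, n, replace = TRUE),
                   sample.int(fm$seq_length - 100L, n) - 1L)
  ends <- ifelse(runif(n) < 0.3,
                 sample(fr$end, n, replace = TRUE),
                 starts + sample(30:80, n, replace = TRUE))
  keep <- starts < ends
  aln <- data.frame(start = starts[keep], end = ends[keep])
  fast <- count_fragments(aln, fm)
  slow <- brute_count(aln, fm)
  expect_equal(as.integer(fast), as.integer(slow))
  expect_equal(attr(fast, "discarded"), attr(slow, "discarded"))
})

test_that("cpm_normalize scales included fragments to one million", {
  expect_equal(cpm_normalize(c(1, 3)), c(250000, 750000))
  expect_equal(cpm_normalize(5), 1e6)
  set.seed(2)
  raw <- rpois(100, 10)
  mask <- runif(100) < 0.8
  norm <- cpm_normalize(raw, mask)
  expect_equal(sum(norm), 1e6)
  expect_true(all(norm[!mask] == 0))
  expect_error(cpm_normalize(c(0, 0)), "empty library")
})

test_that("rolling_mean implements shrinking-window centered smoothing", {
  expect_equal(rolling_mean(c(0, 0, 21, 0, 0), 3), c(0, 7, 7, 7, 0))
  x <- rnorm(50)
  expect_equal(rolling_mean(x, 1), x)
  expect_equal(rolling_mean(rep(4.2, 30), 21), rep(4.2, 30))
  expect_error(rolling_mean(x, 4), "odd")
  # NA edge policy marks positions without a full window
  r <- rolling_mean(x, 5, edge = "na")
  expect_true(all(is.na(r[c(1, 2, 49, 50)])))
  expect_false(anyNA(r[3:48]))
})

test_that("zero-padding makes the rolling mean total-preserving", {
  set.seed(4)
  for (w in c(3L, 9L, 21L)) {
    x <- rpois(100, 5)
    padded <- c(rep(0, w), x, rep(0, w))
    expect_equal(sum(rolling_mean(padded, w)), sum(x))
  }
})

test_that("quantify_region summarizes fragments by midpoint", {
  tr <- toy_track()
  # exactly one fragment: its value
  q1 <- quantify_region(tr, region("one", 0, 100))
  expect_equal(q1$value, tr$normalized[1])
  # two fragments: their mean; sum behind the flag
  q2 <- quantify_region(tr, region("two", 0, 260))
  expect_equal(q2$value, mean(tr$normalized[1:2]))
  expect_equal(quantify_region(tr, region("two", 0, 260), stat = "sum")$value,
               sum(tr$normalized[1:2]))
  expect_error(quantify_region(tr, region("empty", 101, 120)), "overlaps no")

  # brute-force midpoint filter oracle on random regions
  set.seed(6)
  for (i in 1:50) {
    a <- sort(sample.int(1000, 2))
    reg <- region("r", a[1], a[2])
    mid <- (tr$start + tr$end) / 2
    sel <- mid >= reg$start & mid < reg$end & tr$included
    if (!any(sel)) {
      expect_error(quantify_region(tr, reg))
    } else {
      expect_equal(quantify_region(tr, reg)$value, mean(tr$normalized[sel]))
    }
  }
})

test_that("allele tracks partition the combined track per fragment", {
  loc <- shared_locus()
  lib <- shared_library()
  res <- run_synthetic_4c(lib, loc)
  raw_sum <- Reduce(`+`, lapply(res$tracks[names(res$tracks) != "all"],
                                function(t) t$raw))
  expect_identical(raw_sum, res$tracks$all$raw)
})

test_that("contact_track excludes the viewpoint and its neighbors", {
  loc <- shared_locus()
  lib <- shared_library()
  res <- run_synthetic_4c(lib, loc)
  tr <- res$tracks$all
  vp <- loc$viewpoint$viewpoint_fragment
  expect_false(any(tr$included[vp + 0:2]))  # vp-1, vp, vp+1 (1-based rows)
  expect_equal(sum(tr$normalized), 1e6)
  expect_equal(attr(tr, "window"), 21L)
})
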