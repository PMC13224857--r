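# Independent oracles and shared fixtures. Oracles deliberately avoid the
# code paths they check: naive substring scans, per-read loops, and
# point-in-mask lookups.

# naive motif scan: compare every substring against the motif
naive_scan <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(integer(0))
  i <- seq_len(n - k + 1L)
  which(substring(seq, i, i + k - 1L) == motif) - 1L
}

# naive digest: cut at primary sites, validate per fragment on its own
# substring (a straddling secondary occurrence is absent from the
# substring, matching the definition)
naive_digest <- function(seq, primary, secondary) {
  L <- nchar(seq)
  sites <- naive_scan(seq, primary)
  bounds <- unique(c(0L, sites, L))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  valid <- vapply(seq_along(starts), function(i) {
    frag <- substring(seq, starts[i] + 1L, ends[i])
    length(naive_scan(frag, secondary)) > 0L
  }, logical(1))
  data.frame(start = starts, end = ends, valid = valid)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# per-read brute-force fragment counting
brute_count <- function(alignments, fmap) {
  fr <- fmap$fragments
  counts <- integer(nrow(fr))
  discarded <- 0L
  for (i in seq_len(nrow(alignments))) {
    hit_s <- which(fr$start == alignments$start[i])
    hit_e <- which(fr$end == alignments$end[i])
    hits <- unique(c(hit_s, hit_e))
    if (length(hits) == 1L) counts[hits] <- counts[hits] + 1L
    else if (length(hits) > 1L) discarded <- discarded + 1L
  }
  structure(counts, discarded = discarded)
}

# one shared locus + mid-sized library per test run (generation is seeded,
# so this is reproducible; caching keeps the suite fast)
.fixture_env <- new.env(parent = emptyenv())

shared_locus <- function() {
  if (is.null(.fixture_env$locus))
    .fixture_env$locus <- make_diploid_locus(seed = 101L)
  .fixture_env$locus
}

shared_library <- function() {
  if (is.null(.fixture_env$lib))
    .fixture_env$lib <- simulate_4c_library(
      shared_locus(), contact_model(n_reads = 20000L), seed = 101L)
  .fixture_env$lib
}

# tiny deterministic contact track for region-quantification tests
toy_track <- function(raw = c(5L, 10L, 0L, 20L, 15L),
                      starts = c(0L, 100L, 250L, 400L, 700L),
                      ends = c(100L, 250L, 400L, 700L, 1000L),
                      valid = rep(TRUE, 5)) {
  hap <- haplotype("toy", random_dna(1000))
  fmap <- list(haplotype = "toy", enzymes = enzyme_pair(),
               seq_length = 1000L,
               fragments = data.frame(index = seq_along(raw) - 1L,
                                      start = starts, end = ends,
                                      valid = valid))
  class(fmap) <- "FragmentMap"
  contact_track(raw, fmap, window = 1L)
}
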