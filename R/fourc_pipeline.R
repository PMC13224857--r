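# Viewpoint demultiplexing, junction trimming, allele splitting, fragment
# counting, normalization and smoothing of 4C-seq libraries.

ALLELE_LEVELS <- c("129", "CAST", "unassigned")

#' Define a 4C viewpoint
#'
#' A viewpoint is identified by its reading primer, which ends in (reads
#' into) the primary restriction motif of its anchor fragment. For
#' allele-resolved 4C the mate read covers a discriminating SNV downstream
#' of the reverse primer.
#'
#' @param name Viewpoint label.
#' @param primer_seq Reading-primer DNA (read prefix to match).
#' @param viewpoint_fragment 0-based index of the anchor fragment in the
#'   [build_fragment_map()] output.
#' @param max_mismatch Maximum Hamming mismatches allowed when matching the
#'   primer against a read prefix (default 2).
#' @param allele_snv Optional `list(offset =, base129 =, baseCAST =)`
#'   giving the 0-based offset of the discriminating SNV on the mate read
#'   and the two allele bases.
#' @return An object of class `ViewpointSpec`.
#' @export
viewpoint_spec <- function(name, primer_seq, viewpoint_fragment = NA_integer_,
                           max_mismatch = 2L, allele_snv = NULL) {
  .check_dna(primer_seq, "primer", allow_n = FALSE)
  stopifnot(max_mismatch >= 0L)
  if (!is.null(allele_snv)) {
    stopifnot(all(c("offset", "base129", "baseCAST") %in% names(allele_snv)))
    if (allele_snv$base129 == allele_snv$baseCAST)
      stop("allele SNV bases must differ", call. = FALSE)
  }
  structure(list(name = name, primer_seq = toupper(primer_seq),
                 viewpoint_fragment = as.integer(viewpoint_fragment),
                 max_mismatch = as.integer(max_mismatch),
                 allele_snv = allele_snv),
            class = "ViewpointSpec")
}

# vectorized Hamming distance between each read prefix and a primer;
# reads shorter than the primer get Inf
.prefix_hamming <- function(reads, primer) {
  plen <- nchar(primer)
  d <- numeric(length(reads))
  too_short <- nchar(reads) < plen
  pr <- strsplit(primer, "")[[1L]]
  for (j in seq_len(plen)) {
    d <- d + (substr(reads, j, j) != pr[j])
  }
  d[too_short] <- Inf
  d
}

#' Match a read against the viewpoint primers
#'
#' Primer matching is anchored at read position 0: the Hamming distance
#' between each primer and the read prefix of equal length is computed, and
#' the read is assigned to the unique viewpoint with distance at most its
#' `max_mismatch`. Reads qualifying for two or more viewpoints are flagged
#' ambiguous and excluded from analysis (tallied in QC).
#'
#' @param read_seq A single read sequence.
#' @param viewpoints List of [viewpoint_spec()] objects.
#' @return `list(name =, status =)` with status one of `"matched"`,
#'   `"none"`, `"ambiguous"`; `name` is `NA` unless matched.
#' @export
match_viewpoint <- function(read_seq, viewpoints) {
  if (!nzchar(read_seq)) stop("read must be non-empty", call. = FALSE)
  hits <- vapply(viewpoints, function(vp) {
    .prefix_hamming(read_seq, vp$primer_seq) <= vp$max_mismatch
  }, logical(1))
  if (sum(hits) == 1L)
    list(name = viewpoints[[which(hits)]]$name, status = "matched")
  else if (sum(hits) > 1L)
    list(name = NA_character_, status = "ambiguous")
  else
    list(name = NA_character_, status = "none")
}

#' Trim a matched read to the primary restriction site
#'
#' Locates the first primary-motif occurrence at or after position
#' `primer_len - nchar(primary_motif)` (the motif the primer reads into)
#' and returns the read suffix starting at that motif. Reads without a
#' motif occurrence yield `NA` and are discarded upstream (tallied).
#'
#' @param read_seq Read sequence(s); vectorized.
#' @param primer_len Length of the matched primer.
#' @param primary_motif Primary restriction motif.
#' @return Character vector of trimmed sequences (each beginning with the
#'   motif), `NA` where no occurrence was found.
#' @export
trim_to_primary_site <- function(read_seq, primer_len, primary_motif) {
  k <- nchar(primary_motif)
  from <- max(primer_len - k, 0L)
  suffix <- substring(read_seq, from + 1L)
  pos <- regexpr(primary_motif, suffix, fixed = TRUE)
  out <- ifelse(pos > 0L, substring(suffix, pos), NA_character_)
  out
}

#' Assign a mate read to an allele at the discriminating SNV
#'
#' @param mate_seq Mate sequence(s); vectorized.
#' @param allele_snv `list(offset =, base129 =, baseCAST =)` as in
#'   [viewpoint_spec()].
#' @return Character vector over `c("129", "CAST", "unassigned")`; any base
#'   other than the two allele bases (including `N`), or an out-of-range
#'   offset, yields `"unassigned"`.
#' @export
split_allele <- function(mate_seq, allele_snv) {
  if (is.null(allele_snv)) return(rep("unassigned", length(mate_seq)))
  b <- substr(mate_seq, allele_snv$offset + 1L, allele_snv$offset + 1L)
  out <- rep("unassigned", length(mate_seq))
  out[b == allele_snv$base129] <- "129"
  out[b == allele_snv$baseCAST] <- "CAST"
  out
}

#' Demultiplex a paired 4C library by viewpoint and allele
#'
#' Runs primer matching, trimming to the primary restriction site, and
#' allele splitting over a whole library. The QC tally partitions the input
#' exactly: `matched + unmatched_primer + ambiguous + no_motif == n`.
#'
#' @param read1,read2 Character vectors of equal length: the reading-primer
#'   mates and their paired mates.
#' @param viewpoints List of [viewpoint_spec()] objects.
#' @param enz An [enzyme_pair()] providing the primary motif.
#' @return A `data.frame` of class `DemuxedReads` with columns `id`,
#'   `viewpoint`, `allele`, `trimmed_seq`, `mate_seq`, restricted to
#'   matched reads, plus an attribute `qc` (named integer tally with
#'   entries matched, unmatched_primer, ambiguous, no_motif).
#' @export
demux_reads <- function(read1, read2, viewpoints, enz = enzyme_pair()) {
  stopifnot(length(read1) == length(read2))
  n <- length(read1)
  motif <- enz$primary_motif
  if (n == 0L) {
    out <- data.frame(id = integer(0), viewpoint = character(0),
                      allele = character(0), trimmed_seq = character(0),
                      mate_seq = character(0), stringsAsFactors = FALSE)
    attr(out, "qc") <- c(matched = 0L, unmatched_primer = 0L,
                         ambiguous = 0L, no_motif = 0L)
    class(out) <- c("DemuxedReads", "data.frame")
    return(out)
  }
  nhits <- integer(n)
  vp_idx <- integer(n)
  for (v in seq_along(viewpoints)) {
    vp <- viewpoints[[v]]
    ok <- .prefix_hamming(read1, vp$primer_seq) <= vp$max_mismatch
    nhits <- nhits + ok
    vp_idx[ok] <- v
  }
  ambiguous <- nhits > 1L
  unmatched <- nhits == 0L
  matched1 <- nhits == 1L

  trimmed <- rep(NA_character_, n)
  allele <- rep(NA_character_, n)
  for (v in seq_along(viewpoints)) {
    vp <- viewpoints[[v]]
    sel <- matched1 & vp_idx == v
    if (!any(sel)) next
    trimmed[sel] <- trim_to_primary_site(read1[sel], nchar(vp$primer_seq),
                                         motif)
    allele[sel] <- split_allele(read2[sel], vp$allele_snv)
  }
  no_motif <- matched1 & is.na(trimmed)
  keep <- matched1 & !is.na(trimmed)

  out <- data.frame(
    id = which(keep),
    viewpoint = vapply(vp_idx[keep], function(v) viewpoints[[v]]$name, ""),
    allele = allele[keep],
    trimmed_seq = trimmed[keep],
    mate_seq = read2[keep],
    stringsAsFactors = FALSE)
  attr(out, "qc") <- c(matched = sum(keep),
                       unmatched_primer = sum(unmatched),
                       ambiguous = sum(ambiguous),
                       no_motif = sum(no_motif))
  class(out) <- c("DemuxedReads", "data.frame")
  out
}

#' Count aligned reads per restriction fragment
#'
#' A read contributes one count to fragment f iff its start coincides with
#' f's start or its end with f's end (4C junction reads begin exactly at a
#' fragment boundary). A read matching both boundaries of one fragment
#' counts once; a read matching boundaries of two different fragments is
#' discarded (tallied), never double-counted.
#'
#' @param alignments `data.frame` with 0-based half-open `start`, `end`
#'   columns, pre-filtered to paired, uniquely mapped reads.
#' @param fmap A `FragmentMap`.
#' @return Integer vector of raw counts, one per fragment, with attribute
#'   `discarded` (reads matching two different fragments).
#' @export
count_fragments <- function(alignments, fmap) {
  fr <- fmap$fragments
  if (nrow(alignments) == 0L)
    return(structure(integer(nrow(fr)), discarded = 0L))
  si <- match(alignments$start, fr$start)
  ei <- match(alignments$end, fr$end)
  conflict <- !is.na(si) & !is.na(ei) & si != ei
  frag <- ifelse(!is.na(si), si, ei)
  frag[conflict] <- NA
  counts <- tabulate(frag[!is.na(frag)], nbins = nrow(fr))
  structure(as.integer(counts), discarded = sum(conflict))
}

#' Library-size normalization to counts per million
#'
#' Scales raw fragment counts so that the included fragments sum to 1e6.
#' Fragments outside `valid_mask` (blind fragments and, by default, the
#' viewpoint fragment with its immediate neighbors) are set to zero and
#' excluded from the denominator.
#'
#' @param raw Non-negative integer count vector.
#' @param valid_mask Logical vector, `TRUE` for fragments included in the
#'   library-size denominator.
#' @return Numeric CPM vector of the same length.
#' @export
cpm_normalize <- function(raw, valid_mask = rep(TRUE, length(raw))) {
  stopifnot(length(raw) == length(valid_mask), all(raw >= 0))
  total <- sum(raw[valid_mask])
  if (total <= 0) stop("empty library", call. = FALSE)
  norm <- raw * 1e6 / total
  norm[!valid_mask] <- 0
  norm
}

#' Centered rolling mean with shrinking-window edges
#'
#' Smooths a per-fragment track with a centered mean of odd width `window`
#' (default 21 fragments). At the edges the window is truncated
#' symmetrically to what exists, so the smoother is average-preserving in
#' the interior; `edge = "na"` emits `NA` where the full window does not
#' fit.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer window width.
#' @param edge Either `"shrink"` (default) or `"na"`.
#' @return Numeric vector of the same length.
#' @export
rolling_mean <- function(x, window = 21L, edge = c("shrink", "na")) {
  edge <- match.arg(edge)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer", call. = FALSE)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  half <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hw <- pmin(half, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  out <- (cs[i + hw + 1L] - cs[i - hw]) / (2 * hw + 1)
  if (edge == "na") out[hw < half] <- NA_real_
  out
}

#' Assemble a per-fragment contact track
#'
#' Combines raw counts with CPM normalization and rolling-mean smoothing.
#' Blind (invalid) fragments and the viewpoint fragment plus
#' `exclude_viewpoint_neighbors` fragments on each side are excluded from
#' the normalization denominator and zeroed (self-ligation and undigested
#' products dominate near the viewpoint).
#'
#' @param raw Integer count vector (one per fragment).
#' @param fmap A `FragmentMap`.
#' @param viewpoint_fragment 0-based index of the viewpoint fragment, or
#'   `NA` to skip viewpoint exclusion.
#' @param exclude_viewpoint_neighbors Number of fragments on each side of
#'   the viewpoint to exclude (default 1).
#' @param window Rolling-mean window in fragments (default 21).
#' @param viewpoint,allele,replicate Metadata labels stored on the track.
#' @return A `data.frame` of class `ContactTrack` with columns `index`,
#'   `start`, `end`, `included`, `raw`, `normalized`, `smoothed` and
#'   metadata attributes.
#' @export
contact_track <- function(raw, fmap, viewpoint_fragment = NA_integer_,
                          exclude_viewpoint_neighbors = 1L, window = 21L,
                          viewpoint = NA_character_, allele = NA_character_,
                          replicate = NA_character_) {
  fr <- fmap$fragments
  stopifnot(length(raw) == nrow(fr))
  mask <- fr$valid
  if (!is.na(viewpoint_fragment)) {
    excl <- viewpoint_fragment + seq(-exclude_viewpoint_neighbors,
                                     exclude_viewpoint_neighbors)
    excl <- excl[excl >= 0L & excl < nrow(fr)]
    mask[excl + 1L] <- FALSE
  }
  norm <- cpm_normalize(raw, mask)
  out <- data.frame(index = fr$index, start = fr$start, end = fr$end,
                    included = mask, raw = as.integer(raw),
                    normalized = norm,
                    smoothed = rolling_mean(norm, window))
  attr(out, "viewpoint") <- viewpoint
  attr(out, "allele") <- allele
  attr(out, "replicate") <- replicate
  attr(out, "window") <- as.integer(window)
  class(out) <- c("ContactTrack", "data.frame")
  out
}

#' Quantify a contact track over a region
#'
#' Summarizes the normalized (pre-smoothing) values of fragments whose
#' midpoint falls in `[region$start, region$end)`. The mean (default) is
#' invariant to the number of fragments spanned; the sum is available for
#' comparison. Blind/excluded fragments carry structural zeros rather than
#' measurements, so by default only included fragments enter the summary.
#'
#' @param track A `ContactTrack`.
#' @param reg A [region()].
#' @param stat `"mean"` (default) or `"sum"`.
#' @param included_only Restrict to fragments included at normalization
#'   (default `TRUE`).
#' @return A one-row `data.frame` (class `RegionQuant`) with columns
#'   `region`, `viewpoint`, `allele`, `replicate`, `n_fragments`, `value`.
#' @export
quantify_region <- function(track, reg, stat = c("mean", "sum"),
                            included_only = TRUE) {
  stat <- match.arg(stat)
  mid <- (track$start + track$end) / 2
  sel <- mid >= reg$start & mid < reg$end
  if (included_only) sel <- sel & track$included
  if (!any(sel))
    stop("region '", reg$name, "' overlaps no fragment", call. = FALSE)
  v <- track$normalized[sel]
  value <- if (stat == "mean") mean(v) else sum(v)
  structure(
    data.frame(region = reg$name,
               viewpoint = attr(track, "viewpoint") %||% NA_character_,
               allele = attr(track, "allele") %||% NA_character_,
               replicate = attr(track, "replicate") %||% NA_character_,
               n_fragments = sum(sel), value = value,
               stringsAsFactors = FALSE),
    class = c("RegionQuant", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the 4C pipeline from demultiplexed reads to allele tracks
#'
#' Convenience driver: places trimmed reads with an aligner function,
#' filters to paired unique alignments, counts fragments per allele, and
#' builds one [contact_track()] per allele (129, CAST, unassigned, and the
#' combined track "all").
#'
#' @param demuxed A `DemuxedReads` table from [demux_reads()].
#' @param fmap A `FragmentMap`.
#' @param vp The [viewpoint_spec()] the reads belong to.
#' @param aligner Function mapping a character vector of trimmed sequences
#'   to an alignment `data.frame` (`start`, `end`, `is_paired`,
#'   `is_unique`, one row per input read, NA start for unmapped); e.g.
#'   `function(s) naive_align(s, locus)` for synthetic data, or an adapter
#'   around externally aligned reads.
#' @param ... Passed to [contact_track()].
#' @return Named list of `ContactTrack`s: `all` plus one per observed
#'   allele.
#' @export
fourc_tracks <- function(demuxed, fmap, vp, aligner, ...) {
  aln <- aligner(demuxed$trimmed_seq)
  ok <- !is.na(aln$start) & aln$is_paired & aln$is_unique
  aln <- aln[ok, , drop = FALSE]
  allele <- demuxed$allele[ok]
  tracks <- list()
  tracks[["all"]] <- contact_track(
    count_fragments(aln, fmap), fmap,
    viewpoint_fragment = vp$viewpoint_fragment,
    viewpoint = vp$name, allele = "all", ...)
  for (a in ALLELE_LEVELS) {
    raw <- count_fragments(aln[allele == a, , drop = FALSE], fmap)
    if (sum(raw) == 0L) next  # no library for this allele
    tracks[[a]] <- contact_track(
      raw, fmap, viewpoint_fragment = vp$viewpoint_fragment,
      viewpoint = vp$name, allele = a, ...)
  }
  tracks
}
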