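# Synthetic diploid locus: a random base sequence carrying SNVs at a mean
# spacing of ~135 bp (the 129 x CAST F1 polymorphism density), with SNVs
# kept out of restriction motifs so both haplotypes share one fragment map
# and one coordinate system (no liftover needed).

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their seed without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed or `NULL` (use the current stream).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv()))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Configuration for the synthetic diploid locus
#'
#' Defaults describe the toy world the package is validated on: a 100 kb
#' locus, SNVs every ~135 bp, a viewpoint anchored mid-locus, a looping
#' target region 25-35 kb downstream and a mirror-distance control region
#' upstream (equal distance, so a pure distance-decay library gives a
#' target/control ratio of 1 in expectation).
#'
#' @param length Locus length in bp (default 100000, minimum 5000).
#' @param snv_spacing Mean SNV spacing in bp (default 135).
#' @param viewpoint_pos Approximate viewpoint position (default `length/2`).
#' @param target,control [region()]s quantified downstream; defaults are
#'   mirror-symmetric about the viewpoint.
#' @param enzymes An [enzyme_pair()].
#' @param primer_flank Bases of viewpoint-fragment sequence in the reading
#'   primer before the primary motif (default 16; primer length is
#'   `primer_flank + nchar(primary_motif)`).
#' @param mate_len Mate-read length (default 30).
#' @param min_valid_fragments Required number of valid fragments
#'   (default 50).
#' @return List of class `LocusConfig`.
#' @export
locus_config <- function(length = 100000L, snv_spacing = 135,
                         viewpoint_pos = NULL,
                         target = NULL, control = NULL,
                         enzymes = enzyme_pair(),
                         primer_flank = 16L, mate_len = 30L,
                         min_valid_fragments = 50L) {
  length <- as.integer(length)
  if (length < 5000L) stop("locus length must be >= 5 kb", call. = FALSE)
  stopifnot(snv_spacing > 0)
  if (is.null(viewpoint_pos)) viewpoint_pos <- length %/% 2L
  if (is.null(target))
    target <- region("target", viewpoint_pos + length %/% 4L,
                     min(length, viewpoint_pos + 7L * (length %/% 20L)))
  if (is.null(control))
    control <- region("control",
                      max(0L, viewpoint_pos - 7L * (length %/% 20L)),
                      viewpoint_pos - length %/% 4L)
  stopifnot(target$end <= length, control$start >= 0L)
  structure(list(length = length, snv_spacing = snv_spacing,
                 viewpoint_pos = as.integer(viewpoint_pos),
                 target = target, control = control, enzymes = enzymes,
                 primer_flank = as.integer(primer_flank),
                 mate_len = as.integer(mate_len),
                 min_valid_fragments = as.integer(min_valid_fragments)),
            class = "LocusConfig")
}

# does setting chars[pos+1] <- alt create a new occurrence of motif?
.creates_motif <- function(chars, pos0, alt, motif) {
  k <- nchar(motif)
  L <- length(chars)
  lo <- max(0L, pos0 - k + 1L)
  hi <- min(L - k, pos0)
  if (hi < lo) return(FALSE)
  tmp <- chars[(lo + 1L):min(L, hi + k)]
  tmp[pos0 - lo + 1L] <- alt
  s <- paste(tmp, collapse = "")
  length(scan_motif(s, motif)) > 0L
}

#' Generate a synthetic diploid locus with known ground truth
#'
#' Draws a uniform random base sequence (the 129 haplotype), places SNVs by
#' a Poisson process at the configured spacing with the alternate base
#' chosen uniformly among the other three (the CAST haplotype), and
#' excludes SNVs from restriction-motif occurrences and from the viewpoint
#' primer so both haplotypes share one fragment map. A discriminating SNV
#' is planted in the mate-read window downstream of the viewpoint so reads
#' can be allele-split. Errors if the configuration cannot yield the
#' required number of valid fragments.
#'
#' @param cfg A [locus_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return List of class `DiploidLocus`: `hap129`, `hapCAST`
#'   ([haplotype()]s), `snvs` ([snv_table()]), `fmap` (shared
#'   [build_fragment_map()]), `viewpoint` ([viewpoint_spec()] with primer
#'   and allele SNV), `mate_start`, `target`, `control`, `config`.
#' @export
make_diploid_locus <- function(cfg = locus_config(), seed = 1L) {
  with_seed(seed, {
    L <- cfg$length
    enz <- cfg$enzymes
    chars <- sample(DNA_BASES, L, replace = TRUE)
    seq129 <- paste(chars, collapse = "")
    hap129 <- haplotype("129", seq129)
    fmap <- build_fragment_map(hap129, enz)
    if (sum(fmap$fragments$valid) < cfg$min_valid_fragments)
      stop("locus constraints unsatisfiable: only ",
           sum(fmap$fragments$valid), " valid fragments", call. = FALSE)

    # positions that must stay identical between haplotypes
    occupied <- logical(L)
    for (motif in c(enz$primary_motif, enz$secondary_motif)) {
      sites <- scan_motif(seq129, motif)
      if (length(sites))
        occupied[as.vector(outer(sites, seq_len(nchar(motif)) - 1L, `+`)) +
                   1L] <- TRUE
    }

    # viewpoint fragment: nearest valid fragment to the requested position
    # that leaves room for the primer and the mate window
    fr <- fmap$fragments
    flank <- cfg$primer_flank
    cand <- which(fr$valid & (fr$end - fr$start) >= flank + 8L &
                    fr$end > flank &
                    fr$end + 4L + cfg$mate_len + 4L < L)
    if (!length(cand)) stop("no usable viewpoint fragment", call. = FALSE)
    mid <- (fr$start + fr$end) / 2
    vp_row <- cand[which.min(abs(mid[cand] - cfg$viewpoint_pos))]
    vp_end <- fr$end[vp_row]
    k1 <- nchar(enz$primary_motif)
    primer <- substr(seq129, vp_end - flank + 1L, vp_end + k1)
    occupied[(vp_end - flank + 1L):(vp_end + k1)] <- TRUE

    # designated allele-discriminating SNV inside the mate window
    mate_start <- vp_end + k1
    window1 <- (mate_start + 6L):(mate_start + cfg$mate_len - 2L)  # 1-based
    mate_free0 <- window1[!occupied[window1]] - 1L
    if (!length(mate_free0))
      stop("no room for the discriminating SNV", call. = FALSE)
    snv_vp_pos <- mate_free0[1L]  # 0-based
    # remaining SNVs: Poisson count, uniform over unoccupied positions
    n_snv <- rpois(1L, L / cfg$snv_spacing)
    free <- which(!occupied) - 1L
    free <- setdiff(free, snv_vp_pos)
    n_extra <- max(0L, n_snv - 1L)
    if (length(free) < n_extra)
      stop("locus constraints unsatisfiable: too few free positions",
           call. = FALSE)
    pos <- sort(c(snv_vp_pos, sample(free, n_extra)))

    # mutate sequentially against the evolving CAST sequence: nearby SNVs
    # could otherwise jointly create a motif that single-site checks miss
    castChars <- chars
    keep <- logical(length(pos))
    alt <- character(length(pos))
    for (i in seq_along(pos)) {
      ref <- chars[pos[i] + 1L]
      for (a in sample(setdiff(DNA_BASES, ref))) {
        if (!.creates_motif(castChars, pos[i], a, enz$primary_motif) &&
            !.creates_motif(castChars, pos[i], a, enz$secondary_motif)) {
          keep[i] <- TRUE; alt[i] <- a
          castChars[pos[i] + 1L] <- a
          break
        }
      }
      if (!keep[i] && pos[i] == snv_vp_pos)
        stop("discriminating SNV cannot avoid motif creation", call. = FALSE)
    }
    pos <- pos[keep]; alt <- alt[keep]
    hapCAST <- haplotype("CAST", paste(castChars, collapse = ""))
    snvs <- snv_table(pos, chars[pos + 1L], alt)

    fmapCAST <- build_fragment_map(hapCAST, enz)
    stopifnot(identical(fmap$fragments$start, fmapCAST$fragments$start),
              identical(fmap$fragments$valid, fmapCAST$fragments$valid))

    i <- match(snv_vp_pos, snvs$pos)
    vp <- viewpoint_spec(
      name = "vp1", primer_seq = primer,
      viewpoint_fragment = fr$index[vp_row],
      allele_snv = list(offset = snv_vp_pos - mate_start,
                        base129 = snvs$base129[i],
                        baseCAST = snvs$baseCAST[i]))
    structure(list(hap129 = hap129, hapCAST = hapCAST, snvs = snvs,
                   fmap = fmap, viewpoint = vp, mate_start = mate_start,
                   target = cfg$target, control = cfg$control,
                   config = cfg),
              class = "DiploidLocus")
  })
}

#' @export
print.DiploidLocus <- function(x, ...) {
  cat(sprintf(
    "DiploidLocus: %d bp, %d SNVs, %d fragments (%d valid), viewpoint fragment %d\n",
    x$config$length, nrow(x$snvs), nrow(x$fmap$fragments),
    sum(x$fmap$fragments$valid), x$viewpoint$viewpoint_fragment))
  invisible(x)
}
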