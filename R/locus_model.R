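# Coordinate convention used throughout the package: 0-based, half-open
# [start, end), as in BED. A motif "position" is the 0-based offset of its
# leftmost base. Fragment indices are 0-based ordinals along the sequence.

DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(x, what, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (grepl(sprintf("[^%s]", alphabet), x))
    stop(what, " contains characters outside {", alphabet, "}", call. = FALSE)
  invisible(x)
}

#' Construct a haplotype
#'
#' A haplotype is one parental copy of the locus: a name (conventionally
#' "129" or "CAST" for the F1 hybrid genetic background) and an uppercase
#' DNA sequence on the shared locus coordinate system.
#'
#' @param name Character label, e.g. `"129"`.
#' @param seq Uppercase DNA string over `{A,C,G,T,N}`.
#' @return An object of class `Haplotype` with fields `name`, `seq`,
#'   `length`.
#' @export
haplotype <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seq <- toupper(seq)
  .check_dna(seq, "haplotype sequence", allow_n = TRUE)
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "Haplotype")
}

#' @export
print.Haplotype <- function(x, ...) {
  cat(sprintf("Haplotype '%s': %d bp\n", x$name, x$length))
  invisible(x)
}

#' Construct an SNV table
#'
#' Records the single-nucleotide variants that distinguish the two parental
#' alleles on the shared locus coordinates.
#'
#' @param pos Integer vector of 0-based positions, strictly increasing.
#' @param base129,baseCAST Single-character bases; must differ at every
#'   position.
#' @return A `data.frame` of class `SnvTable` with columns `pos`,
#'   `base129`, `baseCAST`.
#' @export
snv_table <- function(pos, base129, baseCAST) {
  pos <- as.integer(pos)
  if (length(pos) && any(diff(pos) <= 0L))
    stop("SNV positions must be strictly increasing", call. = FALSE)
  if (length(base129) != length(pos) || length(baseCAST) != length(pos))
    stop("base vectors must match the number of positions", call. = FALSE)
  if (any(base129 == baseCAST))
    stop("base129 and baseCAST must differ at every SNV", call. = FALSE)
  if (!all(c(base129, baseCAST) %in% DNA_BASES))
    stop("SNV bases must be in {A,C,G,T}", call. = FALSE)
  structure(
    data.frame(pos = pos, base129 = as.character(base129),
               baseCAST = as.character(baseCAST),
               stringsAsFactors = FALSE),
    class = c("SnvTable", "data.frame"))
}

#' Primary/secondary restriction enzyme pair
#'
#' Defaults correspond to a DpnII (primary) and Csp6I (secondary) double
#' digest, the standard high-resolution 4C combination. Fragments are
#' delimited by the primary motif; a fragment lacking an internal secondary
#' site is "blind" (poorly recoverable by the circularization step) and is
#' flagged invalid.
#'
#' @param primary_motif Recognition sequence of the fragment-defining
#'   enzyme (default `"GATC"`, DpnII).
#' @param secondary_motif Recognition sequence of the trimming enzyme
#'   (default `"GTAC"`, Csp6I).
#' @return An object of class `EnzymePair`.
#' @export
enzyme_pair <- function(primary_motif = "GATC", secondary_motif = "GTAC") {
  .check_dna(primary_motif, "primary motif", allow_n = FALSE)
  .check_dna(secondary_motif, "secondary motif", allow_n = FALSE)
  structure(list(primary_motif = toupper(primary_motif),
                 secondary_motif = toupper(secondary_motif)),
            class = "EnzymePair")
}

#' Named genomic region on the shared locus
#'
#' @param name Region label.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @return An object of class `Region`.
#' @export
region <- function(name, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start >= end) stop("region start must be < end", call. = FALSE)
  structure(list(name = name, start = start, end = end), class = "Region")
}

#' Find all exact occurrences of a motif
#'
#' Scans a DNA string for exact matches of `motif`, including overlapping
#' occurrences. `N` bases in the sequence never match. Both default enzyme
#' motifs are reverse-complement palindromes, so a single-strand scan covers
#' both strands.
#'
#' @param seq DNA string (may be empty).
#' @param motif Non-empty DNA string over `{A,C,G,T}`.
#' @return Sorted integer vector of 0-based start positions.
#' @export
scan_motif <- function(seq, motif) {
  .check_dna(motif, "motif", allow_n = FALSE)
  if (!nzchar(motif)) stop("motif must be non-empty", call. = FALSE)
  if (is.null(seq) || !nzchar(seq)) return(integer(0))
  .check_dna(seq, "sequence", allow_n = TRUE)
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(integer(0))
  sv <- charToRaw(seq)
  mv <- charToRaw(motif)
  idx <- seq_len(n - k + 1L)
  ok <- sv[idx] == mv[1L]
  if (k > 1L) for (j in 2:k) ok <- ok & (sv[idx + (j - 1L)] == mv[j])
  which(ok) - 1L
}

#' Build the double-digest fragment map
#'
#' Cuts the haplotype sequence at every primary-motif start position; each
#' cut places the motif at the start of the downstream fragment, so trimmed
#' viewpoint reads align at fragment starts. A fragment is `valid` iff at
#' least one secondary-motif occurrence lies entirely within it; occurrences
#' straddling a primary boundary validate neither neighbor.
#'
#' @param hap A [haplotype()].
#' @param enz An [enzyme_pair()].
#' @return An object of class `FragmentMap`: fields `haplotype`, `enzymes`,
#'   `seq_length` and `fragments` (data.frame with 0-based `index`, `start`,
#'   `end`, logical `valid`).
#' @export
build_fragment_map <- function(hap, enz = enzyme_pair()) {
  stopifnot(inherits(hap, "Haplotype"), inherits(enz, "EnzymePair"))
  if (hap$length <= 0L) stop("haplotype must be non-empty", call. = FALSE)
  L <- hap$length
  sites <- scan_motif(hap$seq, enz$primary_motif)
  bounds <- c(0L, sites[sites > 0L], L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  sec <- scan_motif(hap$seq, enz$secondary_motif)
  k2 <- nchar(enz$secondary_motif)
  # fragment containing each secondary occurrence start vs its end
  fi_start <- findInterval(sec, starts)
  fi_end <- findInterval(sec + k2 - 1L, starts)
  inside <- fi_start == fi_end            # does not straddle a boundary
  valid <- logical(length(starts))
  valid[unique(fi_start[inside])] <- TRUE
  structure(list(
    haplotype = hap$name,
    enzymes = enz,
    seq_length = L,
    fragments = data.frame(
      index = seq_along(starts) - 1L,
      start = starts, end = ends, valid = valid)),
    class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  cat(sprintf("FragmentMap for '%s': %d fragments over %d bp (%d valid)\n",
              x$haplotype, nrow(x$fragments), x$seq_length,
              sum(x$fragments$valid)))
  invisible(x)
}

#' Number of fragments in a map
#' @param fmap A `FragmentMap`.
#' @return Integer count.
#' @export
n_fragments <- function(fmap) nrow(fmap$fragments)

#' Locate the fragment containing a position
#'
#' @param fmap A `FragmentMap`.
#' @param pos 0-based coordinate(s), `0 <= pos < seq_length`.
#' @return 0-based fragment index (vectorized over `pos`).
#' @export
fragment_of <- function(fmap, pos) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= fmap$seq_length))
    stop("position out of range", call. = FALSE)
  findInterval(pos, fmap$fragments$start) - 1L
}

#' Midpoints of all fragments
#' @param fmap A `FragmentMap`.
#' @return Numeric vector of fragment midpoints on locus coordinates.
#' @export
fragment_midpoints <- function(fmap) {
  (fmap$fragments$start + fmap$fragments$end) / 2
}
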