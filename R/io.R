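# Readers and writers for the standard formats the pipeline consumes and
# emits. Sequence formats go through Biostrings, interval formats through
# rtracklayer/GenomicRanges, alignments through Rsamtools/GenomicAlignments;
# tables are plain TSV.

#' Read haplotypes from a FASTA file
#' @param path FASTA file.
#' @return Named list of [haplotype()] objects.
#' @export
read_haplotypes <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    haplotype(names(ss)[i], as.character(ss[[i]])))
  names(out) <- names(ss)
  out
}

#' Write haplotypes to a FASTA file
#' @param haps List of [haplotype()] objects.
#' @param path Output file.
#' @export
write_haplotypes <- function(haps, path) {
  ss <- Biostrings::DNAStringSet(vapply(haps, `[[`, "", "seq"))
  names(ss) <- vapply(haps, `[[`, "", "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads to FASTQ
#' @param seqs Character vector of read sequences.
#' @param path Output file.
#' @param ids Read names (default `read1..readN`).
#' @export
write_fastq <- function(seqs, path, ids = paste0("read", seq_along(seqs))) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file as a character vector of sequences
#' @param path FASTQ file.
#' @return Named character vector.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), names(ss))
}

#' Write a fragment map as BED
#'
#' Columns: chrom = haplotype name, start, end (0-based half-open),
#' name = fragment index, score = validity as 0/1.
#'
#' @param fmap A `FragmentMap`.
#' @param path Output BED file.
#' @export
write_fragment_map_bed <- function(fmap, path) {
  fr <- fmap$fragments
  gr <- GenomicRanges::GRanges(
    seqnames = fmap$haplotype,
    ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end),
    name = as.character(fr$index), score = as.integer(fr$valid))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read regions from a BED file
#' @param path BED file.
#' @return List of [region()] objects (0-based half-open).
#' @export
read_regions_bed <- function(path) {
  df <- as.data.frame(rtracklayer::import(path, format = "BED"))
  nm <- if (!is.null(df$name)) df$name else paste0("region", seq_len(nrow(df)))
  lapply(seq_len(nrow(df)), function(i)
    region(nm[i], df$start[i] - 1L, df$end[i]))
}

#' Write a contact track as bedGraph
#'
#' One file per track stage; values are the chosen column over fragments.
#'
#' @param track A `ContactTrack`.
#' @param path Output bedGraph file.
#' @param value Which column to export: `"normalized"` (default),
#'   `"smoothed"` or `"raw"`.
#' @param chrom Chromosome/locus name (default `"locus"`).
#' @export
write_track_bedgraph <- function(track, path,
                                 value = c("normalized", "smoothed", "raw"),
                                 chrom = "locus") {
  value <- match.arg(value)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = as.numeric(track[[value]]))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read alignments from SAM/BAM or a plain alignment table
#'
#' SAM files are converted to BAM and parsed with GenomicAlignments;
#' "uniquely mapped" is operationalized as mapping quality at least
#' `min_mapq` and no secondary-alignment flag. The TSV alternative must
#' have columns `start`, `end` (0-based half-open), `is_paired`,
#' `is_unique`.
#'
#' @param path SAM (`.sam`), BAM (`.bam`) or TSV file.
#' @param min_mapq Mapping-quality threshold for uniqueness (default 20).
#' @return `data.frame` with `ref`, `start`, `end`, `is_paired`,
#'   `is_unique`.
#' @export
read_alignments <- function(path, min_mapq = 20L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    path <- bam
    ext <- "bam"
  }
  if (ext == "bam") {
    ga <- as.data.frame(GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(what = c("flag", "mapq"))))
    secondary <- bitwAnd(ga$flag, 256L) != 0L
    data.frame(
      ref = as.character(ga$seqnames),
      start = ga$start - 1L,
      end = ga$end,
      is_paired = bitwAnd(ga$flag, 1L) != 0L,
      is_unique = !is.na(ga$mapq) & ga$mapq >= min_mapq & !secondary,
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("start", "end", "is_paired", "is_unique")
    if (!all(need %in% names(df)))
      stop("alignment table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (is.null(df$ref)) df$ref <- "locus"
    df
  }
}

#' Read a dual alignment-score table
#'
#' TSV with columns `id`, `score_129`, `score_CAST`, as produced by
#' extracting AS tags from two coordinate-matched alignments.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
read_dual_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("score_129", "score_CAST") %in% names(df)))
  df
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#' @param path Input file.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
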