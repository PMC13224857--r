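# Simulated sequencing-scale inputs with recorded ground truth: 4C paired
# reads from a distance-decay + loop-enrichment contact model, negative-
# binomial allelic count tables, and Ct tables for qPCR statistics.

#' Contact model for simulated 4C libraries
#'
#' Background contact probability decays with genomic distance as
#' `d^-decay_exponent`; inside the target (loop) region it is multiplied by
#' an allele-specific enrichment `lambda`. Defaults describe the validated
#' world: decay exponent 1, a four-fold 129-specific loop over a neutral
#' CAST allele, 100,000 read pairs, 0.1% per-base substitution error.
#'
#' @param decay_exponent Positive decay exponent `alpha`.
#' @param lambda_129,lambda_CAST Multiplicative loop enrichment inside the
#'   target region per allele (>= 0).
#' @param n_reads Library size in read pairs.
#' @param error_rate Per-base substitution error rate.
#' @param allele_mix Probability that a read originates from the 129
#'   allele (default 0.5).
#' @param read_len Length of the reading-primer mate (default 70).
#' @return List of class `ContactModel`.
#' @export
contact_model <- function(decay_exponent = 1, lambda_129 = 4,
                          lambda_CAST = 1, n_reads = 100000L,
                          error_rate = 0.001, allele_mix = 0.5,
                          read_len = 70L) {
  stopifnot(decay_exponent > 0, lambda_129 >= 0, lambda_CAST >= 0,
            n_reads >= 0, error_rate >= 0, error_rate < 1,
            allele_mix >= 0, allele_mix <= 1)
  structure(list(decay_exponent = decay_exponent, lambda_129 = lambda_129,
                 lambda_CAST = lambda_CAST, n_reads = as.integer(n_reads),
                 error_rate = error_rate, allele_mix = allele_mix,
                 read_len = as.integer(read_len)),
            class = "ContactModel")
}

#' True per-fragment contact probabilities of a locus under a model
#'
#' Fragments must be valid and outside the viewpoint fragment and its
#' immediate neighbors to be capturable; probabilities normalize to 1 per
#' allele over those fragments.
#'
#' @param locus A `DiploidLocus`.
#' @param model A [contact_model()].
#' @return `data.frame`: `index` (0-based fragment), `p_129`, `p_CAST`.
#' @export
contact_probabilities <- function(locus, model) {
  fr <- locus$fmap$fragments
  vp <- locus$viewpoint$viewpoint_fragment
  mid <- (fr$start + fr$end) / 2
  vp_mid <- mid[vp + 1L]
  eligible <- fr$valid & abs(fr$index - vp) > 1L
  w <- ifelse(eligible, abs(mid - vp_mid)^(-model$decay_exponent), 0)
  in_target <- mid >= locus$target$start & mid < locus$target$end
  w129 <- w * ifelse(in_target, model$lambda_129, 1)
  wCAST <- w * ifelse(in_target, model$lambda_CAST, 1)
  data.frame(index = fr$index, p_129 = w129 / sum(w129),
             p_CAST = wCAST / sum(wCAST))
}

# substitute random bases at the given per-base rate (vectorized draws,
# then a short loop over the realized substitutions)
.add_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  m <- rbinom(1L, total, rate)
  if (m == 0L) return(seqs)
  gpos <- sample.int(total, m)
  cs <- cumsum(lens)
  rd <- findInterval(gpos - 1L, cs) + 1L
  off <- gpos - c(0L, cs)[rd]
  alts <- sample(DNA_BASES, m, replace = TRUE)
  for (i in seq_len(m)) {
    cur <- substr(seqs[rd[i]], off[i], off[i])
    new <- if (alts[i] == cur) setdiff(DNA_BASES, cur)[1L] else alts[i]
    substr(seqs[rd[i]], off[i], off[i]) <- new
  }
  seqs
}

#' Simulate a paired allele-resolved 4C library
#'
#' For each read pair an allele is drawn from the mixture, a captured
#' fragment is drawn from that allele's contact distribution, and the
#' reading mate is emitted as primer + junction sequence into the captured
#' fragment (the junction retains the primary motif, so trimming recovers
#' the fragment prefix). The mate read covers the discriminating SNV
#' downstream of the reverse primer. Substitution errors are applied at
#' the model's rate. The truth bundle records the allele and captured
#' fragment of every read.
#'
#' @param locus A `DiploidLocus` from [make_diploid_locus()].
#' @param model A [contact_model()].
#' @param seed Integer seed.
#' @return List of class `FourCLibrary`: `read1`, `read2` (character
#'   vectors), `truth` (`data.frame` `id`, `allele`, `fragment`), `prob`
#'   (from [contact_probabilities()]).
#' @export
simulate_4c_library <- function(locus, model = contact_model(), seed = 1L) {
  with_seed(seed, {
    n <- model$n_reads
    prob <- contact_probabilities(locus, model)
    if (n == 0L) {
      return(structure(list(
        read1 = character(0), read2 = character(0),
        truth = data.frame(id = integer(0), allele = character(0),
                           fragment = integer(0)),
        prob = prob), class = "FourCLibrary"))
    }
    fr <- locus$fmap$fragments
    vp <- locus$viewpoint
    primer <- vp$primer_seq
    k1 <- nchar(locus$config$enzymes$primary_motif)
    jlen <- model$read_len - nchar(primer)
    stopifnot(jlen > 10L)

    allele <- ifelse(runif(n) < model$allele_mix, "129", "CAST")
    frag <- integer(n)
    is129 <- allele == "129"
    if (any(is129))
      frag[is129] <- sample(fr$index, sum(is129), replace = TRUE,
                            prob = prob$p_129)
    if (any(!is129))
      frag[!is129] <- sample(fr$index, sum(!is129), replace = TRUE,
                             prob = prob$p_CAST)

    hapseq <- c("129" = locus$hap129$seq, "CAST" = locus$hapCAST$seq)
    starts <- fr$start[frag + 1L]
    junction <- substr(hapseq[allele], starts + k1 + 1L,
                       pmin(starts + k1 + jlen, locus$config$length))
    read1 <- .add_seq_errors(paste0(primer, junction), model$error_rate)
    read2 <- .add_seq_errors(
      substr(hapseq[allele], locus$mate_start + 1L,
             locus$mate_start + locus$config$mate_len),
      model$error_rate)
    structure(list(read1 = unname(read1), read2 = unname(read2),
                   truth = data.frame(id = seq_len(n), allele = allele,
                                      fragment = frag),
                   prob = prob),
              class = "FourCLibrary")
  })
}

#' Exact-prefix placer for synthetic trimmed reads
#'
#' Places each trimmed read (which begins with the primary motif) at the
#' unique fragment whose start-anchored prefix of length `k`, on either
#' haplotype, matches the read prefix exactly. Reads with an error in
#' their first `k` bases go unmapped; prefixes shared by two fragments are
#' flagged non-unique. This is a test-closure device for synthetic data,
#' not an aligner.
#'
#' @param seqs Character vector of trimmed read sequences.
#' @param locus A `DiploidLocus`.
#' @param k Prefix length used for placement (default 24).
#' @return `data.frame` with `start`, `end` (0-based half-open; `NA` when
#'   unmapped), `is_paired`, `is_unique`.
#' @export
naive_align <- function(seqs, locus, k = 24L) {
  fr <- locus$fmap$fragments
  pref <- c(substring(locus$hap129$seq, fr$start + 1L, fr$start + k),
            substring(locus$hapCAST$seq, fr$start + 1L, fr$start + k))
  frag_of_pref <- rep(seq_len(nrow(fr)), 2L)
  # a prefix observed for >1 distinct fragment is ambiguous
  amb <- tapply(frag_of_pref, pref, function(v) length(unique(v)) > 1L)
  first <- !duplicated(pref)
  dict <- data.frame(pref = pref[first], row = frag_of_pref[first])
  dict$amb <- as.logical(amb[dict$pref])
  m <- match(substr(seqs, 1L, k), dict$pref)
  row <- dict$row[m]
  start <- fr$start[row]
  end <- pmin(start + nchar(seqs), locus$config$length)
  unique_ok <- !is.na(m) & !dict$amb[m]
  data.frame(start = ifelse(is.na(m), NA_integer_, start),
             end = ifelse(is.na(m), NA_integer_, end),
             is_paired = TRUE,
             is_unique = ifelse(is.na(m), FALSE, unique_ok))
}

#' Simulate negative-binomial allelic count tables
#'
#' Per design cell, `n_129 ~ NB(mean = total * ratio)` and
#' `n_CAST ~ NB(mean = total * (1 - ratio))` with a shared dispersion;
#' unassigned totals are NB with mean `total * unassigned_factor`.
#' `dispersion = 0` gives the Poisson limit.
#'
#' @param features Feature/region labels (default `c("Sox2", "SCR")`).
#' @param conditions Condition labels (default the two reciprocal
#'   reporter states).
#' @param replicates Replicates per condition (default 3).
#' @param total Mean total assigned reads per cell (default 5000).
#' @param ratio 129-allele proportion: a single number, or a matrix
#'   `features x conditions`.
#' @param dispersion NB dispersion `alpha` (`var = mu + alpha mu^2`),
#'   default 0.05.
#' @param unassigned_factor Unassigned reads relative to `total`
#'   (default 3).
#' @param seed Integer seed.
#' @return `data.frame` of class `AllelicCountTable` (`feature`,
#'   `condition`, `replicate`, `n_129`, `n_CAST`, `n_unassigned`) with a
#'   `truth` attribute recording the ratio matrix.
#' @export
simulate_allelic_counts <- function(features = c("Sox2", "SCR"),
                                    conditions = c("129ON_CASTOFF",
                                                   "129OFF_CASTON"),
                                    replicates = 3L, total = 5000,
                                    ratio = 0.5, dispersion = 0.05,
                                    unassigned_factor = 3,
                                    seed = 1L) {
  if (!is.matrix(ratio))
    ratio <- matrix(ratio, length(features), length(conditions),
                    dimnames = list(features, conditions))
  stopifnot(all(ratio > 0 & ratio < 1), dispersion >= 0)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        condition = conditions, feature = features,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    r <- ratio[cbind(grid$feature, grid$condition)]
    draw <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    out <- data.frame(feature = grid$feature, condition = grid$condition,
                      replicate = grid$replicate,
                      n_129 = draw(total * r),
                      n_CAST = draw(total * (1 - r)),
                      n_unassigned = draw(rep(total * unassigned_factor,
                                              nrow(grid))))
    attr(out, "truth") <- ratio
    class(out) <- c("AllelicCountTable", "data.frame")
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' `Ct = baseline + condition effect + replicate intercept + noise`; the
#' housekeeping gene shares each sample's replicate intercept (a common
#' pipetting/input shift), so it cancels in delta-Ct.
#'
#' @param conditions Condition labels; the first is the reference.
#' @param replicates Number of replicates (default 4, as in quadruplicate
#'   qPCR).
#' @param targets Non-housekeeping targets (default `c("gene",
#'   "enhancer")`).
#' @param effects Condition effects in cycles: matrix `targets x
#'   conditions` (default 0).
#' @param baseline Named baseline Ct per target; housekeeping baseline 20.
#' @param replicate_sd,residual_sd Random-intercept and residual standard
#'   deviations in cycles.
#' @param seed Integer seed.
#' @return `data.frame` of class `CtTable` (`condition`, `replicate`,
#'   `target`, `ct`) with a `truth` attribute holding the effect matrix.
#' @export
simulate_qpcr <- function(conditions = c("untreated", "depleted"),
                          replicates = 4L,
                          targets = c("gene", "enhancer"),
                          effects = NULL,
                          baseline = c(gene = 25, enhancer = 28),
                          replicate_sd = 0.3, residual_sd = 0.2,
                          seed = 1L) {
  stopifnot(replicate_sd >= 0, residual_sd >= 0)
  if (is.null(effects))
    effects <- matrix(0, length(targets), length(conditions),
                      dimnames = list(targets, conditions))
  with_seed(seed, {
    rep_int <- rnorm(replicates, 0, replicate_sd)
    grid <- expand.grid(replicate = seq_len(replicates),
                        condition = conditions,
                        target = c(targets, "housekeeping"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tg <- grid$target != "housekeeping"
    base <- rep(20, nrow(grid))
    base[tg] <- baseline[grid$target[tg]]
    eff <- numeric(nrow(grid))
    eff[tg] <- effects[cbind(grid$target[tg], grid$condition[tg])]
    ct <- base + eff + rep_int[grid$replicate] +
      rnorm(nrow(grid), 0, residual_sd)
    out <- data.frame(condition = grid$condition,
                      replicate = grid$replicate, target = grid$target,
                      ct = ct, stringsAsFactors = FALSE)
    attr(out, "truth") <- effects
    class(out) <- c("CtTable", "data.frame")
    out
  })
}

#' Simulate delta-Ct values with replicate-level intercepts
#'
#' Direct generator for the mixed-model calibration world: delta-Ct =
#' condition effect + per-replicate random intercept + residual noise,
#' with every condition measured in every replicate.
#'
#' @param conditions Condition labels.
#' @param replicates Number of biological replicates, i.e. random-intercept
#'   levels (default 4).
#' @param n_wells Technical qPCR wells per condition and replicate
#'   (default 4, quadruplicate plating).
#' @param effects Per-condition effects in cycles (default 0).
#' @param replicate_sd,residual_sd Random-intercept and per-well residual
#'   standard deviations in cycles (defaults 0.3 and 0.2).
#' @param target Target label for the output table.
#' @param seed Integer seed.
#' @return `data.frame` with `condition`, `replicate`, `target`, `dct`.
#' @export
simulate_dct_table <- function(conditions = c("untreated", "depleted"),
                               replicates = 4L, n_wells = 4L,
                               effects = rep(0, length(conditions)),
                               replicate_sd = 0.3, residual_sd = 0.2,
                               target = "gene", seed = 1L) {
  with_seed(seed, {
    rep_int <- rnorm(replicates, 0, replicate_sd)
    grid <- expand.grid(well = seq_len(n_wells),
                        replicate = seq_len(replicates),
                        condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    eff <- effects[match(grid$condition, conditions)]
    data.frame(condition = grid$condition, replicate = grid$replicate,
               target = target,
               dct = eff + rep_int[grid$replicate] +
                 rnorm(nrow(grid), 0, residual_sd),
               stringsAsFactors = FALSE)
  })
}

#' Run the full 4C pipeline on a simulated library
#'
#' End-to-end convenience for validation: demultiplexes the paired reads,
#' trims and allele-splits them, places the trimmed reads with
#' [naive_align()], and builds per-allele contact tracks plus target and
#' control region quantifications.
#'
#' @param lib A `FourCLibrary` from [simulate_4c_library()].
#' @param locus The `DiploidLocus` it was simulated from.
#' @param window Rolling-mean window (default 21 fragments).
#' @param stat Region summary statistic (see [quantify_region()]).
#' @return List with `tracks` (named `ContactTrack` list), `quants`
#'   (`data.frame` of region values per allele), `qc` (demux tally).
#' @export
run_synthetic_4c <- function(lib, locus, window = 21L, stat = "mean") {
  dm <- demux_reads(lib$read1, lib$read2, list(locus$viewpoint),
                    locus$config$enzymes)
  tracks <- fourc_tracks(dm, locus$fmap, locus$viewpoint,
                         aligner = function(s) naive_align(s, locus),
                         window = window)
  quants <- do.call(rbind, lapply(names(tracks), function(a) {
    rbind(quantify_region(tracks[[a]], locus$target, stat),
          quantify_region(tracks[[a]], locus$control, stat))
  }))
  list(tracks = tracks, quants = quants, qc = attr(dm, "qc"))
}
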