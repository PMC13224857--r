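---
title: "alleloop: models, synthetic worlds, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{alleloop: models, synthetic worlds, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific models behind each module, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical and design choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## 1. The 4C-seq contact model

4C-seq converts spatial proximity into ligation junctions: after
cross-linking, a primary restriction digest (DpnII, `GATC`) and
re-ligation, circles are trimmed by a secondary enzyme (Csp6I, `GTAC`) and
inverse PCR from a viewpoint primer amplifies whatever fragment the
viewpoint was ligated to. Read counts per fragment are therefore a
relative contact frequency profile of the viewpoint.

**Coordinates.** All coordinates are 0-based, half-open (BED convention);
a motif position is its leftmost base; fragment indices are 0-based.

**Fragment map.** A cut places the primary motif at the *start* of the
downstream fragment, so reading primers — which read into the motif — give
trimmed reads that align exactly at fragment starts, and the exact
boundary-match counting rule follows naturally. A fragment is *valid* only
if a secondary-motif occurrence lies entirely inside it; a secondary site
straddling a primary boundary cannot be cut within either fragment and
validates neither. Both default motifs are reverse-complement palindromes,
so one-strand scanning suffices (asserted in tests). Blind (invalid)
fragments are retained in the map with `valid = FALSE` and excluded at
normalization; dropping them earlier would silently change fragment
indices.

**Demultiplexing.** Primer matching is anchored at read position zero
(the field's convention; it also makes ambiguity well defined). Hamming
distance up to `max_mismatch = 2` is allowed. Reads matching two
viewpoints are ambiguous and are excluded but tallied; the QC tally
partitions the input exactly — an invariant the tests assert, because
silent read loss is the most common 4C pipeline bug.

**Counting.** A read contributes to a fragment only if its start or end
coincides exactly with a fragment boundary. A read matching boundaries of
two *different* fragments is discarded, never double-counted —
conservative and total-preserving.

**Normalization.** Counts per million over *included* fragments: valid
fragments minus the viewpoint fragment and `exclude_viewpoint_neighbors`
(default 1) fragments on each side, whose signal is dominated by
self-ligation and undigested products. The library is viewpoint-local, so
the denominator is cis-only; both choices are configurable.

**Smoothing.** Centered rolling mean, default window 21 fragments. Edge
policy is a symmetrically shrinking window (`edge = "na"` available):
window halfwidth at position i is `min((w-1)/2, i, n-1-i)`, which makes
the smoother average-preserving away from edges (asserted via the
zero-padding identity).

**Region quantification** uses the *normalized, pre-smoothing* values of
fragments whose midpoints fall in the region. The mean (not the sum) is
the default so values are invariant to how many fragments a region spans;
the sum is behind a flag. Only included fragments enter the summary:
blind fragments carry structural zeros, not measurements, and averaging
them in biases a region by its blind-fragment fraction (observed ~6-9% on
the synthetic locus before this choice was made).

## 2. The synthetic diploid locus and library

The generator builds the world the pipeline is validated in. It is a
stated world, not a tuning knob:

* locus length 100 kb, uniform random base composition;
* SNVs from a Poisson process with mean spacing 135 bp (the 129×CAST F1
  density), alternate base uniform over the other three;
* SNVs are excluded from restriction-motif occurrences, from the primer
  window, and are rejected (sequentially, against the evolving CAST
  sequence) if they would *create* a motif — so both haplotypes share one
  fragment map and one coordinate system. This sidesteps liftover, which
  the real F1 analysis needs and which is out of scope; it is the main
  deliberate difference from real data.
* viewpoint mid-locus; loop target region 25-35 kb downstream; control
  region mirror-symmetric upstream, so under pure distance decay the
  expected target/control ratio is 1;
* contact model: background probability ∝ distance^(−α) with α = 1
  (typical intra-TAD cis decay), multiplied inside the target region by an
  allele-specific loop factor; defaults λ₁₂₉ = 4, λ_CAST = 1, library
  100,000 read pairs, 0.1% per-base substitution error, 50:50 allele mix.

Reads are emitted as primer + junction into the captured fragment (the
junction retains the `GATC`, so trimming reconstructs the fragment
prefix), with the mate covering a deliberately planted discriminating SNV
downstream of the reverse primer. The shipped `naive_align()` is an
exact-prefix placer over both haplotypes' fragment-start 24-mers — a test
closure device, not an aligner; reads with an error in the prefix go
unmapped, symmetrically for both alleles. Real libraries enter through
SAM/BAM (`read_alignments()`, mapq ≥ 20 and no secondary flag as the
operational definition of "uniquely mapped").

What a green recovery test establishes: that the pipeline recovers
relative, allele-resolved contact changes from sequence-level input under
realistic noise. What it does not establish: behavior under PCR
duplicates, mappability structure, trans contacts, or genome-scale
fragment maps.

Because the control region is only mirror-*distance* matched, a fixed
fragment layout leaves a few-percent wobble in the λ = 1 target/control
ratio. The λ = 1 acceptance check therefore replicates the entire
simulation (locus and library) over ten seeds and compares the mean ratio
to 1 within three empirical Monte-Carlo standard errors — the honest
estimator for a generator whose map is itself random.

## 3. Allelic quantification

**Score-based assignment** abstracts dual-genome alignment into a scored
pair per read (+1 match / −4 mismatch against each haplotype at the same
shared coordinate); the read goes to the higher score, ties are
unassigned. With SNVs every ~135 bp, 75 bp reads and 0.1% error, nearly
all SNV-overlapping reads are assigned correctly (asserted ≥ 99%).

**Allelic proportions** divide size-factor-normalized counts; size
factors default to each sample's unassigned-read total (allele-agnostic
depth), scaled to geometric mean 1. Within one sample the factor cancels
— it matters only across samples.

**The imbalance test** is a deliberately simplified stand-in for a
genome-wide shrinkage-based Wald test: a log-linear GLM
`count ~ allele * condition` with a *common* moment dispersion (pooled
ratio-of-sums over the four design cells; Poisson fallback when the
estimate is non-positive), testing the interaction coefficient. Two
numerical points:

* the pooled moment estimator is used because averaging per-cell
  dispersion ratios is far noisier at n = 3 replicates;
* p-values come from the GLM summary's own reference — t on the residual
  degrees of freedom when dispersion is estimated. A plain normal
  reference is anticonservative at 2-3 replicates (measured ≈ 0.095
  type-I at α = 0.05 in the calibration world) because dispersion
  uncertainty is ignored; the t reference restores calibration (≈ 0.056)
  at a negligible power cost (0.998 at a 4-fold allelic-ratio shift).

Calibration world, chosen once: 5,000 assigned reads per cell, NB
dispersion 0.05, 3 replicates — typical for targeted allelic counts over
biological replicates. No numerical equivalence to any external package
is claimed.

**Methylation.** Bisulfite conversion leaves methylated C as C and
converts unmethylated C to T, so per CpG the methylation level is
C/(C+T) over covering reads, other bases ignored. Reads are assigned to
an allele by majority vote over the (typically two) discriminating
variants they cover; ties and uninformative reads are excluded — the
defensible default where no tie policy is established.

## 4. qPCR statistics

ΔCt = Ct(target) − Ct(housekeeping) per sample. Fold change is
2^−(ΔCt − mean(ΔCt_ref)): the arithmetic mean of reference ΔCt in the
exponent *is* the geometric mean of reference expression values (exact
identity, asserted). Fold changes are invariant to global Ct shifts.

Differential testing fits, per target, a linear mixed model of ΔCt with
fixed condition effects and a per-replicate random intercept (absorbing
systematic between-replicate shifts), compares against the no-condition
model by a likelihood-ratio test on ML fits, and applies
Benjamini–Hochberg across targets within the experiment (the grouping key
is configurable; BH is a hand-written step-up, cross-checked against
`stats::p.adjust` as an independent oracle). A single replicate falls
back to an ordinary linear model with a warning; a constant response
short-circuits to p = 1.

The calibration world uses 4 biological replicates (random-intercept sd
0.3 cycles), residual sd 0.2 cycles, and quadruplicate technical wells
per condition and replicate. The well count matters: with one measurement
per cell the asymptotic χ² reference for the LRT is anticonservative at
this size (measured ≈ 0.13 type-I), a generic small-sample LRT effect,
not a mixed-model defect; quadruplicate plating — standard qPCR practice
— gives 32 observations and calibrated tests (≈ 0.056). Power for a
one-cycle shift at this noise level is essentially complete.

## 5. smFISH quantification

**Segmentation** is 2D on maximum-intensity projections (chosen for
robustness at this scale): Otsu threshold on the nuclear channel for
nuclei, on the FISH channel (diffuse cytoplasmic signal) for cell bodies
with a nuclear-dilation fallback, connected-component labeling, then
seeded growth of cell labels outward from nuclei over the cell mask — a
geodesic-distance watershed that splits touching cells along the midline
between their nuclei. The Otsu implementation takes the *middle* of a
plateau of the between-class variance, so clean bimodal images threshold
mid-gap rather than at the background edge.

**Spot detection** follows the fixed-sigma iterative Gaussian-mask
scheme; the parameters the original description leaves open are set here
as: PSF sigma 1.5 px lateral / 1.0 plane axial; candidate threshold 5
robust sds (MAD) above the median; local background from a 3-5 sigma
ellipsoidal shell; convergence at < 0.01 px movement or 20 iterations;
candidates closer than 1 sigma merged keeping the brighter. Four
numerical hardenings matter in crowded or thin stacks (each was driven by
a planted-truth failure and is covered by tests): the axial baseline per
(y,x) column is the 25th percentile along z (a spot spanning near half of
a thin stack contaminates the column *median*, which then subtracts a
scaled copy of the spot's own lateral profile); the refinement window is
±2 sigma (a ±3 sigma window lets a neighbor at the 5 px resolution limit
drag centers toward the blend); shell voxels above median + 3 robust sds
are trimmed before the background median (neighboring spot cores);
refined peaks whose amplitude falls below the candidate threshold are
rejected as clipped-window artifacts. Reported intensity is the
background-corrected integrated intensity (amplitude × Gaussian volume),
so detection is intensity-scale equivariant.

**Classification.** Spots map to cells by their (y,x) center; zero-spot
cells are excluded (in practice they indicate failed segmentation) and
tallied. The single-RNA normalizer is the median cytoplasmic spot
intensity pooled over all cells; per cell the brightest (MS2, one tagged
allele) or two brightest (Sox2, two alleles) nuclear spots are candidate
transcription sites, active iff ≥ 2.5 RNA equivalents (boundary
inclusive). Cells with fewer nuclear spots than alleles contribute
zero-intensity inactive calls for the missing alleles, which keeps the
active-allele fraction well defined.

**Simulator.** Disk cells with concentric nuclei on a jittered grid;
cytoplasmic single RNAs (lognormal intensity around 1 RNA, sd 0.15 in
log), nuclear sites active with probability 0.3 at 4-8 RNAs, otherwise
silent or a dim 0.2-1.2-RNA focus; 27 z-planes as in a typical
acquisition; Gaussian read noise at SNR 10 per single RNA over a
constant sCMOS-like camera offset of 100 counts (so noise is Gaussian,
not zero-clipped); planted spots keep ≥ 5 px mutual distance so truth
matching is unambiguous. Not emulated: aberrations, z-dependent PSF,
autofluorescence texture, cell-shape irregularity — a green test shows
the detector and the ≥ 2.5-RNA rule recover planted truth under Gaussian
optics, not robustness to those artifacts.

## 6. Interfaces and formats

FASTA/FASTQ through Biostrings; BED/bedGraph through
rtracklayer/GenomicRanges; SAM/BAM through Rsamtools/GenomicAlignments;
tables as TSV. Multi-page TIFF support is a minimal built-in codec
(uncompressed little-endian 32-bit float grayscale, one strip per page)
because no R TIFF package is available in the target environment; it
round-trips the package's own stacks and is readable by standard
scientific TIFF readers. The `alleloop` script under `inst/cli/` exposes
simulation, the 4C pipeline, qPCR, allelic and smFISH quantification as
subcommands.

## 7. Known limitations

* One shared coordinate system for both haplotypes; no liftover, no
  haplotype-specific indels.
* The imbalance test is not a reimplementation of the genome-wide
  shrinkage machinery it stands in for; it is validated only by its own
  simulation calibration.
* The naive read placer serves synthetic data only; real reads must be
  aligned externally.
* Segmentation is 2D; overlapping cells in dense fields are split by
  geodesic distance, not intensity topography.
* Fragment maps are built in memory per sequence; genome-scale (mm10)
  maps are supported in principle but untested beyond toy scale.
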