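# alleloop

Allele-resolved 4C-seq contact quantification, with the companion
quantifications used alongside enhancer–promoter loop perturbation
experiments in F1 hybrid (129 × CAST) mouse embryonic stem cells.

## The problem

Circular chromosome conformation capture (4C-seq) measures how often a
chosen *viewpoint* locus (for example a gene promoter) touches every other
restriction fragment in cis. In an F1 hybrid line the two parental
chromosomes differ by a single-nucleotide variant roughly every 135 bp, so
reads can be split by allele and the contact profile of each chromosome
measured separately — e.g. to ask whether an enhancer–promoter loop such as
*Sox2*–SCR responds to a perturbation on only one allele.

The pipeline implemented here follows the standard high-resolution 4C
design with a DpnII (primary) / Csp6I (secondary) double digest:

1. **Fragment map** — scan the sequence for primary-motif occurrences and
   cut at each; a fragment is *valid* only if a secondary site lies fully
   inside it (blind fragments are retained but excluded from
   normalization).
2. **Demultiplex** — match reading primers against read prefixes with up
   to 2 mismatches; trim each read to the primary restriction site; split
   reads by the sequenced base at the allele-discriminating SNV on the
   mate.
3. **Count** — a paired, uniquely mapped read counts for a fragment iff
   its start or end coincides exactly with a fragment boundary.
4. **Normalize and smooth** — counts per million over included cis
   fragments, then a centered 21-fragment rolling mean.
5. **Quantify** — mean normalized signal over the fragments of a region of
   interest (e.g. the SCR enhancer cluster), per allele and replicate.

Companion modules implement the surrounding quantifications: allele
assignment by dual-alignment score (ties unassigned), allelic proportions
with unassigned-read size factors, a simplified negative-binomial Wald test
for allele × condition imbalance, per-CpG bisulfite methylation ratios
C/(C+T) on allele-split amplicon reads, ΔCt / 2^–ΔΔCt qPCR statistics with
a replicate random-intercept mixed model (likelihood-ratio test,
Benjamini–Hochberg correction), and smFISH spot detection (Otsu + seeded
watershed segmentation, 3D Gaussian-mask localization) with the ≥2.5-RNA
active-transcription-site rule.

A synthetic-data module generates every input with known ground truth — a
diploid toy locus, 4C libraries from a distance-decay × loop-enrichment
contact model, negative-binomial count tables, Ct tables, and 3D image
stacks with planted Gaussian spots — so the whole pipeline is testable
without any external download.

## Worked example

Simulate a 100 kb diploid locus carrying a 4-fold 129-specific loop between
the viewpoint and the target region, generate a 100,000-read-pair library,
and run the pipeline end to end:

```r
library(alleloop)

locus <- make_diploid_locus(seed = 1)
locus
#> DiploidLocus: 100000 bp, 755 SNVs, 372 fragments (199 valid), viewpoint fragment 180

lib <- simulate_4c_library(locus, contact_model(n_reads = 100000L), seed = 1)
res <- run_synthetic_4c(lib, locus)

res$qc
#>          matched unmatched_primer        ambiguous         no_motif
#>            99600                0                0              400

subset(res$quants, allele %in% c("129", "CAST"))
#>    region viewpoint allele replicate n_fragments value
#> 3  target       vp1    129      <NA>          22  8334
#> 4 control       vp1    129      <NA>          17  2002
#> 5  target       vp1   CAST      <NA>          22  2454
#> 6 control       vp1   CAST      <NA>          17  2249
```

The QC tally partitions the input exactly (99,600 + 400 = 100,000; the 400
lost reads carry sequencing errors in the restriction motif). The `value`
column is the mean CPM per fragment: the 129 allele is strongly enriched in
the target region (8334 vs 2454, a contact ratio of 3.40 — the planted
4-fold loop, compressed slightly because each allele's library is
renormalized), while the mirror-distance control region is allele-neutral.

Testing a planted allelic-ratio shift (0.5 → 0.8) in a count table:

```r
tb <- simulate_allelic_counts(
  features = "Sox2",
  ratio = matrix(c(0.5, 0.8), 1, 2,
                 dimnames = list("Sox2", c("129ON_CASTOFF", "129OFF_CASTON"))),
  seed = 1)
imbalance_test(tb)
#> Allelic imbalance Wald test (negative binomial, dispersion 0.04163)
#>   interaction log-fold change: 1.559 (se 0.2483), z = 6.279, p = 0.0002381
```

The recovered interaction (1.56 on the log scale, ≈ e^1.56 ≈ 4.8-fold odds
shift; truth 4-fold) is significant at n = 3 replicates.

A command-line front end covering simulation, the 4C pipeline, qPCR,
allelic and smFISH quantifications is installed at
`system.file("cli", "alleloop", package = "alleloop")`; run it without
arguments for usage.

## Vignette

`vignettes/alleloop-methods.Rmd` describes the models, the synthetic
worlds and their parameters, numerical choices, and known limitations.
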