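---
title: "Chimeric-read NIPT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chimeric-read NIPT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraNIPT)
```

## The problem and the library design

Non-invasive prenatal testing detects fetal trisomies 13, 18 and 21 from
cell-free DNA (cfDNA) in maternal plasma. cfDNA is short — maternal
fragments cluster around 166 bp and fetal (placental) fragments around
143 bp — so on long-read sequencing chemistry most of each read is wasted.
The chimeric-read design works around this: cfDNA is enzymatically
fragmented further, pieces of 40–50 bp are retained by two-sided size
selection, and the pieces are randomly self-ligated into molecules longer
than 300 bp. A single PE250 read pair over such a molecule then carries
several independent genomic tags instead of one. A parallel SNP amplicon
library over high-MAF sites supplies the fetal-fraction estimate that
gates the aneuploidy call.

`chimeraNIPT` implements this workflow end to end on simulated data with
known ground truth: library simulation, deconstruction of chimeric
alignments into filtered fragment tags, dosage calling by chromosomal
Z-scores, fetal-fraction and fetal-sex estimation, SNP panel design
filters, and diagnostic-performance arithmetic.

## The aneuploidy model

Per sample, filtered fragment tags are counted into fixed-width genomic
bins (50 kb at human scale; toy genomes are split into ~1000 bins so that
per-bin counting statistics behave comparably — see
`default_bin_size()`). Three variation-reduction steps are applied in a
fixed order:

1. **Peak correction** — per sample, bins above mean + 3 SD of the
   sample's non-zero bins are reset to the sample mean. Removes isolated
   pile-up artefacts.
2. **GC correction** — bins are stratified by GC rounded to 0.01 and each
   stratum is rescaled to the sample's global mean bin count. Strata with
   fewer than 10 bins are left alone (their stratum mean is too noisy to
   be a correction factor).
3. **Chi-squared correction** — controls are scaled to a common total;
   bins whose between-control reduced chi-squared exceeds 3.5 are damped
   by that factor in every sample, and bins with zero control mean are
   masked everywhere.

The test statistic is the chromosomal fraction: counts on the target
chromosome divided by counts on all autosomes *except* 13, 18 and 21.
Excluding the three testable chromosomes (and the sex chromosomes) from
the denominator means a real trisomy cannot deflate its own normaliser.
The fraction is standardised against a control cohort; the call is
aneuploid iff `z > 3`, strictly and one-sided — the assay targets
trisomies, not monosomies, and z = 3.00 exactly is still euploid because
the exclusion rules are phrased as strict inequalities throughout
(similarly, a sample with exactly 2,500,000 filtered fragments or exactly
4% fetal fraction passes QC).

Under the dosage model a fetal trisomy multiplies the fetal sampling rate
of one chromosome by 1.5 (three copies instead of two), so the expected
chromosomal-fraction inflation is `(1 - ff) + 1.5 ff = 1 + ff/2`: a 10%
fetal fraction shifts the target fraction by 5%. With 2.5 million
filtered fragments, chromosome 21 carries roughly 1.5% of them, so the
counting coefficient of variation is about 0.5% and the expected case
z-score is around 9 — comfortably above threshold. This is why the sample
QC floor of 2.5 million fragments matters: at a tenth of that depth the
expected z drops near 3 and sensitivity collapses. The package's
cohort-scale evaluations therefore run at the 2.5e6-fragment floor the QC
itself enforces.

Performance is estimated by repeated case–control cross-validation: each
run tests all cases plus an equal number of randomly drawn controls,
standardised against the remaining controls, averaging sensitivity,
specificity and rank-statistic AUC (ties count 0.5) over 200 runs.

## Fetal fraction and fetal sex

At an *informative* SNP — mother homozygous, fetus heterozygous — the
fetal paternal allele is carried by half the fetal genomes, so its read
fraction is `ff/2` and the estimator is twice the minor-allele fraction,
aggregated as the **median** over informative SNPs. The median was chosen
over the mean because single misclassified sites (a maternal heterozygote
slipping through the read-fraction gate) produce gross outliers. Without
parental genotypes, informativeness is gated by the minor-allele read
fraction: floor 0.005 (below that, no paternal signal distinguishable
from error) and ceiling 0.20 (above that, the mother is likely
heterozygous herself). On simulated data, truth genotypes short-circuit
the gate. Samples whose mean panel coverage is below 50× are excluded.

The chromosome-Y route interpolates the observed Y-fragment share between
two anchors: the female background (mismapping floor; exactly zero in
simulation) and the share of a fully male cfDNA pool,
`(L_Y/2) / (L_autosomes + L_X/2 + L_Y/2)` (hemizygous X and Y). Clinical
implementations rely on externally calibrated formulas; the anchored
linear form is this package's documented stand-in, and it recovers the
simulated fetal fraction of male fetuses within ±0.02.
A fetus is called female when the SNP-based fetal fraction exceeds 4%
(enough signal to trust the absence of Y) while the Y-derived estimate
stays at or below 1%; male when the Y-derived estimate exceeds 2%; the
band between 1% and 2% is deliberately indeterminate.

## What the simulator emulates, and what it does not

The generator is a pure function of (configuration, seed). Its defaults
encode the study conditions: maternal/fetal length modes 166/143 bp
(SD 10), fragmentase target 43.8 bp, retention window 40–50 bp, chimera
floor 300 bp, PE250 reads, a repeat track covering half the genome,
a 102-SNP panel at ~5000× coverage, and a toy 24-chromosome genome with
human length proportions (1/1000 scale, ~3.1 Mb, for cohort work).

* **Fragmentation** is modelled as a Poisson number of cuts per parent
  (mean `length/43.8 − 1`) at uniform breakpoints. Only the outcome
  statistics of the real enzymatic step are known, so the cut model is a
  deliberate, simple choice. One consequence is worth stating plainly:
  with a *hard* 40–50 bp retention window, the conditional mean of
  retained pieces is ~44.8 bp for essentially any realistic cut rate —
  the mean of a narrow window cannot drop to 43.8 unless the piece-length
  density decays implausibly fast across it. A wet-lab 43.8 bp average
  reflects soft bead-based size selection with leaky tails, which the
  simulator intentionally does not model (tests rely on the hard window:
  no emitted piece may be 39 or 51 bp). Tests therefore pin the
  simulator's retained mean at 44.8 ± 0.3 bp rather than 43.8.
* **Ligation** consumes pieces in random order without replacement,
  assigns each an independent ±50% orientation (both strands are observed
  in real chimeras), and closes a molecule as soon as it exceeds the
  length floor; an unfinished tail is discarded.
* **Reads** are exact prefix/suffix windows of the molecule with optional
  substitution errors; no adapters, indels, quality-score realism or PCR
  duplicates. The method never uses base-level variants from chimeric
  reads, so substitution-only errors suffice.
* **Truth alignments** stand in for the aligner: every covered part gets
  a record with soft-clip CIGARs, SA tags and MAPQ 60 (a configurable
  fraction can be planted with low MAPQ to exercise the filter). This is
  the one place where passing tests say the least about real data:
  genuine 40–50 bp tags frequently map ambiguously (MAPQ < 60) or not at
  all, so real per-pair yields of filtered tags (around 2.4 in clinical
  practice) sit well below the simulator's ~3.6 unique tags per pair. The
  round-trip tests validate the *deconstruction machinery*, not aligner
  behaviour.
* **Amplicon counts** draw maternal genotypes from Hardy–Weinberg at the
  panel allele frequency, one transmitted maternal allele plus a
  population paternal allele, Poisson depth and binomial allele counts.
  Amplicon dropout is exposed as a simple zero-depth probability; the
  real dropout mechanism is unpublished.
* The maternal genome has no Y chromosome; a male fetus is hemizygous
  X/Y. Mosaicism, sex-chromosome aneuploidies, multiple gestations and
  maternal malignancy are out of scope.

## Numerical and interface choices

* Coordinates are 0-based half-open internally and in BED/TSV output; the
  SAM writer emits 1-based coordinates per the format.
* Read-pair merging scans overlaps from 250 down to 20 in both innie and
  outie geometry, accepts the lowest mismatch density ≤ 0.20 with ties
  going to the larger overlap, and counts ambiguous bases as mismatches.
  Note the geometry bound: PE250 with a minimum overlap of 20 cannot
  merge molecules longer than 480 bp, so "unmerged" only brackets the
  molecule length from below; the molecule-length floor is exposed as a
  parameter rather than resolving the 460-vs-480 bp ambiguity.
* A fragment overlapping a repeat or amplicon interval by ≥ 1 bp is
  removed (RepeatMasker-style convention; full containment would be
  weaker). Removal reasons are reported first-failing in the fixed order
  mapping-quality → repeat → amplicon → second-pass flags.
* MAPQ is taken from each record itself (primary or supplementary), not
  inherited from the primary.
* The amplicon-region rule differs by library on purpose: chimeric-read
  fragments *inside* amplicons are discarded (they would double-count the
  targeted loci), while amplicon libraries keep only on-target reads.
* The Wilson interval uses the normal quantile at full precision
  (1.959964…), not 1.96; for k = n the lower bound reduces to
  `n/(n + z²)`.
* The exact Hardy–Weinberg test enumerates the conditional distribution
  of heterozygote counts given the allele counts in log space; the
  two-sided p sums all outcomes no more likely than the observed one.
* LD pruning greedily removes the later SNP of a pair at r² ≥ 0.5 within
  50-SNP windows stepping by 5; constant genotypes are treated as
  unlinked. Primer rules pin the unpublished details: "repetitions" means
  ≥ 4 consecutive dinucleotide units, and "a large number of GC at the
  3′ end" means more than 3 of the last 5 bases.
* The chr6 p-arm (HLA) exclusion is a configurable interval ending at
  59.8 Mb, since exact boundaries are not published.

## Problem sizes

The test suite and the acceptance script run on toy genomes: unit tests
mostly on a 2-chromosome 100 kb genome or a 1/5000-scale human-shaped
genome (~620 kb), and the cohort evaluations on the 1/1000 scale (~3.1 Mb)
with 20 controls + 5 trisomy-21 cases at fetal fraction 0.10 and 2.5e6
fragments per sample, 200 cross-validation runs. The round-trip check
uses ~12,000 chimeric molecules (~140,000 truth parts). Fetal-fraction
recovery uses 200 replicates of 30 informative SNPs at 5000× per point of
the ff grid {0.04, 0.08, 0.12}. These sizes were chosen so each
evaluation completes in about a minute while keeping per-bin and per-SNP
counting statistics in the same regime as clinical data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, fetal_fraction = 0.10,
                  n_cfdna_fragments = 2.5e6)
report <- run_pipeline(cfg, n_controls = 20, n_cases = 5,
                       trisomy_chrom = "chr21")
report$cv          # cross-validated sensitivity/specificity/AUC
subset(report$z, is_case)   # per-case z-scores and calls
```

## Known limitations

* No aligner is embedded: real two-pass mapping output is consumed as
  SAM/BAM, and on simulated data the truth writer replaces the first
  pass. Mappability-driven tag losses are therefore absent from all
  simulated yields.
* The anchored linear chromosome-Y estimator and the read-fraction
  informativeness gate are documented stand-ins for unpublished details.
* GC coupling between fragment sampling and genome composition is not
  simulated, so the GC correction is exercised mechanically (its
  closed-form behaviour is unit-tested) rather than against a planted
  bias.
* Fetal-fraction estimation from fragment-length profiles or nucleosome
  footprints, segmental CNVs, and sex-chromosome aneuploidies are out of
  scope.
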