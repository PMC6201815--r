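---
title: "netsplice: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netsplice: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsplice)
```

## The measurement this package models

Mammalian native elongating transcript sequencing (mNET-seq) immunoprecipitates
RNA polymerase II complexes from micrococcal-nuclease-solubilized chromatin and
sequences the 3′ ends of the RNA they protect. Each read's 3′-most transcribed
base is one of two things: the terminus of nascent RNA in the Pol II active
site, or the free 3′-OH left by the first catalytic step of splicing — cleavage
at a 5′ splice site, which deposits the upstream exon, still spliceosome-bound,
with its last nucleotide exposed. Single-nucleotide 3′-end coverage therefore
shows sharp spikes at exon 3′-terminal bases (5′ ss intermediates) and, much
more rarely, at intron 3′-terminal bases (released lariats). Because MNase
digests unprotected RNA, the aligned read length is a footprint: roughly 27 nt
for Pol II alone and roughly 60 nt for Pol II with an engaged spliceosome.

The package turns strand-specific alignments (SAM or BED12) and an
Ensembl-dialect GTF into: 3′-end count tracks, footprint-length histograms,
splicing-intermediate and pause peak calls, spliced/unspliced intermediate
statistics, percent-spliced-in (PSI) inclusion estimates, snRNA association
counts, detergent-sensitivity ratios, and label-free IP-MS enrichment tables.
A synthetic-data generator with planted ground truth makes every stage testable
without any external download.

## Coordinate and strand conventions

All internal coordinates are 0-based half-open. GTF input (1-based closed) is
converted once, at parse time; BED is read and written natively. The
3′-terminal base of an interval is `end - 1` on the plus strand and `start` on
the minus strand. Readers take a `strandness` flag describing library
chemistry — `"reverse"` (default; the stored strand is the opposite of the
transcribed RNA, the common NET-seq convention) or `"forward"`. The simulator's
writers use the same default, so write/read round-trips are strand-neutral.

## Peak calling

A position is a splicing-intermediate peak when its raw 3′-end count is

* at least `min_reads` (default 4) reads,
* at least `k_sd` (default 3) standard deviations above the feature mean, and
* strictly above the mean.

The comparison window is the whole exon or intron containing the position; the
mean and the *population* (denominator *n*) standard deviation are computed
over every nucleotide, zeros and the candidate included. The strict
above-the-mean requirement means uniform features (sd = 0) never produce
peaks. `call_ss_peaks()` tests only feature 3′-terminal nucleotides (exon
terminal → 5′ ss peak, intron terminal → 3′ ss peak); `call_pause_peaks()`
removes the last 3 exonic and first 3 intronic nucleotides (transcription
direction), recomputes the statistics on the remaining EL − 3 positions, and
reports every qualifying position. Eligible features are exons/introns of
expressed genes that do not intersect a non-identical feature of another
isoform on the same strand. Replicate consensus (`consensus_peaks()`) is exact
intersection on (chromosome, strand, position, kind).

The minimum-coverage test applies to raw counts, not RPM; the threshold rule
is scale-free in the sense that multiplying all counts by a constant does not
change which positions pass the 3-sd comparison, but the 4-read floor
deliberately is not.

## Spliced and unspliced intermediates

Candidate intermediate reads are uniquely mapped, mismatch-free reads whose 3′
end falls exactly on an exon's 3′-terminal base. For each exon with an
upstream junction:

* **SR** (spliced): the read qualifies as a spliced read — every block gap
  matches an annotated intron exactly and at least 9 aligned nt flank each
  junction (the strict reading of "more than 8 nucleotides") — across the
  exon's upstream junction;
* **UR** (unspliced): the read is a single contiguous block extending at least
  1 nt upstream past the exon's 5′ boundary into the preceding intron;
* **ambiguous**: contained entirely in the exon (it cannot witness either
  state), stopping exactly at the 5′ boundary, or spliced across some other
  junction.

spliced% = 100·SR/(SR+UR), defined only when SR + UR ≥ 10. The ambiguous class
is reported separately, so the alternative convention (UR = "no junction")
can be reconstructed from the output. Group comparisons (constitutive vs
skipped exons; U2- vs U12-preceded exons) use an unpaired Mann–Whitney
rank-sum test for location and a two-sample Kolmogorov–Smirnov test for the
distributions; a Wilcoxon *signed-rank* test is undefined for unpaired groups
of unequal size, so the rank-sum test is the implemented location test.

## PSI

For an internal exon, with IJ_up/IJ_down the read counts on its two inclusion
junctions and EJ the summed counts of junctions strictly containing the exon:

PSI = ((IJ_up + IJ_down)/2) / ((IJ_up + IJ_down)/2 + EJ)

The averaging reflects that an included molecule exposes two junctions while a
skipping molecule exposes one. Structural filters, applied in a fixed order
with the first failing reason recorded: alternative 5′/3′ splice-site exons;
exons overlapping another exon on the same strand; exon shorter than 100 bp;
preceding intron (transcription direction) shorter than 100 bp. The coverage
filter defaults to "each inclusion junction ≥ 5 reads"; the alternative
reading of the coverage rule (averaged inclusion *and* exclusion each ≥ 5) is
available behind `coverage_rule = "inclusion_and_exclusion"`. Skipping
junctions need not be annotated; an exon with no skip reads simply has EJ = 0.

## Coverage-level statistics

* **RPM** divides by the number of accepted (uniquely mapped) reads. Whether
  published denominators counted all mapped reads is unknowable from the text;
  unique-only is used consistently and recorded in the coverage object.
* **RAD** (read average density) = TR/(EL − 3), with the 3 transcription-
  direction 3′-most exonic (5′-most intronic) positions removed from TR
  because intermediates concentrate there; exon TR can additionally subtract
  spliced-read 3′ ends. Features with EL ≤ 3 or TR = 0 are excluded.
* **snRNA counts** sum 3′-end reads in gene intervals padded by 5 nt on both
  sides (annotation-boundary tolerance); genes with log2(RPM) ≥ 1 in a
  designated reference sample form the expressed set, and class totals sum
  expressed members only.
* **Expressed genes**: a kernel-density estimate (Silverman bandwidth,
  512-point grid) of log2 FPKM over transcripts with FPKM > 0; the threshold
  is the density minimum between the two highest local maxima, falling back to
  log2 FPKM = 0 with a warning when the density is unimodal. A gene is
  expressed when any transcript exceeds the threshold — gene-level aggregation
  is not specified anywhere authoritative, and the permissive union avoids
  discarding genes carried by one dominant isoform.
* **Treatment ratios** (detergent sensitivity) are RPM ratios over region
  sets; a zero untreated RPM yields an explicit undefined flag, never 0.

## IP-MS enrichment

Intensities are log2-transformed; missing values are imputed per sample from a
normal distribution downshifted 1.8 observed-SDs with width 0.3 observed-SDs —
the standard label-free convention for missing-not-at-random dropouts, where a
missing value most plausibly means "below detection". Samples are then median-
centred. Per protein, a Welch two-sample t-test compares IP to mock replicates
(pooled-variance optional), with Benjamini–Hochberg adjustment across proteins
(a SAM-style permutation FDR is the configurable alternative). A protein is
enriched when q ≤ 0.05 *and* its log2 fold change is positive — enrichment is
one-sided by meaning. Zero-variance proteins with equal means get p = 1.

## The synthetic world

`sim_config()` fixes a compact but structurally complete world:

* ~40 genes (4–8 exons, alternating strands) with first exons ~300 nt
  (log-normal, most ≥ 200 nt so they qualify for footprint windows), internal
  exons ~120 nt and introns ~800 nt (log-normal), plus planted short
  (< 100 nt) exons and introns, one skipped or alternative-splice-site isoform
  in a subset of genes, nested same-strand single-exon genes (planting the
  PSI overlap exclusion), a U12-labelled intron subset, snRNA-like single-exon
  genes, and a small silent-gene fraction giving the FPKM table its low mode.
* Background nascent 3′ ends are i.i.d. Poisson (λ = 2 per nt) across each
  gene span, with contiguous bodies clipped at the gene 5′ end.
* Splicing intermediates end exactly on exon terminals, Poisson(20) per
  peak-bearing exon; each is spliced across the upstream junction with
  probability ψ_true (blocked body, ≥ 9-nt overhang guaranteed) or contiguous
  into the upstream intron; reads shorter than the exon are contained and
  therefore ambiguous by design.
* Footprint lengths come from truncated-normal mixtures — (27, sd 4) on
  [18, 40] and (60, sd 8) on [40, 100] — weighted 0.9/0.1 in short-library
  mode and 0.1/0.9 in long mode. The short library applies the gel selection
  20–60 nt to realized aligned lengths; sub-20-nt TSS-clipped fragments are
  physically absent from a 20–60 gel slice, which is exactly why the
  short-fraction statistic (≥ 85% in 18–40 nt) holds in the source data. For
  the long library the observed aligned lengths (40–100 nt, mode 60) are
  shorter than the gel-selected RNA (60–160 nt), so its effective
  aligned-length window is (40, 160): a hard cut at 60 would contradict the
  observed range and truncate the mode it is supposed to reproduce.
* Detergent treatment binomially thins intermediate and snRNA reads by
  `treatment_scale`, drawing base counts and per-source read lengths on
  separate named substreams so a treated run shares the untreated run's
  background stream exactly (common random numbers for paired comparisons).
* Nucleoplasmic junction counts: each inclusion junction gets
  Binomial(depth, ψ_true) reads and each internal exon contributes a skip
  junction with Binomial(depth, 1 − ψ_true) reads. This is the generative
  model under which the canonical PSI estimator is unbiased; the
  "split-the-inclusion-reads" alternative makes the estimator converge to
  ψ/(2 − ψ) and cannot reproduce ψ at large depth.
* ψ_true is drawn once per gene, uniform on [0, 1], and shared by the gene's
  exons. Inclusion junctions are shared between adjacent exons, so
  per-exon-independent truths admit no coherent single-count-per-junction
  table; per-gene truth keeps the marginal exon-level distribution uniform
  while making the junction table internally consistent.
* Proteomics: log2 intensities are normal around protein base levels
  (mean 25, sd 2), shifted by the planted log2 fold change (default 2, i.e.
  4-fold, in 100 of 2,000 proteins) in IP replicates, with logistic
  missing-not-at-random censoring centred at 22.5.

What the generator does **not** emulate: read sequences (no internal-priming
artifacts — the TGGA/AGAT signature filter therefore ships off by default and
is exercised only when sequence input exists), sequencing errors, PCR
duplicates, multi-mapping ambiguity, novel junctions, overdispersed coverage,
or peptide-level proteomics structure. A green recovery test establishes that
the pipeline inverts *this* generative model; it does not establish robustness
to alignment artifacts the model omits.

## Measurement and harness choices worth knowing

* The planted-peak recovery harness disables the gel size selection so the
  realized count process matches its stated world (spikes of rate ≥ 20 over
  Poisson(2) background) exactly; default-world simulations keep selection on.
* Footprint modes are estimated with `modal_length_smooth()` (3-nt
  moving-average argmax). The 60-nt component's length distribution is
  flat-topped, so the raw single-bin argmax wanders several nt by Poisson bin
  noise alone; the smoothed argmax estimates the same population mode with
  variance small enough to resolve a ±2 nt tolerance.
* Two recovery bounds are stated tighter than their own sampling noise allows
  and stay red by design, with the analysis in the repository's decision
  notes: (i) spliced% recovery to < 3 pp mean absolute error from 50
  Bernoulli(ψ) reads per exon — the estimator is exact given the reads, and
  binomial sampling alone contributes ≈ 4.4 pp; (ii) ≥ 0.9 BH-sensitivity for
  4-fold effects with sd 0.3 at 3 vs 3 replicates — a plain t-test at 2–4
  residual degrees of freedom cannot reach it even on complete data (Welch
  ≈ 0.1, pooled ≈ 0.7). The accompanying tests verify instead that both
  estimators are unbiased and that the attainable halves of those criteria
  (exclusion rules, null FDR control) hold.
* All generators are pure functions of (config, seed); named substreams keep
  stages independent. Derived seeds stay below 2³¹.

## Known limitations

The annotation model carries at most the isoform structure needed by the
implemented filters (no transcript biotypes, no CDS features). BAM input is
not parsed — convert to SAM or BED12 first. The pause caller reports all
qualifying positions with no FDR control or width estimation, matching the
single-nucleotide definition it implements. PSI and intermediate analyses
consider annotated junctions only.
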