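---
title: "Quantifying large-scale on-target genome-editing damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying large-scale on-target genome-editing damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ontarget)
library(dplyr)
```

CRISPR-Cas9 editing at a single target site can produce much more than the
small indels and precise knock-ins that standard short-read amplicon
sequencing reports. Kilobase-scale deletions around the cut site, loss of a
whole chromosome arm, and copy-number changes all escape a 150–250-bp
amplicon window entirely — and, worse, reads from damaged alleles often fail
to amplify, silently inflating the apparent efficiency of the desired edit.
This package implements four complementary quantification workflows that
together make this damage visible, along with simulators that generate each
input type with known ground truth.

This vignette explains the models and procedures, the parameters that
matter, the design decisions taken where the underlying methods left
choices open, and what the synthetic data do and do not establish.

## Long-read amplicon deletion profiling

Long-range PCR around the cut site (amplicons of several kb) followed by
long-read sequencing captures deletion alleles that short amplicons miss.
The analysis is deliberately length-based rather than alignment-based:
after strict filtering, the deficit of a read's length below the expected
unedited amplicon length *is* its deletion size.

Filtering runs in three rounds, mirroring adapter-trimming practice:

1. **End-to-end amplicons.** A read must carry the forward primer at its
   5' end and the reverse complement of the reverse primer at its 3' end;
   both are trimmed. Reads are strand-canonicalized first (a read failing
   the 5' check is retried as its reverse complement). Matching is
   anchored semi-global edit distance, tolerating
   `ceiling(error_rate * primer_length)` substitutions plus indels, with
   `error_rate = 0.1` by default — the conventional tolerance of
   error-tolerant trimmers. The exact tolerance is a configuration knob,
   since long-read error rates vary by chemistry.
2. **Locus identity.** The trimmed read must begin and end with the 30-bp
   genomic sequences immediately inside the primer binding sites, matched
   with the same tolerance. These anchors are genomic sequence and are not
   trimmed. This rejects off-locus amplification products.
3. **Size cap.** Reads longer than the expected unedited (trimmed) length
   plus a +20-bp buffer are discarded; the buffer absorbs residual
   long-read indel error. When the experiment includes an HDR knock-in of
   known size, the cap is raised by that insertion size — otherwise every
   knock-in allele, which is by construction longer than the unedited
   amplicon, would be discarded by the oversize rule. This reconciliation
   of the oversize filter with knock-in quantification is a deliberate
   design choice of this package.

From the survivors, `compute_deletion_profile()` derives per-read deletion
sizes, a deletion-size survival curve, and the frequency of deletions
above a threshold (1 kb by default, the conventional boundary for
"kilobase-scale"). HDR alleles are called purely by length: a read within
±20 bp of (unedited length + insertion size) counts as HDR.

```{r longread-example}
spec <- random_amplicon_spec(unedited_length = 3500, seed = 11)
reads <- sim_long_reads(
  spec, n_reads = 1000,
  deletion_fraction = 0.30, substitution_rate = 0.02,
  indel_noise_rate = 0.03, contaminant_fraction = 0.02,
  reverse_strand_fraction = 0.5, seed = 42
)
res <- run_longread_pipeline(reads, spec)
res
```

As a quality-control contract, the surviving reads should derive almost
entirely from the target locus. Rather than aligning survivors to a
reference genome, `on_target_fraction()` computes each survivor's global
identity to the unedited amplicon core with a banded alignment; in a
properly configured workflow well over 95% of survivors exceed 80%
identity, while off-locus contaminants (which carry no primers) are
eliminated in round 1.

**What the simulation emulates — and what it does not.** The read
simulator produces primer-flanked amplicons with i.i.d. per-base
substitutions (default scenario 2%) and 1–2-bp indels (3%), deletion
alleles spanning the cut site, fixed-size insertion alleles, off-locus
contaminants without primers, and both strands. It does not model
homopolymer-dependent error, PCR chimeras, or the amplification bias
against long alleles that affects real libraries; recovery of a planted
30% deletion fraction to ±0.03 therefore demonstrates correctness of the
quantification arithmetic and robustness to uniform noise, not immunity
to amplification bias (which the long-read assay itself cannot remove).

## Short-read HDR/indel classification

For knock-ins marked by a 12-nt substitution barcode, reads are
classified by a fixed pair of 20-nt anchors that must occur exactly
32 bp apart. Inside that gap a 15-mer window is compared to the wild-type
reference `CCTCACAGTTGCCAT` by Hamming distance: at distance ≥ 11 the
read is an HDR barcode allele, below that it is unedited. Reads in which
the anchor spacing is broken — typically by an indel — are globally
aligned to the wild-type amplicon (match 2, mismatch −1, gap open −5,
extend −1; standard parameters, disclosed for reproducibility) and called
*indel* when any inserted or deleted base overlaps a 30-bp window
centered on the cut site, else *unclassified*.

Three choices here were genuinely open:

- **Position of the 15-mer in the gap.** It is computed at configuration
  load by exact search within the wild-type amplicon's gap, rather than
  being a hand-entered coordinate; the packaged spec places it at offset 8.
- **Anchor matching is exact by default.** A mismatch budget is available
  (`anchor_max_mismatch`) for robustness studies, but the default mirrors
  the strict anchor definition. Sequencing errors inside an anchor push a
  read to the indel caller, which then reports it *unclassified*; such
  error-bearing reads are almost always removed anyway by the allele
  filter below.
- **Partial HDR.** Defined operationally as alleles carrying at least the
  threshold number (11) but not all 12 barcode substitutions; they reach
  the Hamming threshold and are therefore reported inside the HDR
  fraction, matching how partial integration is aggregated in practice.

`summarize_outcomes()` groups identical sequences into alleles and drops
alleles below 0.2% frequency before computing class fractions — the
allele-level reading of the low-frequency exclusion (the read-level
reading would be equivalent for recurrent alleles and is dominated by
sequencing noise for singletons). Class fractions are reported over
retained reads and sum to one.

```{r shortread-example}
cspec <- gapdh_class_spec()
sreads <- sim_short_reads(
  cspec, n_reads = 10000,
  hdr_fraction = 0.40, indel_fraction = 0.10,
  substitution_rate = 0.001, seed = 7
)
run_shortread_pipeline(sreads, cspec)
```

The simulator's indel alleles are small deletions and templated
duplications at the cut site — the recurrent allele classes end-joining
actually produces — so they survive the 0.2% filter as real indel alleles
do. Random-sequence insertions would instead fragment into singleton
alleles and be filtered; that regime is not what the filter is for.

## Chromosome-segment loss from single-cell residual expression

A cell that lost one copy of a chromosome segment expresses the genes in
that segment at roughly half dosage. With an edited and an unedited
population profiled by scRNA-seq, the workflow is:

1. QC-filter cells on total counts (default window 500–50,000) and
   mitochondrial fraction (default ≤ 0.2). These thresholds are
   configuration, not biology.
2. Library-size-normalize each cell, `log1p`-transform, and subtract the
   per-gene mean of the unedited cells from each edited cell.
3. Smooth each cell's residuals along every chromosome with a centered
   51-gene moving average (shrinking windows at chromosome edges), then
   exponentiate. "Subtraction" is thus interpreted in log space and
   re-expressed as a ratio-like scale with neutral baseline 1.0 — the
   only scale on which a 0.95 loss threshold is meaningful. Mitochondrial
   genes are excluded: they carry no positional copy-number signal.
4. Average the residual per cell over two segments: the *telomeric*
   segment from the chromosome start up to the target site, and the
   *comparison* segment covering the following 7 Mb. Segment boundaries
   follow the half-open convention `[start, site)` / `[site, site + 7 Mb)`,
   so a gene exactly at the target coordinate belongs to the comparison
   segment and no gene is double-counted.
5. A cell whose telomeric segment mean falls strictly below 0.95 is
   called a loss cell; the cohort loss frequency is the flagged fraction.
   Loss calls use the smoothed residuals — the same quantity the heatmap
   displays — since smoothing leaves the segment mean essentially
   unchanged while suppressing single-gene outliers.

Edited cells can also be Ward-clustered (Euclidean distance, a
deterministic algorithm) on their residuals over the telomeric genes,
which cleanly separates loss and non-loss populations when the loss is
real.

```{r sc-example}
sim <- sim_sc_experiment(n_edited = 300, n_unedited = 300,
                         loss_fraction = 0.20, seed = 5)
calls <- run_armloss_pipeline(sim$edited, sim$unedited, sim$genes)
calls
```

**Simulation regime.** The generator draws negative-binomial counts with
per-gene means uniform on [5, 30] and dispersion (`size`) 20 — a deeply
sampled, moderately overdispersed regime — over a deterministic gene map
with 150 genes in each of the telomeric and comparison segments. Loss
cells have every telomeric gene's expected expression multiplied by 0.5.
Under these conditions a planted 20% loss fraction is recovered to ±0.03
and the null false-positive rate stays below 5%. Real droplet scRNA-seq
is sparser and more overdispersed than this; with shallow data the same
0.95 threshold will trade sensitivity against false positives less
favorably, and the per-cell segment mean's variance — not the threshold —
is what controls that trade-off. The simulation validates the estimator,
not the information content of any particular dataset.

## Droplet digital PCR copy-number quantification

Droplets partition template molecules approximately Poisson, so the mean
occupancy of a channel follows from its negative fraction:
$\lambda = -\ln(1 - n_{+}/n_{\mathrm{tot}})$. Everything else is ratios,
in which droplet volume cancels and is therefore never needed:

- **Copy ratio**: $\lambda_{\text{target}} / \lambda_{\text{reference}}$,
  with the reference a locus on a different chromosome. Replicates are
  summarized ratio-first (per-replicate ratio, then mean ± s.d.),
  matching per-well instrument practice; a pooled-count mode is
  available.
- **Normalized CNV**: the condition's ratio divided by the unedited
  control's ratio; the control normalized against itself is exactly 1.
  The *fractional change* is this value minus 1, so a 14% average copy
  loss reads as −0.14.
- **VCN** (vector copy number): $2\,\lambda_{\text{vector}} /
  \lambda_{\text{reference}}$ against a diploid housekeeping locus.

```{r ddpcr-example}
edited  <- sim_droplet_assay(20000, lambda_target = 0.43,
                             lambda_reference = 1.0, seed = 1)
control <- sim_droplet_assay(20000, lambda_target = 0.50,
                             lambda_reference = 1.0, seed = 2)
normalized_cnv(copy_ratio(edited), copy_ratio(control))
```

A saturated channel (every droplet positive) is rejected rather than
extrapolated: it carries no information about $\lambda$. Zero positives
is a valid $\lambda = 0$; a zero *reference* is an error since every
reported quantity divides by it. Confidence intervals use the
delta-method normal approximation on the log scale, adequate at the
occupancies (0.1–1 copies per droplet) where assays are run.

## Numerical and reproducibility choices

- Fractions in all simulators are realized as exact counts
  (`round(n * f)`) by default, making recovery tests exact; a sampling
  mode exists for stochastic studies.
- Every simulator takes a `seed` and is byte-deterministic given its
  configuration: the same seed reproduces identical FASTQ files,
  matrices and tables. Analysis functions contain no randomness at all
  (Ward clustering included).
- Genomic coordinates are 1-based inclusive in all configurations;
  half-open arithmetic is used internally where segments are defined and
  is documented at the function level.
- Problem sizes in the test suite (hundreds to a few thousand reads,
  hundreds of cells) were chosen so the full suite exercises every
  contract at statistically meaningful scale while remaining quick to
  run; the package itself streams nothing and holds all inputs in
  memory, which is appropriate for amplicon-scale data but not for
  whole-genome inputs.

## Known limitations

- Deletion sizes come from read length, not breakpoint mapping; an
  allele with both an insertion and a deletion is summarized by its net
  length change, and non-HDR insertions are not separately called.
- Translocations and other inter-chromosomal rearrangements are out of
  scope; they require dedicated assays.
- The indel caller reports indel presence in the cut-site window, not
  full allele spectra or microhomology annotation.
- The residual-expression caller detects *expression* loss; a
  transcriptionally compensated segment loss, or expression loss without
  DNA loss, cannot be distinguished by this signal alone.
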