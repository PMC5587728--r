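---
title: "Methods: alternative polyadenylation analysis from 3' end reads"
author: "apatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternative polyadenylation analysis from 3' end reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatlas)
```

## The measurement model

3′ end sequencing captures fragments that end at a transcript's cleavage
and polyadenylation site. After reverse transcription the read begins
with a short run of Ts transcribed from the poly(A) tail; an aligner
cannot place those Ts on the genome, so they appear as a soft clip at
the read's 5′ side. Three facts drive the whole analysis:

* the first aligned base adjacent to that clip is the transcript's last
  templated nucleotide — the cleavage position, at single-nucleotide
  resolution;
* clipped Ts that happen to match the adjacent genomic sequence are not
  evidence of a tail (they could have been aligned, and genomic A/T
  stretches are exactly what internal priming artifacts look like), so
  they are subtracted before the tail is counted;
* cleavage is heterogeneous over a couple of dozen nucleotides, so raw
  cleavage positions must be clustered before they can be treated as
  "the" PAS of an isoform.

A read therefore qualifies as PAS-supporting (PASS) when it is a primary
alignment with MAPQ above 10 and at least two non-genomic 5′ Ts remain
after subtraction. Both thresholds are exposed
(`identify_pass_reads(min_tail=, max_mapq_rejected=)`) but their
defaults are the standard operating point of the assay. We count only
the contiguous T-stretch at the read's 5′ end; clip bases beyond the
first non-T are adapter or error sequence and never contribute.

Reads are assumed to be reverse complements of transcript 3′ ends: a
plus-strand gene yields a minus-strand alignment whose trailing
soft-clipped A-stretch is the tail in SAM orientation, and a
minus-strand gene a plus-strand alignment with leading clipped Ts. The
protocol convention is not universal, so the simulator can emit the
opposite (sense-read) convention via
`sim_config(read_orientation = "forward")`; the caller in this package
implements the 5′-T convention, and the two differ only in the SAM FLAG
strand bit.

## Atlas construction

Cleavage events are clustered per contig and strand by an iterative
greedy rule with a 24 nt window: repeatedly take the unclustered site
with the highest pooled count, absorb all unclustered sites within
±24 nt, and record it as the cluster's representative. Membership is
measured from the representative, not chained, so a cluster spans at
most 49 nt. Ties between equal-count sites are broken toward the 5′-most
position in transcript orientation, which makes the procedure fully
deterministic; the implementation is tested against a brute-force
re-derivation on a thousand random instances.

A cluster is kept when at least one sample supports it with **both** ≥ 2
reads **and** > 5% of the gene's reads in that same sample. Requiring
the two conditions jointly in one sample (rather than in any pair of
samples) is the stricter and more natural reading: a site backed by two
reads in a shallow sample and 6% abundance in a deep one has neither
kind of evidence anywhere. The filter is monotone in both thresholds.

Gene assignment requires the representative position to lie on the
gene's strand within the gene span or within a downstream extension
(default 4,000 nt — long enough for unannotated distal sites, short
enough to rarely reach a neighbor; configurable). When extensions of two
same-strand genes overlap, a span match wins over an extension match and
the nearer 3′ end wins among extensions. Region labels:
`three_prime_region` for the 3′-most exon plus the extension, `upstream`
for anything else inside the gene (introns, internal exons). Upstream
flanks (−40..−1) classify the poly(A) signal hierarchically: canonical
AAUAAA, else one of ten single-nucleotide variants (AUUAAA, UAUAAA,
AGUAAA, AAGAAA, AAUAUA, AAUACA, CAUAAA, GAUAAA, AAUGAA, ACUAAA;
configurable, as published variant lists differ), else A-rich (a
hexamer with ≥ 5 As, also configurable), else none.

## Quantification and regulation calls

Isoform expression is RPM — reads per million PASS reads in the sample —
so each sample's RPM column sums to exactly 10⁶ and gene RPM (the sum
over the gene's retained isoforms) is a partition of it. Changes between
samples are log2 RPM ratios with a pseudocount equal to one read at the
mean depth of the two samples, applied to both sides. This exact form
matters for two invariants: a unit absent from both samples has a
log2 ratio of exactly 0, and swapping sample labels flips only the sign.
Pass `pseudocount = 0` to disable (then filter zero rows yourself).

A transcript or gene is called regulated when |log2fc| > 1 (fold change
2) **and** the two compared samples together contribute more than 50 raw
reads — raw reads, not RPM, because reads are the evidence. The down/up
ratio, the low/median/high expression strata (quartiles of control-
sample gene RPM) compared by two-sample two-sided K-S tests, the
mRNA-vs-lncRNA comparison, and 1 − Pearson average-linkage sample
clustering all operate on these calls and ratios.

## APA statistics

For 3′UTR APA each gene contributes its two most abundant retained
3′-region isoforms (configurable in principle; the two-top rule is
standard practice and robust to weak third sites), labelled proximal and
distal in transcript orientation. The isoform × sample 2×2 count table
is tested with a two-sided exact conditional test — Fisher's exact test,
computed in a vectorized hypergeometric routine using the customary
relative slack of 1e−7 when comparing point probabilities, verified
against `stats::fisher.test` and against direct log-factorial
enumeration. Tables with a zero row or column margin carry no
information about *relative* usage and are flagged not testable rather
than given a p-value. BH FDR (threshold 0.05) is computed across
testable genes.

RED = log2((distal + 1)/(proximal + 1)); ΔRED = RED_kd − RED_ctrl.
Significant genes with ΔRED < 0 are shortened, ΔRED > 0 lengthened; an
optional |ΔRED| effect-size gate exists and defaults to off. The global
trend is log2((#shortened + 0.5)/(#lengthened + 0.5)); the 0.5 guards
empty classes, and the trend is flagged undefined when no gene is
significant at all. Because a deeper library mechanically wins more
small-p tables, the deeper sample's counts are first binomially
downsampled to the shallower sample's PASS total with a seeded draw
(switchable off via `equalize = FALSE`). Upstream-region APA aggregates
each gene's upstream clusters against its 3′-region clusters and runs
the same machinery; a positive shift of relative upstream usage in the
knockdown is "activated", a negative one "suppressed".

## Motif scoring

A PFM is a positions × (A,C,G,U) matrix of relative frequencies. Each
position carries information content I_p = 2 − entropy(f) bits, and a
window scores Σ_p f_{p,n(p)} · I_p, so conserved positions dominate and
uninformative positions contribute nothing; the score of any window
lies in [0, Σ_p I_p]. Ambiguous bases contribute 0 — conservative, and
it keeps every window defined. Scanning −100..+100 around a PAS gives
195 window scores; meta-profiles average them position-wise over a PAS
set and smooth with LOWESS, span 0.05. LOWESS robustness iterations are
**off** by default: a genuine motif concentrated at a fixed offset is a
sharp peak in the mean profile, and robustness iterations treat exactly
such peaks as outliers and flatten them (we observed the smoothed
maximum drift several nt off a planted offset with one iteration, and
land on it with none). Set `iter` to restore robust fitting for noisy
profiles.

The per-PAS upstream score averages the windows fully contained in
−100..−41 (starts −100..−47; 54 windows). Averaging only fully
contained windows avoids scoring sequence outside the stated region; a
`partial = TRUE` flag includes edge-overlapping windows for comparison.
One algebraic property is worth knowing: summing f·I window scores over
a region is, up to edge effects, a weighted *composition* statistic of
the region (each base contributes Σ_p f_{p,b} I_p to every window
covering it), so this score ranks sequences by how enriched they are in
the motif's preferred letters rather than by exact positional matches.
Percentile groupings (90th, or 10th/90th tails; linear-interpolation
quantiles, ties to the lower-score group) feed two-sided K-S
comparisons of expression changes. k-mer (k = 4) enrichment compares
per-sequence presence between a group and a background with Fisher's
exact test over all 256 k-mers in each of the four regions −100..−41,
−40..−1, +1..+40, +41..+100 (the downstream two mirror the stated
upstream pair). Signal-class composition between two PAS groups uses a
χ² homogeneity test, falling back to the exact test with a warning when
an expected cell drops below 1.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob. Defaults:
500 non-overlapping genes (2,500 nt, 1,000 nt 3′-most exon, 600 nt gaps)
on one contig of uniform random sequence; two 3′UTR PASs per gene
(~300 nt apart, jittered) plus an upstream-region PAS in 30% of genes at
15% baseline usage; 20% of genes labelled lncRNA; gene expression
log-normal with σ = 1.25 log2 units (set 0 for equal coverage);
two conditions ("ctrl", "kd") at 125,000 reads × 100 nt per sample
(~250 reads per gene per sample at equal expression); 30% of genes get a
−1.5 log2 shift of distal-PAS usage in the knockdown (multiplying the
distal usage by 2^shift and renormalizing, which moves the
distal/proximal log2 ratio by exactly the shift); cleavage jitter is
symmetric binomial on ±2 nt so that clustering is actually exercised;
non-genomic tail lengths are geometric with P(k < 2) ≈ 0.1 so that the
PASS filter has something to reject; 5% of reads get MAPQ ≤ 10; 10% of
PASs carry the bundled PFM consensus planted at a uniform random start
in −100..−47.

The generator guarantees that the transcript-sense base immediately
following every possible (jittered) cleavage position is not an A, so a
simulated tail is never partially attributable to the genome and the
expected PASS set is exactly \{MAPQ > 10, k ≥ 2\} — the fidelity the
tests assert read by read. Consequently the genomic-subtraction code
path is exercised by dedicated constructed cases, not by the bulk
fixture.

The bundled PFM (`inst/extdata/starpap_like_pfm_synthetic.tsv`, marked
synthetic) is an AUA-like matrix: consensus AAUAUAA with per-position
top frequency 0.85. The A/U-rich consensus is deliberate: by the
composition property above, only a compositionally distinct motif is
recoverable through the −100..−41 mean score, and an AUA-repeat element
within otherwise unbiased sequence is both recoverable and biologically
sensible for a uridylate-adjacent A-rich binding preference. In
recovery fixtures, planted transcripts receive a −1 log2fc shift over
N(0, 0.3) background noise — about the counting noise of a few hundred
reads per transcript.

What the simulator does *not* emulate: RT/PCR and adapter artifacts,
internal priming beyond genomic-base adjacency, base-call errors and
meaningful quality strings, overlapping genes, multi-exon structure
beyond a single 3′-most exon boundary, expression-dependent tail
lengths, and biological replicate variance (one sample per condition).
Passing tests therefore demonstrate the correctness of the machinery
and its statistical behavior under the stated model — not robustness to
every artifact of real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; a cleavage position is
  a single base (the last templated nucleotide). BED output is 0-based,
  SAM 1-based, as those formats require.
* Clustering ties: 5′-most in transcript orientation, making results
  independent of input order.
* Zero-total samples abort RPM with the sample named; zero gene totals
  simply cannot qualify a cluster in that sample.
* K-S groups below 5 units and empty or degenerate percentile groups
  return NA p-values with warnings instead of fabricating a test.
* The exact test's two-sided p sums hypergeometric point probabilities
  ≤ the observed one times (1 + 1e−7), matching the conventional
  implementation; p-values are capped at 1.
* Constant fold-change columns are dropped (with a warning) before
  correlation-based sample clustering.
* All simulation and downsampling randomness flows from explicit integer
  seeds; identical config + seed reproduces every output file
  checksum-identically.

## Problem sizes

The shipped tests run the full chain at the design scale — 500 genes,
two samples of 125,000 reads for parameter recovery; 1,000 PASs with
~100 planted motifs for motif recovery; 1,000 random instances for the
clustering oracle; every 2×2 table with margins ≤ 30 (about 2.6 × 10⁵
tables) for the exact-test oracle — totalling a few minutes on one CPU.
These sizes were chosen to make planted-effect recovery statistically
decisive (sensitivity and error bounds hold across seeds) while staying
desk-scale.

## Known limitations

Single-sample-per-condition comparisons cannot separate biological from
technical variance; the exact test treats reads as independent draws,
so overdispersion in real replicates would inflate significance.
Gene assignment assumes non-overlapping same-strand genes. The atlas
carries no transcript-structure awareness beyond the 3′-most exon span.
The bundled PFM is a synthetic stand-in, not a measured binding model;
analyses of real data should supply a measured matrix via `read_pfm()`.
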