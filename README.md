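# apatlas

Alternative polyadenylation (APA) analysis from 3′ end sequencing reads.

Most mammalian genes carry several polyadenylation sites (PASs), so a
single gene expresses 3′-end isoforms that differ in 3′UTR length or even
coding sequence. Protocols that sequence transcript 3′ ends (3′READS and
relatives) leave a few poly(A)-derived residues on each read, which makes
individual cleavage sites directly observable from alignments. `apatlas`
turns such alignments into a quantitative APA analysis:

1. **PASS reads** — a read supports a PAS when it is uniquely mapped
   (MAPQ > 10) and carries ≥ 2 additional 5′ Ts that cannot be aligned to
   the genome (poly(A)-tail residue). Soft-clipped Ts that match the
   adjacent reference are treated as genomic and subtracted.
2. **PAS atlas** — cleavage positions within 24 nt are iteratively
   clustered (highest pooled count first; that site becomes the cluster's
   representative). A PAS is kept when, in at least one sample, it has
   ≥ 2 PASS reads that also exceed 5% of its gene's reads in that sample.
   Each PAS is annotated with its gene, region (3′-most exon + downstream
   extension vs upstream), and poly(A)-signal class (AAUAAA / variant /
   A-rich / none).
3. **Quantification** — expression in RPM (reads per million PASS reads
   per sample); gene expression is the sum of its isoforms' RPM. Changes
   are log2 RPM ratios; a transcript is *regulated* when fold change > 2
   and the two samples together provide > 50 reads. Down/up ratios,
   expression-stratified K-S comparisons and correlation-based sample
   clustering summarize the regulation landscape.
4. **APA statistics** — for each gene the two most abundant 3′UTR
   isoforms (or the upstream-region vs 3′-region groups) form a 2×2
   read-count table tested with a two-sided exact test (SAAP-style),
   BH-adjusted. RED = log2(distal/proximal) reads; ΔRED = RED_kd −
   RED_ctrl, so ΔRED < 0 is 3′UTR shortening. The global trend (GAAP) is
   log2((#shortened + 0.5) / (#lengthened + 0.5)), computed after seeded
   binomial depth equalization.
5. **Motif analyses** — a 7×4 position frequency matrix is scanned over
   −100..+100 of every PAS. A window scores Σₚ f₍ₚ,ₙ₎·Iₚ with
   Iₚ = 2 − (−Σₙ fₙ log₂ fₙ), the position's information content in bits.
   The package builds LOWESS-smoothed meta-profiles, mean scores in
   −100..−41, score-percentile group K-S comparisons, k-mer (k = 4)
   enrichment by Fisher exact test, and χ² signal-composition tests.

A first-class synthetic-data module simulates a toy genome, annotation,
ground truth and SAM-format reads with the structure the analysis assumes
(multi-PAS genes, planted usage shifts, poly(A)-tail soft clips, MAPQ
noise, planted motifs), so the whole pipeline is testable at desk scale
without external data.

## Worked example

```r
library(apatlas)

# simulate a two-condition 3' end sequencing study
cfg <- sim_config(n_genes = 60, n_reads = 20000, seed = 42)
fx  <- simulate_fixture(cfg)
dir <- tempfile()
manifest <- write_fixture_bundle(fx$assets, fx$truth, fx$reads, dir)

res <- run_pipeline(list(
  genome     = file.path(dir, "genome.fa"),
  annotation = file.path(dir, "annotation.tsv"),
  samples    = data.frame(sample_id = c("ctrl", "kd"),
                          path = file.path(dir, c("ctrl.sam", "kd.sam")),
                          condition = c("ctrl", "kd")),
  out_dir    = file.path(dir, "out"),
  seed       = 42))

s <- res$summary
cat("PASS reads (ctrl):", s$reads$ctrl$pass, "of", s$reads$ctrl$records, "\n")
cat("PAS clusters retained:", s$atlas$retained, "in", s$atlas$genes, "genes\n")
cat("regulated PAS transcripts:", s$regulation$transcripts_regulated,
    "(down/up ratio", round(s$regulation$down_up_ratio, 2), ")\n")
cat("3'UTR APA: ", s$apa$utr_shortened, "shortened vs",
    s$apa$utr_lengthened, "lengthened; trend =", round(s$apa$utr_trend, 2), "\n")
cat("UR-APA trend:", round(s$apa$ur_trend, 2), "\n")
```

Output:

```
PASS reads (ctrl): 17092 of 20000
PAS clusters retained: 141 in 60 genes
regulated PAS transcripts: 6 (down/up ratio 2 )
3'UTR APA:  17 shortened vs 0 lengthened; trend = 5.13
UR-APA trend: 2.32
```

Reading the numbers: ~85% of simulated reads qualify as PASS (the rest
lack a ≥ 2-T tail or have low MAPQ, by design of the simulator); the
atlas recovers the planted PASs; the planted distal-usage knockdown
shifts drive a strongly positive 3′UTR shortening trend (17 genes
shortened, none lengthened), and the relative usage of upstream-region
PASs rises correspondingly (positive UR-APA trend). Per-stage tables
(atlas BED/TSV, fold changes and calls, per-gene APA tests, trend
ratios, motif profiles and enrichments) are written under `out_dir`,
with a `summary.json` and an MD5 manifest.

## Documentation

The methods vignette (`vignettes/apa-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and units,
what the simulator does and does not emulate, and the numerical design
choices.
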