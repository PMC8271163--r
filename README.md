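# cracDecay

Target identification for sequence-specific RNA-binding proteins from CRAC
(cross-linking and analysis of cDNAs) data, and quantification of the decay
consequence of binding from SLAM-seq time courses — for molecular biologists
working on post-transcriptional regulation who want a transparent,
transcript-space reimplementation of this analysis with a fully synthetic
test bed.

## What it computes

**CRAC side.** UV crosslinking leaves a covalent protein–RNA adduct that
reverse transcriptase reads through by skipping exactly one base, so a
single-nucleotide deletion in a read marks the contact site. The pipeline:

* pre-processes raw reads (PCR-duplicate collapsing on the full-length read,
  in-line 5' barcode demultiplexing, exact 3'-adapter trimming);
* aligns to the transcriptome with a built-in seed-and-extend aligner that
  models at most one substitution and one 1-nt deletion per read
  (external alignments enter through `read_sam()`);
* builds per-transcript coverage and deletion profiles;
* calls peaks as order-20 windowed coverage maxima screened by a
  within-transcript permutation FDR (Benjamini–Hochberg, q ≤ 0.001);
* scores genes as the sum of peak heights in reads-per-million, averages two
  replicates, normalizes by RNA-seq FPKM (genes with FPKM = 0 are
  eliminated) and ranks targets;
* discovers a degenerate binding consensus (widths 6–10, E < 0.05,
  given strand, shuffled background) in windows of ±10 or ±50 nt centered
  on the deletions, and tests its positional concentration at the crosslink.

**Decay side.** SLAM-seq reports metabolic labeling as T→C conversions.
Per gene, technical replicates are pooled at the count level, conversion
rates are normalized to the chase start, and a first-order decay
y(t) = e^(−λt) is fitted by nonlinear least squares (λ ≥ 0); the half-life
is t½ = ln 2 / λ. Bound (top-N ranked) and unbound (peak-free) transcripts
are compared by two-sided Mann–Whitney U tests on half-life and on
expression log2 fold change.

A seeded synthetic-data generator (`simulate_config()`,
`simulate_transcriptome()`, `simulate_crac_reads()`, `simulate_expression()`,
`simulate_slamseq_counts()`) produces transcriptomes with planted
AUKAAWU-family sites, CRAC libraries with crosslink deletions and PCR
duplicates, expression tables, and binomial T→C count series — with a
ground-truth ledger, so every stage has a recovery test.

## Worked example

```r
library(cracDecay)

## end-to-end CRAC pipeline on the default synthetic conditions
p <- run_crac_pipeline(simulate_config(seed = 1))
nrow(p$replicates[[1]]$peaks)                      # 60 retained peaks, rep 1
head(p$ranking$gene_id, 3)                         # top-ranked target genes
mean(p$sim$truth$sites$gene_id %in%
     head(p$ranking$gene_id, 60))                  # 1: all planted sites recovered
round(p$regions$region_fractions, 3)               # UTR5 0.133 CDS 0.050 UTR3 0.817
p$motifs[[1]]$consensus                            # "AUKAAWU" (width 7, E ~ e-7382)
central_enrichment(p$windows, "AUKAAWU")$positional_p  # 0 (all matches central)

## SLAM-seq decay on two noiseless median series (minutes)
t <- c(0, 30, 60, 120, 540, 1440)
fit_decay(t, c(1.0000, 0.8909, 0.7937, 0.6300, 0.1250, 0.0039))$t_half  # 180.0
fit_decay(t, c(1.0000, 0.9113, 0.8306, 0.6898, 0.1881, 0.0116))$t_half  # 224.0
```

The first block plants 60 binding sites (80% in 3'UTRs), pushes ~60k raw
reads per replicate through preprocessing, alignment, peak calling and
ranking, and recovers every planted target in the top-60 of the
FPKM-normalized list; the recovered peak-region fractions match the planted
ones, and the deletion-centered windows yield the planted AUKAAWU consensus
itself, overwhelmingly concentrated at the crosslink.
The second block shows the decay estimator returning half-lives of 180 and
224 minutes on the two worked series — a 20% reduction for the bound
cohort.

A thin CLI over the same functions lives at `inst/cli/crac-decay.R`
(`simulate`, `run`, `slam` subcommands).

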