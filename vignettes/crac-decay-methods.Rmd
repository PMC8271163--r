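---
title: "Mapping RNA-binding-protein targets from crosslink deletions and measuring the decay consequence"
author: "cracDecay authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping RNA-binding-protein targets from crosslink deletions and measuring the decay consequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CRAC (cross-linking and analysis of cDNAs) maps where an RNA-binding protein
touches the transcriptome. UV irradiation forms a covalent bond between the
protein and (usually) a uridine; when reverse transcriptase reads through the
residual peptide adduct it frequently skips exactly one base, so
single-nucleotide deletions in the sequenced cDNA are the most precise marker
of the contact site. cracDecay turns raw CRAC reads into a ranked list of
target transcripts and a binding consensus, and then asks what binding does to
those transcripts, by fitting mRNA half-lives from SLAM-seq metabolic-labeling
time courses and comparing bound against unbound genes.

Everything runs in *transcript space*: coordinates are 0-based, half-open,
5'→3' on the mature transcript, and conversions to the 1-based file formats
(GTF, SAM) happen only at file boundaries. Genomic (spliced) alignment is out
of scope, which is why the SAM reader rejects the `N` CIGAR op instead of
skipping it.

## The pipeline

1. **Pre-processing** (`collapse_duplicates`, `split_by_barcode`,
   `trim_adapter`): PCR duplicates are collapsed on the *full-length raw
   read* before the in-line 5' barcode is removed — this order mirrors the
   standard CRAC protocol, and because barcodes here are fixed per library it
   conflates nothing; users with randomized barcodes can call the three
   stages in any order. Adapter trimming is exact-match (longest read suffix
   equal to an adapter prefix, at least 5 nt); the only quality filter is a
   minimum retained length of 18 nt.

2. **Alignment** (`build_kmer_index`, `align_reads`): a seed-and-extend
   aligner over exact 12-mers, allowing at most one substitution and at most
   one single-nucleotide deletion, with the gap scored at every interior
   position. This is deliberately small-scale — it exists so the pipeline can
   represent crosslink-induced deletions end-to-end without an external
   aligner; real mammalian-scale data should be aligned externally and fed in
   through `read_sam()`. Score ties across loci are broken by a random draw
   under the run seed (the transcriptome-aligner convention for multimappers),
   and ambiguous deletion placements inside homopolymers are left-aligned.

3. **Profiles** (`build_profiles`): coverage counts every M/D position of a
   read's footprint; the deletion vector counts only length-1 D ops, at the
   deleted base's own transcript position. Multi-nucleotide deletions keep
   their coverage footprint but contribute no crosslink evidence.

4. **Peak calling** (`call_peaks`): a candidate is a position whose coverage
   is maximal within ±20 nt (order 20) and at least 5; within an adjacent
   run of equal values only the leftmost position is reported. Significance
   comes from a within-transcript permutation null — read start positions
   are re-placed uniformly, read widths preserved — which keeps per-transcript
   depth and read-length structure without any parametric assumption. Each
   candidate's p-value is the add-one-smoothed fraction of null
   transcript-maxima at least as high as its coverage;
   Benjamini–Hochberg across all candidates in the replicate; peaks with
   q ≤ 0.001 are retained.

   *Permutation resolution.* The smoothed empirical p can never fall below
   1/(n+1), and after BH the q-value can never fall below the p-value, so a
   fixed permutation count near 1/FDR makes the screen unpassable by
   construction. `call_peaks` therefore uses a sequential scheme: every
   transcript gets a first block of 2,000 permutations, and only candidates
   that no null has yet matched are refined in further blocks up to 50,000
   (stopping as soon as a null exceedance appears, since such a candidate is
   then pinned near p ≈ 1/2000 and cannot survive BH at 0.001 anyway). Null
   candidates stay cheap; genuine peaks reach a floor of 2×10⁻⁵.

5. **Ranking** (`gene_peak_scores`, `rank_targets`): per gene and replicate
   the peak score is the sum of retained peak heights in reads-per-million;
   peak intensity is the coverage height at the maximum, the simplest
   reading of a pointwise profile. The two replicates are averaged (a gene
   seen in only one replicate gets 0 from the other — down-weighted, not
   dropped), normalized by the replicate-mean FPKM from RNA-seq, and genes
   with FPKM 0 are eliminated. The final list size is data-dependent; the
   package reports whatever survives and flags the top-500 head.

6. **Motif discovery** (`extract_windows`, `discover_motif`,
   `central_enrichment`): windows of ±10 or ±50 nt are cut around each
   deletion *from the transcript sequence*, not the read — the crosslinked
   base is missing from the read, and the consensus could not be discovered
   at the crosslink if the window lacked it. Discovery is DREME-style:
   every exact word of width 6–10 present in ≥5 windows is tested by a
   one-sided Fisher exact test (presence/absence, given strand only) against
   the same windows mononucleotide-shuffled once under the run seed, and the
   top words are greedily generalized position-by-position to two-letter
   IUPAC codes, each generalization kept only if it lowers the p-value
   (compared as log hypergeometric tails, so deeply enriched words never
   stall on floating-point underflow). The E-value is the best p times the
   number of candidates at that width — a Bonferroni-style analogue, not a
   reimplementation of MEME's E-value. The multiplicity counts *every*
   exact w-mer present in the windows plus every generalization evaluated:
   the ≥5-window support rule only prunes hopeless words, and counting only
   the survivors would hide the selection step it performs and leave the
   screen anti-conservative on signal-free data. Central concentration is a one-sided binomial test of matches
   covering the deleted base against the uniform expectation p₀ =
   width / window length. The "spanning 20 bases" window is read as ±10
   (21 nt total); both half-widths are exposed.

7. **Decay** (`collapse_technical`, `normalize_series`, `fit_decay`):
   technical replicates are pooled by summing counts before any rate is
   computed (so replicates are weighted by coverage), rates are normalized
   to t = 0 per gene, and y(t) = exp(−λt) is fitted by nonlinear least
   squares in linear space (`nls`, port algorithm, λ ≥ 0, tolerance 1e-10),
   initialized from — and in the tests cross-checked against — the
   log-linear regression. λ at the zero boundary is reported as status
   `degenerate` (no measurable decay), never as a numeric half-life; fewer
   than four usable timepoints is `insufficient`. No background
   conversion-rate subtraction is applied. Biological replicates are fitted
   independently.

8. **Group comparison** (`assign_groups`, `compare_half_lives`,
   `compare_fold_change`): "Bound" is the top-N ranking head; "Not bound"
   is genes with zero retained peaks in either replicate; peak-bearing genes
   outside the top-N belong to neither group. Two-sided Mann–Whitney U
   (exact when both groups are ≤8 and untied), with medians, quartiles and
   ECDFs. Fold change is log2((A + 1)/(B + 1)) on replicate-mean FPKM; the
   pseudocount of 1 FPKM is an implementation choice and is recorded in the
   output.

## What the synthetic generator emulates — and what it does not

`simulate_config()` defaults define the study conditions all recovery tests
run under: 300 transcripts (85% mRNA), 60 bound transcripts carrying one
planted AUKAAWU-family site each, site regions drawn with probabilities
0.1/0.1/0.8 over 5'UTR/CDS/3'UTR, crosslink-deletion rate 0.3 per
site-spanning read, 200 site reads per site and replicate,
expression-proportional background reads (2 reads per FPKM unit, FPKM
lognormal around 20 with 5% true zeros), Poisson(1)+1 PCR copies per unique
fragment, 50-nt reads with 5-nt in-line barcodes, 26–36-nt inserts and a
13-nt 3' adapter. Half-lives are lognormal around 224 min with bound
transcripts shortened by 20%; SLAM-seq counts are binomial draws from
r0·2^(−t/t½) at 0, 30, 60, 120, 540 and 1440 min with two technical
replicates. The deletion rate of 0.3 is a modeling choice — published CRAC
work does not report a per-read deletion frequency.

Design points worth stating explicitly:

* The crosslink position is the **uridine of the planted instance nearest
  the motif center** (ties leftmost). This encodes the pyrimidine preference
  of UV crosslinking while keeping every planted instance a valid expansion
  of the consensus (the literal center of AUKAAWU is an A, so "force the
  central base to U" would contradict the motif itself).
* Unexpressed genes (true FPKM 0) are never selected as bound: crosslinking
  requires the transcript to be present. This keeps the FPKM = 0
  elimination rule from silently deleting planted truth.
* Insert lengths are drawn from 26–36 nt rather than full read length so
  that the 3' adapter actually appears within the 50-nt read and every
  pre-processing stage does real work.
* All randomness flows from the single config seed (stage offsets keep the
  streams reproducible regardless of call order); same seed, same bytes.

The generator does **not** model sequencing errors, quality scores,
truncation (iCLIP-style) cDNAs, readthrough substitutions at the crosslink,
multi-site transcripts, or realistic fragment-length distributions. Passing
recovery tests therefore demonstrates that the analysis logic is correct
under its own assumptions — not that it is robust to every artifact of real
libraries.

## Numerical choices and problem sizes

* Windowed maxima use `zoo::rollmax` on a −∞-padded vector; a property test
  checks equality with a naive O(L·order) scan up to length 10,000.
* The permutation null's inner loop is C++ (Rcpp) using R's RNG, so results
  are reproducible under `set.seed()` and a full default-condition run
  (two replicates, 300 transcripts) completes in about two minutes.
* Enrichment p-values are computed as hypergeometric tails (`phyper`) and
  are tested to 1e-12 agreement against `fisher.test`.
* The test suite runs the default pipeline once and shares it across files;
  cohort-scale checks use 500 genes at coverage 5,000 (decay recovery) and
  1,000 clean transcripts (peak-FDR calibration), sizes chosen so each
  property is measured at useful precision in minutes on one CPU.

## Known limitations

Transcript-space only; exactly two replicates for ranking (a deliberate
error otherwise, since the published averaging is defined over two); no
peak-width estimation; no dinucleotide shuffle background by default
(mononucleotide, a logged choice); the aligner is not built for
mammalian-transcriptome scale. Whether published class-distribution figures
count reads or unique loci is ambiguous in the protocol this follows —
cracDecay counts reads.
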