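# tuatlas

Transcript-boundary mapping and promoter modeling for bacteria from
strand-specific RNA end-coverage data.

High-resolution end-enriched sequencing pins transcript boundaries to single
nucleotides: TSS-seq captures RNA 5' ends (with an RppH-treated/untreated
library pair separating true triphosphorylated initiation events from
processed monophosphorylated ends), and term-seq captures RNA 3'-hydroxyl
ends (a mixture of termination and processing products). `tuatlas` turns
per-base counts of these end events into statistically called transcription
start sites (TSSs), termination sites (TTSs), RNA processing sites, 5'-UTR
and leaderless-transcript annotations, a sequence model of the housekeeping
sigma-factor promoter, and a catalog of experimentally supported intrinsic
terminators. It is written for microbial genomics groups annotating
transcription units in non-model bacteria, where curated boundary catalogs
do not exist.

## Methods at a glance

* **TSS calling** — per-position one-sided negative-binomial Wald test of
  RppH-treated over untreated 5'-end counts (median-of-ratios size factors,
  pooled method-of-moments dispersion), in paired and unpaired designs, BH
  FDR < 0.05 in either; contiguous calls resolve to a primary TSS at the
  highest treated coverage. Prefilter: nonzero coverage, then the 95th
  percentile of replicate-averaged treated counts.
* **TTS calling** — per-library Poisson test with a *dynamic lambda*: the
  largest of the strand-specific genome mean, replicon mean, and 13/51/251/
  501/1001-bp centered window means; BH per library, then an exact-position
  consensus over >= 2 biological replicates.
* **Processing-site integration** — a 3' end immediately followed by a
  5'-monophosphoryl end (called from untreated 5'-end libraries by the same
  Poisson machinery, minus all TSS positions) is a processing site, as are
  3' ends in tRNAs; processing sites pool across conditions and purge every
  condition's TTS list.
* **TU annotation** — TSSs assign to the nearest downstream same-strand
  start codon within 650 bp (leaderless = leader of 5 nt or less);
  unassigned TSSs classify as intragenic / antisense / intergenic;
  regulated promoters show a 10-fold activity contrast above the
  chromosomal mean; constant-promoter candidates intersect flat expression
  (|log2FC| < 0.45, padj > 0.05 in all comparisons) with
  intergenic-or-leaderless TSSs detected in all growth-phase samples.
* **Promoter model** — information-theoretic alignment (`malign`) of -10
  hexamers maximizing R = sum(2 - H_l - e(n)) bits over a discriminator
  range of 3..12 nt, then `multiscan` placement of -35 hexamers maximizing
  Ri(-35) minus the spacer gap surprisal GS(d) = log2(n_mode/n_d) over
  spacers 12..22 nt. Outputs frequency/information matrices (PFM text),
  spacer and discriminator histograms and per-promoter placements.
* **Terminator analysis** — TTSs map to predicted intrinsic terminators
  when 1..12 nt after the hairpin (U tract + 4 nt), with
  reverse-complement ("r") rescue of bidirectional terminators; orientation
  classes (in-line / internal / convergent / divergent), U-tract stop
  histograms, nearest-neighbor hairpin delta-G, and flank (A-tract/U-tract)
  frequency matrices.
* **Synthetic data** — generators plant TSSs, TTSs, processing pairs,
  terminator hairpins and promoter motifs with known truth into simulated
  genomes and negative-binomial coverage, so calibration and recovery are
  testable end to end offline.

Inputs: bedGraph pairs or 3-column per-base depth (plus/minus), FASTA,
GFF3 or a gene TSV, TransTermHP reports or an equivalent TSV, and an
optional differential-expression table. Outputs: TSV/BED6 site catalogs,
model matrices and placement tables, and a JSON run manifest.

## Worked example

Simulate a compact study (30-kb genome, 18 genes, 10 planted TSSs, 6 TTSs,
3 processing pairs, 3 terminator hairpins, 3 replicates per library) and run
the callers:

```r
library(tuatlas)
sc <- default_scenario(seed = 42, length = 3e4, n_genes = 18,
                       n_terminators = 3, n_tss = 10, n_tts = 6,
                       n_processing = 3, n_mono = 2)

tss <- call_tss_condition(sc$tss$treated, sc$tss$untreated, "cond1")
table(tss$site_kind)
#> tss_primary
#>          10

prelim <- call_tts_condition(sc$term, condition_id = "cond1")
mono   <- call_monophosphate_sites(sc$tss$untreated, tss,
                                   condition_id = "cond1")
cl <- classify_termini(prelim, mono, sc$genes)
vapply(cl, nrow, integer(1))
#> processing        tts    removed
#>          3          6          0

asn <- assign_tss_to_genes(tss[tss$site_kind == "tss_primary", ], sc$genes)
compute_utr_stats(asn$pairs)[c("median", "n_leaderless")]
#> $median
#> [1] 140
#> $n_leaderless
#> [1] 0

matches <- map_tts_to_terminators(cl$tts, sc$terminators)
u_tract_position_histogram(matches)$mode
#> [1] 7
```

All 10 planted TSSs are recovered as primary calls; the 3 planted
processing pairs separate from the 6 true termination sites; the planted
terminator-linked TTSs sit at the modal U-tract position, 7 nt after the
hairpin. `run_pipeline()` chains the same stages from one config and writes
catalogs plus a manifest; `build_promoter_model()` fits the two-hexamer
promoter model on extracted TSS windows.

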