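---
title: "Mapping bacterial transcript boundaries and promoters from 5'/3'-end coverage"
author: "tuatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bacterial transcript boundaries and promoters from 5'/3'-end coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuatlas)
```

# Overview

`tuatlas` infers bacterial transcription-unit architecture from
strand-specific, per-nucleotide counts of RNA end events:

* **TSS calling** contrasts RppH-treated with untreated 5'-end sequencing
  libraries. RppH converts 5'-triphosphoryl ends (true initiation events) to
  ligatable monophosphoryl ends, so genuine TSSs show an excess of reads in
  treated over untreated libraries, while processed/degraded 5' ends appear
  equally in both.
* **3'-terminus calling** finds positions in term-seq coverage whose counts
  are implausibly high under a locally estimated Poisson background.
* **End integration** distinguishes RNA-processing sites (a 3'-hydroxyl end
  immediately followed by a 5'-monophosphoryl end on the same strand) from
  transcription termination sites (TTSs).
* **TU annotation** assigns TSSs to downstream start codons, yielding 5'-UTR
  lengths, leaderless transcripts, antisense/intragenic/intergenic classes,
  regulated promoters and constant-promoter candidates.
* **Promoter modeling** learns a flexible two-hexamer sigma-A (-35/-10)
  model by information-content maximization with spacer penalties.
* **Terminator analysis** maps TTSs onto predicted intrinsic terminators and
  characterizes hairpins, U tracts and flanking A tracts.

Every stage is validated against synthetic data with planted ground truth
(the `simulate_*` family), so the package's statistical behaviour — false-call
control and planted-signal recovery — is checked by its own test suite
without external downloads.

# Statistical models

## TSS exceedance test

For each condition, positions are prefiltered in two steps: positions with
zero coverage across every library of the condition are removed, and the
remainder must have a replicate-averaged RppH-treated count at or above the
95th percentile (linear interpolation) of the surviving positions. The
percentile source is the treated libraries by default
(`prefilter_source = "treated"`); the treated libraries carry the TSS signal,
and the choice is configurable because either convention is defensible.

Candidate positions are then tested one-sidedly (treated > untreated) under
a negative-binomial count model with

* **size factors** by median-of-ratios, estimated over the zero-filter
  survivors rather than the candidate rows — at single-nucleotide resolution
  the rows with all-positive counts in the top-coverage candidate set are
  almost exclusively true signal, which would otherwise absorb the
  treatment effect into the normalization;
* a **pooled method-of-moments dispersion** with floor `1e-8` (the planted
  recovery and calibration targets do not require per-position shrinkage
  estimators, and an external engine can be substituted upstream);
* a **Wald test** on the treatment coefficient, fitted by IRLS in compiled
  code. Two designs are computed: *unpaired* (treatment only) and *paired*
  (replicate as a blocking factor). A position is a TSS when its BH-adjusted
  P value is below 0.05 in either design and the fold change is positive.

Runs of adjacent calls are resolved to one primary TSS (highest
replicate-averaged treated coverage; ties to the strand-aware upstream-most
position), the rest becoming secondary. Merging across conditions removes
secondaries first and then counts the conditions of detection per site.

## Poisson dynamic-lambda 3'-terminus test

Per library, candidate positions have counts strictly above the 95th
percentile of the library's nonzero counts (both strands, all replicons
pooled). Each candidate's rate parameter is the **maximum** of the
strand-specific genome-wide mean, the per-replicon mean, and the mean counts
in 13-, 51-, 251-, 501- and 1,001-bp windows centered on the position.
Window means include the tested position's own count and count zeros;
windows truncate at replicon ends with the denominator equal to the number
of in-range positions. Including the center count and taking the maximum are
both conservative choices (they can only raise lambda). The one-sided
Poisson probability P(X >= x) is BH-adjusted within the library's candidate
set; sites at FDR < 0.05 found at the **exact same position** in at least
two biological replicates become preliminary 3' termini — no fuzzy matching,
as positional tolerance would inflate site counts.

The same machinery applied to the RppH-untreated 5'-end libraries yields
5'-monophosphoryl sites (after removing every TSS position, primary and
secondary — the conservative default, flag-controlled). A preliminary 3'
terminus with a monophosphoryl site immediately downstream (strand-aware,
offset 1 nt) is a processing site; 3' termini inside same-strand tRNAs are
processing sites; a terminus whose monophosphoryl partner lies at its own
position or upstream violates the cleavage geometry and is removed with a
reason code. Processing sites are pooled across conditions and removed from
every condition's TTS list: a site shown to be a cleavage product anywhere
is unlikely to be a terminator elsewhere.

## Promoter model

Promoter windows are 61 nt ending at the TSS (wide enough for a -35 at the
maximal spacer plus discriminator). The -10 element is found by *malign*:

1. five windows are drawn at random and **all** combinations of their
   allowed offsets are scored; the maximum-information alignment seeds a
   profile;
2. every window is aligned once to the growing profile, the seed
   contribution is removed, and re-placement passes continue until the gain
   per pass is below 0.01 bits. Each re-placement maximizes the profile's
   total information, so passes never decrease it and termination is
   guaranteed (information is bounded by 12 bits for a hexamer).

Information content is \(R = \sum_l (2 - H_l - e(n))\) bits with the
large-*n* small-sample correction \(e(n) = 3/(2\ln(2)\,n)\); individual
information uses pseudocounted frequencies (0.25 per base per position).

Two numerical choices deserve emphasis because the design was genuinely
open:

* **Register canonicalization.** When a motif's flanking columns carry no
  information (a `TAnnnn`-shaped -10), shifting every placement together
  leaves \(R\) unchanged — the register is translationally degenerate, and
  with it the discriminator-length histogram. After convergence the
  alignment is therefore shifted, while information is preserved to within
  0.1 bits, to the TSS-proximal register; offset ties during placement
  resolve the same way. This makes discriminator and spacer lengths
  identifiable instead of being padded by uninformative motif columns.
* **Restarts.** Coordinate ascent from a single five-sequence draw
  occasionally converges to a mixed-register local optimum (information
  smeared across neighbouring columns). `malign()` runs three independent
  draws and keeps the highest-information fit.

Sequences with non-positive individual information against the -10 model
are dropped. A preliminary -35 profile is built at the positions implied by
a 17-bp spacer and optimized by template-seeded malign passes; *multiscan*
then re-places each -35 to maximize \(R_i(-35) - GS(\text{spacer})\), where
the gap surprisal \(GS(d) = -\log_2(n_d/N) - \min_{d'}(-\log_2(n_{d'}/N))\)
is re-derived from the current placements each iteration (unobserved
spacings in 12..22 receive a 0.5 pseudocount). Sequences whose total score
\(R_i(-10) + R_i(-35) - GS\) is non-positive are dropped as nonconforming.
Search ranges default to discriminator 3..12 nt and spacer 12..22 nt.

## Terminator mapping and hairpin energetics

A TTS maps to a predicted intrinsic terminator if it falls 1..12 nt after
the hairpin in transcript orientation (the 8-nt U tract plus 4 nt). TTSs on
the opposite strand falling in the mirrored window off the hairpin's other
end are rescued as the reverse-complement terminator (id suffixed `r`) —
these are bidirectional terminators whose reverse orientation fell below
the predictor's score cutoff. Orientation classes (`internal` when >50 bp
after a same-strand start codon, else `convergent`/`divergent`/`in_line`
from the nearest flanking genes) partition all sites; sites beyond the last
annotated gene default to `in_line`.

Hairpin free energies are a nearest-neighbor sum over stem stacks plus a
loop-initiation term, using Turner-89-style constants embedded in
`R/rna_energy.R`. They support ordinal statements (longer or GC-richer
stems are more stable; A-U stems less stable than G-C stems) — they are not
a replacement for a full secondary-structure energy model, and tests
therefore assert orderings, not absolute values.

# The synthetic study and what it does (not) show

`default_scenario()` fixes the reference conditions used throughout the
validation suite: a 100-kb genome at GC 0.5 with 60 packed genes (2 tRNAs),
10 planted terminator hairpins, 40 TSSs with treated mean 200 versus
untreated mean 2 (the sharp contrast RppH produces at real TSSs), 25 TTS
pileups of mean 100 (10 at terminator U tracts, stop 7 nt after the
hairpin), 10 processing pairs (3'-OH at p, 5'-P at p+1, appearing equally
in treated and untreated 5'-end libraries), 5 standalone monophosphoryl
background sites, and 3 replicates per library kind with NB dispersion 0.1
(variance \(m + \alpha m^2\)). TSS-seq background is 0.1 events/position,
term-seq background 1.0. Planted events add to, never replace, background.

These simulations emulate the *signal structure* of end-enriched
sequencing — sparse background, sharp single-nucleotide pileups, paired-end
signatures of processing — but not sequence-dependent ligation bias,
rRNA-depletion artifacts, alignment multi-mapping, or replicate-correlated
batch effects. Passing tests therefore demonstrate that the statistical
machinery is calibrated and recovers planted truth under the stated noise
model; they do not guarantee the same operating characteristics on real
libraries, where filter percentiles and replicate-consistency rules carry
more of the burden.

Problem sizes in the test suite (null calibration at 100 seeds on kilobase
genomes, recovery at 20 seeds on the 100-kb scenario, promoter recovery on
500 windows over 20 seeds) were chosen so the whole suite completes in a
few minutes while keeping Monte-Carlo standard errors well below the margins
being asserted.

# Degenerate inputs and edge rules

* Coordinates are 1-based inclusive throughout; BED-family I/O converts at
  the boundary. "Downstream" of p is p+1 on `+` and p-1 on `-` everywhere.
* Circular replicons are treated as linear (no wraparound windows); the
  dynamic-lambda windows truncate at ends.
* Ambiguity codes other than N are rejected; windows containing N are
  excluded from promoter modeling.
* Genomic tie rules (adjacent-TSS resolution, the 15-bp refinement) go to
  the strand-aware upstream-most site; motif-offset ties go TSS-proximal
  (see register canonicalization above).
* Coalescing is greedy by descending normalized read count; seeds are
  pairwise more than the window apart by construction, which makes the
  operation idempotent.
* An all-zero library is a hard error in size-factor estimation (named in
  the message); empty tracks yield empty catalogs with a warning.

# Known limitations

* The exceedance backend is a fixed-dispersion Wald test; no shrinkage
  across positions. On real data with few replicates the paired design can
  be underpowered relative to moderated engines.
* The Poisson 3'-end test inherits anticonservativeness under strong
  overdispersion; the dynamic-lambda maximum and replicate-consistency rule
  are the (deliberate) guards.
* `select_constant_promoters()` implements only the automated candidate
  stage; the published-style final catalog required manual curation, which
  is approximated (optionally) by UTR-length and predominance filters.
* Hairpin delta-G values are nearest-neighbor approximations with embedded
  constants; use them for rankings and distributions, not thermodynamics.

# A minimal run

```{r example, eval = TRUE}
sc <- default_scenario(seed = 42, length = 3e4, n_genes = 18,
                       n_terminators = 3, n_tss = 10, n_tts = 6,
                       n_processing = 3, n_mono = 2)
tss <- call_tss_condition(sc$tss$treated, sc$tss$untreated, "cond1")
table(tss$site_kind)
prelim <- call_tts_condition(sc$term, condition_id = "cond1")
mono <- call_monophosphate_sites(sc$tss$untreated, tss,
                                 condition_id = "cond1")
cl <- classify_termini(prelim, mono, sc$genes)
vapply(cl, nrow, integer(1))
```

(The scenario above shrinks both the genome and the planted-event load for
illustration; the reference conditions are the function's defaults.)
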