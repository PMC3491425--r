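---
title: "Linking cytosine modification to programmed DNA elimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cytosine modification to programmed DNA elimination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methelim)
```

## The biological problem

During sexual development the ciliate *Oxytricha trifallax* rebuilds its
somatic macronucleus (MAC) from a germline micronucleus (MIC), eliminating
~95% of germline sequence: satellite repeats, transposons, the spacer IESs
between macronuclear-destined segments (MDSs), and the entire parental
somatic genome.  Cytosine methylation (mC) and hydroxymethylation (hmC)
appear transiently on exactly the DNA classes being destroyed.  `methelim`
implements the computational chain used to establish that link:

1. **meDIP-seq normalization** — per-contig RPKM and the
   vegetative-subtracted *signal* per antibody (mC, hmC, IgG control).
2. **Germline classification** — separating polytenized MIC-limited
   contigs from telomere-capped MAC nanochromosomes on the IgG
   vegetative-vs-46 h copy-number scatter.
3. **Cohort calling** — fixed read-excess thresholds defining the
   methylation, hydroxymethylation and CC-motif cohorts, and their Venn
   overlap.
4. **Motif scanning** — a 20-column position weight matrix scored
   genome-wide against an exact dynamic-programming null, thresholded at a
   per-occurrence false-discovery rate of 1e-7.
5. **Bisulfite calling** — per-cytosine, all-context, strand-resolved
   methylation calls from clone sequences, with skip-run statistics and a
   conversion control.
6. **Junction annotation** — tiling rearrangement products against a
   scrambled locus map, recovering pointer microhomologies, and flagging
   aberrant products joined at 3–4 bp cryptic pointers.
7. **ddCt quantification** — bisulfite-qPCR signals, drug-induced
   demethylation and sequence retention, with one-tailed Welch tests.

Every stage is exercised end to end on a synthetic genome/read generator
whose defaults encode the study conditions, so each method can be tested
against planted truth.

## The synthetic study design

`sim_config()` freezes the study conditions: 200 MAC nanochromosomes
(mean 2 kb, G4T4-capped at both ends), 10 MIC contigs (five satellite
tandem arrays — one with the signature 170 bp unit — and five
transposon-like contigs) amplified 5-fold by polytenization at 46 h,
six immunoprecipitation libraries of 1e5 fragments of 300 bp, cytosine
modification planted at 91% (forward) / 84% (reverse) strand density, and
~99.5% bisulfite conversion.  Eleven chromosomes carry co-planted mC+hmC
regions (the methylation-cohort truth) and five carry hmC-only regions
(ribosomal-gene analogs).  The real libraries held 5–9 million reads; 1e5
reads per library keeps a full six-library run in seconds while leaving
per-contig counting error far below the cohort thresholds, and is the
problem size used throughout the tests and the acceptance script.

### The immunoprecipitation model

Fragments are fixed-length sliding windows sampled with replacement —
the simplest fragmentation model that preserves composition-weighted
enrichment (the real protocol shears to ~300 bp, with an unstated length
distribution).  A window's weight is

$$w = \beta + \gamma\, n_C + \alpha_{ab}\, n_{mod},$$

with $\beta$ the bead/background weight, $\gamma$ the antibodies' weak
cross-reactivity per cytosine (both strands counted), and $\alpha_{ab}$
the specific affinity per recognized modified cytosine ($\alpha_{IgG}=0$;
the mC and hmC antibodies recognize only their own mark by default —
cross-recognition is a config knob left at 0 since no cross-reactivity
figures are available).  Contig weights are multiplied by the copy number,
which is how polytenization enters.  Defaults $\beta=1$, $\gamma=0.02$,
$\alpha=1$ give 46 h cohort chromosomes a ~2000-read excess over their
vegetative baseline — comfortably above the 100-read threshold, as in the
study — while unmodified chromosomes stay within counting noise of zero.

### Modification placement

Within a designated region, each strand's cytosines follow an alternating
renewal process: modified stretches (geometric, mean set by the density
target) interrupted by *skip runs* of unmodified cytosines whose lengths
are geometric truncated to 1–8 — the study reports observed runs of 3–8
without a distributional claim, and a truncated geometric is the least
structured law consistent with that range.  hmC is a relabeling of a
fraction (default 0.5) of modified sites, reflecting that
hydroxymethylation requires pre-existing methylation; `hmc_only` regions
relabel every modified site.

### One genomic track versus per-molecule patterns

The shared `ModificationTrack` is what meDIP sees: a per-position genomic
summary.  Bisulfite clones, however, are individual molecules, and the
study's clone alignments show different skip runs in different reads.
`simulate_bisulfite_clones(per_molecule = TRUE)` therefore replants the
modification states independently per clone; with the shared-track default
the clones reproduce the genomic truth exactly, which is what the
perfect-recovery tests use.  A single 5 kb track realization has realized
strand densities spread roughly ±4 percentage points (skip-run blocks are
long-correlated), so percentage-recovery checks use the per-molecule mode,
where pooling 20 clones tightens the spread to well under a point.

## Design choices where the method was genuinely open

**Excess reads, not RPKM, for cohort thresholds.**  The cohort cutoffs are
quoted in reads ("over 100 excess reads"), while the plots use RPKM; both
columns are emitted, and membership uses depth-normalized raw-count
differences rounded half away from zero.  The methylation threshold is
strict (`> 100`), the hydroxymethylation thresholds inclusive (`>= 40`
excess and ratio `>= 1.5`), encoding the wording of each rule literally.
A contig with non-positive IgG signal passes the ratio test by definition
— IgG depletion cannot mask enrichment — with a 1-read floor guarding the
division otherwise.  An automatic "natural break" threshold finder
(largest gap in the sorted tail) is provided but off by default.

**Amplification as a gradient ratio.**  RPKM is compositional: with ~7% of
the synthetic genome germline-limited and 5-fold amplified, every somatic
RPKM deflates at 46 h, shrinking both fitted through-origin slopes by a
common factor (~0.78 and ~3.9 rather than 1 and 5).  The real libraries
barely show this because germline reads are a tiny fraction of total.
`fit_enrichment_populations()` therefore reports `amplification_fold`, the
high-population slope over the low-population slope — equivalent to
drawing the 5:1 dashed line against the somatic cloud as the unit
gradient, which is how the original scatter is read.

**Two-means with a strong-structure guard.**  The two copy-number
populations are separated by exact 1-D two-means on
$r=\log_2((\mathrm{rpkm}_{46h}+\epsilon)/(\mathrm{rpkm}_{veg}+\epsilon))$
($\epsilon = 0.1$ RPKM guards vegetative-absent contigs); the published
separation is visual, so the simplest method matching the figure is used
rather than a mixture model.  Splitting unimodal data is refused when the
mean silhouette falls below 0.7, the classic "strong structure" cutoff: an
exact two-means split of *unimodal* 1-D data still measures ~0.55–0.65
mean silhouette, so the conventional 0.5 would never refuse; true 5:1
mixtures measure ~0.95.  Unamplified inputs thus yield a single population
and a warning instead of a forced split.

**Integer-rounded motif scoring.**  Log-odds scores are rounded per column
to a 0.01-bit grid (maximum per-window discretization error 0.1 bit for
the 20-column motif, asserted < 0.5 bit), and the *same* rounded scores
are used by the scan, the dynamic-programming null distribution, the
calibrated threshold and the per-hit p-values.  The null is therefore
exact for the deployed scoring system — there is no discretization gap
between calibration and scanning — and enumeration over all $4^w$ words
reproduces the hit set exactly for small widths.  The background defaults
to the scanned genome's mononucleotide frequencies (the organism is
AT-rich; a uniform background would misprice C-rich motifs).  The
per-occurrence false-discovery rate of 1e-7 is the study's own stringency;
the expected genome-wide false count (rate x windows scanned) is reported
alongside.  Motif *discovery* is out of scope: the matrix is an input
(MEME minimal format supported).

**Bisulfite template detection.**  Clones arrive unlabeled from either
strand, so alignment tries both templates against the clone and its
reverse complement (four candidates) with bisulfite-aware scoring — ref C
vs read T (forward template) or ref G vs read A (reverse) score as
matches — and keeps the candidate with fewest non-bisulfite mismatches.
Percentages are computed over scored cytosines only (ambiguous pairings
and primer-masked positions excluded); when no primer intervals are given
the outermost 20 bp are masked with a warning, since primer-site
methylation cannot be sequenced from PCR products.  Pooled counting is
the default for strand percentages; per-clone averaging is a flag, as the
original report does not say which was used.

**Junction annotation by maximal-extension tiling.**  Products are tiled
greedily with maximal exact matches (20 bp seed minimum, both
orientations; mismatch-tolerant tiling is a non-goal since products come
from clone sequencing of the same strain).  The pointer at each junction
falls out of maximality: the overlap between the left segment's furthest
forward extension and the right segment's furthest backward extension is
precisely the maximal string that is simultaneously a suffix of the left
germline context and a prefix of the right.  A junction is *programmed*
only when both segments reproduce MAC-adjacent MDS footprints exactly and
the overlap equals the map's derived pointer; anything else — including a
blunt zero-length join — is *cryptic*.  Locus-map generation resamples
IES bases that would extend a programmed pointer by chance, so programmed
pointers are maximal by construction and the truth is exactly recoverable;
similarly, sampled cryptic pointer pairs must have mismatching flanks and
both retained arms must keep >= 30 bp so every planted junction remains
annotatable.

**Replicate-level ddCt testing.**  Fold changes are $2^{-\Delta\Delta Ct}$
with standard errors propagated as the root sum of squared arm SEMs, but
significance comes from one-tailed Welch tests on replicate-level
$\Delta Ct$ values, not on pre-averaged folds — testing on means of three
would discard the replicate variance the test needs.  Undetermined Cts
are imputed at cycle 45 (the program length) and flagged.  No
multiple-testing correction is applied by default, mirroring the original
analysis; a Holm option exists.  The bisulfite-qPCR *retained signal*
$L = 2^{-(\bar{Ct}_{bis}-\bar{Ct}_{nat})}$ normalizes each
bisulfite-treated measurement to the same template untreated, and the
methylation fold is $L_{sample}/L_{control}$.

## Coordinates and formats

In-memory objects use 1-based closed coordinates (the R/Bioconductor
idiom); all BED output is 0-based half-open per the BED standard, and
every table is written as headered TSV.  SAM input is consumed through
Rsamtools with primary-alignment filtering (multi-mapping reads count
once, a consequential choice in satellite repeats, so it is stated here as
a caveat rather than hidden).  Count tables use a one-line `#total=`
header so library depth survives the round trip.  Reverse-strand
modification states are stored at the forward-frame position of the
complementary G.

## What the generator does not emulate

No sequencing-error model beyond bisulfite conversion, no quality scores,
no PCR duplicates, no insert-size variance, no chimeric fragments, and no
mappability structure: reads are counted at their true origin (or passed
through an exact SAM round trip).  Passing tests therefore demonstrate
that the analysis recovers what its own statistical model plants — the
identifiability of the IP model, the correctness of the thresholds, the
exactness of the null — not robustness to alignment artifacts, repeat
collapse or real antibody behavior.  In particular, satellite contigs are
perfectly assembled tandem arrays here, whereas real germline repeats
assemble poorly and can absorb multi-mapping reads unpredictably.

## Numerical notes

- Two-means is solved exactly by scanning all split points of the sorted
  ratios; no random restarts, fully deterministic.
- Through-origin fits report uncentered R² (the standard choice when the
  intercept is suppressed).
- The score-distribution convolution keeps the full integer support; its
  mass is asserted to be within 1e-6 of 1.
- "Excess reads" rounding is half-away-from-zero, so +0.5 and -0.5 excess
  do not collapse asymmetrically onto zero.
- Every generator accepts a seed and is byte-reproducible; the pipeline
  derives all stage seeds from one integer.

## Known limitations

- The germline classifier assumes two populations; intermediate
  amplification levels (partial polytenization) would need the mixture
  upgrade listed as a non-goal.
- The hmC/IgG ratio reading of the hydroxymethylation rule follows the
  signal-based interpretation; the original text does not say whether
  signal or raw RPKM sat in the denominator.
- Bisulfite calling cannot distinguish mC from hmC (chemical identity of
  the assay), and the caller does not attempt it.
- Junction tiling is exact-match only; a single sequencing error inside a
  pointer would split or shift a segment.
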