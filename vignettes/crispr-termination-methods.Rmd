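---
title: "Methods: quantifying Rho termination and BoxA antitermination in CRISPR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Rho termination and BoxA antitermination in CRISPR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprterm)
```

## The scientific problem

Bacterial CRISPR arrays are long, untranslated transcription units:
identical repeats alternate with variable spacers, transcribed as one
precursor RNA from a leader-proximal promoter and processed into
crRNAs.  Untranslated RNA is a natural substrate for the termination
factor Rho, so transcription can terminate prematurely *inside* the
array.  Under a constant per-interval termination hazard, leader-distal
spacers receive geometrically less transcription than leader-proximal
ones, and the corresponding crRNAs become depleted.  A *boxA* element
in the leader recruits the Nus antitermination complex to RNA
polymerase and suppresses this hazard, rescuing the distal spacers.

Per-spacer crRNA levels are hard to read directly, but they leave a
footprint: the type I-E effector complex Cascade binds chromosomal
off-target sites using only a short PAM-proximal "seed" of the crRNA,
so the ChIP occupancy of Cascade at sites attributable to a given
spacer is a proxy for that spacer's crRNA abundance.  This package
implements the computational chain from ChIP peaks to per-spacer
occupancy profiles, the pooled-conjugation readout of interference, and
the phylogenetic screen for *boxA*-like motifs upstream of CRISPR
arrays — together with a synthetic-data generator that emulates the
termination process so that every stage is testable against planted
ground truth.

## Spacer-to-peak assignment

Cascade off-target binding requires very little pairing, which the
matcher encodes as two modes:

* **PAM + seed** — a PAM 3-mer (`AAG` or `ATG`; the AWG consensus)
  immediately 5′ of an exact match to spacer positions 1–5;
* **seed + 7–8** — an exact match to positions 1–5 and 7–8 with any
  base at position 6 and *no PAM required* (not "PAM forbidden": a hit
  of this mode is valid even if a PAM happens to be adjacent).

Peak regions are fixed 101-bp windows centered on input peak positions;
overlapping or abutting windows are merged and the floor of the merged
midpoint becomes the *peak center* at which coverage is later read.  A
peak is assigned a spacer only when exactly one spacer identity matches
anywhere in its region.

Design choices made where the procedure was genuinely open:

* Spacer position 1 is the PAM-proximal 5′ end of the protospacer, and
  the PAM sits immediately 5′ of it with zero gap — the standard
  type I-E geometry.
* Both DNA strands are searched, since Cascade can bind a protospacer
  on either strand; minus-strand hits are reported at the leftmost
  forward-strand base of the matched segment.
* Spacers with identical sequence are collapsed to a single candidate
  identity before assignment, so an exact duplicate (such duplicates do
  occur in natural arrays) cannot force spurious ambiguity.
* `N` bases never match in any comparison.

The matcher is validated against an independent brute-force enumerator
over every offset × strand × spacer × mode, on 1,000 random instances
per run.

## Occupancy, scaling, and ratio-based refinement

Occupancy at a peak is the strand-summed coverage at the single
peak-center position.  Replicates are placed on a common scale by
multiplying the second replicate by the constant that equates the
summed values over the analyzed peak set.  This preserves rank order
within a replicate and makes per-peak ratios comparable across
replicates.

Peaks matched by spacers from both arrays can be resolved with a strain
in which one array (here "CRISPR-I") is deleted.  For each ambiguous
peak the deletion:reference coverage ratio is computed per replicate;
if **both** ratios are `< 0.2` the candidates are restricted to the
deleted array's spacers, and if **both** are `> 1.0` to the other
array's.  A peak becomes uniquely assigned only when exactly one
candidate survives; discordant replicates leave it untouched, and
already-unique peaks are never modified.  The asymmetric thresholds are
deliberate: deleting an array removes its sites' signal (ratio near
background), while the remaining sites gain relative coverage because
sequencing depth redistributes over fewer binding sites (ratio above
1).  The coverage simulator reproduces this by normalizing expected
coverage to a fixed library size when asked (`library_size`).

Zero-denominator ratios receive a pseudo-count of 1 added to numerator
and denominator; the pseudo-count is applied *only* on a zero
denominator so that at realistic depth the ratio arithmetic is exact.

Per-spacer effect profiles (mutant vs. reference strain) average the
two replicate ratios per peak, normalize by the mean ratio over peaks
assigned to a reference array (making that array's mean exactly 1 by
construction), and average per spacer.  A termination change-point is
localized by fitting, for every candidate spacer k, a piecewise model
in log space — flat at 0 through k, linear decay after — and taking the
k with minimal residual sum of squares.  Under a hazard jump the decay
of log ratios is linear in spacer index, so this estimator is the
least-squares change-point of the implied geometric profile.

## Pooled-conjugation interference

Each protospacer plasmid is identified in amplicon reads by a 10-nt tag
chosen within its protospacer: centered by default, shifted outward one
base at a time on collision (with the other protospacers' subsequences
and the control construct), erroring only if no unique tag exists.
Identical protospacers are collapsed first.  A read counts for a
plasmid iff exactly one tag occurs as an exact substring of the read in
either orientation; reads matching zero or several tags are tallied,
never silently dropped.  Protospacers with fewer than 50 reads in the
interference-free (Δ*cascade*) sample in either replicate are
discarded; exactly 50 is retained.

Normalized conjugation efficiency doubly normalizes counts — first to
the Δ*cascade* count for the same plasmid, then to the same ratio for
the no-protospacer control — and is reported in percent.  The control
therefore scores exactly 100% in every sample, and any per-sample depth
rescaling cancels.

## ZOOPS-EM motif discovery

The *boxA* screen learns a fixed-width position probability matrix
under the "zero or one occurrence per sequence" model: each sequence
carries a motif occurrence with probability γ at a uniformly
distributed offset, all other positions drawn from a background
distribution.  The E-step computes per-offset occurrence
responsibilities; the M-step re-estimates the matrix (pseudo-count
α = 0.25 per base), γ, and the background from expected non-motif base
counts.  Only the given strand is scanned, matching how upstream flanks
are oriented.

Restart seeding is the one genuinely open design point.  Uniformly
random w-mer seeds find a motif present in ~28% of sequences with low
probability per start, so half the restarts are seeded from the most
frequent distinct w-mers in the data (an exactly or nearly repeated
motif dominates that ranking) and the rest from w-mers drawn by a
seeded RNG.  Every start runs a 5-iteration burn-in; the three most
promising by log-likelihood are refined to convergence
(tolerance 10⁻⁶ on the log-likelihood gain, cap 100 iterations) and
the best final log-likelihood wins.  The log-likelihood trace is
retained and is non-decreasing at every recorded iteration — the EM
guarantee doubles as a runtime self-check.  Sequences with posterior
occurrence above 0.5 are reported as hits.  Defaults: width 12 (the
visual width of consensus-class *boxA* elements), 20 restarts, scanning
threshold 8 bits of log-odds.

## Flank preparation rules

For each *cas2* gene the 300 bp immediately 3′ (in the gene's
orientation) are extracted; the flank is trimmed at the first 15-mer
that recurs exactly later in the same flank — the likely first CRISPR
repeat — and discarded if no 15-mer recurs or if the trimmed prefix is
shorter than 20 bp.  Recurrence is direct-strand only (CRISPR repeats
are direct repeats) and searched within the flank, not genome-wide.
For genera whose arrays run opposite to *cas2* (common in type II-C
systems) the complementary extractor returns the 300 bp at the
cas2-distal end of the array, oriented toward the array.

One subtlety the synthetic generator must respect: if the base
preceding a planted tandem repeat equals the repeat's last base, the
window one position upstream also recurs and the trim point shifts
left.  The generator therefore draws repeats whose final base differs
from the preceding base, making planted trim points exact.

## The synthetic-data generator

The generator is the package's study system.  Its defaults emulate a
two-array type I-E locus: an 8-spacer first array and a 23-spacer
second array (the configuration in which loss of *boxA* protection
depresses leader-distal spacers), 32-bp spacers, 29-bp repeats, a
100-bp leader with a 12-nt boxA-like element 40 bp upstream of the
first repeat, two or three planted off-target sites per spacer with
AWG PAMs, expected depth 200 per fully transcribed site, Poisson
counting noise over a uniform background of 0.5 per strand per
position, and a 60-bp symmetric binding footprint (typical ChIP
fragment scale; only relative heights matter downstream).

Per-spacer crRNA abundance follows the survival model
`abundance_i = A0 · Π_{j<i}(1 − ρ_j)`, with the protected hazard used
when *boxA* is intact, plus an optional internal-promoter contribution
propagated under the same survival.  No quantitative Rho hazard is
published for these arrays; the ρ values used in tests (0.01 baseline,
jumping to 0.25 after spacer 8 in the mutant) are simulation
parameters chosen to produce an effect of the magnitude seen in real
occupancy profiles, not estimates of the biology.

Spacer seeds (positions 1–5) are made mutually distinct by default, so
planted sites are distinguishable by construction; each site's 101-bp
window is additionally verified against the package's own matcher and
re-randomized (background and free tail positions only) on collision.
Determinism is end-to-end: one master seed feeds per-stage derived
streams, and identical configurations reproduce outputs byte for byte.

What the generator does **not** emulate: read-level sequencing (no
FASTQ qualities, no mapping errors — counts-level noise only), PCR
amplification bias in conjugation pools, non-uniform chromosomal
background (replication-origin gradients, copy-number structure), or
degenerate terminal repeats unless a mismatch budget is requested.
Passing tests therefore demonstrate correctness of the *computational
chain* under the stated statistical assumptions, not robustness to
every artefact of real sequencing data.

## Problem sizes and runtime choices

The test suite and acceptance script run the full chain at sizes the
methods are meant for while staying quick: a 120-kb genome with 31
spacers and 93 planted sites for assignment, refinement and profile
recovery (20 noise replicates for the change-point), conjugation pools
of 10⁵ reads over a 12-point efficiency grid spanning 10⁻³–1, and the
motif screen at 187 flanks of 300 nt with 52 planted instances — the
canonical size for this kind of genus-level screen.

## Known limitations

* The matcher is exact-match only; near-seed matches with mismatches
  are out of scope, as is peak calling itself (peaks are inputs; the
  bundled local-maximum caller exists only to exercise synthetic
  coverage).
* The EM reports no enrichment E-value; comparisons with external
  motif-finder outputs are qualitative (consensus and site lists), and
  a numeric PWM must be learned or supplied — never transcribed from a
  published logo.
* The ChIP-qPCR "background-subtracted relative enrichment" arithmetic
  is under-specified in the field; `relative_occupancy()` documents the
  interpretation used (difference of target and mock enrichments, each
  relative to a control region), and the Cq helper exposes
  amplification efficiency as a parameter rather than assuming it.
* `estimate_changepoint()` assumes a single change-point and geometric
  decay; profiles with multiple hazard regimes or internal promoters
  need the full survival model instead.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, genome_length = 30000,
                  arrays = list(array_spec("CRISPR-I", 3),
                                array_spec("CRISPR-II", 3)),
                  offtargets_per_spacer = 2)
sim <- make_crispr_genome(cfg)
regions <- build_regions(sim$sites$center,
                         contig_length = nchar(sim$genome))
peaks <- assign_peaks(regions, sim$genome, sim$spacers)
attr(peaks, "summary")
#>      total     unique  ambiguous unassigned
#>         12         12          0          0
```
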