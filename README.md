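# crisprterm

Analysis of premature Rho-dependent transcription termination in
bacterial CRISPR arrays, and of its rescue by BoxA/Nus-factor
antitermination.

CRISPR arrays are long untranslated transcripts — exactly the substrate
the termination factor Rho acts on.  If Rho fires inside an array,
leader-distal spacers are transcribed less than leader-proximal ones
and their crRNAs are depleted; a *boxA* element in the leader recruits
the Nus antitermination complex and suppresses this loss.  `crisprterm`
is for microbiologists and bioinformaticians who want to quantify this
process from sequencing readouts:

* **Spacer-to-peak assignment** — match ChIP-seq peak regions of a
  type I-E Cascade complex to the crRNA spacers that direct them, using
  the two minimal match modes of off-target binding: a PAM (`AAG`/`ATG`,
  the AWG consensus) immediately 5′ of an exact match to spacer
  positions 1–5, or an exact match to positions 1–5 and 7–8 with no PAM
  required.  A peak is assigned iff exactly one spacer matches its
  101-bp region.
* **Occupancy and ratio refinement** — strand-summed coverage at peak
  centers, replicate sum-scaling, and resolution of ambiguous peaks by
  comparing an array-deletion strain to the wild type (both replicate
  ratios < 0.2 → deleted array; both > 1.0 → the other array).
* **Per-spacer termination profiles** — mutant/reference occupancy
  ratios per spacer, normalized to a reference array, with a
  least-squares change-point estimator for the spacer at which
  antitermination protection is lost.
* **Pooled-conjugation interference** — exact 10-nt tag counting of
  amplicon reads, a ≥50-read filter in the interference-free sample,
  and doubly-normalized conjugation efficiency (%) per protospacer.
* **boxA discovery** — cas2-flank extraction, trimming at the first
  recurring 15-mer, and a ZOOPS-EM motif finder with PWM scanning.
* **Synthetic data** — a generator that plants arrays, off-target
  sites, termination-shaped coverage, conjugation pools, and motif
  flank sets with full ground truth, so the entire chain is testable
  with no external data.

## The core model

Transcription initiating at the leader survives the interval after
spacer *j* with probability 1 − ρ<sub>j</sub>, so the crRNA abundance
of spacer *i* is

    abundance_i = A0 · Π_{j<i} (1 − ρ_j)  (+ internal-promoter terms)

with a reduced hazard when *boxA* is intact.  Cascade ChIP occupancy at
off-target sites assigned to spacer *i* is proportional to
abundance<sub>i</sub>, which is what the per-spacer ratio profiles
measure.  Normalized conjugation efficiency is

    eff(p) = [n(p, strain) / n(p, Δcascade)] ÷
             [n(ctrl, strain) / n(ctrl, Δcascade)] × 100

so the no-protospacer control scores exactly 100% and sequencing depth
cancels.

## Worked example

```r
library(crisprterm)

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
head(peaks[, c("start", "end", "center", "status", "spacer_id")], 4)
#>   start   end center status   spacer_id
#> 1   422   523    472 unique CRISPR-II:3
#> 2  3719  3820   3769 unique  CRISPR-I:1
#> 3  6718  6819   6768 unique  CRISPR-I:2
#> 4 14272 14373  14322 unique CRISPR-II:2
```

All 12 planted off-target sites are recovered as unique, correct
assignments.  The termination survival model, with and without BoxA
protection (hazard 0.15 vs. 0.015 per interval):

```r
round(simulate_crrna_abundance(termination_model(rep(0.15, 6))), 3)
#> [1] 1.000 0.850 0.722 0.614 0.522 0.444
round(simulate_crrna_abundance(
  termination_model(rep(0.15, 6), boxa_intact = TRUE)), 3)
#> [1] 1.000 0.985 0.970 0.956 0.941 0.927
```

Interference recovery from a simulated 10⁵-read conjugation pool with
true efficiencies 2%, 50% and 100%:

```r
eff <- setNames(c(0.02, 0.5, 1), c("ps1", "ps2", "ps3"))
cnt <- simulate_conjugation_counts(eff, depth = 1e5, seed = 7)
ef  <- normalize_efficiency(filter_low(cnt)$counts)
wt  <- ef[ef$sample == "boxA_wt", ]
round(tapply(wt$efficiency, wt$protospacer_id, mean), 1)
#> control     ps1     ps2     ps3
#>   100.0     2.0    50.2   101.0
```

A single-command pipeline over all stages, driven by a YAML config, is
available as `run_pipeline()` (and `inst/scripts/crisprterm.R` for
shell use); it writes per-stage outputs plus a manifest with md5 hashes
and reproduces bit-for-bit under a fixed seed.

## Documentation

The methods vignette
(`vignettes/crispr-termination-methods.Rmd`) describes the models, the
tunable parameters and their defaults, the design decisions taken where
the procedures were open, what the synthetic generator does and does
not emulate, and known limitations.
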