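---
title: "Methods: MSI panel design from UMI-Seq repeat-length profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI panel design from UMI-Seq repeat-length profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Microsatellite instability (MSI) is the somatic gain or loss of repeat units
at short-tandem-repeat tracts in tumors whose DNA mismatch repair is
deficient (dMMR). A clinical MSI assay reduces to three questions: *which*
repeat loci to interrogate, *how* to decide a locus is unstable in a given
tumor, and *how many* unstable loci make the tumor MSI-high. `msipanel`
implements one complete, testable answer to all three, built around
UMI-tagged amplicon sequencing, where every input molecule carries a unique
molecular identifier (UMI) so PCR stutter can be cancelled by per-molecule
consensus.

# Locus discovery

`scan_reference()` reports every maximal tandem tract whose primitive unit
is 1–5 bp long and repeats 7–13 whole times — short enough to amplify
reliably from fragmented FFPE DNA, long enough to be slippage-prone.
Conventions:

* **Whole copies only.** A trailing partial unit is excluded from the tract
  and does not count; this makes "occurring 7 to 13 times" well defined.
* **Inclusive bounds; longer tracts excluded.** A tract of 14+ copies is
  not truncated to 13 — it is a different (hypermutable, poorly typeable)
  kind of locus and is dropped entirely. `enforce_upper = FALSE` relaxes
  this for exploration.
* **Canonical primitive units.** `"TA"`, `"AT"` and `"ACAC"` describe the
  same repeat; every tract is reported once, under the lexicographically
  smallest rotation of its primitive unit, anchored at the leftmost position
  where the period cannot extend. Forward strand only: a tract and its
  reverse complement are one genomic feature.
* **`N` breaks tracts** rather than erroring — masked references are
  common.
* Locus ids are `<chrom>:<start>-<end>:<unit>` (0-based half-open), stable
  across runs.

The scanner is verified against a brute-force enumerator that tests every
(position, unit-length) anchor directly; the test suite checks set-equality
on random and adversarially low-complexity sequences, idempotence,
reverse-complement mirroring, and coordinate uniqueness.

# The synthetic cohort

There is no public per-read repeat-length dataset bundled with the package;
instead `simulate_cohort()` generates one with known truth. It emulates the
study design the pipeline targets — matched tumor/normal pairs forming a
training cohort plus unmatched tumors forming a validation cohort — at
repeat-tract-length resolution (no base-level reads, FASTQ or alignment).

Generative model per (sample, locus):

* UMI family count ~ Poisson(`families_per_locus`, default 60); family
  size ~ zero-truncated Poisson(rate `reads_per_family`, default 4).
* A tumor draws "truly unstable" per locus: probability `p_unstable_dmmr`
  (0.85) at informative loci of dMMR tumors, `p_unstable_pmmr` (0.02) in
  pMMR tumors, `p_decoy_unstable` (0.01) at all other loci. An unstable
  draw picks a somatic shift from `shift_set` ({−3,−2,−1,+1,+2} units).
* Each family derives from the shifted allele with probability `purity`
  (0.6), else the germline allele; normals never carry somatic shifts.
* Each read reports its molecule's length, or ±1 unit with probability
  `stutter_eps` (0.08), split equally up and down — symmetric single-unit
  stutter. Real stutter is contraction-biased and occasionally ±2; symmetry
  keeps the closed-form oracles exact, and the simplification is
  conservative for the consensus step it exists to test.
* `polymorphic_frac` (5%) of non-informative loci are germline-polymorphic:
  each patient has a 50% chance of a ±1- or ±2-unit germline offset there.
  These give the polymorphism filter real signal to remove. Informative
  loci are drawn from the *non*-polymorphic mononucleotide loci: germline
  polymorphism is an orthogonal nuisance, and planting signal on top of it
  would conflate two failure modes in every downstream test.

None of the noise, purity or prevalence values are measured quantities —
the emulated study reports no such parameters — they are documented
stand-ins chosen to be plausible for FFPE amplicon data. dMMR labels are
assigned by deterministic proportional fill over the patient index, giving
exact class counts (e.g. exactly 50 dMMR among 100 at `frac_dmmr = 0.5`)
and prefix-stability. Every (sample, locus) pair draws from its own RNG
substream derived by hashing, so enlarging a cohort never changes existing
samples' reads. `simulate_cohort()` accepts a pre-built catalog and
informative set so a validation cohort simulated under a different seed
shares the training cohort's loci.

What passing tests on this generator do **not** show: robustness to
contraction-biased or multi-unit stutter, UMI collisions or sequencing
errors inside UMIs, locus-specific amplification efficiency, CNV/LOH, or
purity varying across samples. The pipeline's thresholds are exposed as
arguments precisely so they can be recalibrated on real data.

# UMI consensus

`collapse_to_profile()` groups reads by (sample, locus, UMI) and keeps one
consensus length per family: the **strict majority** read length. Families
with no strict majority are dropped and tallied in a per-sample QC table
(`collapse_qc()`), as are families below `min_family_size`. Strict majority
was chosen over plurality or mean because it is auditable and conservative:
a family only votes when more than half its reads agree, and ties — rare at
family size ≥ 3 — abstain rather than guess. `min_family_size` defaults to
1 so non-UMI data degrades gracefully to per-read analysis (the transform is
then the identity); 3 is recommended when families are real. The noise
argument: a read is wrong with probability ε, so a size-3 family's majority
is wrong with probability O(ε²) — the suite verifies the consensus error is
strictly below the raw-read error at ε ∈ {0.05, 0.1, 0.2}.

# Instability calling

Instability means *new allele lengths*, so the statistic is the fraction of
tumor consensus families whose length is **novel** — outside the normal
allele support, the set of lengths backed by ≥ `min_allele_frac` (5%,
boundary inclusive) of the normal's families. This is deliberately not a
distributional test (KS, chi-square): the novel fraction is exactly
brute-forceable, robust at low family counts, and directly interpretable as
the fraction of molecules carrying somatic lengths.

* **Paired mode:** unstable ⇔ statistic ≥ τ (0.10) and both samples have
  ≥ `min_cov` (20) families; low coverage on either side yields a no-call,
  never a call.
* **Baseline mode** (unmatched tumors): the support is the union of all
  normals' supports per locus (leave-one-in: each normal is scored against
  a pool that includes itself, so the baseline's mean novel fraction is
  never inflated by its own holdout). Instability additionally requires
  the statistic to exceed the baseline mean by `z_min` (3) baseline
  standard deviations, with an SD floor of 0.01 so a noiseless baseline
  cannot make every nonzero statistic infinitely significant. With a single
  normal and the z-criterion disabled, baseline mode reduces exactly to
  paired mode — a property the suite checks.

τ, `min_cov`, `min_allele_frac`, `z_min` and the SD floor are all exposed;
none is a measured quantity. No-call loci count as stable at classification
time (conservative toward specificity) and are excluded from all frequency
denominators. Tumor-only germline inference is deliberately not attempted;
the panel-of-normals is the only unmatched path.

# The selection cascade

`select_candidate_loci()` chains four stages, each exported and testable on
its own:

1. **Polymorphism filter.** A locus whose modal consensus length differs in
   more than 5% of normals (integer-count comparison, boundary inclusive)
   is germline-polymorphic and removed.
2. **dMMR-enrichment filter.** Keep loci with training instability
   frequency ≥ 0.30 in dMMR and ≤ 0.05 in pMMR tumors.
3. **Clustering.** Loci are embedded as (frequency in dMMR, frequency in
   pMMR, overall frequency) — frequency features rather than per-sample
   indicator vectors, so the embedding is independent of sample order and
   cohort size. Hierarchical Ward clustering cut into six categories gives
   the descriptive landscape (the heatmap layer); K-means seeded at the
   category centroids refines it. Features are **not** column-standardized
   by default: standardization rescales the near-constant pMMR column so
   that one discordant tumor (frequency 0 vs 0.02) dominates all
   distances; on shared-scale frequencies this is both unnecessary and
   harmful (`standardize = TRUE` remains available).
4. **Differential-group selection.** The operational decision is binary —
   differential vs background — so the cascade separates the same feature
   space into two groups and applies the selection rule: all loci of the
   cluster with the largest mean (dMMR − pMMR) frequency gap, plus any
   cluster within 0.05 of that maximum. A fixed six-way partition is the
   wrong granularity for this decision: a homogeneous marker group carries
   the largest binomial sampling variance in frequency space
   (sd ≈ √(p(1−p)/n) ≈ 0.05 at p = 0.85, n = 50), so six-way cuts land
   inside it and split true markers across near-tied clusters. The
   two-group cut makes the differential side recover the planted marker
   set across seeds, which the six-way cut provably does not.

Candidates are the differential group intersected with the
enrichment-filtered pool, so the cascade is monotone: candidates ⊆
dMMR-filtered ⊆ polymorphism-filtered ⊆ catalog. By default only
mononucleotide loci are eligible candidates (the MSI-H rule is defined over
mononucleotide repeats); a flag relaxes this.

# Panel optimization and classification

`optimize_panel()` enumerates **all** candidate subsets of size `k_min`–
`k_max` (2–8; a budget guard refuses enumerations beyond 10⁶ subsets, and a
greedy mode is a possible extension, not a default). Each subset is scored
by the decision rule *MSI-H ⇔ ≥ `min_unstable` (2) panel loci unstable*,
with no-calls counted stable. The returned panel maximizes training
sensitivity subject to 100% training specificity; ties break toward the
smaller subset, then the lexicographically smallest sorted locus-id string —
fully deterministic. If no subset reaches 100% specificity the
(specificity, sensitivity)-lexicographic optimum is returned flagged
`constraint_met = FALSE`. The per-size best is logged (`tidy()` on the
panel), mirroring a combination-scan table. An independent exhaustive
oracle in the test suite confirms lexicographic optimality on random call
matrices.

`classify_samples()` applies the rule, demanding an explicit row (call or
no-call) for every panel locus — silently missing loci are an error.
`confusion_metrics()` reports sensitivity, specificity, PPV and NPV with
dMMR/MSI-H as the positive class, percentages formatted at two decimals;
zero-denominator metrics are `NA` and flagged, never coerced to zero.

# Numerical conventions and degenerate inputs

* Thresholds are boundary-inclusive (support floor, polymorphism fraction,
  τ); the polymorphism filter compares integer counts to avoid
  floating-point boundary artifacts.
* Modal-length ties in the polymorphism filter break toward the shorter
  length; consensus ties abstain (dropped + tallied).
* A read from a length-1 molecule that slips downward is clamped at 1
  (tract lengths are ≥ 1 by construction); reachable only at degenerate
  configurations.
* Coincident K-means starting centroids (possible when fewer distinct
  feature vectors than clusters) fall back to the hierarchical assignment,
  which is already the fixed point being refined.
* Empty cohorts, empty profiles, single-class label sets and missing
  baselines raise typed errors or explicit no-calls, never silent zeros.

# Problem sizes used by the shipped checks

The test suite and acceptance script run the full pipeline on a synthetic
study of 100 matched training pairs (50% dMMR) over 200 loci with 8 planted
informative ones at the default noise settings, validated on 60 unmatched
tumors in baseline mode — large enough for stable frequencies at the
default thresholds, small enough to re-run routinely (a few minutes on one
core). Scanner and panel-search verifications use 100 random sequences up
to 2 kb and 50 random call matrices with up to 13 candidate loci.

# Known limitations

* The novel-fraction statistic does not model stutter probabilistically;
  very low-purity tumors (purity × shift fraction < τ) fall below the
  default threshold by construction.
* Baseline mode presumes the pooled normals span the population's germline
  alleles at each locus; rare private germline alleles in unmatched tumors
  can false-positive at polymorphic loci — which is exactly why the
  polymorphism filter precedes panel selection.
* Panel candidates are selected and scored on the same training cohort;
  the held-out cohort guards the final panel, not each cascade stage.
* Gene-level consolidation of loci (many tracts per gene) is out of scope;
  an optional `gene_label` is carried through unmodified.
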