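---
title: "Detecting and dating ancient introgression with introscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ancient introgression with introscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Four closely related species, one diploid genome each, plus an outgroup: did
any of them exchange genes after speciation, where in the genome, and when?
With a single individual per species there is no population allele-frequency
information, so every statistic here is built from diploid genotypes
(frequencies in {0, 0.5, 1}) or consensus sequences. The package implements
the full tool-chain for this design — genome-wide tests, window scans,
block dating, diversity and demographic summaries — together with a
coalescent simulator that generates data of exactly this shape with known
truth, so that every stage can be calibrated and its parameter recovery
measured.

The motivating system is a dwarf-lemur clade with species tree
`(((major, crossleyi), medius), sibreei)` and a deeply diverged outgroup.
Throughout, the clade-wide constants are a per-generation mutation rate
μ = 0.8e-8, a generation time g = 4 years, and hence a per-year clock rate
μ_y = μ/g = 0.2e-8.

# Site-pattern tests

**Patterson's D.** After polarizing alleles with the outgroup (sites with a
heterozygous or missing outgroup are excluded, as are sites with any missing
ingroup genotype — the frequency terms are undefined otherwise), each site
contributes frequency-form weights

    abba = (1 − p1) · p2 · p3 · (1 − p4)
    baba = p1 · (1 − p2) · p3 · (1 − p4)

and D = (Σabba − Σbaba)/(Σabba + Σbaba). Under incomplete lineage sorting
alone the two patterns are symmetric and D ≈ 0; gene flow between P3 and P2
(or P1) skews the balance. We use the deterministic frequency form rather
than single-read sampling: with one diploid per population it is exact, and
the sampled variant is equivalent only in expectation.

Significance comes from a delete-one block jackknife over contiguous
coordinate blocks (1 Mb by default; the calibration studies use 250 kb on
5-Mb genomes so that 20 blocks exist). SE = sqrt((m−1)/m · Σ(D₋ᵢ − mean)²),
Z = D/SE. Blocks are the unit of resampling because linkage makes per-site
resampling anticonservative. Fewer than 20 blocks is an error, not a
warning — a jackknife on a handful of blocks is not a standard error.

**Windowed f_d.** To localize admixture we scan 40-kb windows advanced by
10 kb. Per window, f_d = Σnum/Σden with num = abba − baba and den the same
quantity evaluated with donor frequencies pD = max(p2, p3) substituted for
both p2 and p3 — the site-wise "dynamic donor" variant, chosen because it
remains a valid admixture-proportion estimate under bidirectional flow.
Windows whose own D is not positive (or whose denominator is not positive)
get f_d := 0 with a flag rather than being dropped: the estimator is only
meaningful for an ABBA excess, and dropping windows would bias the
genome-wide distribution used for the cutoff. Windows with no SNPs are
omitted.

Candidate regions are the windows in the top 0.05% of the genome-wide f_d
distribution over unmasked windows (the quantile is computed jointly over
the genome, not per scaffold, because the reference distribution is the
genome-wide one). The cutoff is the k-th largest value with
k = floor(n × 0.0005), all ties at the cutoff are kept, selected windows are
merged (touching intervals merge) and clipped to scaffold ends. Coverage
masking happens first: a site fails when its cross-sample mean depth is
strictly above twice or strictly below half the per-scaffold mean (values
exactly at a threshold pass — the rule is "higher than"/"lower than"), and a
window is masked when strictly more than 30% of its sites fail.

# Block detection and the divergence clock

The f_d scan localizes admixture to tens of kilobases; dating needs precise
block boundaries. The block stage works on per-sample IUPAC consensus
sequences and scans species triplets without pre-defined coordinate windows:
windows of 100 segregating sites (step 50) slide along each scaffold, the
strictly most similar pair is recorded per window, and maximal runs of
windows won by the same pair become candidate blocks.

Run boundaries are then refined to the maximal-scoring contiguous
subsegment, scoring +1 at sites where the pair is identical and the third
sequence differs and −2 at sites where the pair differs. Inside a true
introgressed tract the pair-support density is far above background, so this
trims the window-quantization overhang (windows straddling a tract boundary
otherwise drag several hundred base pairs of background divergence into the
block and inflate its age; with refinement the block-age recovery bias drops
from roughly +70% to under +10% in the calibration study). The score weights
are a design choice: −2 makes any region whose pair-mismatch density exceeds
half its support density net-negative, which holds for background sequence
in all triplets of this clade while keeping genuine low-divergence cores
intact.

Heterozygous consensus positions use a half-difference convention: an
ambiguity code against a base it contains counts 0.5 differences, disjoint
allele sets count 1, identical codes count 0 (0.5 when both are the same
heterozygous code — the expected difference between random haplotypes).
Positions where any sequence is masked (N or other ≥3-allele codes) are
excluded from counts and from the effective block length.

Each block is tested against the pair's background divergence — estimated
genome-wide from all valid sites outside candidate block spans, since
including the candidate spans would inflate the null — with the binomial
lower tail p = P(X ≤ diffs), X ~ Bin(len, background). Retention requires at
least 10 segregating sites and p < 1e-6, and blocks between the sister pair
of the triplet are removed wholesale: the sister pair is expected to be most
similar under the species tree, so its runs carry no introgression signal.
Retained blocks are dated by age = (diffs/len)/(2 μ_y): the two sequences
stopped diverging through their common history at the admixture time, so
their divergence accumulates along two branches of length `age`.

# Diversity, topology and demography

**Heterozygosity** is counted per individual in non-overlapping 100-kb
windows as n_het/(window − n_missing): positions absent from the variant
table are assumed genotyped homozygous-reference, so the denominator is the
callable window length. The paper-style rule that counts missing calls in
any species is available as `joint_missing = TRUE`; the default is per-focal
-sample, which is the statistic plotted per species. Non-overlapping windows
(rather than sliding) avoid double counting in genome-wide means; a step
option exists. Both the unweighted window mean and the pooled estimate
Σn_het/Σcallable are reported — the pooled one is invariant to window size.

**Quartet topologies.** Each 100-kb window with at least 50 SNPs gets the
neighbor-joining split of the four ingroup individuals from the
allele-sharing distance d(i,j) = mean |fᵢ − fⱼ|: for four taxa NJ reduces to
the four-point condition, the pairing minimizing d(i,j) + d(k,l). Ties are
unresolved (U). Runs of equal labels are fused into segments, and the genome
fraction per label is reported. This is deliberately a transparent surrogate
for HMM-based local-phylogeny segmentation: the deliverable — the fraction
of the genome supporting each local relationship — is the same, but there is
no hidden-state machinery to validate. Note that introgression between taxa
that sit on the same side of the central split (e.g. medius and sibreei)
shortens branches without changing the unrooted quartet topology; only
cross-split flow (e.g. medius into crossleyi) produces discordant labels.

**Demography.** MSMC2-format output (time_index, scaled boundaries, λ) is
parsed with contiguity checks, converted by t_years = (t_scaled/μ)·g and
Ne = 1/(2μλ), and summarized by the harmonic mean of Ne excluding the first
five and last five time segments, where SMC-type inference is least
reliable. The mean is unweighted across segments — the natural reading of a
"mean over time segments" — with duration weighting available as an option.
The package also emits this format for any piecewise-constant trajectory
(`make_msmc_output()`), which makes the conversion chain testable as an
exact round trip.

**Enrichment.** Whether a focal gene set (e.g. hibernation-associated genes)
is over- or under-represented among genes overlapping candidate regions is
tested with the 2×2 chi-square (df = 1), overlap meaning ≥ 1 bp under
half-open semantics. No continuity correction by default (the corrected
variant is a flag), and the direction of association is always reported
alongside p, since a "significant" result can be a deficit.

# The simulator

`simulate_dataset()` draws, for every recombination block (5 kb by default),
an independent genealogy of the ten haplotypes under the multispecies
coalescent on the fixed species tree: haplotype pairs coalesce within their
species at rate 1/(2Ne), surviving lineages enter ancestral populations at
the split times, and deep coalescence across splits produces genuine
incomplete lineage sorting — which is what makes the null D calibration
meaningful. Sequences then evolve by JC69 with per-branch Bernoulli
mutations (binomial count, uniform positions, uniform alternative base), and
all segregating sites — including the few percent that become multiallelic
through repeat hits on this deep tree — are genotyped. Multiallelic sites
are written to the VCF and excluded by the biallelic reader and the
polarization step (as in a real pipeline), but they do count for
heterozygosity; dropping them there would censor ~15–20% of heterozygous
sites and bias diversity estimates low.

Introgression tracts are implemented genealogically: within a tract the
recipient haplotype's lineage is grafted onto the donor haplotype's ancestral
lineage at the admixture time, so the tract's divergence clock age is its
specified age by construction, recombination-free and exact. A heterozygous
tract (the default) grafts one recipient haplotype; a fixed tract
(`zygosity = "hom"`) grafts both, representing a pulse that later fixed.
The outgroup can never donate or receive — the site-pattern statistics
assume an unadmixed outgroup.

Default study conditions (all overridable): splits at 2, 3, 4.5 and 7.5
million generations (8–30 My at g = 4), Ne = 100,000 on every branch —
matching the harmonic-mean Ne scale of the real species — μ = 0.8e-8,
Poisson(30) per-site coverage, and optional uniform genotype missingness.
Under these conditions expected heterozygosity is 4Neμ = 3.2e-3 and
medius–sibreei divergence is ~7%, both in the range the real genomes show.

What the simulator does *not* emulate: recombination within 5-kb blocks and
linkage beyond block boundaries (tract edges are specified, not emergent, so
block-boundary recovery is easier than in real data), mapping and
genotype-calling error, coverage autocorrelation along the genome, selection,
and population structure within species. Passing the recovery suites
therefore validates the statistical machinery and its calibration, not
robustness to upstream artifacts.

# Numerical choices and degenerate inputs

- Coordinates are 0-based half-open everywhere internally; VCF positions are
  converted at the boundary, BED passes through. Touching intervals merge.
- "Scaffolds > 100 kb" is read strictly; boundary windows are clipped, and
  regions starting beyond the scaffold end are dropped with a warning.
- The top-tail count floor(n(1−q)) is computed with a 1e-9 epsilon so that
  binary representation of quantiles like 0.9995 cannot change the count.
- f_d windows with non-positive D or denominator are zeroed and flagged;
  windows with no SNPs are omitted; all-masked inputs are errors.
- The jackknife reports Z = ±Inf with a flag when SE = 0 (e.g. perfectly
  homogeneous blocks) rather than NaN.
- Binomial block p-values floor half-integer difference counts.
- Empty region sets, empty block sets and header-only VCFs round-trip
  through every summary without special-casing by the caller.

# Calibration studies and problem sizes

The validation suite (also re-run by `scripts/acceptance.R`) uses these
study sizes, chosen to give each check clear resolution at desk-scale
runtime:

- **Null Z calibration**: 200 replicate 5-Mb genomes (ten 0.5-Mb scaffolds),
  no gene flow, jackknife blocks of 250 kb; |Z| > 3 must occur in ≤ 5% of
  replicates. Observed rates are ~1–2%.
- **f_d recovery**: 20 replicates of a 10-Mb genome with 25 fixed 40-kb
  sibreei→medius tracts (10% of the genome) at 100,000 generations; the
  genome-wide mean f_d must land within ±30% of 0.10, and ≥ 80% of tracts
  must overlap a called candidate region with the candidate quantile matched
  to the planted fraction (0.90) — the extreme 0.05% tail is the right
  cutoff for rare introgression in a 2-Gb genome, not for a toy genome that
  is 10% introgressed.
- **Block dating**: 20 replicates of 2-Mb genomes with eight 25-kb fixed
  tracts planted at 1.0 My; the mean retained-block age must be within ±25%.
  The residual +~9% bias is expected: the recipient's tract lineage
  coalesces with the sampled donor haplotype at the admixture time, but the
  donor's other haplotype can be older, and consensus comparison averages
  over both.
- **Heterozygosity**: three 5-Mb genomes at Ne = 1e5; the mean pooled
  heterozygosity must be within ±10% of 4Neμ (a single 5-Mb genome carries
  ~5% coalescent noise, so three are averaged).
- **Topology concordance**: one 5-Mb null genome; ≥ 99% of classified 100-kb
  windows must carry the species-tree label.
- **Oracles**: 1,000 random interval instances against per-base brute force,
  and window sums against naive per-site loops at 1e-12.

The headline numbers of the real-data study (D = 0.014/0.06 with Z up to 54,
f_d cutoffs of 0.137/0.188, mean block age 4.12 My, harmonic-mean Ne near
1e5, heterozygosity 0.001–0.004) derive from ~30× whole genomes and are not
reproducible at these scales; what the studies above verify is that every
estimator recovers known truth under the stated conditions.

# Known limitations

- One diploid per species is assumed throughout; the statistics do not use
  population frequencies and the simulator cannot generate them.
- The species-tree shape is the fixed ladder topology with a sister cherry;
  other four-taxon shapes would need a different simulator configuration.
- Block dating assumes a strict clock and no recombination within blocks;
  ages of overlapping or recombined tracts will be mosaics.
- The topology stage cannot see same-side introgression (by construction of
  unrooted quartets), and the block stage removes sister-pair blocks, so
  gene flow between sister species is outside the detectable scope — as it
  is for the D and f_d statistics themselves.
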