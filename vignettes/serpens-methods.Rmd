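---
title: "Models and methods behind serpens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serpens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

serpens detects genes under repeated directional selection across replicated
pairs of populations on contrasting substrates — the motivating system is
autotetraploid plants colonising toxic serpentine soils from adjacent
non-serpentine source populations — and classifies the evolutionary source of
each parallel candidate allele: independent de novo mutation, shared
ancestral standing variation, or migration between adapted populations. This
vignette explains the models, the tunable parameters, the synthetic-data
generators, and the numerical and design choices; it states no empirical
result that the package's tests do not themselves compute.

## The analysis chain

1. **Ingestion and filtering.** Genotypes are allele dosages 0–4 read from a
   ploidy-4 VCF. A genotype is kept only at read depth >= `min_depth`
   (default 8; applied as an inclusive minimum); a site is dropped when its
   fraction of filtered genotypes exceeds `max_missing_fraction` (default
   0.2). Two site masks flag likely collapsed paralogs: mean depth above the
   global mean plus `depth_mask_sd` (2) standard deviations, and a fraction
   of heterozygous calls (dosage not in {0, 4}; all heterozygote classes
   treated identically) above `het_excess_threshold` (default 0.9 — the
   exact cutoff is a free choice, so it is exposed). Minor-allele-frequency
   floors are stage-local: none for diversity statistics, 0.05 for the
   association stage.
2. **Windowed differentiation scan.** Hudson's F~ST~ estimator with
   ratio-of-averages aggregation over non-overlapping 1-kb windows anchored
   at position 0 of each chromosome, requiring >= 10 SNPs per window. Fixed
   windows keep positions identical across population pairs so candidate
   windows are directly comparable; the estimator was chosen for its
   robustness to unequal sample sizes. Negative estimates are kept — they
   fall below any upper-quantile threshold anyway. Outlier windows are the
   upper 1% of the empirical distribution per pair (ties included); genes
   overlap outlier windows by >= 1 bp over their full spans (UTRs and
   introns included). Genes flagged in at least two pairs are *parallel
   differentiation candidates*; multi-list overlap significance uses the
   exact hypergeometric tail for two lists and, for more lists, a
   product-form binomial tail cross-checked against a seeded Monte Carlo
   permutation oracle (disagreement beyond 3 Monte Carlo standard errors
   raises a warning rather than silently preferring either).
3. **Genotype–environment association.** For each of the four soil
   variables that discriminate the substrates (Ca/Mg ratio and bioavailable
   Mg, Ni, Co), each SNP's centered dosage is regressed on the centered
   variable plus K latent ancestry factors (default K = 5, matching the
   number of population pairs). The factors are the truncated-SVD scores of
   the column-centered dosage matrix, the closed-form deterministic
   equivalent of a ridge latent-factor association model; z-scores are
   recalibrated by the genomic inflation factor
   λ~GC~ = median(z²)/0.4549 before χ²₁ p-values, and q-values control the
   FDR (Benjamini–Hochberg with conservative π₀ = 1 by default; Storey's
   estimate is opt-in). A gene is environment-associated when at least one
   SNP in its span has q < 0.05 for at least one variable; each variable is
   tested separately and results are unioned. The final *serpentine
   adaptation candidates* are the intersection of the parallel and the
   environment-associated lists.
4. **Mode-of-convergence classification.** For each candidate gene on each
   quartet of populations formed by two supporting pairs
   (S_i, N_i, S_j, N_j), a composite likelihood compares four scenarios of
   allele-frequency coancestry around a proposed selected site (below).

## The coancestry model

The neutral baseline F is a 4×4 matrix of standardized allele-frequency
covariances estimated from genome-wide putatively neutral SNPs: per SNP the
sample frequencies are centered on the across-population mean ε and divided
by sqrt(ε(1−ε)); F is the mean outer product, with the binomial sampling
term 1/a_i removed from the diagonal and a projection to the nearest
positive-semidefinite matrix when estimation noise requires it. The baseline
is estimated on the same mean-frequency class the likelihood later scores
(ε in [0.05, 0.95]): under realistic site-frequency spectra the standardized
covariance of rare variants is systematically smaller than that of common
variants, and a baseline averaged over the (mostly rare) genome would make
every common site look over-dispersed, which a scenario fit could soak up
spuriously.

A sweep at distance d keeps a neutral lineage linked with probability
y = exp(−r d τ), with sweep duration τ = log(A s)/s and A = ploidy × N_e
allele copies (so the machinery runs diploid by setting ploidy = 2; defaults
r = 2e−8 per bp per generation and N_e = 30,000, both configurable — the
order of magnitude is consistent with the observed diversity near 0.03 at a
mutation rate of 4.3e−8). The four scenarios transform F entrywise:

* **NEUTRAL** — F unchanged.
* **IND** (independent de novo mutations): for each selected population,
  F'_ii = y² + (1−y²)F_ii. Off-diagonals are untouched: independent sweeps
  never raise cross-population covariance.
* **STANDING** (shared ancestral standing variation at frequency g for t
  generations): coalescence at rate δ = 1/(A g) competes with per-lineage
  recombination ρ = r d during the standing window;
  P_coal = (δ/λ)(1 − e^{−λt}) with λ = δ + 2ρ. Cross-population selected
  entries become y²(P_coal + (1−P_coal) F_ij) + (1−y²)F_ij.
* **MIG** (transfer from a source population at rate m): recipient–source
  and recipient–recipient entries use
  P_mig = 1/(1 + 2 A m ρ) in place of P_coal, anchored on the source's
  coancestry.

Selected-population *diagonals* take the sweep-forced form
y² + (1−y²)F_ii under every non-neutral scenario: the sweep itself forces
within-population coalescence of linked lineages whatever the allele's
origin, and only cross-population sharing carries information about that
origin. (Applying the standing-phase formula to the diagonal as well makes
the selected block nearly rank-one; with four mean-centered populations a
rank-one raise of the selected pair is exactly collinear with raising the
opposite pair, which destroys the identifiability of *where* selection
acted. The diagonal/cross split restores the discriminating signal while
preserving the defining property that only shared origins raise
cross-population covariance.)

The composite log-likelihood of a scenario for one gene sums, over all SNPs
within the gene ± 25 kb with quartet mean frequency ε in [0.05, 0.95], the
Gaussian log-density of the mean-centered frequency vector in the
3-dimensional mean-free subspace, with covariance
ε(1−ε)·C(F'(d)), where C adds binomial sampling variance to the diagonal.
The added sampling term is max(1−F'_ii, 0.5)/a_i: the model term
(1−F'_ii)/a_i alone vanishes as F'_ii → 1, making extreme grid corners
exactly singular — unbounded log-density spikes that reward whichever run
happens to place them near the data — whereas sampled frequencies in fact
always retain residual binomial noise because hitchhiking is never complete.
Eight proposed selected-site positions are spaced evenly across the gene
body (the flanks enter only through distance), and the maximum over
positions and the parameter grid (s in {0.001, 0.01, 0.05, 0.1, 0.5},
g in {0.001, 0.005, 0.01, 0.05, 0.1}, t in {50, 500, 1000, 5000},
m in {1e−5, …, 1e−2}, source in the selected set) is the scenario's MCL.
Composite likelihoods are valid for model comparison, not standard errors.

### Decision rules

Each case is fitted twice: selection placed in the two serpentine members
and in the two non-serpentine members. Let Δ_S and Δ_N be the largest MCL
advantage of any non-neutral scenario over neutral in each run. A case is

* **neutral** unless Δ_S > 21, a conservative cutoff taken as the maximum of
  the neutral-simulation difference distribution (the package's neutral
  calibration test reproduces this: at the default threshold at least 95% of
  neutral simulations classify as neutral);
* otherwise **excluded as ambiguous** unless Δ_S exceeds
  (1 + 0.10)·max(Δ_N, 0) — selection in the serpentine populations must fit
  considerably (10%) better than selection in the non-serpentine ones. The
  "10% higher" rule is applied to ΔMCL (scenario minus neutral), not raw
  MCLs, since raw composite log-likelihoods are sign-ambiguous; the margin
  and its base are arguments.
* otherwise classified by the best non-neutral scenario, with one
  qualification: the STANDING and MIG families nest IND (their
  sharing probability can approach zero on the grid), so a plain argmax
  would never return IND — the richer family always gains a small
  grid-overfitting advantage. A shared-origin scenario is therefore chosen
  over IND only when its MCL advantage exceeds a parsimony margin of 8,
  calibrated once as a conservative bound just above the largest overfit
  gap observed on data simulated under independent sweeps (the same
  max-of-null logic as the neutral threshold). STANDING and MIG are
  reported individually and also collapsed to *shared origin*, since both
  mean selection called on the same allele rather than independent
  mutations.

## Synthetic data

Two generators cover different needs.

**The multivariate-normal generator** draws quartet frequencies directly
from the coancestry model: ε from a neutral-SFS-like density ∝ 1/x
truncated to [0.02, 0.98], the frequency vector from
N(ε, ε(1−ε)F'(d)) truncated to [0, 1], then binomial sampling to the
per-population allele-copy counts. It is the calibration instrument: by
construction the only mismatch between generator and classifier is
truncation and binomial sampling.

**The forward Wright–Fisher pair simulator** emulates the study design: a
common root, regional ancestors, and five serpentine/non-serpentine pairs
splitting T_pair = 3,000 generations ago (the reported range is roughly
2,700–4,300), eight tetraploid individuals per population, N_e = 30,000.
Its design choices:

* *Branch drift* uses conditioned Beta (Balding–Nichols) transitions with
  variance factor 1 − exp(−t/A) — exactly the coancestry accumulation the
  downstream model assumes — rather than generation-by-generation binomial
  drift, which at A = 120,000 copies across ~10^5 sites and thousands of
  generations would cost orders of magnitude more time while changing
  nothing the pipeline consumes. Planted selected loci *are* iterated
  generation by generation (deterministic genic selection with a
  dosage-response exponent, then binomial drift), conditioned on
  establishment: a planted sweep that drift happens to lose is a failed
  plant, not a study condition.
* *Regional structure* is a Gaussian copula across regions on the
  stationary 1/x frequency marginal (`rho_regional = 0.985`). The copula
  preserves the stationary site-frequency spectrum exactly; an equivalently
  deep mutation-free drift branch would deplete rare variants and push
  Tajima's D above its realistic range (observed values in such systems are
  mildly positive). The default makes regions 2–3× more differentiated than
  the pairs within them — populations group by geography, not substrate —
  while keeping the within-pair neutral correlation moderate; very tight
  within-pair coupling makes "selection on S" and "selection on N"
  statistically near-equivalent in a mean-centered quartet, which would
  defeat the direction rule on any data.
* *Site densities*: 36 ancestrally polymorphic plus 62 invariant sites per
  1-kb window. The polymorphic:total ratio pins the analytic expectation of
  per-site diversity (`analytic_pi()`) at ≈ 0.030, the observed level in
  the motivating system; with μ = 4.3e−8 and N_e = 30,000, strict
  mutation-drift equilibrium would instead give ≈ 0.010 — the published
  parameters are only order-of-magnitude consistent, and the generator
  anchors on the observed diversity, using N_e for the drift timescale.
* *Hitchhiking* around planted loci is applied deterministically at
  sampling time: in each selected population, linked-site frequencies move
  toward the swept haplotype with weight y(d)·q_B (q_B the final beneficial
  frequency), with r = 2e−6 per bp per generation so the footprint decays
  within a few kb — consistent with the rapid decay of genotypic
  correlations (hundreds of bp) reported for such genomes; a textbook
  r = 2e−8 would sweep half-megabase footprints across the 1-Mb fixture.
  Haplotype identity between the two selected populations is drawn per site
  with the model's own sharing probability (the standing-phase competing
  exponentials, or the migration form), shared draws coming from the
  ancestral pool and unshared draws from each population's own pre-sweep
  frequencies; under IND the draws are always independent. A consequence of
  taking the sharing formula seriously: planted standing alleles must be
  rare (g = 0.001 in the canned fixtures) for coalescence to beat
  recombination at kb scales — the canonical rare-standing-variant regime.
  Distinct sites are otherwise unlinked; this is the generator's key
  simplification, so it cannot be used to study LD-based statistics.
* *Soil covariates* get substrate-shifted means (higher Mg, Ni, Co; lower
  Ca/Mg on serpentine), pair-level random effects, and individual noise;
  TE presence/absence variants are scattered at 0.3/kb with one placed
  inside each planted gene so the TE-based scan has true positives.
* Everything is a pure function of (configuration, seed).

What passing tests on this data do *not* show about real data: calling
error and depth artifacts beyond simple Poisson depths, linkage
disequilibrium among neutral sites, soft or partial sweeps, gene flow among
non-selected populations, and reference bias are all outside the generator.

## Pipeline choices

`run_all()` estimates the ancestry factors on SNPs outside 5%-outlier
F~ST~ windows (any pair): sweeps at selected loci otherwise create a
substrate-aligned dosage axis that truncated-SVD factors absorb, erasing
the very associations the stage must detect — the analogue of running
structure analyses on putatively neutral SNPs. The neutral SNP set for the
coancestry baseline is, absent a codon-level annotation, taken as SNPs
outside gene spans ± 5 kb; with a FASTA and CDS-bearing GFF3,
`fourfold_degenerate_sites()` provides the classical fourfold-degenerate
mask instead. All randomness flows from the single config seed; reruns are
identical.

Problem sizes used by the shipped checks (chosen to exercise every stage at
desk scale): the default fixture is one 1-Mb chromosome, 50 genes, 5 pairs,
80 individuals, ~98,000 sites, with four planted STANDING genes and one
planted IND gene (shared origins dominant with a single de novo exception,
echoing the study design the package emulates); the tiny fixture is 200 kb,
2 pairs, 10 genes. Estimator-sanity checks use 30 replicates of a 50-kb
neutral simulation; neutral calibration uses 100 model-faithful replicates;
scenario recovery uses 50 genes per scenario at s = 0.05, 150 SNPs, 32
copies per population.

## Known limitations

* The composite likelihood treats SNPs as independent; p-values or standard
  errors must not be read off it, only model comparisons.
* With four mean-centered populations the direction rule (S vs N) loses
  power as within-pair neutral correlation approaches 1; quartets of very
  tightly coupled pairs will legitimately return "ambiguous".
* The MIG constructor follows a self-contained closed form whose coupling
  probability decreases with m·ρ; MIG/STANDING discrimination is weak by
  construction and the two are reported collapsed as shared origin.
* The Gaussian score is a second-moment approximation; sites with extreme
  quartet mean frequency, where hitchhiked frequencies are Bernoulli-like,
  are excluded (ε window) rather than modelled.
* Tetraploid genotype uncertainty (dosage mis-calls) is not modelled beyond
  the depth filter.
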