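# serpens

Detecting parallel selection across replicated population pairs and
classifying where the selected alleles came from.

## The problem

When several populations of one species independently colonise the same
hostile environment — here, autotetraploid plants invading toxic serpentine
soils (low Ca/Mg, elevated Mg, Ni, Co) from adjacent non-serpentine
populations — the same genes are often hit by selection repeatedly. Three
evolutionary routes can produce that pattern: independent **de novo**
mutations at the same locus, repeated recruitment of **shared ancestral
standing variation**, and **migration** of an adaptive allele between
already-adapted populations. Telling these apart matters: it determines how
repeatable adaptation is and how fast a species can respond when the
selective challenge recurs.

serpens implements the full inference chain for replicated
serpentine/non-serpentine (S/N) population pairs with tetraploid dosage
genotypes:

1. ploidy-aware VCF ingestion with depth / missingness / paralog filters;
2. windowed Hudson *F*~ST~ scans (1-kb windows, ratio of averages,
   ≥ 10 SNPs) and top-1% outlier candidate genes per pair, plus diversity
   statistics (π, Tajima's *D*) with per-site downsampling and
   fourfold-degenerate site extraction;
3. parallel differentiation candidates (genes flagged in ≥ 2 pairs) with
   exact/Monte-Carlo multi-set intersection tests, and a TE-associated
   candidate scan;
4. genotype–environment association with latent-factor confounder
   correction, genomic control, and q-value FDR;
5. a composite-likelihood model of allele-frequency coancestry around
   proposed selected sites that fits four scenarios — neutral, independent
   mutation (IND), standing variation (STANDING), migration (MIG) — on each
   candidate gene × population quartet, and classifies the source with
   conservative decision rules (neutral unless ΔMCL > 21; excluded unless
   the serpentine-selected fit beats the non-serpentine one by > 10%;
   STANDING/MIG collapsed to *shared origin*).

The core statistic is the composite log-likelihood of mean-centered quartet
allele frequencies x ~ N(ε, ε(1−ε)·C(F′(d))), where F′(d) transforms the
neutral coancestry matrix F under each scenario as a function of distance d
from the proposed selected site through the sweep-retention probability
y = exp(−r·d·log(A·s)/s), with A = 4·N~e~ allele copies (tetraploid).
Only shared-origin scenarios raise *cross*-population covariance between
selected populations; independent sweeps raise within-population terms
only — that asymmetry is what the classifier exploits.

A first-class synthetic-data module supplies everything the pipeline
consumes: a forward Wright–Fisher tetraploid pair simulator with planted
selected genes, substrate-shifted soil covariates and TE variants, and a
model-faithful multivariate-normal generator used for calibration. See the
methods vignette (`vignettes/serpens-methods.Rmd`) for models, parameter
defaults, and design rationale.

## Worked example

Simulate a replicated study (five S/N pairs, 1-Mb chromosome, four genes
selected from shared standing variation and one by independent de novo
mutations), then run the whole pipeline:

```r
library(serpens)

paths <- emit_fixture("default", dir = "fixture", seed = 42)
bundle <- attr(paths, "bundle")

cfg <- run_config(vcf = paths$vcf, gff = paths$gff,
                  popmap = paths$popmap, env = paths$env, te = paths$te,
                  r_bp = bundle$cfg$r_bp, seed = 42)
report <- run_all(cfg, out_dir = "fixture/out")
report
```

```
serpens pipeline report
  80 individuals, 98005 sites, 5 population pairs
  per-pair candidate genes: 2, 2, 3, 2, 1
  parallel candidates (>= 2 pairs): 5 (intersection p = 1)
  environment-associated genes: 7 (lambda_gc: 1.87, 1.84, 1.81, 1.80)
  serpentine adaptation candidates: 5
  TE-based parallel candidates: 5
  source classification:
    neutral      0
    ambiguous    1
    de_novo      1
    standing     3
    migration    0
```

Reading this: each pair's top-1% *F*~ST~ windows flag 1–3 genes; five genes
are candidates in at least two pairs (with only 50 genes in the universe the
overlap count itself is unsurprising — hence the intersection p near 1);
seven genes carry soil-associated SNPs (λ~GC~ ≈ 1.8 reflects the residual
within-pair structure the five latent factors cannot absorb; the genomic
control step recalibrates for it), and their intersection with the parallel
list leaves the five planted genes as serpentine adaptation candidates. The classifier then recovers the planted
design: three of the four standing-variation genes as `standing` (shared
origin), the de novo gene as `de_novo`, one case left `ambiguous` by the
conservative 10% direction rule:

```r
report$sources$per_gene[, c("gene", "classification", "source")]
merge(bundle$truth[, c("gene", "mode")], report$sources$per_gene)
```

Per-gene truth vs call (from the run above): `gene_002 STANDING → standing`,
`gene_014 STANDING → standing`, `gene_026 STANDING → ambiguous`,
`gene_037 STANDING → standing`, `gene_049 IND → de_novo`.

Diversity statistics on the same data land where the emulated system lives
(π ≈ 0.03, mildly positive Tajima's *D*, pairwise *F*~ST~ ≈ 0.025):

```r
gm <- read_tetraploid_vcf(paths$vcf, paths$popmap)
nucleotide_diversity(gm, "S1")
#> diversity_stat [S1]: pi = 0.030359 over 98005 sites (>= 6 inds/site)
```

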