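---
title: "Genomic cline outlier detection with clinekit: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic cline outlier detection with clinekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinekit)
```

## The model

Genomic cline analysis contrasts per-locus introgression against the
genome-wide admixture gradient. Each admixed individual carries a hybrid
index $h \in [0,1]$, the fraction of its genome derived from parental
population 1. Under the polynomial genomic cline model, the probability
that a gene copy at locus $i$ in an individual with hybrid index $h$
derives from population 1 is

$$\phi_i(h) = h + 2h(1-h)\left[\alpha_i + \beta_i(2h - 1)\right],$$

clamped to $[0,1]$. The two per-locus parameters have direct
interpretations: the **cline center** $\alpha$ shifts ancestry probability
up ($\alpha>0$, excess population-1 ancestry) or down ($\alpha<0$), and
the **cline rate** $\beta$ steepens ($\beta>0$) or widens ($\beta<0$) the
ancestry transition. The polynomial form pins the endpoints,
$\phi(0)=0$ and $\phi(1)=1$, because $2h(1-h)$ vanishes there; clamping
only activates when $|\alpha|$ or $|\beta|$ is large enough to push the
cubic outside the unit interval, and never for the neutral cline. The
useful algebraic identities — $\phi(h;0,0)=h$,
$\phi(0.5;\alpha,\beta)=0.5+0.5\alpha$, and the ancestry symmetry
$\phi(h;\alpha,\beta) + \phi(1-h;-\alpha,\beta) = 1$ before clamping —
are asserted by the test suite over dense grids and random parameters.

`clinekit` does not estimate $\alpha$ and $\beta$; that is the job of the
bgc MCMC sampler (or Introgress). The package prepares bgc/Introgress
inputs, aggregates bgc's posterior output, classifies outlier loci, and
visualizes the results.

## Posterior aggregation

bgc is run as several independent replicate chains; its `estpost` tool
extracts per-parameter text files which must be named
`prefix_stat_param_replicate`. `combine_bgc_output()` discards the first
`burnin` draws of each replicate and keeps every `thin`-th draw
thereafter. The retention convention is anchored at the burn-in point:
0-based draw indices $i \ge \text{burnin}$ with
$(i - \text{burnin}) \bmod \text{thin} = 0$ are kept, so each replicate of
$S$ draws retains exactly $\lceil (S - \text{burnin})/\text{thin} \rceil$
draws and retained counts are predictable before parsing. Replicates are
concatenated in replicate order with per-draw provenance, which
`trace_stats()`/`plot_traces()` use for visual mixing checks
(per-replicate mean, variance, and lag-1 autocorrelation, with the lag-1
autocorrelation of a constant trace defined as 0). Diagnostics are
advisory; nothing downstream is gated on them, because convergence
assessment for these models is conventionally visual.

estpost's text orientation varies across versions and flags, so the
parser takes explicit `orientation` and `has_header` arguments rather
than sniffing the file — deterministic parsing was preferred over
convenience. Direct HDF5 ingestion (bypassing estpost) is not
implemented; the text route is the supported path.

## Outlier detection

`classify_outliers()` applies up to two rules per locus, independently
for $\alpha$ and $\beta$, and tracks signs throughout.

**Credible-interval rule.** A locus is an outlier when its equal-tailed
posterior credible interval at mass `level` (default 0.95) excludes the
neutral value 0 — positive if the lower bound is above 0, negative if the
upper bound is below 0. Equal-tailed intervals use the type-7
linear-interpolation quantile rule, which makes intervals nest: raising
`level` never turns a non-outlier into an outlier (a property test). An
HPD option exists (`ci_method = "hpd"`) for skewed posteriors but is not
the default: equal-tailed is the common choice in bgc practice and is
directly testable against an order-statistic oracle.

**Prior-quantile rule.** bgc also reports, per locus, the quantile of the
point estimate within the zero-mean Gaussian conditional prior (the
$\gamma$ quantile for $\alpha$, the $\zeta$ quantile for $\beta$). The
rule flags loci whose posterior *median* quantile falls in the prior's
tails: below $(1-n)/2$ or above $(1+n)/2$, where $n$ is the central prior
mass (default 0.95). Two documented interpretations were required here:

* The bound pair is sometimes printed as "$n/2$ and $(1-n)/2$", which
  cannot define a two-sided region (for $n=0.95$ it would be 0.475 and
  0.025). The implemented reading treats $n$ as the central credibility
  mass with symmetric tails $(1-n)/2$ on each side, so that uniform
  quantiles are flagged at rate $1-n$ — the calibration the test suite
  verifies to within ±0.01 at $n \in \{0.90, 0.95, 0.975\}$.
* The posterior **median** (not mean) of the quantile parameter is used,
  for robustness to skewed quantile posteriors.

The final per-parameter verdict combines the selected methods by OR
(`combine = "any"`, default) or AND (`"all"`). $\alpha$ and $\beta$
classifications never influence one another; "both" is reported, not
imposed. No multiple-testing correction is applied beyond these two
rules.

## Input preparation and filtering

`read_vcf()` codes diploid genotypes as the count of the first ALT allele
(0/1/2, `NA` missing) and extracts allele-depth (`AD`) read counts when
present, for bgc's genotype-uncertainty mode. `read_phylip()` decodes
concatenated-SNP alignments: two-base IUPAC ambiguity codes are
heterozygotes, `N`/`-`/`?` are missing, and three/four-base codes
(B, D, H, V) are treated as missing with a warning because a biallelic
model cannot represent them. PHYLIP allele order is by first observation
in the column and is recorded so exports are reproducible.

`filter_genotypes()` applies its rules in a fixed order — non-biallelic,
monomorphic, per-locus occupancy, per-individual occupancy (over
surviving loci), minor allele frequency (over non-missing calls of
surviving individuals), seeded random subsampling — because each stage's
statistics are computed on the previous stage's survivors and the output
depends on the order. Site-validity before occupancy before frequency is
the common convention. Two consequences worth knowing:

* Whether per-individual missingness is computed before or after locus
  filters is a genuine design choice; computing it after (as here) means
  an individual is judged on the loci that remain analysable.
* Monomorphism is judged from the per-locus allele count recorded at read
  time (VCF allele declarations, or bases observed in the alignment), not
  re-derived from surviving genotypes — a polymorphic locus is not
  reclassified because missing calls hide one allele.

MAF is computed over non-missing genotypes of retained individuals.
Subsampling uses an isolated, explicitly seeded PRNG stream and never
perturbs the session's RNG state.

The bgc three-file dialect (per-locus `locus_<i>` headers, per-admixed-
population `pop_<j>` headers, two-integer lines summing to 2 in genotype
mode or read depths in read-count mode, `-9 -9` missing) is pinned by the
writer/reader pair: `read_bgc_input()` is the exact inverse of
`write_bgc_input()` up to synthesized sample names, and a `strict` flag
rejects malformed lines. Introgress tables are written loci-as-rows,
individuals-as-columns, genotypes as `A/C`-style allele pairs with
`NA/NA` missing and a codominant (`C`) loci table.

## Genome mapping

Coordinate conventions are pinned per format: GFF3 is 1-based inclusive
(kept as-is), PAF target coordinates are 0-based half-open (shifted by +1
on input), and everything internal is 1-based inclusive. When a scaffold
has several alignments, the best mapping wins: highest mapping quality,
ties by longest alignment block, then file order — deterministic even
though the upstream scaffolding tools do not document their ordering.
Lifting is exactly invertible per scaffold (`unlift_coordinates()`), a
property tested on 1000 random SNPs. SNPs on unmapped scaffolds are
carried as `UNPLACED`, not errors. Gene overlap uses inclusive interval
containment; a SNP overlapping several genes is assigned the gene with
the lowest start coordinate (arbitrary but deterministic). Ideogram bands
are centred on the lifted position, wide for in-gene SNPs and narrow for
scaffold SNPs (defaults 2 Mb and 0.5 Mb, sized for chromosomes of tens to
hundreds of Mb; both are user parameters), and clipped to chromosome
bounds.

## Environmental associations

`clines_x_environment()` consumes a pre-extracted per-sample covariate
table (raster extraction and niche modelling are out of scope). The
hybrid-index panel is an ordinary least-squares fit of hybrid index on
the covariate; per-locus panels regress genotype class (0/1/2) on the
covariate, linear by default with a logistic option on the allele-copy
proportion — the smoother is a documented choice, since the per-locus
relationship has no canonical form. Confidence bands default to 95%.
Zero-variance covariates are rejected by name.

## The synthetic-data generator

`simulate_bgc_posterior()` emulates bgc's *output*, not hybridization
itself. Its noise model is the part that matters for interpreting test
results:

* Each locus first draws a **point estimate** once,
  $\hat\alpha_i \sim \mathcal N(\alpha_i^{\mathrm{true}}, \sigma)$ (and
  likewise $\hat\beta_i$), shared across replicates — analysing a finite
  dataset does not centre the posterior on the truth. MCMC draws then
  scatter as $\mathcal N(\hat\alpha_i, \sigma)$ with the same
  `posterior_sd` $\sigma$ (default 0.2). This makes the simulated
  posteriors frequentist-calibrated: a true-zero locus's 95% credible
  interval excludes zero with probability close to 5%, so the type-I rate
  and sensitivity/FPR of the outlier rules are meaningful measurements
  rather than artefacts of the generator.
* Prior-quantile draws are the point estimate's quantile within the
  $\mathcal N(0, \sigma_{\mathrm{prior}})$ conditional prior
  ($\sigma_{\mathrm{prior}} = 1$ by default; only its relative scale
  matters) plus small Gaussian noise, clipped to $[0,1]$.
* Hybrid-index draws are Beta-distributed around each individual's true
  $h$; the log-likelihood trace is a stationary AR(1) series (default
  lag-1 autocorrelation 0.5) so trace diagnostics have something to
  measure.
* Draws are otherwise iid across iterations. Real MCMC output is
  autocorrelated and occasionally non-stationary; passing tests therefore
  demonstrate correct burn-in/thinning arithmetic, interval computation,
  and classification logic, *not* robustness to poorly mixed chains —
  that remains the user's visual check via `plot_traces()`.
* Default MCMC geometry is 2 replicates × 1000 draws; the statistical
  acceptance checks run at these defaults with the worked aggregation
  settings (burn-in 200, thinning 2), giving 800 retained draws per
  replicate pair per locus. Sizes were chosen to keep the full suite in
  the minutes range while leaving binomial noise well inside the asserted
  tolerances.

`simulate_genotype_data()` draws parental genotypes
$\mathrm{Bin}(2, p)$ at per-population allele frequencies (defaults 0.1
vs 0.9 — strongly differentiated loci, the informative case for cline
input), admixed genotypes $\mathrm{Bin}(2, h p_1 + (1-h) p_0)$ with
per-individual $h \sim \mathrm U(0.1, 0.9)$, and serializes the same
matrix as VCF (with depths proportional to allele copies), PHYLIP, and a
popmap. It does not simulate linkage, genotyping error beyond missingness,
or spatial structure. All generators are pure functions of their seed;
byte-identical output under a repeated seed is itself a test.

## Numerical and degenerate-input choices

* Quantiles everywhere are type-7 (linear interpolation between order
  statistics); intervals from them nest in the level.
* Lag-1 autocorrelation of a constant trace is 0 by definition.
* Outlier classes with fewer than three loci yield no hull polygon
  (degenerate geometry); their points are still reported.
* Hulls default to convex (`grDevices::chull`, deterministic and
  dependency-light). The concave option is a k-nearest-neighbour
  boundary walk that falls back to the convex hull whenever the walk
  fails to enclose every point, so hull containment holds in both modes.
* The 2-D density in α–β space uses `MASS::kde2d` with its
  normal-reference bandwidth on a 100 × 100 grid; purely presentational.
* φ curves and the α–β scatter use posterior medians, consistent with the
  outlier rules; curves are drawn per point estimate, not per posterior
  draw.
* Empty-after-filtering, burn-in ≥ chain length, mismatched α/β replicate
  sets, samples missing from popmaps, out-of-range scaffold positions,
  and karyotype-absent chromosomes are all hard errors that name the
  offending stage, replicate, sample, or chromosome.

## Known limitations

* bgc, Introgress, Minimap2, and niche-modelling tools are not executed;
  the package prepares their inputs and consumes their outputs.
* No HDF5 ingestion; estpost text files are required.
* No linkage-map export for bgc's linkage model, and no genind ingestion
  (VCF/PHYLIP cover the same content).
* The quantile-rule bounds implement a documented interpretation of an
  ambiguously printed expression (see above); results at extreme `n`
  should be read with that in mind.
* Multiallelic sites are dropped rather than decomposed; read counts are
  taken from `AD` only.
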