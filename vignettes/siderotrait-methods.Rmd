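---
title: "Methods: inferring siderophore-uptake trait prevalence and its environmental drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring siderophore-uptake trait prevalence and its environmental drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siderotrait)
```

# The scientific problem

Many *Prochlorococcus* and *Synechococcus* cells cannot synthesise
siderophores but carry a compact gene cluster that lets them pirate
iron bound to siderophores made by other microbes: a TonB-dependent
outer-membrane receptor plus an ABC transporter (solute-binding protein,
permease, ATPase) and the TonB–ExbB–ExbD energising module. Whether a
given picocyanobacterial population carries this uptake cluster — and
which environmental conditions favour carriers — is an ecological
question that can be answered from sequence data alone, but every step
is statistically delicate:

1. genomes (especially single-cell assemblies) are incomplete, so an
   absent cluster is weak evidence of a true non-carrier;
2. metagenomes observe gene abundances, not genomes, so carrier
   fractions must be built from normalized read counts;
3. candidate environmental drivers are many, strongly inter-correlated,
   and partially missing.

`siderotrait` implements the full inferential chain — cluster calling,
completeness-corrected trait-frequency estimation, a metagenomic
trait-fraction statistic, a PCA + random-forest + Boruta driver-ranking
pipeline, and a binned beta regression with marginal means — together
with synthetic-data generators that provide known ground truth for every
stage.

# Cluster calling from gene neighborhoods

A genome is called a **consumer** when an anchor gene (TonB-dependent
receptor, PF00593/COG4771) has at least `quorum` (default 5) of the six
accessory families within `window` genes (default ±8) on the same
contig, **or** when the anchor lies within `edge_margin` genes of a
contig end. The second branch encodes the asymmetry of evidence: a
truncated neighborhood cannot veto a call, because the missing genes are
unobservable rather than absent. The width of "adjacent" is not a
biological constant; ±8 genes spans a typical transport operon plus
slack and is configurable in `trait_profile()`. Coordinates are gene
ordinals, not nucleotides, because the rule is stated in terms of gene
adjacency.

Two deliberate conventions, both switchable: a single gene matching two
accessory families counts both (fused genes exist), and `edge_margin`
defaults to `window` so that "interrupted" means exactly "the window
does not fit". Family assignments are inputs (eggNOG-style annotations);
the package performs no sequence similarity search. Siderophore
*biosynthesis* screening is likewise an upstream concern: a genome
carrying both synthesis and transport genes is a producer, not a pirate,
and callers can supply that flag as an external column.

# Trait frequency from incomplete genomes

Let $d_i \in \{0,1\}$ be the verdict for genome $i$ and $c_i \in (0,1]$
its completeness. Under the simplest dropout model — every gene is
recovered independently with probability $c_i$ — a single-copy locus is
observed with probability $c_i$ given the trait, so the naive rate
$\sum d_i / n$ underestimates the true frequency $f$. Two corrections
are provided:

* **moment**: $\hat f = \sum_i d_i / \sum_i c_i$, the unbiased ratio
  estimator under single-locus detection, clipped to $[0,1]$ with a
  warning (the ratio can exceed 1 in finite samples); a percentile
  bootstrap over genomes (B = 2000) gives the interval.
* **maximum likelihood**: $d_i \sim \mathrm{Bernoulli}(f\,p_i)$ with a
  pluggable detection model $p_i = p(c_i)$, maximised by 1-D bounded
  search with a profile-likelihood interval.

The detection model is where the cluster-calling rule re-enters. The
full rule detects a consumer not when one locus survives but when the
anchor survives *and* (five of six accessory genes survive *or* the
contig is interrupted). `rule_detection_prob()` computes this
probability exactly by enumerating accessory retention patterns and
folding in the binomial law of retained flanking genes; it assumes the
generator's operon layout (three accessory genes on each side of the
anchor) and no dropout-induced contig splitting, which makes it a lower
bound when splitting occurs. Using it as `detection_model` in
`corrected_frequency_mle()` makes the estimator consistent with the
caller; using the identity model matches marker-gene-style single-locus
detection. The choice is exposed rather than hidden because it *is* the
modelling assumption.

# The metagenomic trait fraction

For each sample, counts are length-normalized within each gene family
(count × median family length / gene length), the core abundance is the
median of normalized single-copy core-gene counts, and

$$f_{\mathrm{sidero}} = \frac{\text{summed normalized receptor counts}}
{\text{median normalized core count}}.$$

Receptor variants are summed, not resolved to clades: receptor sequences
do not partition cleanly by clade, so the statistic is a population
fraction. Samples with median core coverage below 100 fail QC; the
statistic is still reported but flagged, as is any value above 1.2
(biologically impossible as a fraction, retained because clipping would
bias downstream regression). The QC threshold applies to the
length-normalized median because the exclusion is a statement about
effective coverage of the reference gene set. Whether family medians or
a single global median normalise lengths is ambiguous in principle;
per-family is the default and a global switch exists
(`family_median = FALSE`).

# Ranking environmental drivers

The driver-ranking pipeline treats "which variables matter" as an
all-relevant feature-selection problem under strong collinearity:

1. **Holdout**: 20% of samples are reserved once and never touched by
   any fitting step.
2. **Per-partition preprocessing**: within 10-fold CV on the remainder,
   each training partition is median-imputed, centred, scaled, and
   decomposed by PCA — all statistics estimated on that partition only,
   so no information leaks from validation folds or the holdout.
3. **Component retention**: every component cumulatively explaining 99%
   of variance in at least one partition is retained (the max over
   partitions, mirroring the union-style retention used with real
   oceanographic data).
4. **Relevance**: Boruta tests each retained component per partition: in
   each iteration every feature gets a row-permuted shadow copy, a
   random forest is fitted, and a feature "hits" when its permutation
   importance beats the best shadow. Hits are compared to
   Binomial(iters, 1/2).
5. **Aggregation**: a component is confirmed when Boruta confirms it in
   at least half the partitions.
6. **Tuning and final fit**: forest hyperparameters (`mtry` over
   $\{\lceil\sqrt p\rceil, p/3, p/2\}$, minimum node size over
   $\{3,5,10\}$) are tuned across the folds by validation RMSE; the
   final forest is refitted on all non-holdout data using confirmed
   components only, and judged on the holdout ($R^2$, RMSE).
7. **Back-projection**: squaring the orthonormal loading matrix gives
   the variance of each variable explained by each component; variables
   with $R^2 \ge 0.1$ on a confirmed component are retained, and each
   variable's **rank contribution** is its squared loadings over
   confirmed components weighted by normalized forest importance.

Numerical conventions: PCA signs are fixed (largest-magnitude loading
positive) for reproducibility; forests run single-threaded with derived
seeds so the whole report is a deterministic function of `(data, seed)`;
a run in which no component beats its shadows falls back to an
intercept-only model, reporting an honest near-zero holdout $R^2$
rather than failing.

Two defaults in `nested_cv_train()` deliberately differ from the
stand-alone `boruta()`: the in-CV screen caps iterations at 50 and tests
at level $\alpha$ *without* Bonferroni adjustment. The stand-alone
function keeps the canonical conservative settings (100 iterations,
adjustment) because its decisions stand alone; inside the pipeline the
cross-partition majority vote already suppresses sporadic false
confirmations, and the shorter cap bounds the cost of features that
would otherwise hover undecided for dozens of forest fits. Tentative
features at the cap count as not-confirmed, the conservative direction.

# Binned beta regression

The trait fraction lives in $(0,1)$ with variance that shrinks toward
the boundaries, which is exactly the beta regression setting: mean
$\mu = \mathrm{logit}^{-1}(X\beta)$, shapes $(\mu\phi, (1-\mu)\phi)$,
constant precision $\phi$ (no covariate named in the dispersion, so none
is modelled). Nitrite and DCM depth enter as terciles with an
interaction, the binning either empirical (type-7 terciles,
left-open/right-closed, lowest bin closed) or at fixed cuts such as the
published nitrite breakpoints 0.040 and 0.073. Exact zeros are pulled
inside the interval by $(y(n-1)+0.5)/n$ before fitting.

The likelihood is maximised by BFGS with analytic gradients from a
logit-linear least-squares start; the covariance is the inverse observed
information. Marginal means for a factor average the linear predictor on
the link scale over the reference grid of the other factors with equal
weights, then inverse-transform; intervals are delta-method on the link
scale (a parametric-bootstrap alternative is available via
`ci = "boot"`), contrasts are z-tests (Tukey adjustment optional, off by default
since single-comparison reporting is the convention being mirrored).
The implementation is validated in the test suite against an
independent beta-likelihood fitter (`glmmTMB`) and an independent
marginal-means implementation (`emmeans`), which agree to four decimals
on shared fixtures; they are cross-checks, not dependencies.

# What the generators emulate — and what they do not

`simulate_genomes()` plants exactly one 7-gene cluster (receptor centred,
three accessory genes per side) in each carrier genome, then drops each
gene independently with probability equal to completeness and re-segments
contigs, breaking at each dropout gap with probability 0.5. Independent
per-gene dropout is the simplest model consistent with single-cell
assembly loss and makes the corrected estimators' assumptions explicit
and testable; real assembly dropout is spatially correlated, so real
detection curves will sit between the single-locus and full-rule models.
Default genome size is 100 genes in 50-gene contigs — a compact stand-in
(real genomes are ~2000 genes) that leaves the calling rule's behaviour
unchanged, because the rule only sees the anchor's contig neighborhood.

`simulate_metagenome()` draws counts directly as Poisson with means
proportional to coverage, gene length, and (for the receptor) the true
carrier fraction. No read-level simulation is attempted: the analysis
consumes classified counts, so simulating reads would only add a
layer whose fidelity could not be checked here.

`simulate_env()` builds predictors from latent Gaussian factors. The
default layout places the five predictive variables inside **one tightly
co-varying complex** (plus two weaker associate members), alongside one
large non-causal complex, four smaller non-causal groups, and pure-noise
columns, with ~5% missingness. This mirrors the empirical situation in
which the variables that track a subsurface trait — nitrite,
deep-chlorophyll-maximum depth, and related light/nutrient measures —
are themselves strongly correlated members of a single environmental
complex, while the ocean's dominant covariation axis (temperature and
its correlates) is not causal. It is also the regime in which the
pipeline's outputs are statistically identifiable: a design that spread
the five signals across five separate factors of similar strength would
make the final forest's importance split across five components whose
relative weights fluctuate severalfold between realisations of this
sample size, and no ranking that weights loadings by importance could
then be stable; conversely, exactly degenerate factor strengths would
leave the component basis arbitrary. Passing recovery tests on this
design therefore demonstrates correct mechanics (localisation,
shadow-testing, aggregation, back-projection) — not that any real
variable set will rank stably, which depends on the data's own
eigenstructure.

The beta-response generator draws from the same mean/precision
parameterisation the fitter uses; its role is calibration (parameter
recovery, interval coverage), not realism.

# Problem sizes and tolerances

The validation suite runs the estimators at the scales at which their
guarantees are stated: 1,000 random genomes for the exact
brute-force comparison of the calling rule; 200 replicates of n = 500
genomes for frequency-estimator bias (±0.02) and interval coverage
(0.90–0.99); 20 seeds of the n = 400, 45-variable driver-recovery study
(all five signal variables retained and ranked top-10 in ≥80% of seeds)
plus pure-noise controls (median holdout $R^2 \le 0.1$); 50 seeds for
Boruta calibration; and 50-seed coefficient calibration plus 100-replicate
interval coverage for the 3×3 beta regression. Monte-Carlo checks use a
simulated coverage of $10^4$ and carrier fractions up to 0.5, where the
Poisson error of the trait fraction stays below 0.02 with margin.

# Known limitations

* The completeness corrections ignore phylogenetic relatedness among
  genomes; frequencies are reported per clade instead.
* The detection enumeration assumes the fixed operon layout and no
  contig splitting; with splitting it is a lower bound.
* The driver pipeline aggregates component decisions by index across
  partitions, which is meaningful only while eigenvalue gaps exceed
  sampling noise; the vignette section above describes when that holds.
* Pairwise contrasts are unadjusted by default; use `adjust = "tukey"`
  when several contrasts are reported together.
* No spatial or temporal autocorrelation handling; samples are treated
  as exchangeable.

# A minimal end-to-end run

```{r example, eval = FALSE}
sim <- simulate_genomes(genome_sim_spec(n_genomes = 200, trait_freq = 0.3,
                                        completeness = c(0.3, 0.9),
                                        seed = 1))
det <- detect_clusters(sim$annotations)
naive_frequency(det$verdicts$is_consumer)
corrected_frequency_mle(det$verdicts$is_consumer,
                        det$verdicts$completeness,
                        detection_model = function(c)
                          rule_detection_prob(c, contig_genes = 50))
```
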