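# siderotrait

Tools for asking, from sequence data alone, whether picocyanobacteria
(*Prochlorococcus*, *Synechococcus*) carry the siderophore-uptake gene
cluster — a TonB-dependent outer-membrane receptor plus ABC transporter
and TonB–ExbB–ExbD genes that lets cells pirate iron bound to foreign
siderophores — and which environmental conditions favour the carriers.

The package implements the full inferential chain as tested, reusable R
functions:

* **Cluster calling** (`detect_clusters()`): a genome is a consumer when
  ≥5 of the 6 accessory families occur within ±8 genes of a receptor
  anchor (PF00593/COG4771), or when the anchor sits close enough to a
  contig end that the neighborhood is unobservable.
* **Completeness-corrected trait frequency** (`naive_frequency()`,
  `corrected_frequency_moment()`, `corrected_frequency_mle()`): with
  detection indicators *d&#8321;…d&#8345;* and completeness
  *c&#8321;…c&#8345;*, the moment estimator is f&#770; = Σd/Σc and the MLE
  maximises Π (f·p&#7522;)^d&#7522; (1−f·p&#7522;)^(1−d&#7522;) with a
  pluggable detection model p(c) — identity for single-locus detection,
  or the exact neighborhood-rule probability from
  `rule_detection_prob()`.
* **Metagenomic trait fraction** (`trait_fraction()`):
  f_sidero = (summed length-normalized receptor counts) / (median
  length-normalized single-copy core-gene count), with QC failing below
  median core coverage 100.
* **Environmental driver ranking** (`nested_cv_train()`): median
  imputation, PCA signal extraction on scaled predictors, 99%
  cumulative-variance component retention, Boruta shadow-feature
  relevance testing with random forests inside nested ten-fold
  cross-validation with a 20% holdout, and back-projection of component
  importance onto variables via squared loadings
  (rank contribution = Σ&#8346; R²[v,p]·importance[p]).
* **Binned beta regression** (`fit_beta_regression()`,
  `marginal_means()`): f_sidero ~ tercile-binned nitrite × DCM depth
  with logit mean link and constant precision φ, plus estimated marginal
  means with delta-method intervals and pairwise contrasts.
* **Synthetic data with known truth** (`simulate_genomes()`,
  `simulate_metagenome()`, `simulate_env()`,
  `simulate_beta_response()`): every stage above is validated against
  these generators, so no external downloads are needed.

## Worked example

Estimate the true consumer frequency from 200 incomplete genomes whose
true carrier rate is 30%:

```r
library(siderotrait)

sim <- simulate_genomes(genome_sim_spec(n_genomes = 200, trait_freq = 0.3,
                                        completeness = c(0.3, 0.9), seed = 1))
det <- detect_clusters(sim$annotations)

naive_frequency(det$verdicts$is_consumer)
#> Trait frequency (naive): 0.1450  [95% CI 0.1029, 0.2005]  (n = 200 genomes)

corrected_frequency_moment(det$verdicts$is_consumer,
                           det$verdicts$completeness, seed = 1)
#> Trait frequency (moment): 0.2494  [95% CI 0.1706, 0.3308]  (n = 200 genomes)

mean(sim$truth$is_consumer)   # realized carrier rate in this draw
#> [1] 0.255
```

The naive rate (0.145) is biased low because incomplete genomes hide
true clusters; dividing detections by summed completeness recovers the
realized carrier rate (0.255) almost exactly, with an interval covering
the population value 0.3. The moment estimator assumes single-locus
detection; for a correction consistent with the full neighborhood rule,
pass `rule_detection_prob()` as the `detection_model` of
`corrected_frequency_mle()`.

A whole-pipeline run over TSV inputs, writing per-stage artifacts and a
reproducibility manifest:

```r
run_pipeline(list(annotations = "annotations.tsv",
                  counts = "counts.tsv", gene_meta = "gene_meta.tsv",
                  env = "env.tsv",
                  bins = list(nitrite_var = "nitrite",
                              depth_var = "dcm_depth"),
                  seed = 42),
             outdir = "results/")
```

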