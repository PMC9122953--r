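# Builds a small self-consistent set of pipeline input files in `dir` and
# returns the matching run_pipeline() configuration.
make_pipeline_inputs <- function(dir, n_samples = 60, seed = 5) {
  set.seed(seed)
  gs <- simulate_genomes(genome_sim_spec(20, 0.4, c(0.5, 1), seed = seed))
  write_annotations(gs$annotations, file.path(dir, "annotations.tsv"))
  mg <- simulate_metagenome(metagenome_sim_spec(
    n_samples, true_fraction = runif(n_samples, 0.05, 0.6), seed = seed))
  write_counts(mg$counts, file.path(dir, "counts.tsv"))
  write.table(mg$gene_meta, file.path(dir, "gene_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ev <- simulate_env(env_sim_spec(n_samples, seed = seed))
  env <- cbind(sample_id = rownames(mg$counts), ev$env)
  env$nitrite <- exp(rnorm(n_samples, -3, 1))
  env$dcm_depth <- runif(n_samples, 40, 180)
  write.table(env, file.path(dir, "env.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  list(
    annotations = file.path(dir, "annotations.tsv"),
    counts = file.path(dir, "counts.tsv"),
    gene_meta = file.path(dir, "gene_meta.tsv"),
    env = file.path(dir, "env.tsv"),
    seed = 77,
    cv = list(cv_folds = 5, num_trees = 100, boruta_trees = 100,
              boruta_max_iter = 15),
    bins = list(nitrite_var = "nitrite", depth_var = "dcm_depth")
  )
}
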