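# Synthetic-data generators with known ground truth.
#
# Every downstream stage (cluster calling, frequency correction, metagenomic
# trait fraction, importance pipeline, beta regression) is validated against
# these generators, so their defaults define the simulated study conditions.

#' Specification for simulating annotated genomes
#'
#' Describes a population of genomes in which a fraction `trait_freq`
#' carries a single-copy 7-gene siderophore transport cluster (a
#' TonB-dependent receptor anchor flanked by three accessory genes on each
#' side), recovered incompletely: each gene is retained independently with
#' probability equal to the genome's completeness, after which contigs are
#' re-segmented at dropout gaps.
#'
#' @param n_genomes number of genomes.
#' @param trait_freq true population frequency of the uptake trait in
#'   \[0, 1\].
#' @param completeness either a single value in (0, 1\] (point mass) or a
#'   length-2 vector giving the bounds of a uniform law.
#' @param genes_per_genome genes per genome before dropout.
#' @param contig_genes genes per contig before dropout (the last contig may
#'   be shorter).
#' @param break_prob probability that a run of dropped genes splits the
#'   contig during re-segmentation.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return an object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_genomes, trait_freq,
                            completeness = 1,
                            genes_per_genome = 100,
                            contig_genes = 50,
                            break_prob = 0.5,
                            seed = 1) {
  n_genomes <- assert_count(n_genomes, "n_genomes")
  assert_fraction(trait_freq, "trait_freq")
  if (!length(completeness) %in% 1:2 ||
      any(completeness <= 0 | completeness > 1)) {
    abort("`completeness` must be one value or two bounds in (0, 1]")
  }
  genes_per_genome <- assert_count(genes_per_genome, "genes_per_genome")
  if (trait_freq > 0 && genes_per_genome < 7) {
    abort("consumer genomes need at least 7 genes to hold the transport cluster; got genes_per_genome = %d",
          genes_per_genome)
  }
  contig_genes <- assert_count(contig_genes, "contig_genes")
  assert_fraction(break_prob, "break_prob")
  structure(list(n_genomes = n_genomes, trait_freq = trait_freq,
                 completeness = completeness,
                 genes_per_genome = genes_per_genome,
                 contig_genes = contig_genes, break_prob = break_prob,
                 seed = as.integer(seed)),
            class = "genome_sim_spec")
}

draw_completeness <- function(spec, n) {
  if (length(spec$completeness) == 1) rep(spec$completeness, n)
  else stats::runif(n, spec$completeness[1], spec$completeness[2])
}

## Fixed operon layout: 3 accessory genes, the anchor, 3 accessory genes.
cluster_gene_families <- function(profile = trait_profile()) {
  grp <- vapply(profile$accessory_groups, `[`, character(1), 1)
  c(grp[["abc_solute_binding"]], grp[["abc_permease"]], grp[["abc_atpase"]],
    profile$anchor_families[1],
    grp[["tonb"]], grp[["exbb"]], grp[["exbd"]])
}

#' Simulate annotated genomes with partial recovery
#'
#' Generates per-genome gene tables in the annotation schema consumed by
#' [detect_clusters()], together with a truth table of consumer status and
#' completeness. Consumer genomes carry exactly one contiguous transport
#' cluster; gene dropout then mimics incomplete single-cell genome
#' recovery.
#'
#' @param spec a [genome_sim_spec()].
#' @return list with `annotations` (one data frame for all genomes) and
#'   `truth` (`genome_id`, `is_consumer`, `completeness`).
#' @export
#' @examples
#' sim <- simulate_genomes(genome_sim_spec(10, trait_freq = 0.5, seed = 42))
#' head(sim$truth)
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  G <- spec$genes_per_genome
  is_consumer <- stats::runif(n) < spec$trait_freq
  completeness <- draw_completeness(spec, n)
  op_fams <- cluster_gene_families()

  pieces <- vector("list", n)
  for (g in seq_len(n)) {
    gid <- sprintf("genome%04d", g)
    fam <- rep(NA_character_, G)
    len <- sample(500:3000, G, replace = TRUE)
    contig0 <- (seq_len(G) - 1L) %/% spec$contig_genes
    if (is_consumer[g]) {
      ## place the 7-gene run inside one contig
      sizes <- tabulate(contig0 + 1L)
      ok <- which(sizes >= 7L)
      if (!length(ok)) abort("no contig can hold a 7-gene cluster")
      ct <- ok[sample.int(length(ok), 1)]
      offset <- sum(sizes[seq_len(ct - 1L)])
      start <- offset + sample.int(sizes[ct] - 6L, 1)
      fam[start:(start + 6L)] <- op_fams
      len[start + 3L] <- 2500L  # receptor is the longest gene in the cluster
    }
    keep <- stats::runif(G) < completeness[g]
    if (!any(keep)) { pieces[[g]] <- NULL; next }
    kept <- which(keep)
    ## re-segmentation: a dropout gap splits the contig with prob break_prob
    gap <- c(FALSE, diff(kept) > 1L) | c(FALSE, diff(contig0[kept]) != 0L)
    new_ct <- cumsum(ifelse(diff(c(0L, contig0[kept])) != 0L, TRUE,
                            gap & stats::runif(length(kept)) < spec$break_prob))
    ords <- stats::ave(seq_along(kept), new_ct, FUN = seq_along) - 1L
    pieces[[g]] <- data.frame(
      genome_id = gid,
      contig_id = sprintf("%s_c%02d", gid, new_ct),
      ordinal = as.integer(ords),
      gene_id = sprintf("%s_g%04d", gid, kept),
      length_nt = len[kept],
      families = fam[kept],
      completeness = completeness[g],
      stringsAsFactors = FALSE
    )
  }
  annotations <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(annotations)) {
    abort("no genes survived recovery in any genome; raise completeness")
  }
  rownames(annotations) <- NULL
  truth <- data.frame(genome_id = sprintf("genome%04d", seq_len(n)),
                      is_consumer = is_consumer,
                      completeness = completeness,
                      stringsAsFactors = FALSE)
  list(annotations = annotations, truth = truth)
}

#' Exact detection probability of the cluster rule under gene dropout
#'
#' For a consumer genome whose genes are retained independently with
#' probability `completeness`, computes the probability that the
#' neighborhood rule detects the cluster, by enumerating retention patterns
#' of the six accessory genes and folding in the binomial distribution of
#' retained background genes on each side of the anchor (which governs the
#' contig-interruption branch). Assumes the generator's fixed operon layout
#' (3 accessory genes each side of the anchor) and no dropout-induced contig
#' splitting (`break_prob = 0`); splitting only shortens contigs, so this is
#' a lower bound when `break_prob > 0`.
#'
#' @param completeness retention probability in (0, 1\]; vectorised.
#' @param contig_genes genes on the anchor's contig before dropout.
#' @param profile a [trait_profile()] supplying quorum and edge margin.
#' @return detection probability, averaged over the uniform placement of
#'   the cluster within the contig.
#' @export
rule_detection_prob <- function(completeness, contig_genes = 50,
                                profile = trait_profile()) {
  q <- profile$quorum
  m <- profile$edge_margin
  starts <- 0:(contig_genes - 7L)
  nL <- starts                      # background genes left of the run
  nR <- contig_genes - starts - 7L  # background genes right of the run
  vapply(completeness, function(cc) {
    tot <- rep(0, length(starts))
    for (i in 0:3) for (j in 0:3) {
      pij <- stats::dbinom(i, 3, cc) * stats::dbinom(j, 3, cc)
      if (i + j >= q) { tot <- tot + pij; next }
      ## quorum missed: detection only via interruption
      pL <- stats::pbinom(m - i - 1, nL, cc, lower.tail = FALSE)
      pR <- stats::pbinom(m - j - 1, nR, cc, lower.tail = FALSE)
      tot <- tot + pij * (1 - pL * pR)
    }
    cc * mean(tot)
  }, numeric(1))
}

#' Specification for simulating metagenomic gene counts
#'
#' @param n_samples number of metagenome samples.
#' @param true_fraction per-sample consumer fraction in \[0, 1\] (recycled).
#' @param n_core_genes number of single-copy core gene families.
#' @param core_lengths gene lengths in nt for the core genes (recycled).
#' @param receptor_length receptor gene length in nt.
#' @param mean_core_coverage expected reads per core gene at unit length
#'   ratio (recycled per sample).
#' @param seed integer seed.
#' @return an object of class `metagenome_sim_spec`.
#' @export
metagenome_sim_spec <- function(n_samples, true_fraction,
                                n_core_genes = 50,
                                core_lengths = NULL,
                                receptor_length = 2500,
                                mean_core_coverage = 500,
                                seed = 1) {
  n_samples <- assert_count(n_samples, "n_samples")
  assert_fraction(true_fraction, "true_fraction")
  n_core_genes <- assert_count(n_core_genes, "n_core_genes")
  if (any(mean_core_coverage <= 0)) abort("`mean_core_coverage` must be > 0")
  if (is.null(core_lengths)) {
    ## typical single-copy core gene lengths, fixed by seed
    core_lengths <- round(seq(600, 1800, length.out = n_core_genes))
  }
  if (any(core_lengths <= 0) || receptor_length <= 0) {
    abort("gene lengths must be positive")
  }
  structure(list(n_samples = n_samples,
                 true_fraction = rep_len(true_fraction, n_samples),
                 n_core_genes = n_core_genes,
                 core_lengths = rep_len(core_lengths, n_core_genes),
                 receptor_length = receptor_length,
                 mean_core_coverage = rep_len(mean_core_coverage, n_samples),
                 seed = as.integer(seed)),
            class = "metagenome_sim_spec")
}

#' Simulate a metagenomic gene-count table
#'
#' Core-gene counts are Poisson with mean proportional to sequencing
#' coverage and gene length; receptor counts additionally scale with the
#' per-sample consumer fraction, emulating reads classified to the
#' TonB-dependent receptor versus single-copy core families.
#'
#' @param spec a [metagenome_sim_spec()].
#' @return list with `counts` (sample x gene integer matrix), `gene_meta`
#'   (`gene_id`, `length_nt`, `role`, `family`) and `truth`
#'   (`sample_id`, `true_fraction`).
#' @export
simulate_metagenome <- function(spec) {
  stopifnot(inherits(spec, "metagenome_sim_spec"))
  set.seed(spec$seed)
  nS <- spec$n_samples
  nC <- spec$n_core_genes
  med_core <- stats::median(spec$core_lengths)
  core_mu <- outer(spec$mean_core_coverage, spec$core_lengths / med_core)
  rec_mu <- spec$true_fraction * spec$mean_core_coverage  # length ratio = 1
  counts <- cbind(
    matrix(stats::rpois(nS * nC, core_mu), nS, nC),
    stats::rpois(nS, rec_mu)
  )
  gene_ids <- c(sprintf("core%03d", seq_len(nC)), "tonb_receptor_1")
  dimnames(counts) <- list(sprintf("sample%03d", seq_len(nS)), gene_ids)
  gene_meta <- data.frame(
    gene_id = gene_ids,
    length_nt = c(spec$core_lengths, spec$receptor_length),
    role = c(rep("core", nC), "receptor"),
    family = c(sprintf("core%03d", seq_len(nC)), "tonb_receptor"),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(sample_id = rownames(counts),
                      true_fraction = spec$true_fraction,
                      stringsAsFactors = FALSE)
  list(counts = counts, gene_meta = gene_meta, truth = truth)
}

#' Specification for simulating environmental predictor matrices
#'
#' Emulates oceanographic predictor sets: blocks of collinear variables
#' driven by shared latent factors (water-mass structure), plus independent
#' noise variables, a response generated from a known subset of "signal"
#' variables, and missing-at-random entries.
#'
#' Variables are organised in `length(block_sizes)` blocks of collinear
#' variables, one latent factor per block; remaining variables are
#' independent noise. The default layout mimics oceanographic predictor
#' sets, where the variables that drive a subsurface trait (nitrite,
#' chlorophyll-maximum depth and related light/nutrient measures) are
#' themselves strongly co-varying members of one environmental complex:
#' the first block holds the five signal variables (tightly loading on
#' their shared factor, `signal_r2`) plus two weaker "guilt by
#' association" members; the remaining blocks are non-causal covariation
#' complexes of graded size (a dominant temperature/latitude-style axis
#' and smaller water-mass groups), and the last columns are independent
#' noise.
#'
#' @param n_samples number of samples.
#' @param n_vars number of environmental variables.
#' @param block_sizes collinear variables per latent factor; the number of
#'   latent factors is `length(block_sizes)`.
#' @param signal_vars indices of the truly predictive variables; default
#'   the first `min(5, block_sizes[1])` variables (members of the first
#'   block).
#' @param signal_r2,member_r2 squared correlation of signal / non-signal
#'   block members with their latent factor; `member_r2` may be a
#'   per-block vector (recycled).
#' @param response_fn function mapping the matrix of signal columns to the
#'   noiseless response; default is their row sum (linear, unit weights).
#' @param noise_sd standard deviation of additive response noise.
#' @param missing_rate fraction of entries deleted completely at random.
#' @param seed integer seed.
#' @return an object of class `env_sim_spec`.
#' @export
env_sim_spec <- function(n_samples, n_vars = 45,
                         block_sizes = c(7, 8, 7, 6, 5, 4),
                         signal_vars = NULL,
                         signal_r2 = 0.9,
                         member_r2 = c(0.35, 0.4, 0.3, 0.3, 0.35, 0.4),
                         response_fn = rowSums,
                         noise_sd = 1, missing_rate = 0.05,
                         seed = 1) {
  n_samples <- assert_count(n_samples, "n_samples")
  n_vars <- assert_count(n_vars, "n_vars")
  n_latent <- length(block_sizes)
  if (n_latent < 1 || any(block_sizes < 1)) {
    abort("`block_sizes` must be positive counts")
  }
  if (n_latent > n_vars) abort("`block_sizes` implies %d factors but n_vars = %d",
                               n_latent, n_vars)
  if (sum(block_sizes) > n_vars) {
    abort("latent blocks need %d variables but n_vars = %d",
          sum(block_sizes), n_vars)
  }
  if (is.null(signal_vars)) {
    signal_vars <- seq_len(min(5L, block_sizes[1]))
  }
  if (!all(signal_vars %in% seq_len(n_vars))) {
    abort("`signal_vars` must index variables 1..%d", n_vars)
  }
  assert_fraction(missing_rate, "missing_rate", open_right = TRUE)
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  structure(list(n_samples = n_samples, n_vars = n_vars,
                 n_latent = n_latent, block_sizes = as.integer(block_sizes),
                 signal_vars = as.integer(signal_vars),
                 signal_r2 = signal_r2,
                 member_r2 = rep_len(member_r2, n_latent),
                 response_fn = response_fn, noise_sd = noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "env_sim_spec")
}

#' Simulate an environmental matrix with a known predictive subset
#'
#' @param spec an [env_sim_spec()].
#' @return list with `env` (data frame, `NA` for missing), `response`
#'   (numeric vector, fully observed), and `truth` (signal indices and
#'   names, block assignment, per-variable factor R-squared).
#' @export
#' @examples
#' sim <- simulate_env(env_sim_spec(n_samples = 50, seed = 7))
#' sim$truth$signal_names
simulate_env <- function(spec) {
  stopifnot(inherits(spec, "env_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_vars
  block <- rep(NA_integer_, p)
  block[seq_len(sum(spec$block_sizes))] <-
    rep(seq_len(spec$n_latent), times = spec$block_sizes)
  r2 <- ifelse(is.na(block), 0, spec$member_r2[pmax(block, 1L)])
  r2[spec$signal_vars] <- ifelse(is.na(block[spec$signal_vars]), 0,
                                 spec$signal_r2)
  fac <- matrix(stats::rnorm(n * spec$n_latent), n)
  X <- matrix(stats::rnorm(n * p), n, p)
  for (j in which(!is.na(block))) {
    X[, j] <- sqrt(r2[j]) * fac[, block[j]] + sqrt(1 - r2[j]) * X[, j]
  }
  colnames(X) <- sprintf("env%02d", seq_len(p))
  y <- spec$response_fn(X[, spec$signal_vars, drop = FALSE]) +
    stats::rnorm(n, 0, spec$noise_sd)
  mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
  Xobs <- X
  Xobs[mask] <- NA
  list(env = as.data.frame(Xobs),
       response = y,
       truth = list(signal_vars = spec$signal_vars,
                    signal_names = colnames(X)[spec$signal_vars],
                    block = block, factor_r2 = r2))
}

#' Simulate beta-distributed fractional responses over a factorial design
#'
#' Draws each response from a beta law parameterised by mean and precision:
#' mean = inverse-logit of the linear predictor, shapes (mu * phi,
#' (1 - mu) * phi).
#'
#' @param design data frame of covariates (typically factors).
#' @param coefficients named numeric vector matching the columns of
#'   `model.matrix(formula, design)`.
#' @param precision beta precision parameter phi > 0.
#' @param formula model formula over `design`; default crosses all columns.
#' @param seed integer seed.
#' @return numeric vector of fractions in (0, 1) with attribute `"mu"`
#'   holding the true cell means.
#' @export
#' @examples
#' d <- expand.grid(a = factor(c("lo", "hi")))
#' simulate_beta_response(d, coefficients = c(0, 1), precision = 50, seed = 1)
simulate_beta_response <- function(design, coefficients, precision,
                                   formula = NULL, seed = 1) {
  if (precision <= 0) abort("`precision` must be positive")
  formula <- formula %||% stats::as.formula(
    paste("~", paste(names(design), collapse = " * ")))
  X <- stats::model.matrix(formula, design)
  if (ncol(X) != length(coefficients)) {
    abort("design has %d model columns but %d coefficients were given",
          ncol(X), length(coefficients))
  }
  set.seed(seed)
  mu <- inv_logit(drop(X %*% coefficients))
  y <- stats::rbeta(nrow(X), mu * precision, (1 - mu) * precision)
  attr(y, "mu") <- mu
  y
}
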