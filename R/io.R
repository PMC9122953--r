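# Table readers/writers and the end-to-end pipeline driver.
#
# All tables are UTF-8, tab-delimited, with header rows and "NA" for
# missing values. Gene coordinates are gene-ordinal (0-based along the
# contig), the coordinate system of the neighborhood rule.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read genome annotation tables
#'
#' Accepts either the package's TSV annotation schema (`genome_id`,
#' `contig_id`, `ordinal`, `gene_id`, `length_nt`, `families`, optional
#' `completeness`, `clade`) or a GFF3 file plus a family-mapping TSV
#' (`gene_id`, `families`). For GFF3, 0-based gene ordinals are derived by
#' sorting gene features by start coordinate within each sequence region;
#' GFF3 support requires the `rtracklayer` package.
#'
#' @param path annotation TSV or GFF3 file.
#' @param format `"tsv"` or `"gff3"` (guessed from the file extension).
#' @param family_map for GFF3 input, path to a TSV mapping `gene_id` to
#'   semicolon-separated `families`.
#' @param genome_id genome identifier for GFF3 input (one genome per file).
#' @return annotation data frame in the TSV schema.
#' @export
read_annotations <- function(path, format = NULL, family_map = NULL,
                             genome_id = NULL) {
  format <- format %||%
    if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    ann <- read_tsv_strict(path)
    if (nrow(ann) == 0) {
      warning("annotation file '", path, "' is empty")
      return(ann)
    }
    if (anyDuplicated(ann[c("genome_id", "gene_id")])) {
      abort("duplicate (genome_id, gene_id) keys in %s", path)
    }
    for (g in split(ann, ann$genome_id)) validate_genome(g)
    return(ann)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("GFF3 input requires the 'rtracklayer' and 'GenomicRanges' packages")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) {
    warning("no gene features in '", path, "'")
    return(data.frame())
  }
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    gene_id = gr$ID,
    length_nt = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$contig_id, df$start), ]
  df$ordinal <- as.integer(stats::ave(df$start, df$contig_id,
                                      FUN = seq_along) - 1)
  df$genome_id <- genome_id %||% sub("\\.gff3?$", "", basename(path))
  df$families <- NA_character_
  if (!is.null(family_map)) {
    fm <- read_tsv_strict(family_map)
    df$families <- fm$families[match(df$gene_id, fm$gene_id)]
  }
  df[c("genome_id", "contig_id", "ordinal", "gene_id", "length_nt",
       "families")]
}

#' Write genome annotations in the package TSV schema
#' @param annotations annotation data frame.
#' @param path output file.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_strict(annotations, path)
}

#' Read a long-format gene count table
#'
#' @param counts_path TSV with `sample_id`, `gene_id`, `count`.
#' @param meta_path TSV with `gene_id`, `length_nt`, `role`, optional
#'   `family`.
#' @return list with `counts` (sample x gene matrix) and `gene_meta`.
#' @export
read_counts <- function(counts_path, meta_path) {
  long <- read_tsv_strict(counts_path)
  meta <- read_tsv_strict(meta_path)
  samples <- sort(unique(long$sample_id))
  genes <- meta$gene_id
  counts <- matrix(0, length(samples), length(genes),
                   dimnames = list(samples, genes))
  counts[cbind(match(long$sample_id, samples),
               match(long$gene_id, genes))] <- long$count
  list(counts = counts, gene_meta = meta)
}

#' Write a count matrix in long format
#' @param counts sample x gene matrix.
#' @param path output TSV.
#' @export
write_counts <- function(counts, path) {
  long <- data.frame(
    sample_id = rep(rownames(counts), ncol(counts)),
    gene_id = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$sample_id, long$gene_id), ]
  write_tsv_strict(long, path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order — cluster detection, trait
#' frequency estimation, metagenomic trait fractions, environmental driver
#' ranking, binned beta regression — writing each stage's outputs to
#' `outdir` plus a manifest recording input hashes, the seed, and the
#' package version.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `annotations` (TSV path), `counts` and `gene_meta` (TSV paths),
#'   `env` (TSV path, with a `sample_id` column), `seed` (required),
#'   and optional `outdir`, `qc_min`, `profile` overrides (a list of
#'   [trait_profile()] arguments), `cv` (list of [nested_cv_train()]
#'   arguments), `bins` (list: `nitrite_var`, `depth_var`, optional fixed
#'   `nitrite_breaks` / `depth_breaks`). Stages whose inputs are absent
#'   are skipped, except that configured stages missing their inputs
#'   raise an error before anything runs.
#' @param outdir output directory (overrides `config$outdir`).
#' @param verbose emit a message as each stage starts and finishes.
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(config, outdir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must set a `seed`")
  outdir <- outdir %||% config$outdir %||% abort("no output directory given")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ## validate configured inputs before executing anything
  for (key in c("annotations", "counts", "gene_meta", "env")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort("configuration error: %s file '%s' does not exist",
            key, config[[key]])
    }
  }
  seed <- as.integer(config$seed)
  results <- list()
  inputs <- character()

  stage <- function(name, expr) {
    if (verbose) message(sprintf("[%s] running", name))
    out <- tryCatch(expr, error = function(e) {
      abort("stage '%s' failed: %s", name, conditionMessage(e))
    })
    if (verbose) message(sprintf("[%s] done", name))
    out
  }

  if (!is.null(config$annotations)) {
    results$detect <- stage("detect-clusters", {
      ann <- read_annotations(config$annotations)
      profile <- do.call(trait_profile, config$profile %||% list())
      det <- detect_clusters(ann, profile)
      write_tsv_strict(det$calls, file.path(outdir, "cluster_calls.tsv"))
      write_tsv_strict(det$verdicts, file.path(outdir, "genome_verdicts.tsv"))
      det
    })
    inputs["annotations"] <- config$annotations

    if ("completeness" %in% names(results$detect$verdicts)) {
      results$trait_freq <- stage("trait-freq", {
        v <- results$detect$verdicts
        rep <- clade_frequencies(v, method = "moment",
                                 seed = derive_seed(seed, 11))
        jsonlite::write_json(rep, file.path(outdir, "trait_frequency.json"),
                             dataframe = "rows", auto_unbox = TRUE,
                             digits = NA)
        rep
      })
    }
  }

  if (!is.null(config$counts)) {
    results$abundance <- stage("metag-abundance", {
      ct <- read_counts(config$counts, config$gene_meta)
      tf <- trait_fraction(ct$counts, ct$gene_meta,
                           qc_min = config$qc_min %||% 100)
      write_tsv_strict(tf, file.path(outdir, "trait_fraction.tsv"))
      tf
    })
    inputs["counts"] <- config$counts
    inputs["gene_meta"] <- config$gene_meta
  }

  if (!is.null(config$env)) {
    if (is.null(results$abundance)) {
      abort("configuration error: the importance stage needs a counts table to supply the response")
    }
    env <- read_tsv_strict(config$env)
    tf <- results$abundance
    tf <- tf[tf$qc_pass, ]
    idx <- match(tf$sample_id, env$sample_id)
    if (anyNA(idx)) abort("env table lacks sample(s): %s",
                          paste(tf$sample_id[is.na(idx)], collapse = ", "))
    envv <- env[idx, setdiff(names(env), "sample_id"), drop = FALSE]
    inputs["env"] <- config$env

    results$importance <- stage("importance", {
      cv_args <- config$cv %||% list()
      rep <- do.call(nested_cv_train,
                     c(list(env = envv, response = tf$f_sidero,
                            seed = derive_seed(seed, 21)), cv_args))
      jsonlite::write_json(
        list(retained_k = rep$retained_k,
             confirmed_pcs = rep$confirmed_pcs,
             pc_importance = as.list(rep$pc_importance),
             ## fraction of total variance captured by confirmed PCs,
             ## and the same quantity relative to the retained PC set
             confirmed_variance_total = rep$confirmed_variance,
             confirmed_variance_of_retained = if (rep$retained_k > 0)
               rep$confirmed_variance /
                 sum(rep$pca$variance_explained[seq_len(rep$retained_k)])
             else 0,
             kept_variables = rep$kept_variables,
             rank_contribution = as.list(rep$rank_contribution),
             holdout_r2 = rep$holdout_r2, holdout_rmse = rep$holdout_rmse),
        file.path(outdir, "importance.json"), auto_unbox = TRUE, digits = NA)
      write_tsv_strict(rep$pearson, file.path(outdir, "pearson.tsv"))
      rep
    })

    bins <- config$bins
    if (!is.null(bins)) {
      results$betareg <- stage("betareg", {
        nit <- env[[bins$nitrite_var]][idx]
        dep <- env[[bins$depth_var]][idx]
        d <- data.frame(
          f = squeeze_unit_interval(pmin(1, pmax(0, tf$f_sidero))),
          nitrite_bin = tercile_bin(nit, breaks = bins$nitrite_breaks),
          dcm_bin = tercile_bin(dep, breaks = bins$depth_breaks)
        )
        fit <- fit_beta_regression(f ~ nitrite_bin * dcm_bin, d)
        mm <- marginal_means(fit, "nitrite_bin", by = "dcm_bin")
        write_tsv_strict(mm$means, file.path(outdir, "marginal_means.tsv"))
        write_tsv_strict(mm$contrasts, file.path(outdir, "contrasts.tsv"))
        jsonlite::write_json(
          list(coefficients = as.list(coef(fit)), phi = fit$precision_phi,
               loglik = fit$loglik, n = fit$n),
          file.path(outdir, "betareg.json"), auto_unbox = TRUE, digits = NA)
        list(fit = fit, marginal_means = mm)
      })
    }
  }

  manifest <- list(
    package = "siderotrait",
    version = as.character(utils::packageVersion("siderotrait")),
    seed = seed,
    inputs = as.list(stats::setNames(tools::md5sum(inputs),
                                     basename(inputs))),
    outputs = local({
      paths <- setdiff(list.files(outdir, full.names = TRUE,
                                  pattern = "\\.(tsv|json)$"),
                       file.path(outdir, "manifest.json"))
      ## keyed by file name so reruns in different directories hash equal
      as.list(stats::setNames(tools::md5sum(paths), basename(paths)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
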