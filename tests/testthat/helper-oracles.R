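# Independent oracles and fixture builders used across the suite.

## All family identifiers of the default trait profile, by group.
oracle_groups <- list(
  abc_solute_binding = c("PF01497", "COG0614"),
  abc_permease       = c("PF01032", "COG0609"),
  abc_atpase         = c("PF00005", "COG1120"),
  tonb               = c("PF03544", "COG0810"),
  exbb               = c("PF01618", "COG0811"),
  exbd               = c("PF02472")
)
oracle_anchor <- c("PF00593", "COG4771")

## Brute-force re-implementation of the neighborhood rule: plain loops over
## genes, no shared code with the package internals.
brute_force_calls <- function(genome, quorum = 5, window = 8, margin = 8) {
  out <- list()
  fam_of <- strsplit(ifelse(is.na(genome$families), "", genome$families), ";")
  for (i in seq_len(nrow(genome))) {
    if (!any(fam_of[[i]] %in% oracle_anchor)) next
    contig <- genome$contig_id[i]
    on_contig <- which(genome$contig_id == contig)
    clen <- length(on_contig)
    found <- rep(FALSE, length(oracle_groups))
    for (j in on_contig) {
      if (j == i) next
      if (abs(genome$ordinal[j] - genome$ordinal[i]) > window) next
      for (g in seq_along(oracle_groups)) {
        if (any(fam_of[[j]] %in% oracle_groups[[g]])) found[g] <- TRUE
      }
    }
    interrupted <- genome$ordinal[i] < margin ||
      (clen - 1 - genome$ordinal[i]) < margin
    out[[length(out) + 1]] <- data.frame(
      genome_id = genome$genome_id[i],
      anchor_gene_id = genome$gene_id[i],
      n_found = sum(found),
      interrupted = interrupted,
      is_consumer = sum(found) >= quorum || interrupted,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$anchor_gene_id), , drop = FALSE]
}

## Enumeration oracle for the generator's detection probability: iterate the
## 64 retention patterns of the six accessory genes explicitly; the
## interruption branch folds in the binomial law of retained background
## genes on each contig side. Assumes break_prob = 0 and the generator's
## operon layout (3 accessory genes each side of the anchor).
enum_detection_prob <- function(cc, contig_genes = 50, quorum = 5, margin = 8) {
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  total <- 0
  starts <- 0:(contig_genes - 7)
  for (s in starts) {
    n_left <- s
    n_right <- contig_genes - s - 7
    p_start <- 0
    for (r in seq_len(nrow(patterns))) {
      pat <- unlist(patterns[r, ])
      k <- sum(pat)
      p_pat <- cc^k * (1 - cc)^(6 - k)
      if (k >= quorum) {
        p_start <- p_start + p_pat
      } else {
        a_left <- sum(pat[1:3]); a_right <- sum(pat[4:6])
        ## P(side has >= margin retained genes) given accessory pattern
        p_left_ok <- sum(stats::dbinom(max(0, margin - a_left):n_left,
                                       n_left, cc))
        p_right_ok <- sum(stats::dbinom(max(0, margin - a_right):n_right,
                                        n_right, cc))
        if (margin - a_left > n_left) p_left_ok <- 0
        if (margin - a_right > n_right) p_right_ok <- 0
        p_start <- p_start + p_pat * (1 - p_left_ok * p_right_ok)
      }
    }
    total <- total + p_start
  }
  cc * total / length(starts)
}

## Random annotated genomes with scattered decoy families, exercising the
## calling rule's edge cases (partial quorums, edge anchors, multi-anchor).
random_genomes <- function(n, seed, max_genes = 50) {
  set.seed(seed)
  all_acc <- unlist(oracle_groups, use.names = FALSE)
  pieces <- vector("list", n)
  for (g in seq_len(n)) {
    ng <- sample(8:max_genes, 1)
    n_contig <- sample(1:3, 1)
    contig <- sort(sample.int(n_contig, ng, replace = TRUE))
    ord <- unlist(lapply(split(seq_len(ng), contig), seq_along),
                  use.names = FALSE) - 1L
    fam <- rep(NA_character_, ng)
    n_anchor <- stats::rbinom(1, 2, 0.4)
    if (n_anchor > 0) {
      at <- sample.int(ng, n_anchor)
      fam[at] <- sample(oracle_anchor, n_anchor, replace = TRUE)
    }
    scatter <- which(is.na(fam) & stats::runif(ng) < 0.25)
    fam[scatter] <- vapply(scatter, function(i) {
      paste(sample(all_acc, sample(1:2, 1)), collapse = ";")
    }, character(1))
    pieces[[g]] <- data.frame(
      genome_id = sprintf("rg%04d", g),
      contig_id = sprintf("rg%04d_c%d", g, contig),
      ordinal = ord,
      gene_id = sprintf("rg%04d_g%03d", g, seq_len(ng)),
      length_nt = sample(500:2500, ng, replace = TRUE),
      families = fam,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, pieces)
}
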