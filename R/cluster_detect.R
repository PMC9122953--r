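# Anchor-gene neighborhood calling of siderophore transport clusters.
#
# A genome is called a siderophore consumer when a TonB-dependent receptor
# gene (the anchor) has at least `quorum` of the six accessory transport
# families in its gene neighborhood, or when the anchor sits close enough to
# a contig end that the neighborhood is unobservable ("interrupted").

#' Trait profile for siderophore transport cluster detection
#'
#' Bundles the family identifiers and calling parameters for the
#' anchor-gene neighborhood rule. The defaults describe the canonical
#' picocyanobacterial siderophore uptake cluster: a TonB-dependent
#' outer-membrane receptor anchor (PF00593/COG4771) flanked by six accessory
#' families (ABC solute-binding, ABC permease, ABC ATPase, TonB, ExbB,
#' ExbD). A genome is a consumer when at least `quorum` accessory families
#' are found within `window` genes of an anchor, or when the anchor lies
#' within `edge_margin` genes of a contig end (the neighborhood is then
#' treated as interrupted and unobservable).
#'
#' @param anchor_families character vector of anchor family identifiers.
#' @param accessory_groups named list of character vectors; each element is
#'   one accessory family group (a gene matching any identifier in a group
#'   counts that group once).
#' @param quorum minimum number of distinct accessory groups required.
#' @param window number of genes scanned on each side of the anchor.
#' @param edge_margin anchors closer than this to a contig end are treated
#'   as interrupted; defaults to `window`.
#' @param multi_count should a single gene matching several accessory
#'   groups count each of them? Fused genes make this the safer default.
#' @return an object of class `trait_profile`.
#' @export
#' @examples
#' trait_profile(window = 5)
trait_profile <- function(anchor_families = c("PF00593", "COG4771"),
                          accessory_groups = list(
                            abc_solute_binding = c("PF01497", "COG0614"),
                            abc_permease       = c("PF01032", "COG0609"),
                            abc_atpase         = c("PF00005", "COG1120"),
                            tonb               = c("PF03544", "COG0810"),
                            exbb               = c("PF01618", "COG0811"),
                            exbd               = c("PF02472")
                          ),
                          quorum = 5,
                          window = 8,
                          edge_margin = window,
                          multi_count = TRUE) {
  quorum <- assert_count(quorum, "quorum")
  window <- assert_count(window, "window")
  edge_margin <- assert_count(edge_margin, "edge_margin", min = 0)
  if (quorum > length(accessory_groups)) {
    abort("`quorum` (%d) exceeds the number of accessory groups (%d)",
          quorum, length(accessory_groups))
  }
  if (is.null(names(accessory_groups)) || anyNA(names(accessory_groups))) {
    abort("`accessory_groups` must be a named list")
  }
  structure(list(anchor_families = anchor_families,
                 accessory_groups = accessory_groups,
                 quorum = quorum, window = window,
                 edge_margin = edge_margin, multi_count = multi_count),
            class = "trait_profile")
}

#' @export
print.trait_profile <- function(x, ...) {
  cat("Trait profile: anchor {", paste(x$anchor_families, collapse = ", "),
      "}\n", sep = "")
  cat(sprintf("  %d accessory groups, quorum %d, window +/-%d genes, edge margin %d\n",
              length(x$accessory_groups), x$quorum, x$window, x$edge_margin))
  invisible(x)
}

## Split a semicolon-separated families column into a list of character sets.
split_families <- function(families) {
  if (is.list(families)) return(families)
  families <- as.character(families)
  families[!is.na(families) & families == ""] <- NA_character_
  strsplit(families, ";", fixed = TRUE)
}

validate_genome <- function(genome) {
  req <- c("genome_id", "contig_id", "ordinal", "gene_id", "families")
  miss <- setdiff(req, names(genome))
  if (length(miss)) abort("annotation table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(genome$gene_id)) {
    abort("duplicate gene_id in genome '%s'", genome$genome_id[1])
  }
  ## ordinals must be consecutive 0-based within each contig
  for (ct in split(genome$ordinal, genome$contig_id)) {
    if (!identical(sort(ct), seq_along(ct) - 1L) &&
        !identical(as.integer(sort(ct)), seq_along(ct) - 1L)) {
      abort("ordinals within a contig must be consecutive and 0-based")
    }
  }
  invisible(genome)
}

#' Find anchor genes in a genome annotation
#'
#' Returns every gene whose family assignment intersects the profile's
#' anchor families, ordered by (contig_id, ordinal).
#'
#' @param genome data frame of gene records for a single genome with columns
#'   `genome_id`, `contig_id`, `ordinal` (0-based, consecutive per contig),
#'   `gene_id`, `families` (semicolon-separated identifiers).
#' @param profile a [trait_profile()].
#' @return the subset of `genome` rows that are anchors.
#' @export
find_anchors <- function(genome, profile = trait_profile()) {
  validate_genome(genome)
  fams <- split_families(genome$families)
  hit <- vapply(fams, function(f) any(f %in% profile$anchor_families), logical(1))
  hit[is.na(hit)] <- FALSE
  anchors <- genome[hit, , drop = FALSE]
  anchors[order(anchors$contig_id, anchors$ordinal), , drop = FALSE]
}

#' Gene neighborhood of an anchor
#'
#' All genes on the anchor's contig within `window` ordinal positions of
#' the anchor, the anchor itself excluded.
#'
#' @inheritParams find_anchors
#' @param anchor_gene_id gene_id of the anchor.
#' @param window half-width of the neighborhood in genes.
#' @return data frame of neighboring gene records.
#' @export
neighborhood <- function(genome, anchor_gene_id, window = 8) {
  i <- match(anchor_gene_id, genome$gene_id)
  if (is.na(i)) abort("anchor gene '%s' not found", anchor_gene_id)
  same <- genome$contig_id == genome$contig_id[i]
  near <- abs(genome$ordinal - genome$ordinal[i]) <= window
  out <- genome[same & near & genome$gene_id != anchor_gene_id, , drop = FALSE]
  out[order(out$ordinal), , drop = FALSE]
}

#' Call consumer status at one anchor
#'
#' Applies the neighborhood rule at a single anchor: count the accessory
#' family groups with at least one hit within the window, flag anchors close
#' to a contig end as interrupted, and call the anchor a consumer cluster
#' when the quorum is met or the contig is interrupted.
#'
#' @inheritParams neighborhood
#' @param profile a [trait_profile()].
#' @return one-row data frame with columns `genome_id`, `anchor_gene_id`,
#'   `families_found` (semicolon-separated group names), `n_found`,
#'   `interrupted`, `is_consumer`.
#' @export
call_consumer <- function(genome, anchor_gene_id, profile = trait_profile()) {
  i <- match(anchor_gene_id, genome$gene_id)
  if (is.na(i)) abort("anchor gene '%s' not found", anchor_gene_id)
  nb <- neighborhood(genome, anchor_gene_id, profile$window)
  fams <- split_families(nb$families)

  group_hit <- vapply(profile$accessory_groups, function(ids) {
    hits <- vapply(fams, function(f) any(f %in% ids), logical(1))
    any(hits, na.rm = TRUE)
  }, logical(1))
  if (!profile$multi_count && any(group_hit)) {
    ## each gene may count at most one group: greedy assignment in group order
    used <- rep(FALSE, nrow(nb))
    group_hit <- vapply(seq_along(profile$accessory_groups), function(g) {
      ids <- profile$accessory_groups[[g]]
      j <- which(!used & vapply(fams, function(f) any(f %in% ids), logical(1)))
      if (length(j)) { used[j[1]] <<- TRUE; TRUE } else FALSE
    }, logical(1))
    names(group_hit) <- names(profile$accessory_groups)
  }

  contig_len <- sum(genome$contig_id == genome$contig_id[i])
  ord <- genome$ordinal[i]
  interrupted <- ord < profile$edge_margin ||
    (contig_len - 1 - ord) < profile$edge_margin
  n_found <- sum(group_hit)
  data.frame(
    genome_id = genome$genome_id[i],
    anchor_gene_id = anchor_gene_id,
    families_found = paste(names(group_hit)[group_hit], collapse = ";"),
    n_found = n_found,
    interrupted = interrupted,
    is_consumer = n_found >= profile$quorum || interrupted,
    stringsAsFactors = FALSE
  )
}

#' Detect siderophore transport clusters across genomes
#'
#' Runs anchor finding and neighborhood calling over a multi-genome
#' annotation table and aggregates per-genome verdicts.
#'
#' @param annotations data frame of gene records for one or more genomes
#'   (see [find_anchors()] for required columns).
#' @param profile a [trait_profile()].
#' @param biosynthesis optional named logical vector (or per-genome
#'   `biosynthesis` column in `annotations`) from an external biosynthesis
#'   screen (e.g. antiSMASH): genomes that synthesise their own
#'   siderophores are producers, so `is_consumer` requires the transport
#'   cluster *and* no biosynthesis; the raw cluster verdict is kept in
#'   `has_cluster`.
#' @return list with `calls` (one row per anchor) and `verdicts`
#'   (one row per genome: `genome_id`, `has_cluster`, `is_consumer`, and
#'   `completeness` / `clade` carried through when present).
#' @export
#' @examples
#' sim <- simulate_genomes(genome_sim_spec(n_genomes = 20, trait_freq = 0.5,
#'                                         seed = 1))
#' res <- detect_clusters(sim$annotations)
#' table(called = res$verdicts$is_consumer, truth = sim$truth$is_consumer)
detect_clusters <- function(annotations, profile = trait_profile(),
                            biosynthesis = NULL) {
  genomes <- split(annotations, annotations$genome_id)
  calls <- lapply(genomes, function(g) {
    anchors <- find_anchors(g, profile)
    if (nrow(anchors) == 0) return(NULL)
    do.call(rbind, lapply(anchors$gene_id, function(a)
      call_consumer(g, a, profile)))
  })
  calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(genome_id = character(), anchor_gene_id = character(),
                        families_found = character(), n_found = integer(),
                        interrupted = logical(), is_consumer = logical(),
                        stringsAsFactors = FALSE)
  }
  rownames(calls) <- NULL
  verdicts <- genome_verdict(calls, genome_ids = names(genomes))
  verdicts$has_cluster <- verdicts$is_consumer
  ## carry per-genome metadata through when present
  for (col in c("completeness", "clade", "biosynthesis")) {
    if (col %in% names(annotations)) {
      meta <- vapply(genomes, function(g) g[[col]][1],
                     annotations[[col]][1])
      verdicts[[col]] <- meta[match(verdicts$genome_id, names(genomes))]
    }
  }
  if (!is.null(biosynthesis)) {
    verdicts$biosynthesis <-
      as.logical(biosynthesis[verdicts$genome_id])
  }
  if ("biosynthesis" %in% names(verdicts)) {
    syn <- verdicts$biosynthesis
    syn[is.na(syn)] <- FALSE
    verdicts$is_consumer <- verdicts$has_cluster & !syn
  }
  list(calls = calls, verdicts = verdicts)
}

#' Aggregate anchor calls into per-genome verdicts
#'
#' A genome is a consumer when any of its anchors is called a consumer
#' cluster; genomes without anchors are non-consumers.
#'
#' @param calls data frame of anchor calls from [call_consumer()].
#' @param genome_ids optional character vector of all genomes under study
#'   (so genomes with zero anchors receive a `FALSE` verdict).
#' @return data frame with `genome_id` and logical `is_consumer`.
#' @export
genome_verdict <- function(calls, genome_ids = NULL) {
  genome_ids <- sort(unique(c(as.character(calls$genome_id), genome_ids)))
  pos <- tapply(calls$is_consumer, calls$genome_id, any)
  verdict <- rep(FALSE, length(genome_ids))
  names(verdict) <- genome_ids
  verdict[names(pos)] <- as.logical(pos)
  data.frame(genome_id = genome_ids, is_consumer = unname(verdict),
             stringsAsFactors = FALSE)
}
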