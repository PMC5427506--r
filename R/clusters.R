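## Chromosomal organization
##
## Genes on one chromosome whose successive neighbours lie within a fixed
## distance (default 250 kb, measured start-to-start) form a gene cluster;
## chaining is transitive (single linkage), so A-B and B-C within the
## threshold place A and C in one cluster even when A-C exceeds it.

#' Cluster configuration
#'
#' @param max_gap maximum distance in bp between successive cluster members.
#' @param gap_metric `"start-to-start"` (default) or `"end-to-start"`.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(max_gap = 250000,
                           gap_metric = c("start-to-start", "end-to-start")) {
  stopifnot(max_gap > 0)
  structure(list(max_gap = max_gap, gap_metric = match.arg(gap_metric)),
            class = "cluster_config")
}

#' Assign genes to chromosomal clusters
#'
#' Partitions one species' genes into clusters (>= 2 members), singletons
#' and unanchored genes. Every chromosome-anchored gene lands in exactly one
#' cluster or the singleton list. Ties at identical start coordinates are
#' broken by gene id so output is deterministic and independent of input
#' order.
#'
#' @param genes a [gene_table()] for a single species.
#' @param cfg a [cluster_config()].
#' @return list with `clusters` (list of data.frames: `cluster_id`,
#'   `species`, `chromosome`, `members` (ordered by start), `span`),
#'   `singletons` and `unanchored` (character vectors of gene ids).
#' @export
assign_clusters <- function(genes, cfg = cluster_config()) {
  if (nrow(genes) > 0 && length(unique(genes$species)) > 1)
    stop("assign_clusters expects genes from a single species")
  un <- is_unanchored(genes$chromosome)
  unanchored <- sort(genes$gene_id[un])
  g <- genes[!un, , drop = FALSE]
  clusters <- list()
  singles <- character(0)
  if (nrow(g) > 0) {
    g <- g[order(g$chromosome, g$start, g$gene_id), , drop = FALSE]
    for (chrom in unique(g$chromosome)) {
      cg <- g[g$chromosome == chrom, , drop = FALSE]
      gap <- if (cfg$gap_metric == "start-to-start") {
        diff(cg$start)
      } else {
        cg$start[-1] - cg$end[-nrow(cg)]
      }
      ## new chain starts wherever the gap to the previous gene is too big
      chain <- cumsum(c(1, as.integer(gap > cfg$max_gap)))
      for (id in unique(chain)) {
        members <- cg[chain == id, , drop = FALSE]
        if (nrow(members) >= 2) {
          clusters[[length(clusters) + 1]] <- data.frame(
            cluster_id = NA_character_, species = members$species[1],
            chromosome = chrom,
            members = I(list(members$gene_id)),
            span = max(members$end) - min(members$start) + 1,
            n = nrow(members), stringsAsFactors = FALSE
          )
        } else singles <- c(singles, members$gene_id)
      }
    }
  }
  if (length(clusters) > 0) {
    for (i in seq_along(clusters))
      clusters[[i]]$cluster_id <- sprintf("%s_c%03d",
                                          clusters[[i]]$species, i)
  }
  list(clusters = clusters, singletons = sort(singles),
       unanchored = unanchored)
}

#' Organization summary statistics
#'
#' Computes the clustered/singleton bookkeeping for one species from
#' [assign_clusters()] output: clustered gene and locus counts, the
#' clustered/singleton gene ratio (2 decimals; an infinite sentinel when
#' there are no singletons), mean cluster size, number of clusters with 10
#' or more genes, and the largest cluster with its chromosome.
#'
#' @param assignment output of [assign_clusters()].
#' @param species species label for the summary row (taken from the data
#'   when omitted).
#' @return one-row data.frame.
#' @export
organization_stats <- function(assignment, species = NULL) {
  cl <- assignment$clusters
  sizes <- vapply(cl, function(x) x$n, numeric(1))
  clustered <- sum(sizes)
  if (is.null(species))
    species <- if (length(cl) > 0) cl[[1]]$species else NA_character_
  largest_i <- if (length(sizes) > 0) which.max(sizes) else NA_integer_
  organization_summary(
    species = species,
    clustered_genes = clustered,
    singleton_genes = length(assignment$singletons),
    n_clusters = length(cl),
    largest_cluster_size = if (length(sizes) > 0) max(sizes) else 0,
    largest_cluster_chrom = if (!is.na(largest_i)) cl[[largest_i]]$chromosome
                            else NA_character_,
    n_clusters_ge10 = sum(sizes >= 10)
  )
}

#' Organization summary from raw counts
#'
#' The arithmetic core behind [organization_stats()], usable directly on
#' printed locus/gene counts: derives the clustered/singleton ratio and mean
#' cluster size at the report's fixed precision.
#'
#' @param species species label.
#' @param clustered_genes,singleton_genes gene counts.
#' @param n_clusters number of multi-gene loci.
#' @param largest_cluster_size,largest_cluster_chrom largest cluster info.
#' @param n_clusters_ge10 number of clusters with >= 10 genes.
#' @return one-row data.frame.
#' @export
organization_summary <- function(species, clustered_genes, singleton_genes,
                                 n_clusters, largest_cluster_size = NA,
                                 largest_cluster_chrom = NA,
                                 n_clusters_ge10 = NA) {
  ratio <- if (singleton_genes > 0)
    round_ratio(clustered_genes / singleton_genes) else Inf
  mean_size <- if (n_clusters > 0)
    round_ratio(clustered_genes / n_clusters) else 0
  data.frame(
    species = species,
    anchored_loci = n_clusters + singleton_genes,
    anchored_genes = clustered_genes + singleton_genes,
    singleton_loci = singleton_genes,
    clustered_loci = n_clusters,
    clustered_genes = clustered_genes,
    clustered_singleton_ratio = ratio,
    mean_cluster_size = mean_size,
    clusters_ge10 = n_clusters_ge10,
    largest_cluster_size = largest_cluster_size,
    largest_cluster_chrom = largest_cluster_chrom,
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome, per-subclass gene counts
#'
#' @param genes a classified [gene_table()] (may span several species).
#' @return data.frame `species`, `chromosome` (natural sort order),
#'   `subclass`, `n`. Unanchored genes are excluded.
#' @export
chromosome_distribution <- function(genes) {
  g <- genes[!is_unanchored(genes$chromosome), , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(species = character(0), chromosome = character(0),
                      subclass = character(0), n = integer(0)))
  cnt <- aggregate(list(n = g$gene_id),
                   by = list(species = g$species, chromosome = g$chromosome,
                             subclass = g$subclass), FUN = length)
  ord_chrom <- natural_sort(unique(cnt$chromosome))
  cnt <- cnt[order(cnt$species, match(cnt$chromosome, ord_chrom),
                   cnt$subclass), ]
  rownames(cnt) <- NULL
  cnt
}
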