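## Collinearity blocks, duplication typing and locus conservation
##
## A collinearity (synteny) block is a maximal chain of anchor pairs whose
## gene-order indices are monotone on both sides (increasing on one,
## increasing or decreasing on the other) with bounded index gaps. Terminal
## -branch duplications are typed by position: tandem when both copies share
## a cluster, segmental when the pair sits inside (or within a gene-count
## window of) a within-genome block, ectopic otherwise; copies without a
## chromosome are unanchored. Precedence: unanchored > tandem > segmental >
## ectopic.

#' Gene-order index
#'
#' Ranks genes along each chromosome of each genome by start coordinate
#' (ties by gene id), yielding the order indices the block finder chains.
#'
#' @param genes a [gene_table()], possibly spanning several genomes; filler
#'   (non-NBS) genes may be included to provide anchor context.
#' @return data.frame `gene_id`, `genome`, `chromosome`, `idx`.
#' @export
gene_order_index <- function(genes) {
  g <- genes[!is_unanchored(genes$chromosome), , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(gene_id = character(0), genome = character(0),
                      chromosome = character(0), idx = integer(0)))
  g <- g[order(g$species, g$chromosome, g$start, g$gene_id), , drop = FALSE]
  key <- paste(g$species, g$chromosome)
  idx <- unlist(lapply(split(seq_along(key), key), seq_along))
  idx <- idx[order(unlist(split(seq_along(key), key)))]
  data.frame(gene_id = g$gene_id, genome = g$species,
             chromosome = g$chromosome, idx = as.integer(idx),
             stringsAsFactors = FALSE)
}

#' Find collinear blocks from anchor pairs
#'
#' Greedy longest-first extraction of maximal anchor chains monotone in the
#' gene-order indices of both genomes (same or inverted orientation), with
#' successive index gaps of at most `max_gap_genes` on both sides and at
#' least `min_anchors` anchors. Each anchor belongs to at most one block.
#'
#' @param anchors anchor-pair data.frame (see [read_anchor_table()]).
#' @param gene_orders output of [gene_order_index()] covering every
#'   anchored gene.
#' @param min_anchors minimum anchors per block.
#' @param max_gap_genes maximum gene-index gap between successive anchors.
#' @return list of `synteny_block` lists: `genome_a`, `genome_b`,
#'   `chrom_a`, `chrom_b`, `orientation` (`"same"`/`"inverted"`),
#'   `anchors` (data.frame `gene_a`, `gene_b`, `idx_a`, `idx_b`).
#' @export
find_collinear_blocks <- function(anchors, gene_orders, min_anchors = 5,
                                  max_gap_genes = 25) {
  if (nrow(anchors) == 0) return(list())
  ord <- setNames(gene_orders$idx, gene_orders$gene_id)
  chrom <- setNames(gene_orders$chromosome, gene_orders$gene_id)
  missing <- setdiff(unique(c(anchors$gene_a, anchors$gene_b)),
                     gene_orders$gene_id)
  if (length(missing) > 0)
    stop("anchor gene(s) absent from gene_orders: ",
         paste(head(missing, 5), collapse = ", "))
  a <- anchors
  a$idx_a <- ord[a$gene_a]
  a$idx_b <- ord[a$gene_b]
  a$chrom_a <- chrom[a$gene_a]
  a$chrom_b <- chrom[a$gene_b]
  groups <- split(a, paste(a$genome_a, a$genome_b, a$chrom_a, a$chrom_b,
                           sep = "\r"))
  blocks <- list()
  for (grp in groups) {
    grp <- grp[order(grp$idx_a, grp$idx_b), , drop = FALSE]
    repeat {
      if (nrow(grp) < min_anchors) break
      chain <- longest_chain(grp$idx_a, grp$idx_b, max_gap_genes)
      if (length(chain) < min_anchors) break
      sel <- grp[chain, , drop = FALSE]
      orientation <- if (nrow(sel) >= 2 && sel$idx_b[2] < sel$idx_b[1])
        "inverted" else "same"
      blocks[[length(blocks) + 1]] <- structure(list(
        genome_a = sel$genome_a[1], genome_b = sel$genome_b[1],
        chrom_a = sel$chrom_a[1], chrom_b = sel$chrom_b[1],
        orientation = orientation,
        anchors = sel[, c("gene_a", "gene_b", "idx_a", "idx_b")]
      ), class = "synteny_block")
      grp <- grp[-chain, , drop = FALSE]
    }
  }
  ## longest blocks first for deterministic downstream precedence
  if (length(blocks) > 1)
    blocks <- blocks[order(-vapply(blocks, function(b) nrow(b$anchors),
                                   numeric(1)))]
  blocks
}

## Longest chain monotone increasing in idx_a (input sorted by idx_a) and
## monotone (either direction) in idx_b, with successive gaps <= max_gap on
## both sides. O(n^2) DP, run for both orientations.
longest_chain <- function(idx_a, idx_b, max_gap) {
  best <- integer(0)
  for (dir in c(1, -1)) {
    b <- dir * idx_b
    n <- length(idx_a)
    len <- rep(1L, n)
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        ok <- idx_a[i] > idx_a[j] && b[i] > b[j] &&
          idx_a[i] - idx_a[j] <= max_gap && b[i] - b[j] <= max_gap
        if (ok && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    end <- which.max(len)
    chain <- end
    while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
    if (length(chain) > length(best)) best <- chain
  }
  best
}

#' Type a terminal-branch duplication
#'
#' @param gene_a,gene_b the duplicate gene pair (both in one genome).
#' @param genes the genome's [gene_table()] (for chromosome lookup).
#' @param assignment [assign_clusters()] output for that genome.
#' @param blocks within-genome blocks from [find_collinear_blocks()].
#' @param gene_orders [gene_order_index()] output (for the flanking window).
#' @param max_gap_genes window (in gene-order indices) within which a pair
#'   flanking a block still counts as segmental.
#' @return one of `"tandem"`, `"ectopic"`, `"segmental"`, `"unanchored"`.
#' @export
classify_duplication <- function(gene_a, gene_b, genes, assignment,
                                 blocks = list(), gene_orders = NULL,
                                 max_gap_genes = 25) {
  chra <- genes$chromosome[genes$gene_id == gene_a]
  chrb <- genes$chromosome[genes$gene_id == gene_b]
  if (length(chra) == 0 || length(chrb) == 0)
    stop("duplicate pair gene(s) not found in gene table: ",
         gene_a, " / ", gene_b)
  if (is_unanchored(chra) || is_unanchored(chrb)) return("unanchored")
  for (cl in assignment$clusters) {
    mem <- cl$members[[1]]
    if (gene_a %in% mem && gene_b %in% mem) return("tandem")
  }
  if (length(blocks) > 0) {
    if (is.null(gene_orders))
      stop("gene_orders required when blocks are supplied")
    ord <- setNames(gene_orders$idx, gene_orders$gene_id)
    chrom <- setNames(gene_orders$chromosome, gene_orders$gene_id)
    for (bl in blocks) {
      if (bl$genome_a != bl$genome_b) next
      hit <- (bl$anchors$gene_a == gene_a & bl$anchors$gene_b == gene_b) |
             (bl$anchors$gene_a == gene_b & bl$anchors$gene_b == gene_a)
      if (any(hit)) return("segmental")
      ## flanked by the block: each gene within the window of one side
      in_side <- function(g, side_chrom, lo, hi) {
        !is.na(chrom[g]) && chrom[g] == side_chrom &&
          ord[g] >= lo - max_gap_genes && ord[g] <= hi + max_gap_genes
      }
      ra <- range(bl$anchors$idx_a)
      rb <- range(bl$anchors$idx_b)
      if ((in_side(gene_a, bl$chrom_a, ra[1], ra[2]) &&
           in_side(gene_b, bl$chrom_b, rb[1], rb[2])) ||
          (in_side(gene_b, bl$chrom_a, ra[1], ra[2]) &&
           in_side(gene_a, bl$chrom_b, rb[1], rb[2])))
        return("segmental")
    }
  }
  "ectopic"
}

#' Extract typed duplication events from reconciliations
#'
#' Walks each family's reconciliation, keeps duplications mapped to terminal
#' species-tree branches (the only ones whose copies can be located on a
#' single extant genome), picks a representative extant gene pair for each
#' (the lexicographically first tip below each daughter lineage within the
#' species) and types it with [classify_duplication()].
#'
#' @param recs list of `reconciliation` objects with their gene trees.
#' @param genes combined [gene_table()] of all genomes.
#' @param assignments named list (by species) of [assign_clusters()] output.
#' @param blocks_by_species named list of within-genome block lists.
#' @param gene_orders [gene_order_index()] output.
#' @param max_gap_genes segmental flanking window.
#' @return data.frame `family`, `species`, `gene_a`, `gene_b`, `mechanism`.
#' @export
type_terminal_duplications <- function(recs, genes, assignments,
                                       blocks_by_species = list(),
                                       gene_orders = NULL,
                                       max_gap_genes = 25) {
  rows <- list()
  for (fam in names(recs)) {
    rec <- recs[[fam]]
    gidx <- rec$gene_index
    sidx <- rec$species_index
    if (nrow(rec$duplications) == 0) next
    for (r in seq_len(nrow(rec$duplications))) {
      v <- rec$duplications$node[r]
      m <- rec$map_index[v]
      if (m > sidx$n_tip) next  # internal-branch duplication: not typed
      species <- sidx$tree$tip.label[m]
      kids <- gidx$children[[v]]
      reps <- vapply(kids, function(k) {
        tips <- tips_below(gidx, k, rec$gene_index$tree)
        sort(sub("_[^_]+$", "", tips))[1]
      }, character(1))
      mech <- classify_duplication(
        reps[1], reps[2], genes, assignments[[species]],
        blocks_by_species[[species]] %||% list(), gene_orders,
        max_gap_genes)
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, species = species, gene_a = reps[1], gene_b = reps[2],
        mechanism = mech, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(family = character(0), species = character(0),
                      gene_a = character(0), gene_b = character(0),
                      mechanism = character(0)))
  do.call(rbind, rows)
}

#' Duplication-type contribution summary
#'
#' Counts per mechanism and species, with percentages of the species' total
#' new duplicated genes (one decimal).
#'
#' @param events data.frame with `species` and `mechanism` columns.
#' @return data.frame `species`, `mechanism`, `n`, `pct` (plus a `total`
#'   row per species).
#' @export
duplication_type_summary <- function(events) {
  if (nrow(events) == 0)
    return(data.frame(species = character(0), mechanism = character(0),
                      n = integer(0), pct = numeric(0)))
  rows <- list()
  for (s in sort(unique(events$species))) {
    e <- events[events$species == s, , drop = FALSE]
    tot <- nrow(e)
    rows[[length(rows) + 1]] <- data.frame(
      species = s, mechanism = "total", n = tot, pct = 100,
      stringsAsFactors = FALSE)
    for (m in MECHANISMS) {
      n <- sum(e$mechanism == m)
      rows[[length(rows) + 1]] <- data.frame(
        species = s, mechanism = m, n = n,
        pct = round_pct(100 * n / tot), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cross-genome locus conservation classes
#'
#' Loci (clusters and singletons from [assign_clusters()]) are linked across
#' genomes when at least one member gene of one locus is an anchor, inside a
#' cross-genome collinearity block, to a member gene of the other. Connected
#' groups of linked loci are classed by the set of genomes they span:
#' all-three, a specific genome pair, or species-specific.
#'
#' @param loci named list (by species) of [assign_clusters()] output.
#' @param blocks cross-genome blocks from [find_collinear_blocks()].
#' @return list with `loci` (data.frame `locus_id`, `species`, `class`,
#'   `group`) and `venn` (data.frame `class`, `n_groups`), where `n_groups`
#'   counts conserved locus groups once (not per genome).
#' @export
locus_conservation <- function(loci, blocks) {
  locus_rows <- list()
  gene2locus <- character(0)
  for (s in names(loci)) {
    as <- loci[[s]]
    for (cl in as$clusters) {
      locus_rows[[length(locus_rows) + 1]] <-
        data.frame(locus_id = cl$cluster_id, species = s,
                   stringsAsFactors = FALSE)
      gene2locus[cl$members[[1]]] <- cl$cluster_id
    }
    for (g in as$singletons) {
      id <- paste0(s, "_s_", g)
      locus_rows[[length(locus_rows) + 1]] <-
        data.frame(locus_id = id, species = s, stringsAsFactors = FALSE)
      gene2locus[g] <- id
    }
  }
  ldf <- if (length(locus_rows) > 0) do.call(rbind, locus_rows) else
    data.frame(locus_id = character(0), species = character(0))
  ## union-find over loci joined by in-block cross-genome anchors
  parent <- setNames(ldf$locus_id, ldf$locus_id)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (bl in blocks) {
    if (bl$genome_a == bl$genome_b) next
    for (r in seq_len(nrow(bl$anchors))) {
      la <- gene2locus[bl$anchors$gene_a[r]]
      lb <- gene2locus[bl$anchors$gene_b[r]]
      if (is.na(la) || is.na(lb)) next
      ra <- find(la); rb <- find(lb)
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  ldf$group <- vapply(ldf$locus_id, find, character(1))
  span <- tapply(ldf$species, ldf$group, function(x) sort(unique(x)))
  group_class <- vapply(span, function(sp) {
    if (length(sp) >= 3) "all-three"
    else if (length(sp) == 2) paste0("pair:", paste(sp, collapse = "-"))
    else "species-specific"
  }, character(1))
  ldf$class <- group_class[ldf$group]
  venn <- as.data.frame(table(class = group_class), stringsAsFactors = FALSE)
  names(venn) <- c("class", "n_groups")
  list(loci = ldf, venn = venn)
}
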