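## Subclass and architecture classification
##
## NBS-encoding genes fall into three subclasses by their N-terminal domain
## (TIR -> TNL, CC -> CNL, RPW8 -> RNL) and into four architecture
## categories by which flanking domains survive around the central NBS:
## intact (N-terminal + NBS + LRR), TN/CN/RN (N-terminal + NBS), NL
## (NBS + LRR) and N (NBS only). When the N-terminal domain is gone the
## subclass can still be read from class-diagnostic residues at fixed
## positions in the conserved NBS motifs, or, as a last resort, borrowed
## from the nearest classified neighbour on a gene tree.

#' Filter configuration for phylogeny entry
#'
#' Genes whose NBS domain is shorter than `min_fraction` of a regular NBS
#' domain carry too little signal for alignment-based phylogenetics and are
#' excluded before tree-based analyses.
#'
#' @param regular_nbs_len regular NBS domain length in amino acids.
#' @param min_fraction minimum tolerated fraction of that length.
#' @return a `filter_config` list.
#' @export
filter_config <- function(regular_nbs_len = 290, min_fraction = 2 / 3) {
  stopifnot(min_fraction > 0, min_fraction <= 1, regular_nbs_len > 0)
  structure(list(regular_nbs_len = regular_nbs_len,
                 min_fraction = min_fraction),
            class = "filter_config")
}

#' Classify a domain architecture
#'
#' An N-terminal domain (TIR/CC/RPW8) only counts when it occurs before the
#' NBS domain in N-to-C order, and the LRR module only when it occurs after
#' it; a misplaced domain (e.g. an LRR upstream of the NBS) is ignored for
#' categorisation with a warning, since the categories presuppose the
#' canonical N-terminal--NBS--LRR order.
#'
#' @param domains character vector of domain labels in N-to-C order; must
#'   contain `"NBS"`.
#' @return one of `"intact"`, `"TN"` (N-terminal + NBS, no C-terminal LRR),
#'   `"NL"`, `"N"`.
#' @export
classify_architecture <- function(domains) {
  if (is.character(domains) && length(domains) == 1L && grepl(";", domains))
    domains <- split_domains(domains)
  if (!"NBS" %in% domains)
    stop("not an NBS-encoding gene: no NBS domain in architecture")
  nbs_pos <- which(domains == "NBS")[1]
  has_nterm <- any(domains %in% NTERM_DOMAINS & seq_along(domains) < nbs_pos)
  has_lrr <- any(domains == "LRR" & seq_along(domains) > nbs_pos)
  if (any(domains %in% NTERM_DOMAINS) && !has_nterm)
    warning("N-terminal domain found downstream of NBS; ignored for category")
  if (any(domains == "LRR") && !has_lrr)
    warning("LRR found upstream of NBS (not C-terminal); ignored for category")
  if (has_nterm && has_lrr) "intact"
  else if (has_nterm) "TN"
  else if (has_lrr) "NL"
  else "N"
}

## Diagnostic-residue tests. Positions are 1-based within each motif string.
##   RNL: Kinase-2 position 1 = P  and  RNBS-C position 10 = C
##   TNL: Kinase-2 final position = D
##   CNL: RNBS-C position 7 = W  and  GLPL position 13 = D
## The RNL conjunction is tested before the TNL terminal-D rule: the RNL
## signature is rarer and would otherwise be shadowed whenever an RNL
## Kinase-2 happens to end in D.
motif_residue_subclass <- function(motifs) {
  at <- function(s, i) {
    if (is.null(s) || is.na(s) || nchar(s) < i) NA_character_
    else substr(s, i, i)
  }
  k2 <- motifs$kinase_2
  rc <- motifs$rnbs_c
  gl <- motifs$glpl
  k2_last <- if (is.null(k2) || is.na(k2) || nchar(k2) == 0) NA_character_
             else substr(k2, nchar(k2), nchar(k2))
  if (isTRUE(at(k2, 1) == "P") && isTRUE(at(rc, 10) == "C")) return("RNL")
  if (isTRUE(k2_last == "D")) return("TNL")
  if (isTRUE(at(rc, 7) == "W") && isTRUE(at(gl, 13) == "D")) return("CNL")
  NA_character_
}

#' Classify the subclass of one gene
#'
#' Evidence is used in priority order: (1) an explicit N-terminal domain;
#' (2) diagnostic residues in the conserved NBS motifs; (3) the subclass of
#' the nearest classified neighbour, if supplied. Contradictory N-terminal
#' domains (e.g. both TIR and CC) yield `"unclassified"` with a message.
#'
#' @param domains ordered domain labels of the gene.
#' @param motifs optional one-row list/data.frame with motif strings
#'   (`p_loop`, `kinase_2`, `kinase_3`, `rnbs_c`, `glpl`, `rnbs_d`).
#' @param neighbor_subclass optional subclass of the nearest classified
#'   neighbour on a gene tree.
#' @return list with `subclass` (`"TNL"`, `"CNL"`, `"RNL"` or
#'   `"unclassified"`) and `evidence` (`"domain"`, `"motif"`, `"neighbor"`,
#'   `"none"` or `"conflict"`).
#' @export
classify_subclass <- function(domains, motifs = NULL,
                              neighbor_subclass = NULL) {
  if (is.character(domains) && length(domains) == 1L)
    domains <- split_domains(domains)
  nterm <- intersect(unique(domains), NTERM_DOMAINS)
  if (length(nterm) > 1) {
    message("contradictory N-terminal domains (",
            paste(nterm, collapse = "+"), "); gene left unclassified")
    return(list(subclass = "unclassified", evidence = "conflict"))
  }
  if (length(nterm) == 1) {
    sub <- c(TIR = "TNL", CC = "CNL", RPW8 = "RNL")[[nterm]]
    return(list(subclass = sub, evidence = "domain"))
  }
  if (!is.null(motifs)) {
    sub <- motif_residue_subclass(as.list(motifs))
    if (!is.na(sub)) return(list(subclass = sub, evidence = "motif"))
  }
  if (!is.null(neighbor_subclass) && !is.na(neighbor_subclass) &&
      neighbor_subclass %in% SUBCLASSES)
    return(list(subclass = neighbor_subclass, evidence = "neighbor"))
  list(subclass = "unclassified", evidence = "none")
}

#' Classify every gene in a table
#'
#' Applies [classify_architecture()] and [classify_subclass()] to all genes.
#' Genes still unclassified after the domain and motif stages can borrow the
#' subclass of their nearest classified neighbour on a supplied gene tree
#' (topological distance, deterministic tie-break by leaf order); such
#' assignments are flagged as inferred in the `evidence` column.
#'
#' @param genes a [gene_table()].
#' @param motifs optional motif table (see [read_motif_table()]).
#' @param gene_tree optional `phylo` whose tips are gene ids (or
#'   `geneid_species` labels).
#' @return `genes` with `subclass`, `category` and `evidence` columns filled.
#' @export
assign_subclasses <- function(genes, motifs = NULL, gene_tree = NULL) {
  if (nrow(genes) == 0) {
    genes$category <- character(0)
    genes$evidence <- character(0)
    return(genes)
  }
  motif_rows <- NULL
  if (!is.null(motifs)) motif_rows <- split(motifs, motifs$gene_id)
  res <- lapply(seq_len(nrow(genes)), function(i) {
    doms <- split_domains(genes$domains[i])
    m <- motif_rows[[genes$gene_id[i]]]
    cl <- classify_subclass(doms, motifs = m)
    list(subclass = cl$subclass, evidence = cl$evidence,
         category = classify_architecture(doms))
  })
  genes$subclass <- vapply(res, `[[`, character(1), "subclass")
  genes$evidence <- vapply(res, `[[`, character(1), "evidence")
  genes$category <- vapply(res, `[[`, character(1), "category")

  unc <- which(genes$subclass == "unclassified" & genes$evidence == "none")
  if (length(unc) > 0 && !is.null(gene_tree)) {
    tip_gene <- sub("_[^_]+$", "", gene_tree$tip.label)
    if (!any(tip_gene %in% genes$gene_id)) tip_gene <- gene_tree$tip.label
    known <- setNames(genes$subclass, genes$gene_id)
    for (i in unc) {
      tip <- which(tip_gene == genes$gene_id[i])[1]
      if (is.na(tip)) next
      nb <- nearest_classified_tip(gene_tree, tip, tip_gene, known)
      if (!is.na(nb)) {
        genes$subclass[i] <- nb
        genes$evidence[i] <- "neighbor"
      }
    }
  }
  genes
}

## BFS over the tree's undirected adjacency from a tip, returning the
## subclass of the nearest tip that already has one. Ties are broken by tip
## index so the result is deterministic.
nearest_classified_tip <- function(tree, tip, tip_gene, known) {
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  visited <- logical(n_node)
  frontier <- tip
  visited[tip] <- TRUE
  while (length(frontier) > 0) {
    nxt <- integer(0)
    hits <- frontier[frontier <= length(tip_gene) & frontier != tip]
    if (length(hits) > 0) {
      subs <- known[tip_gene[hits]]
      ok <- which(!is.na(subs) & subs %in% SUBCLASSES)
      if (length(ok) > 0) return(subs[[min(ok)]])
    }
    for (v in frontier) {
      new <- adj[[v]][!visited[adj[[v]]]]
      visited[new] <- TRUE
      nxt <- c(nxt, new)
    }
    frontier <- sort(nxt)
  }
  NA_character_
}

#' Length filter before phylogenetic analysis
#'
#' Keeps genes whose NBS domain length strictly exceeds
#' `floor(min_fraction * regular_nbs_len)` amino acids (194 aa and longer
#' under the defaults). Genes without a measurable `nbs_len` are dropped as
#' unalignable.
#'
#' @param genes a [gene_table()].
#' @param cfg a [filter_config()].
#' @return list with `kept` (gene_table) and `dropped` (data.frame of
#'   `gene_id`, `reason`).
#' @export
phylogeny_length_filter <- function(genes, cfg = filter_config()) {
  thr <- floor(cfg$min_fraction * cfg$regular_nbs_len)
  unalignable <- is.na(genes$nbs_len)
  short <- !unalignable & genes$nbs_len <= thr
  kept <- genes[!unalignable & !short, , drop = FALSE]
  dropped <- data.frame(
    gene_id = genes$gene_id[unalignable | short],
    reason = c(rep("unalignable", sum(unalignable)),
               rep("short_nbs", sum(short)))[
      order(c(which(unalignable), which(short)))],
    stringsAsFactors = FALSE
  )
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped, threshold = thr)
}

#' Summarise classification results
#'
#' Computes the per-species, per-subclass architecture-category counts,
#' subclass proportions (percent of the species total, one decimal), intact
#' counts and proportions, pairwise species total ratios (larger/smaller,
#' two decimals) and the CNL:TNL ratio per species.
#'
#' @param genes a classified [gene_table()] (see [assign_subclasses()]).
#' @return a `classification_summary` list: `counts`, `subclass_totals`,
#'   `species_totals`, `intact`, `pairwise_ratios`, `cnl_tnl_ratio`.
#' @export
summarize_classification <- function(genes) {
  empty <- nrow(genes) == 0
  species <- if (empty) character(0) else sort(unique(genes$species))
  subclasses <- c(SUBCLASSES, "unclassified")
  grid <- expand.grid(species = species, subclass = subclasses,
                      category = ARCH_CATEGORIES, stringsAsFactors = FALSE)
  if (!empty) {
    cnt <- aggregate(list(n = genes$gene_id),
                     by = list(species = genes$species,
                               subclass = genes$subclass,
                               category = genes$category), FUN = length)
    grid <- merge(grid, cnt, all.x = TRUE, sort = FALSE)
    grid$n[is.na(grid$n)] <- 0L
  } else grid$n <- integer(0)
  grid <- grid[grid$subclass %in% unique(c(genes$subclass, SUBCLASSES)), ]
  grid <- grid[order(grid$species, match(grid$subclass, subclasses),
                     match(grid$category, ARCH_CATEGORIES)), ]
  rownames(grid) <- NULL

  sp_tot <- aggregate(list(n = grid$n), by = list(species = grid$species),
                      FUN = sum)
  sub_tot <- aggregate(list(n = grid$n),
                       by = list(species = grid$species,
                                 subclass = grid$subclass), FUN = sum)
  sub_tot$pct <- round_pct(100 * sub_tot$n /
                             sp_tot$n[match(sub_tot$species, sp_tot$species)])
  sub_tot$pct[is.nan(sub_tot$pct)] <- 0

  intact <- aggregate(list(n_intact = grid$n[grid$category == "intact"]),
                      by = list(species = grid$species[grid$category == "intact"]),
                      FUN = sum)
  if (nrow(intact) > 0) {
    intact$pct <- round_pct(100 * intact$n_intact /
                              sp_tot$n[match(intact$species, sp_tot$species)])
    intact$pct[is.nan(intact$pct)] <- 0
  } else intact$pct <- numeric(0)

  pairs <- if (length(species) >= 2) t(utils::combn(species, 2)) else
    matrix(character(0), ncol = 2)
  ratios <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                       stringsAsFactors = FALSE)
  if (nrow(ratios) > 0) {
    na <- sp_tot$n[match(ratios$species_a, sp_tot$species)]
    nb <- sp_tot$n[match(ratios$species_b, sp_tot$species)]
    ratios$ratio <- round_ratio(pmax(na, nb) / pmin(na, nb))
  } else ratios$ratio <- numeric(0)

  cnl <- sub_tot$n[sub_tot$subclass == "CNL"]
  tnl <- sub_tot$n[sub_tot$subclass == "TNL"]
  ct <- data.frame(species = species,
                   ratio = round_ratio(ifelse(tnl > 0, cnl / tnl, Inf)),
                   stringsAsFactors = FALSE)

  structure(list(counts = grid, subclass_totals = sub_tot,
                 species_totals = sp_tot, intact = intact,
                 pairwise_ratios = ratios, cnl_tnl_ratio = ct),
            class = "classification_summary")
}
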