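## Birth-death gene-family simulator
##
## Each ancestral gene founds one family that evolves independently along
## the species tree under a continuous-time birth-death process: exponential
## waiting times between events on each branch (so event order within a
## branch is well defined), duplications copying a lineage with a mechanism
## drawn from the tandem/ectopic/segmental mix, losses deleting one.
## Surviving lineages at the tips become gene records; the complete event
## log, true gene trees, placements and labels are returned as ground truth.

#' Simulator configuration
#'
#' Defaults emulate the study conditions of a three-taxon Solanaceae
#' comparison: species tree ((tomato,potato),pepper) with unit-length
#' internal branches, 176 ancestral families (150 CNL, 22 TNL, 4 RNL), a
#' duplication-mechanism mix dominated by tandem events, and architecture
#' erosion rates that reproduce realistic intact/TN/NL/N proportions.
#'
#' @param species_newick rooted species tree with branch lengths.
#' @param dup_rate,loss_rate events per lineage per unit branch length.
#' @param mechanism_mix named probabilities for `tandem`, `ectopic`,
#'   `segmental`; must sum to 1.
#' @param ancestral_counts named family counts per subclass.
#' @param n_chrom,chrom_size chromosomes per species and their size (bp).
#' @param slot_spacing spacing (bp) between family base loci.
#' @param gene_len gene length in bp.
#' @param tandem_offset min/max distance (bp) of a tandem copy from its
#'   parent.
#' @param p_lose_nterm,p_lose_lrr architecture-erosion probabilities.
#' @param motif_fidelity probability that each motif residue matches the
#'   class consensus (1 = exact consensus, 0 = random residues).
#' @param min_anchors filler anchors emitted per segmental event.
#' @param max_tip_genes runaway-growth guard.
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(species_newick =
                         "((tomato:1,potato:1):1,pepper:2);",
                       dup_rate = 0.3, loss_rate = 0.2,
                       mechanism_mix = c(tandem = 0.59, ectopic = 0.39,
                                         segmental = 0.02),
                       ancestral_counts = c(CNL = 150, TNL = 22, RNL = 4),
                       n_chrom = 12, chrom_size = 6e7,
                       slot_spacing = 4e5, gene_len = 5e3,
                       tandem_offset = c(5e3, 1e5),
                       p_lose_nterm = 0.55, p_lose_lrr = 0.40,
                       motif_fidelity = 1.0, min_anchors = 5,
                       max_tip_genes = 10000, seed = 1) {
  ## YAML configs deliver nested lists; flatten to named vectors
  mechanism_mix <- unlist(mechanism_mix)
  ancestral_counts <- unlist(ancestral_counts)
  tandem_offset <- unlist(tandem_offset)
  stopifnot(dup_rate >= 0, loss_rate >= 0,
            abs(sum(mechanism_mix) - 1) < 1e-9,
            all(mechanism_mix >= 0),
            p_lose_nterm >= 0, p_lose_nterm <= 1,
            p_lose_lrr >= 0, p_lose_lrr <= 1,
            motif_fidelity >= 0, motif_fidelity <= 1,
            all(names(ancestral_counts) %in% SUBCLASSES))
  structure(as.list(environment()), class = "sim_config")
}

NTERM_OF <- c(TNL = "TIR", CNL = "CC", RNL = "RPW8")

## ---- forest simulation --------------------------------------------------

#' Simulate a forest of gene families on the species tree
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (tip [gene_table()] with true subclasses and
#'   eroded architectures; coordinates unset until [place_genes()]),
#'   `trees` (named list of rooted `phylo` gene trees, families with
#'   surviving tips only), `truth` (event log: `events`, `genes`,
#'   `families`, `dup_pairs`, `branch_counts`) and `species_tree`.
#' @export
simulate_forest <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  species_tree <- ape::read.tree(text = cfg$species_newick)
  sidx <- species_index(species_tree)
  fam_sub <- rep(names(cfg$ancestral_counts), cfg$ancestral_counts)
  n_fam <- length(fam_sub)
  fam_ids <- sprintf("fam%03d", seq_len(n_fam))

  all_events <- list()
  all_genes <- list()
  all_pairs <- list()
  trees <- list()
  extinct <- logical(n_fam)
  event_clock <- 0L

  for (f in seq_len(n_fam)) {
    fam <- sim_one_family(fam_ids[f], sidx, cfg)
    event_clock <- event_clock + 1L
    if (nrow(fam$events) > 0) all_events[[f]] <- fam$events
    if (nrow(fam$tips) > 0) {
      all_genes[[f]] <- fam$tips
      trees[[fam_ids[f]]] <- fam$tree
      if (nrow(fam$dup_pairs) > 0) all_pairs[[f]] <- fam$dup_pairs
    } else extinct[f] <- TRUE
  }

  if (length(all_genes) > 0)
    for (f in which(!vapply(all_genes, is.null, logical(1))))
      all_genes[[f]]$subclass <- fam_sub[match(all_genes[[f]]$family,
                                               fam_ids)]
  genes_df <- if (length(all_genes) > 0) do.call(rbind, all_genes) else
    data.frame(gene_id = character(0), family = character(0),
               species = character(0), subclass = character(0),
               creation_mech = character(0), creation_node = integer(0),
               creation_time = numeric(0), parent_rep = character(0))
  if (nrow(genes_df) > cfg$max_tip_genes)
    stop("runaway growth: ", nrow(genes_df), " tip genes exceed the ",
         cfg$max_tip_genes, " guard; lower dup_rate or branch lengths")

  events_df <- if (length(all_events) > 0) do.call(rbind, all_events) else
    data.frame(family = character(0), type = character(0),
               branch = character(0), mechanism = character(0),
               terminal = logical(0))
  pairs_df <- if (length(all_pairs) > 0) do.call(rbind, all_pairs) else
    data.frame(family = character(0), species = character(0),
               mechanism = character(0), gene_a = character(0),
               gene_b = character(0))
  rownames(genes_df) <- rownames(events_df) <- rownames(pairs_df) <- NULL

  ## tip gene records with eroded architectures
  n <- nrow(genes_df)
  lose_n <- runif(n) < cfg$p_lose_nterm
  lose_l <- runif(n) < cfg$p_lose_lrr
  doms <- vapply(seq_len(n), function(i) {
    d <- c(if (!lose_n[i]) NTERM_OF[[genes_df$subclass[i]]], "NBS",
           if (!lose_l[i]) "LRR")
    join_domains(d)
  }, character(1))
  nbs_len <- pmin(pmax(round(rnorm(n, 290, 25)), 80), 400)
  gt <- gene_table(
    gene_id = genes_df$gene_id, species = genes_df$species,
    chromosome = NA_character_, start = 1, end = cfg$gene_len,
    strand = "?", domains = if (n > 0) doms else character(0),
    nbs_len = if (n > 0) nbs_len else numeric(0),
    subclass = genes_df$subclass
  )

  br <- branch_labels(sidx)
  bc <- data.frame(
    branch = br,
    dups = vapply(br, function(b)
      sum(events_df$type == "dup" & events_df$branch == b), numeric(1)),
    losses = vapply(br, function(b)
      sum(events_df$type == "loss" & events_df$branch == b), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(bc) <- NULL

  truth <- list(
    families = data.frame(family = fam_ids, subclass = fam_sub,
                          extinct = extinct, stringsAsFactors = FALSE),
    events = events_df, genes = genes_df, dup_pairs = pairs_df,
    branch_counts = bc
  )
  list(genes = gt, trees = trees, truth = truth,
       species_tree = species_tree)
}

## One family: event-graph simulation, tip extraction, pruned gene tree.
sim_one_family <- function(fam_id, sidx, cfg) {
  ## growing node store: each node is an event on a lineage
  type <- character(0)      # root | dup | loss | spec | tip
  parent <- integer(0)
  side <- integer(0)        # child slot under parent (dup: 2 = new copy)
  branch <- integer(0)      # species node of the branch the event lies on
  mech <- character(0)
  tm <- numeric(0)
  new_node <- function(ty, pa, si, br, me = NA_character_, t = NA_real_) {
    type[length(type) + 1L] <<- ty
    parent[length(parent) + 1L] <<- pa
    side[length(side) + 1L] <<- si
    branch[length(branch) + 1L] <<- br
    mech[length(mech) + 1L] <<- me
    tm[length(tm) + 1L] <<- t
    length(type)
  }
  root_id <- new_node("root", NA_integer_, NA_integer_, sidx$root)
  events <- list()
  clock <- 0

  blen <- function(v) {
    e <- which(sidx$tree$edge[, 2] == v)
    if (length(sidx$tree$edge.length) == 0 || length(e) == 0) 1
    else sidx$tree$edge.length[e]
  }

  evolve <- function(pending, sp_node) {
    ## pending: data.frame(parent=node id, side=slot); branch into sp_node
    L <- blen(sp_node)
    t <- 0
    total_rate <- cfg$dup_rate + cfg$loss_rate
    while (nrow(pending) > 0 && total_rate > 0) {
      dt <- rexp(1, nrow(pending) * total_rate)
      if (t + dt > L) break
      t <- t + dt
      clock <<- clock + 1
      i <- sample.int(nrow(pending), 1)
      if (runif(1) < cfg$dup_rate / total_rate) {
        if (nrow(pending) >= cfg$max_tip_genes)
          stop("runaway growth: one family exceeded ", cfg$max_tip_genes,
               " concurrent lineages; lower dup_rate or branch lengths")
        m <- sample(names(cfg$mechanism_mix), 1,
                    prob = cfg$mechanism_mix)
        d <- new_node("dup", pending$parent[i], pending$side[i], sp_node,
                      m, clock)
        events[[length(events) + 1L]] <<- data.frame(
          family = fam_id, type = "dup", branch = sidx$label[sp_node],
          mechanism = m, terminal = sp_node <= sidx$n_tip, node = d,
          stringsAsFactors = FALSE)
        pending[i, ] <- data.frame(parent = d, side = 1L)
        pending <- rbind(pending, data.frame(parent = d, side = 2L))
      } else {
        new_node("loss", pending$parent[i], pending$side[i], sp_node)
        events[[length(events) + 1L]] <<- data.frame(
          family = fam_id, type = "loss", branch = sidx$label[sp_node],
          mechanism = NA_character_, terminal = sp_node <= sidx$n_tip,
          node = NA_integer_, stringsAsFactors = FALSE)
        pending <- pending[-i, , drop = FALSE]
      }
    }
    if (nrow(pending) == 0) return(invisible(NULL))
    if (sp_node <= sidx$n_tip) {
      for (i in seq_len(nrow(pending)))
        new_node("tip", pending$parent[i], pending$side[i], sp_node)
    } else {
      kids <- sidx$children[[sp_node]]
      spec_ids <- vapply(seq_len(nrow(pending)), function(i)
        new_node("spec", pending$parent[i], pending$side[i], sp_node),
        integer(1))
      for (k in seq_along(kids)) {
        evolve(data.frame(parent = spec_ids, side = k), kids[[k]])
      }
    }
    invisible(NULL)
  }

  for (k in seq_along(sidx$children[[sidx$root]]))
    evolve(data.frame(parent = root_id, side = k),
           sidx$children[[sidx$root]][k])

  tips <- which(type == "tip")
  events_df <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(family = character(0), type = character(0),
               branch = character(0), mechanism = character(0),
               terminal = logical(0), node = integer(0))
  if (length(tips) == 0)
    return(list(tips = data.frame(), events = events_df,
                dup_pairs = data.frame(), tree = NULL))

  gene_id <- setNames(sprintf("%s.g%02d", fam_id, seq_along(tips)), tips)
  species <- sidx$tree$tip.label[branch[tips]]

  ## children lookup
  kids_of <- function(v) which(parent == v)

  ## creation event of a tip: nearest dup ancestor reached via its new-copy
  ## side (side 2); NA for original lineages
  creation <- vapply(tips, function(g) {
    v <- g
    while (!is.na(parent[v])) {
      p <- parent[v]
      if (type[p] == "dup" && side[v] == 2L) return(p)
      v <- p
    }
    NA_integer_
  }, integer(1))

  ## representative extant tip below (node, side) within a species: the tip
  ## whose own lineage was perturbed least recently (earliest creation
  ## event), ties broken by gene id, so the representative's position still
  ## reflects the duplication being typed
  tip_idx_of <- setNames(seq_along(tips), tips)
  rep_tip <- function(node, sd, sp) {
    found <- character(0)
    ctime <- numeric(0)
    walk <- function(v) {
      if (type[v] == "tip") {
        if (sidx$tree$tip.label[branch[v]] == sp) {
          ti <- tip_idx_of[[as.character(v)]]
          cr <- creation[ti]
          found <<- c(found, gene_id[[as.character(v)]])
          ctime <<- c(ctime, if (is.na(cr)) 0 else tm[cr])
        }
        return(invisible(NULL))
      }
      for (w in kids_of(v)) walk(w)
    }
    for (w in kids_of(node)) if (side[w] == sd) walk(w)
    if (length(found) == 0) NA_character_
    else found[order(ctime, found)][1]
  }

  ## recoverable terminal duplication events with both sides surviving
  pair_rows <- list()
  for (d in which(type == "dup" & branch <= sidx$n_tip)) {
    sp <- sidx$tree$tip.label[branch[d]]
    a <- rep_tip(d, 1L, sp)
    b <- rep_tip(d, 2L, sp)
    if (!is.na(a) && !is.na(b))
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        family = fam_id, species = sp, mechanism = mech[d],
        gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  }
  dup_pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame(family = character(0), species = character(0),
               mechanism = character(0), gene_a = character(0),
               gene_b = character(0))

  ## parent representative for placement: sibling (original) side of the
  ## creation event, in the same species
  parent_rep <- vapply(seq_along(tips), function(i) {
    d <- creation[i]
    if (is.na(d)) return(NA_character_)
    rep_tip(d, 1L, species[i])
  }, character(1))

  tips_df <- data.frame(
    gene_id = unname(gene_id), family = fam_id, species = species,
    subclass = NA_character_,
    creation_mech = ifelse(is.na(creation), NA_character_, mech[creation]),
    creation_node = creation,
    creation_time = ifelse(is.na(creation), 0, tm[creation]),
    parent_rep = parent_rep, stringsAsFactors = FALSE)

  ## pruned gene tree over surviving tips
  nwk <- function(v) {
    if (type[v] == "tip")
      return(paste0(gene_id[[as.character(v)]], "_",
                    sidx$tree$tip.label[branch[v]]))
    parts <- character(0)
    for (w in kids_of(v)) {
      s <- nwk(w)
      if (!is.null(s)) parts <- c(parts, s)
    }
    if (length(parts) == 0) return(NULL)
    if (length(parts) == 1) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  core <- nwk(root_id)
  tree_txt <- if (length(tips) == 1) paste0("(", core, ");") else
    paste0(core, ";")
  tree <- ape::read.tree(text = tree_txt)

  list(tips = tips_df, events = events_df, dup_pairs = dup_pairs,
       tree = tree)
}

## ---- chromosomal placement ----------------------------------------------

#' Place simulated genes on chromosomes
#'
#' Every family owns a base locus laid out in the same order along the
#' chromosomes of every species (so retained loci are collinear across
#' genomes). Original lineages sit at the base locus; tandem copies land
#' within `tandem_offset` of their parent copy, ectopic copies at uniform
#' random genome positions, and segmental copies in a fresh region together
#' with `min_anchors` flanking filler genes whose anchor pairs make the
#' copied block detectable by [find_collinear_blocks()].
#'
#' @param sim output of [simulate_forest()].
#' @param cfg the same [sim_config()].
#' @param seed placement seed (default `cfg$seed + 1`).
#' @return list with `genes` (placed [gene_table()]), `fillers` (non-NBS
#'   filler [gene_table()], synteny context only), `anchors` (within-genome
#'   anchor pairs from segmental events plus cross-genome anchor pairs
#'   between surviving original copies of each family).
#' @export
place_genes <- function(sim, cfg = sim_config(), seed = cfg$seed + 1) {
  set.seed(seed)
  genes <- sim$genes
  info <- sim$truth$genes
  fam_ids <- sim$truth$families$family
  slot <- setNames(seq_along(fam_ids), fam_ids)
  base_chrom <- ((slot - 1) %% cfg$n_chrom) + 1
  base_pos <- ((slot - 1) %/% cfg$n_chrom) * cfg$slot_spacing + 1e5

  chrom_name <- function(i) sprintf("Chr%02d", i)
  pos <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  chr <- setNames(rep(NA_integer_, nrow(genes)), genes$gene_id)

  filler_rows <- list()
  anchor_rows <- list()

  ## originals first, then copies in creation order
  ord <- order(info$creation_time, info$gene_id)
  for (i in ord) {
    gid <- info$gene_id[i]
    sp <- info$species[i]
    fam <- info$family[i]
    mechn <- info$creation_mech[i]
    if (is.na(mechn)) {            # original lineage: family base locus
      chr[gid] <- base_chrom[[fam]]
      pos[gid] <- base_pos[[fam]]
      next
    }
    pr <- info$parent_rep[i]
    have_parent <- !is.na(pr) && !is.na(pos[pr])
    if (!have_parent && mechn == "tandem") {
      ## parent copy extinct in this species: fall back to the base locus
      chr[gid] <- base_chrom[[fam]]
      pos[gid] <- base_pos[[fam]] +
        sample(c(-1, 1), 1) * runif(1, cfg$tandem_offset[1],
                                    cfg$tandem_offset[2])
      next
    }
    if (mechn == "tandem") {
      chr[gid] <- chr[pr]
      pos[gid] <- pos[pr] + sample(c(-1, 1), 1) *
        runif(1, cfg$tandem_offset[1], cfg$tandem_offset[2])
    } else if (mechn == "ectopic") {
      chr[gid] <- sample.int(cfg$n_chrom, 1)
      pos[gid] <- runif(1, 1, cfg$chrom_size - cfg$gene_len)
    } else {                       # segmental: copy a block to a new region
      src_chr <- if (have_parent) chr[pr] else base_chrom[[fam]]
      src_pos <- if (have_parent) pos[pr] else base_pos[[fam]]
      dst_chr <- sample.int(cfg$n_chrom, 1)
      dst_pos <- runif(1, 1e6, cfg$chrom_size - 2e6)
      chr[gid] <- dst_chr
      pos[gid] <- dst_pos
      step <- 2 * cfg$gene_len
      for (k in seq_len(cfg$min_anchors)) {
        src_id <- sprintf("%s.%s.src%02d", gid, sp, k)
        dst_id <- sprintf("%s.%s.dst%02d", gid, sp, k)
        filler_rows[[length(filler_rows) + 1L]] <- data.frame(
          gene_id = c(src_id, dst_id), species = sp,
          chromosome = chrom_name(c(src_chr, dst_chr)),
          start = round(c(src_pos + k * step, dst_pos + k * step)),
          stringsAsFactors = FALSE)
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          gene_a = src_id, gene_b = dst_id, genome_a = sp, genome_b = sp,
          score = 1, stringsAsFactors = FALSE)
      }
      if (have_parent)
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          gene_a = pr, gene_b = gid, genome_a = sp, genome_b = sp,
          score = 1, stringsAsFactors = FALSE)
    }
  }

  pos <- pmin(pmax(round(pos), 1), cfg$chrom_size - cfg$gene_len)
  ## resolve exact-start collisions by shifting one gene length
  key <- paste(genes$species, chr[genes$gene_id], pos[genes$gene_id])
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    pos[genes$gene_id[d]] <- pos[genes$gene_id[d]] + cfg$gene_len
    key <- paste(genes$species, chr[genes$gene_id], pos[genes$gene_id])
  }

  genes$chromosome <- chrom_name(chr[genes$gene_id])
  genes$start <- unname(pos[genes$gene_id])
  genes$end <- genes$start + cfg$gene_len - 1
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

  fillers <- if (length(filler_rows) > 0) do.call(rbind, filler_rows) else
    data.frame(gene_id = character(0), species = character(0),
               chromosome = character(0), start = numeric(0))
  if (nrow(fillers) > 0) {
    fillers <- gene_table(gene_id = fillers$gene_id,
                          species = fillers$species,
                          chromosome = fillers$chromosome,
                          start = fillers$start,
                          end = fillers$start + cfg$gene_len - 1,
                          strand = "+", domains = "", nbs_len = NA)
  } else fillers <- gene_table()

  ## cross-genome anchors between surviving original copies of each family
  orig <- info[is.na(info$creation_mech), , drop = FALSE]
  if (nrow(orig) > 0) {
    for (fam in unique(orig$family)) {
      o <- orig[orig$family == fam, , drop = FALSE]
      if (nrow(o) < 2) next
      cmb <- utils::combn(seq_len(nrow(o)), 2)
      for (j in seq_len(ncol(cmb))) {
        a <- cmb[1, j]; b <- cmb[2, j]
        if (o$species[a] == o$species[b]) next
        anchor_rows[[length(anchor_rows) + 1L]] <- data.frame(
          gene_a = o$gene_id[a], gene_b = o$gene_id[b],
          genome_a = o$species[a], genome_b = o$species[b],
          score = 1, stringsAsFactors = FALSE)
      }
    }
  }
  anchors <- if (length(anchor_rows) > 0) do.call(rbind, anchor_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               genome_a = character(0), genome_b = character(0),
               score = numeric(0))
  rownames(anchors) <- NULL
  list(genes = genes, fillers = fillers, anchors = anchors)
}

## ---- motif emission -----------------------------------------------------

## Class consensus strings for the six conserved NBS motifs. Diagnostic
## positions: Kinase-2 position 1 (P in RNL) and final position (D in TNL);
## RNBS-C positions 7 (W in CNL) and 10 (C in RNL); GLPL position 13 (D in
## CNL).
MOTIF_CONSENSUS <- list(
  CNL = c(p_loop = "GMGGLGKTT", kinase_2 = "LLVLDDVW",
          kinase_3 = "GSRVLVT", rnbs_c = "KYLIVLWRTSPE",
          glpl = "GLPLALKVWGSADK", rnbs_d = "CFLYCALFPE"),
  TNL = c(p_loop = "GMGGLGKTT", kinase_2 = "LLVLDDVD",
          kinase_3 = "GSRVLVT", rnbs_c = "KYLIVLDRTSPE",
          glpl = "GLPLALKVWGSALK", rnbs_d = "LHDLLRDMGR"),
  RNL = c(p_loop = "GMGGLGKTT", kinase_2 = "PIVIDDVW",
          kinase_3 = "GSRVLVT", rnbs_c = "KYLIVLDRTCPE",
          glpl = "GLPLALKVWGSALK", rnbs_d = "WICDGFIQNI")
)
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Emit motif profiles for simulated genes
#'
#' Each gene receives the six conserved NBS-motif strings of its true
#' subclass; every residue matches the class consensus with probability
#' `motif_fidelity` and is otherwise drawn uniformly from the 20 amino
#' acids. At fidelity 1 the diagnostic residues are always present; at
#' fidelity 0 the strings are pure noise.
#'
#' @param genes the simulated [gene_table()] (true subclasses filled).
#' @param cfg the [sim_config()].
#' @param seed motif seed (default `cfg$seed + 2`).
#' @return a motif table (see [read_motif_table()]).
#' @export
emit_motifs <- function(genes, cfg = sim_config(), seed = cfg$seed + 2) {
  set.seed(seed)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (m in MOTIF_NAMES) out[[m]] <- NA_character_
  for (i in seq_len(nrow(genes))) {
    cons <- MOTIF_CONSENSUS[[genes$subclass[i]]]
    for (m in MOTIF_NAMES) {
      res <- strsplit(cons[[m]], "")[[1]]
      noise <- runif(length(res)) >= cfg$motif_fidelity
      res[noise] <- sample(AMINO_ACIDS, sum(noise), replace = TRUE)
      out[[m]][i] <- paste(res, collapse = "")
    }
  }
  out
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: [simulate_forest()], [place_genes()] and
#' [emit_motifs()] with seeds derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list `genes`, `fillers`, `anchors`, `motifs`, `trees`, `truth`,
#'   `species_tree`.
#' @export
simulate_all <- function(cfg = sim_config()) {
  sim <- simulate_forest(cfg)
  placed <- place_genes(sim, cfg)
  sim$genes <- placed$genes
  motifs <- emit_motifs(sim$genes, cfg)
  list(genes = placed$genes, fillers = placed$fillers,
       anchors = placed$anchors, motifs = motifs, trees = sim$trees,
       truth = sim$truth, species_tree = sim$species_tree)
}
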