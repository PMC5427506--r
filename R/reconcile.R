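## Duplication-loss parsimony reconciliation
##
## Each gene-tree node is mapped to the last common ancestor (LCA) of its
## leaves' species in the species tree. A node is a duplication when it maps
## to the same species-tree node as at least one of its children; every
## species-tree node skipped along a gene-tree edge implies a loss on the
## branch leading to the off-path child of the skipped node. For a given
## rooting this mapping minimises duplications + losses (unit costs).

## ---- species-tree index -------------------------------------------------

## Precomputes parent/children/depth/ancestor tables for a rooted species
## tree and assigns every node a stable label: leaves keep their tip label,
## internal nodes get existing node labels or the "+"-join of their sorted
## descendant tips. Branch b(n) is the branch leading INTO node n.
species_index <- function(species_tree) {
  st <- species_tree
  n_tip <- length(st$tip.label)
  n_node <- n_tip + st$Nnode
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (k in seq_len(nrow(st$edge))) {
    parent[st$edge[k, 2]] <- st$edge[k, 1]
    children[[st$edge[k, 1]]] <- c(children[[st$edge[k, 1]]], st$edge[k, 2])
  }
  root <- which(is.na(parent))[1]
  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  ord <- root
  queue <- root
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in children[[v]]) {
      depth[w] <- depth[v] + 1L
      ord <- c(ord, w)
      queue <- c(queue, w)
    }
  }
  label <- character(n_node)
  desc_tips <- vector("list", n_node)
  for (v in rev(ord)) {
    if (v <= n_tip) {
      desc_tips[[v]] <- st$tip.label[v]
      label[v] <- st$tip.label[v]
    } else {
      desc_tips[[v]] <- sort(unlist(desc_tips[children[[v]]]))
      lab <- if (!is.null(st$node.label) &&
                 nzchar(st$node.label[v - n_tip] %||% ""))
        st$node.label[v - n_tip] else NA_character_
      label[v] <- if (!is.na(lab)) lab else
        paste(desc_tips[[v]], collapse = "+")
    }
  }
  ## ancestors (self included) for constant-time LCA on small trees
  anc <- vector("list", n_node)
  for (v in seq_len(n_node)) {
    chain <- v
    while (!is.na(parent[chain[length(chain)]]))
      chain <- c(chain, parent[chain[length(chain)]])
    anc[[v]] <- chain
  }
  list(tree = st, n_tip = n_tip, n_node = n_node, parent = parent,
       children = children, root = root, depth = depth, label = label,
       anc = anc, tip_index = setNames(seq_len(n_tip), st$tip.label))
}

sp_lca <- function(idx, a, b) {
  if (a == b) return(a)
  ia <- idx$anc[[a]]
  ib <- idx$anc[[b]]
  common <- intersect(ia, ib)
  common[which.max(idx$depth[common])]
}

## Branches of the species tree keyed by the label of their child node.
branch_labels <- function(idx) {
  idx$label[setdiff(seq_len(idx$n_node), idx$root)]
}

## ---- gene-tree index ----------------------------------------------------

gene_index <- function(gene_tree) {
  gt <- gene_tree
  n_tip <- length(gt$tip.label)
  if (is.null(gt$edge) || nrow(gt$edge) == 0) {
    ## single-leaf tree as read from "(a_x);"
    return(list(tree = gt, n_tip = n_tip, n_node = n_tip,
                parent = NA_integer_, children = list(NULL),
                root = 1L, postorder = 1L))
  }
  n_node <- max(gt$edge)
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  for (k in seq_len(nrow(gt$edge))) {
    parent[gt$edge[k, 2]] <- gt$edge[k, 1]
    children[[gt$edge[k, 1]]] <- c(children[[gt$edge[k, 1]]], gt$edge[k, 2])
  }
  root <- which(is.na(parent))
  root <- root[root > n_tip | n_node == 1]
  ## nodes in postorder (children before parents)
  post <- integer(0)
  stack <- root[1]
  seen <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(seen)
  list(tree = gt, n_tip = n_tip, n_node = n_node, parent = parent,
       children = children, root = root[1], postorder = post)
}

## ---- reconciliation -----------------------------------------------------

#' Reconcile a rooted gene tree against a species tree
#'
#' @param gene_tree rooted `phylo`; leaf species parsed from tip labels via
#'   `species_pattern` (see [leaf_species()]).
#' @param species_tree rooted `phylo` whose tip labels are species names.
#' @param species_pattern regex extracting species from gene-tree tips.
#' @param polytomies `"reject"` (default) refuses non-binary gene trees;
#'   `"resolve"` greedily resolves each polytomy, joining children with the
#'   deepest common species mapping first so spurious duplications are
#'   minimised; the resolution is flagged in the result.
#' @return a `reconciliation` list: `node_map` (species-node label per
#'   gene-tree node), `events` (per internal node `"speciation"` or
#'   `"duplication"`), `duplications` (data.frame `node`, `branch`),
#'   `losses` (data.frame `branch`), `n_dup`, `n_loss`,
#'   `root_lineages` (1 + duplications mapped at the species root),
#'   `root_map` (label), and per-branch `tally` (`branch`, `gains`,
#'   `losses`).
#' @export
lca_reconcile <- function(gene_tree, species_tree,
                          species_pattern = "_([^_]+)$",
                          polytomies = c("reject", "resolve")) {
  polytomies <- match.arg(polytomies)
  resolved <- FALSE
  ## A basal multifurcation is indistinguishable from an unrooted tree in
  ## Newick; both are handled by the polytomy policy (the greedy resolver
  ## keeps the given root position).
  if (length(gene_tree$tip.label) >= 3 &&
      (!ape::is.binary(gene_tree) || !ape::is.rooted(gene_tree))) {
    if (polytomies == "reject")
      stop("gene tree contains polytomies or is unrooted; set ",
           "polytomies = \"resolve\" or root with root_search() first")
    gene_tree <- resolve_polytomies(gene_tree, species_tree, species_pattern)
    resolved <- TRUE
  }
  sidx <- species_index(species_tree)
  gidx <- gene_index(gene_tree)
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  bad <- !(sp %in% names(sidx$tip_index))
  if (any(bad))
    stop("gene-tree species not in species tree: ",
         paste(unique(sp[bad]), collapse = ", "))

  map <- rep(NA_integer_, gidx$n_node)
  for (v in gidx$postorder) {
    if (v <= gidx$n_tip) {
      map[v] <- sidx$tip_index[[sp[[v]]]]
    } else {
      ch <- gidx$children[[v]]
      m <- map[ch[1]]
      for (w in ch[-1]) m <- sp_lca(sidx, m, map[w])
      map[v] <- m
    }
  }

  events <- rep(NA_character_, gidx$n_node)
  dup_rows <- list()
  loss_rows <- list()
  internal <- gidx$postorder[gidx$postorder > gidx$n_tip]
  if (gidx$n_node == 1) internal <- integer(0)
  for (v in internal) {
    ch <- gidx$children[[v]]
    if (length(ch) < 2) {       # unary node (single-leaf tree): no event
      events[v] <- "speciation"
      next
    }
    is_dup <- any(map[ch] == map[v])
    events[v] <- if (is_dup) "duplication" else "speciation"
    if (is_dup) {
      br <- if (map[v] == sidx$root) NA_character_ else sidx$label[map[v]]
      dup_rows[[length(dup_rows) + 1]] <-
        data.frame(node = v, branch = br, stringsAsFactors = FALSE)
    }
  }
  ## losses along each gene-tree edge (parent -> child)
  for (v in seq_len(gidx$n_node)) {
    p <- gidx$parent[v]
    if (is.na(p)) next
    loss_br <- path_losses(sidx, from = map[p], to = map[v],
                           from_inclusive = events[p] == "duplication")
    for (b in loss_br)
      loss_rows[[length(loss_rows) + 1]] <-
        data.frame(branch = b, stringsAsFactors = FALSE)
  }
  duplications <- if (length(dup_rows) > 0) do.call(rbind, dup_rows) else
    data.frame(node = integer(0), branch = character(0))
  losses <- if (length(loss_rows) > 0) do.call(rbind, loss_rows) else
    data.frame(branch = character(0))
  root_lineages <- 1L + sum(map[gidx$root] == sidx$root &
                              events == "duplication" &
                              map == sidx$root, na.rm = TRUE)

  tally <- branch_tally(sidx, duplications, losses)
  structure(list(
    node_map = sidx$label[map], map_index = map, events = events,
    duplications = duplications, losses = losses,
    n_dup = nrow(duplications), n_loss = nrow(losses),
    root_lineages = root_lineages, root_map = sidx$label[map[gidx$root]],
    root_map_index = map[gidx$root],
    tally = tally, resolved_polytomy = resolved,
    species_index = sidx, gene_index = gidx
  ), class = "reconciliation")
}

## Species-tree branches losing the lineage on the way from `from` down to
## `to`. The lineage passes through every node on the path; at each node
## above `to` (including `from` itself only when the parent event was a
## duplication) it is lost in the child subtree off the path.
path_losses <- function(sidx, from, to, from_inclusive) {
  if (from == to) return(character(0))
  path <- to
  while (path[1] != from) path <- c(sidx$parent[path[1]], path)
  out <- character(0)
  first <- if (from_inclusive) 1L else 2L
  last <- length(path) - 1L
  if (first <= last) {
    for (i in first:last) {
      s <- path[i]
      on_path <- path[i + 1L]
      off <- setdiff(sidx$children[[s]], on_path)
      out <- c(out, sidx$label[off])
    }
  }
  out
}

branch_tally <- function(sidx, duplications, losses) {
  br <- branch_labels(sidx)
  gains <- table(factor(duplications$branch, levels = br))
  lsum <- table(factor(losses$branch, levels = br))
  data.frame(branch = br, gains = as.integer(gains),
             losses = as.integer(lsum), stringsAsFactors = FALSE)
}

is.rooted_tree <- function(tree) {
  if (length(tree$tip.label) <= 2) return(TRUE)
  ape::is.rooted(tree)
}

## Greedy polytomy resolution: repeatedly join the two children whose
## species LCA is deepest, so same-species children pair up first.
resolve_polytomies <- function(gene_tree, species_tree, species_pattern) {
  sidx <- species_index(species_tree)
  sp <- leaf_species(gene_tree$tip.label, species_pattern)
  ## operate recursively on a nested-list form of the tree
  gidx <- gene_index(gene_tree)
  build <- function(v) {
    if (v <= gidx$n_tip)
      return(list(label = gene_tree$tip.label[v],
                  map = sidx$tip_index[[sp[[v]]]]))
    kids <- lapply(gidx$children[[v]], build)
    while (length(kids) > 2) {
      best <- c(1L, 2L); best_d <- -1L
      for (i in seq_along(kids)) for (j in seq_along(kids)) {
        if (i >= j) next
        d <- sidx$depth[sp_lca(sidx, kids[[i]]$map, kids[[j]]$map)]
        if (d > best_d) { best_d <- d; best <- c(i, j) }
      }
      joined <- list(kids = list(kids[[best[1]]], kids[[best[2]]]),
                     map = sp_lca(sidx, kids[[best[1]]]$map,
                                  kids[[best[2]]]$map))
      kids <- c(kids[-best], list(joined))
    }
    list(kids = kids, map = sp_lca(sidx, kids[[1]]$map, kids[[2]]$map))
  }
  to_newick <- function(node) {
    if (!is.null(node$label)) return(node$label)
    paste0("(", paste(vapply(node$kids, to_newick, character(1)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(to_newick(build(gidx$root)), ";"))
}

#' Find the duplication-loss-optimal rooting of a gene tree
#'
#' Tries every branch of the (unrooted or arbitrarily rooted) gene tree as
#' the root position, reconciles each candidate and returns the rooting with
#' the fewest duplications + losses. Ties are broken by fewer duplications,
#' then by the lexicographically smallest leaf label in the smaller daughter
#' clade of the root, so the result is canonical.
#'
#' @inheritParams lca_reconcile
#' @return the rooted `phylo` (with attribute `"root_events"` = c(dup, loss)).
#' @export
root_search <- function(gene_tree, species_tree,
                        species_pattern = "_([^_]+)$") {
  n_tip <- length(gene_tree$tip.label)
  if (n_tip < 3) return(gene_tree)
  ut <- ape::unroot(gene_tree)
  candidates <- lapply(seq_len(nrow(ut$edge)), function(k)
    reroot_on_edge(ut, k))
  best <- NULL
  best_key <- NULL
  for (cand in candidates) {
    rec <- lca_reconcile(cand, species_tree, species_pattern)
    ## canonical tie-break key: smaller-side leaf set of the root split
    gidx <- gene_index(cand)
    kids <- gidx$children[[gidx$root]]
    sides <- lapply(kids, function(k) sort(tips_below(gidx, k, cand)))
    small <- sides[[which.min(lengths(sides))]]
    key <- list(rec$n_dup + rec$n_loss, rec$n_dup,
                paste(small, collapse = "|"))
    if (is.null(best) ||
        key[[1]] < best_key[[1]] ||
        (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]]) ||
        (key[[1]] == best_key[[1]] && key[[2]] == best_key[[2]] &&
         key[[3]] < best_key[[3]])) {
      best <- cand
      best_key <- key
      attr(best, "root_events") <- c(dup = rec$n_dup, loss = rec$n_loss)
    }
  }
  best
}

tips_below <- function(gidx, v, tree) {
  if (v <= gidx$n_tip) return(tree$tip.label[v])
  unlist(lapply(gidx$children[[v]], tips_below, gidx = gidx, tree = tree))
}

## Root an unrooted tree on edge k of its edge matrix by inserting a new
## root node in the middle of that edge and orienting all edges away from it.
reroot_on_edge <- function(ut, k) {
  n_tip <- length(ut$tip.label)
  n_node <- max(ut$edge)
  a <- ut$edge[k, 1]; b <- ut$edge[k, 2]
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(ut$edge))) {
    u <- ut$edge[e, 1]; v <- ut$edge[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  ## build children lists away from the new root
  build <- function(v, from) {
    nb <- setdiff(adj[[v]], from)
    if (v <= n_tip && length(nb) == 0) return(ut$tip.label[v])
    parts <- vapply(nb, function(w) build(w, v), character(1))
    ## suppress the old degree-2 attachment if only one child remains
    if (length(parts) == 1) return(parts)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  left <- build(a, b)
  right <- build(b, a)
  ape::read.tree(text = paste0("(", left, ",", right, ");"))
}

#' Sum per-branch events over a forest of reconciliations
#'
#' Aggregates per-family reconciliations into per-species-tree-branch gain
#' and loss totals plus the ancestral lineage count A. A family whose root
#' maps below the species-tree root is counted as present from the root,
#' with one loss on the off-path branch at every species-tree node crossed
#' between the root and the family root's mapping; this keeps the additive
#' ledger c(child) = c(parent) + gains - losses exact for every branch.
#'
#' @param results list of `reconciliation` objects (one per gene family;
#'   single-gene families may be supplied as one-leaf reconciliations).
#' @param species_tree the species tree used for all reconciliations.
#' @return list with `A` (ancestral lineage count), `tally` (data.frame
#'   `branch`, `gains`, `losses`) and `n_families`.
#' @export
tally_branches <- function(results, species_tree) {
  sidx <- species_index(species_tree)
  br <- branch_labels(sidx)
  gains <- setNames(rep(0L, length(br)), br)
  losses <- setNames(rep(0L, length(br)), br)
  A <- 0L
  for (rec in results) {
    A <- A + rec$root_lineages
    t <- rec$tally
    gains[t$branch] <- gains[t$branch] + t$gains
    losses[t$branch] <- losses[t$branch] + t$losses
    ## origin-at-root convention for families mapping below the root
    if (rec$root_map_index != sidx$root) {
      extra <- path_losses(sidx, from = sidx$root, to = rec$root_map_index,
                           from_inclusive = TRUE)
      for (b in extra) losses[b] <- losses[b] + 1L
    }
  }
  list(A = A,
       tally = data.frame(branch = br, gains = as.integer(gains),
                          losses = as.integer(losses),
                          stringsAsFactors = FALSE),
       n_families = length(results))
}

#' Propagate an ancestral count through per-branch gains and losses
#'
#' Checks the duplication-loss ledger: starting from `A` copies at the
#' species-tree root, applies c(child) = c(parent) + gains - losses down
#' every branch and returns the implied copy number at each node. Negative
#' implied counts are flagged as inconsistencies, as are mismatches against
#' observed tip counts when those are provided.
#'
#' @param A ancestral copy number at the species-tree root.
#' @param tally data.frame `branch`, `gains`, `losses` (branches keyed by
#'   child-node label as in [tally_branches()]).
#' @param species_tree rooted species tree.
#' @param observed optional named vector of observed per-species gene counts.
#' @return list with `counts` (data.frame `node`, `implied`), `tips` (named
#'   vector of implied tip counts), `consistent` (logical) and `problems`
#'   (character vector).
#' @export
ledger_check <- function(A, tally, species_tree, observed = NULL) {
  sidx <- species_index(species_tree)
  implied <- rep(NA_real_, sidx$n_node)
  implied[sidx$root] <- A
  ord <- order(sidx$depth)
  problems <- character(0)
  for (v in ord) {
    if (v == sidx$root) next
    lab <- sidx$label[v]
    row <- tally[tally$branch == lab, , drop = FALSE]
    g <- if (nrow(row) > 0) row$gains[1] else 0
    l <- if (nrow(row) > 0) row$losses[1] else 0
    implied[v] <- implied[sidx$parent[v]] + g - l
    if (implied[v] < 0)
      problems <- c(problems, sprintf("negative implied count at %s: %g",
                                      lab, implied[v]))
  }
  tips <- setNames(implied[seq_len(sidx$n_tip)], sidx$tree$tip.label)
  if (!is.null(observed)) {
    for (s in names(observed)) {
      if (!s %in% names(tips)) next
      if (tips[[s]] != observed[[s]])
        problems <- c(problems,
                      sprintf("implied %s count %g != observed %g",
                              s, tips[[s]], observed[[s]]))
    }
  }
  list(counts = data.frame(node = sidx$label, implied = implied,
                           stringsAsFactors = FALSE),
       tips = tips, consistent = length(problems) == 0,
       problems = problems)
}
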