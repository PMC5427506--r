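# Independent brute-force oracles. These deliberately share no code with
# the package: trees are indexed from scratch and optima are found by
# exhaustive enumeration, so agreement with the package is a real check.

# -- tree indexing (standalone) --------------------------------------------

oracle_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge, n_tip)
  parent <- rep(NA_integer_, n_node)
  children <- vector("list", n_node)
  if (!is.null(tree$edge) && nrow(tree$edge) > 0) {
    for (k in seq_len(nrow(tree$edge))) {
      parent[tree$edge[k, 2]] <- tree$edge[k, 1]
      children[[tree$edge[k, 1]]] <- c(children[[tree$edge[k, 1]]],
                                       tree$edge[k, 2])
    }
  }
  root <- which(is.na(parent) & (seq_len(n_node) > n_tip | n_node == 1))[1]
  if (is.na(root)) root <- 1L
  depth <- rep(0L, n_node)
  ord <- root
  q <- root
  while (length(q) > 0) {
    v <- q[1]; q <- q[-1]
    for (w in children[[v]]) {
      depth[w] <- depth[v] + 1L
      ord <- c(ord, w); q <- c(q, w)
    }
  }
  anc <- lapply(seq_len(n_node), function(v) {
    chain <- v
    while (!is.na(parent[chain[length(chain)]]))
      chain <- c(chain, parent[chain[length(chain)]])
    chain
  })
  list(n_tip = n_tip, n_node = n_node, parent = parent,
       children = children, root = root, depth = depth, anc = anc,
       order = ord)
}

# Minimum duplications + losses over all valid reconciliation scenarios:
# every mapping of internal gene-tree nodes to species-tree nodes at or
# above the LCA of their leaves, with each node scored as a speciation when
# geometry allows it (always at least as cheap) and a duplication otherwise.
oracle_reconcile_cost <- function(gene_tree, species_tree,
                                  species_pattern = "_([^_]+)$") {
  si <- oracle_index(species_tree)
  gi <- oracle_index(gene_tree)
  sp_of <- sub(".*_", "", gene_tree$tip.label)
  tipno <- setNames(seq_along(species_tree$tip.label),
                    species_tree$tip.label)
  lca2 <- function(a, b) {
    common <- intersect(si$anc[[a]], si$anc[[b]])
    common[which.max(si$depth[common])]
  }
  post <- rev(gi$order)
  lca_map <- rep(NA_integer_, gi$n_node)
  for (v in post) {
    if (v <= gi$n_tip) lca_map[v] <- tipno[[sp_of[v]]]
    else {
      m <- lca_map[gi$children[[v]][1]]
      for (w in gi$children[[v]][-1]) m <- lca2(m, lca_map[w])
      lca_map[v] <- m
    }
  }
  internal <- post[post > gi$n_tip]
  if (gi$n_node == 1 || length(internal) == 0) return(0)
  cand <- lapply(internal, function(v) si$anc[[lca_map[v]]])
  best <- Inf
  idx <- rep(1L, length(internal))
  repeat {
    M <- lca_map
    for (j in seq_along(internal)) M[internal[j]] <- cand[[j]][idx[j]]
    ok <- TRUE
    for (v in seq_len(gi$n_node)) {
      p <- gi$parent[v]
      if (is.na(p)) next
      if (!(M[p] %in% si$anc[[M[v]]])) { ok <- FALSE; break }
    }
    if (ok) {
      cost <- 0
      for (v in internal) {
        ch <- gi$children[[v]]
        below_distinct <- all(M[ch] != M[v]) &&
          length(ch) == 2 && {
            step <- function(c1) {
              a <- si$anc[[M[c1]]]
              a[which(a == M[v]) - 1]
            }
            M[v] %in% si$anc[[M[ch[1]]]] && M[v] %in% si$anc[[M[ch[2]]]] &&
              step(ch[1]) != step(ch[2])
          }
        if (below_distinct) {
          cost <- cost + sum(si$depth[M[ch]] - si$depth[M[v]] - 1)
        } else {
          cost <- cost + 1 + sum(si$depth[M[ch]] - si$depth[M[v]])
        }
      }
      if (cost < best) best <- cost
    }
    j <- 1L
    while (j <= length(internal)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(cand[[j]])) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(internal)) break
  }
  best
}

# Single-linkage clustering by union-find over every gene pair: same
# chromosome and start-to-start distance <= max_gap.
oracle_single_linkage <- function(ids, chrom, starts, max_gap) {
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  n <- length(ids)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (chrom[i] == chrom[j] && abs(starts[i] - starts[j]) <= max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(ids, comp)
}

# Longest anchor chain by exhaustive subset search (n <= 12): strictly
# monotone in idx_a, strictly monotone (either direction) in idx_b, with
# successive gaps <= max_gap on both sides.
oracle_longest_chain_len <- function(idx_a, idx_b, max_gap) {
  n <- length(idx_a)
  ok_chain <- function(sel) {
    o <- order(idx_a[sel])
    a <- idx_a[sel][o]; b <- idx_b[sel][o]
    if (any(diff(a) <= 0) || any(diff(a) > max_gap)) return(FALSE)
    (all(diff(b) > 0) && all(diff(b) <= max_gap)) ||
      (all(diff(b) < 0) && all(-diff(b) <= max_gap))
  }
  for (k in n:1) {
    if (k == 1) return(1)
    cmb <- utils::combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      if (ok_chain(cmb[, j])) return(k)
    }
  }
  0
}
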