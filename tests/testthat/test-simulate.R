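small_counts <- c(CNL = 25, TNL = 8, RNL = 3)

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 61, ancestral_counts = small_counts)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$motifs, s2$motifs)
  expect_identical(s1$anchors, s2$anchors)
  expect_identical(lapply(s1$trees, ape::write.tree),
                   lapply(s2$trees, ape::write.tree))
  s3 <- simulate_all(sim_config(seed = 62, ancestral_counts = small_counts))
  expect_false(identical(s1$genes$start, s3$genes$start))
})

test_that("zero rates reproduce the ancestral state at every tip", {
  cfg <- sim_config(seed = 63, dup_rate = 0, loss_rate = 0,
                    ancestral_counts = small_counts)
  sim <- simulate_forest(cfg)
  n_fam <- sum(small_counts)
  for (sp in sim$species_tree$tip.label)
    expect_equal(sum(sim$genes$species == sp), n_fam)
  recs <- lapply(sim$trees, lca_reconcile,
                 species_tree = sim$species_tree)
  expect_true(all(vapply(recs, function(r) r$n_dup + r$n_loss == 0,
                         logical(1))))
})

test_that("per-branch event bookkeeping conserves copy numbers", {
  cfg <- sim_config(seed = 64, loss_rate = 0.3,
                    ancestral_counts = small_counts)
  sim <- simulate_forest(cfg)
  bc <- sim$truth$branch_counts
  n_fam <- sum(small_counts)
  paths <- list(tomato = c("potato+tomato", "tomato"),
                potato = c("potato+tomato", "potato"),
                pepper = "pepper")
  for (sp in names(paths)) {
    delta <- sum(bc$dups[bc$branch %in% paths[[sp]]]) -
      sum(bc$losses[bc$branch %in% paths[[sp]]])
    expect_equal(sum(sim$genes$species == sp), n_fam + delta, info = sp)
  }
})

test_that("the runaway-growth guard aborts explosive configurations", {
  cfg <- sim_config(seed = 65, dup_rate = 6, loss_rate = 0,
                    ancestral_counts = c(CNL = 30), max_tip_genes = 100)
  expect_error(simulate_forest(cfg), "runaway")
})

test_that("tandem-only placement builds clusters, ectopic-only does not", {
  tandem_cfg <- sim_config(
    seed = 66, dup_rate = 0.6, loss_rate = 0,
    mechanism_mix = c(tandem = 1, ectopic = 0, segmental = 0),
    ancestral_counts = c(CNL = 20))
  sim <- simulate_all(tandem_cfg)
  for (sp in unique(sim$genes$species)) {
    a <- assign_clusters(sim$genes[sim$genes$species == sp, ])
    dup_fams <- unique(sim$truth$genes$family[
      duplicated(paste(sim$truth$genes$family, sim$truth$genes$species)) &
        sim$truth$genes$species == sp])
    if (length(dup_fams) > 0)
      expect_gte(length(a$clusters), 1)
  }

  ectopic_cfg <- sim_config(
    seed = 67, dup_rate = 0.6, loss_rate = 0,
    mechanism_mix = c(tandem = 0, ectopic = 1, segmental = 0),
    ancestral_counts = c(CNL = 20))
  sim2 <- simulate_all(ectopic_cfg)
  org <- do.call(rbind, lapply(unique(sim2$genes$species), function(sp)
    organization_stats(assign_clusters(
      sim2$genes[sim2$genes$species == sp, ]), species = sp)))
  ratio <- sum(org$clustered_genes) / sum(org$singleton_loci)
  expect_lt(ratio, 0.15)
})

test_that("segmental events leave detectable collinear blocks", {
  cfg <- sim_config(
    seed = 68, dup_rate = 0.35, loss_rate = 0,
    mechanism_mix = c(tandem = 0, ectopic = 0, segmental = 1),
    ancestral_counts = c(CNL = 12))
  sim <- simulate_all(cfg)
  seg <- sim$truth$dup_pairs[sim$truth$dup_pairs$mechanism == "segmental", ]
  if (nrow(seg) > 0) {
    cols <- c("gene_id", "species", "chromosome", "start", "end")
    orders <- gene_order_index(rbind(sim$genes[, cols],
                                     sim$fillers[, cols]))
    blocks <- find_collinear_blocks(sim$anchors, orders)
    within <- Filter(function(b) b$genome_a == b$genome_b, blocks)
    expect_gte(length(within), 1)
    hit <- vapply(seq_len(nrow(seg)), function(i) {
      s <- seg$species[i]
      m <- classify_duplication(
        seg$gene_a[i], seg$gene_b[i], sim$genes,
        assign_clusters(sim$genes[sim$genes$species == s, ]),
        Filter(function(b) b$genome_a == s, within), orders)
      m == "segmental"
    }, logical(1))
    expect_gte(mean(hit), 0.9)
  }
})

test_that("motif emission respects fidelity and the diagnostic residues", {
  cfg <- sim_config(seed = 69, ancestral_counts = c(RNL = 10),
                    motif_fidelity = 1)
  sim <- simulate_all(cfg)
  expect_true(all(substr(sim$motifs$kinase_2, 1, 1) == "P"))
  expect_true(all(substr(sim$motifs$rnbs_c, 10, 10) == "C"))

  cfg0 <- sim_config(seed = 69, ancestral_counts = c(CNL = 40, TNL = 15,
                                                     RNL = 5),
                     motif_fidelity = 0, p_lose_nterm = 1)
  sim0 <- simulate_all(cfg0)
  got <- assign_subclasses(sim0$genes, sim0$motifs)
  truth <- sim0$truth$genes$subclass[
    match(got$gene_id, sim0$truth$genes$gene_id)]
  expect_lt(mean(got$subclass == truth), 0.4)  # near chance
})

test_that("emitted gene trees reconcile to at most the true event counts", {
  cfg <- sim_config(seed = 70, loss_rate = 0.25,
                    ancestral_counts = small_counts)
  sim <- simulate_forest(cfg)
  recs <- lapply(sim$trees, lca_reconcile,
                 species_tree = sim$species_tree)
  tl <- tally_branches(recs, sim$species_tree)
  inferred <- sum(tl$tally$gains) + sum(tl$tally$losses)
  true_total <- nrow(sim$truth$events)
  expect_lte(inferred, true_total)
})
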