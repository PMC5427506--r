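test_that("the distance rule chains neighbours transitively", {
  mk <- function(starts) {
    gene_table(gene_id = sprintf("g%d", seq_along(starts)),
               species = "tomato", chromosome = "Chr01",
               start = starts + 1, end = starts + 1000,
               domains = "NBS", nbs_len = 290)
  }
  # 200 kb apart: one cluster
  a <- assign_clusters(mk(c(100000, 300000)))
  expect_equal(length(a$clusters), 1)
  expect_equal(a$clusters[[1]]$n, 2)
  # 300 kb apart: two singletons
  b <- assign_clusters(mk(c(0, 300000)))
  expect_equal(length(b$clusters), 0)
  expect_equal(length(b$singletons), 2)
  # 0 / 200k / 400k: one 3-gene cluster by transitive chaining
  c3 <- assign_clusters(mk(c(0, 200000, 400000)))
  expect_equal(length(c3$clusters), 1)
  expect_equal(c3$clusters[[1]]$members[[1]], c("g1", "g2", "g3"))
})

test_that("unanchored genes are reported separately and counts conserve", {
  g <- gene_table(gene_id = c("a", "b", "c", "d"), species = "tomato",
                  chromosome = c("Chr01", "Chr01", NA, "UN"),
                  start = c(1, 50000, 1, 1), end = c(1000, 51000, 1000, 1000),
                  domains = "NBS", nbs_len = 290)
  a <- assign_clusters(g)
  expect_setequal(a$unanchored, c("c", "d"))
  total <- sum(vapply(a$clusters, function(x) x$n, numeric(1))) +
    length(a$singletons) + length(a$unanchored)
  expect_equal(total, nrow(g))
})

test_that("cluster assignment equals brute-force single linkage", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:50, 1)
    g <- random_gene_positions(n)
    a <- assign_clusters(g)
    got <- c(lapply(a$clusters, function(x) sort(x$members[[1]])),
             as.list(a$singletons))
    got <- got[order(vapply(got, `[`, character(1), 1))]
    oracle <- oracle_single_linkage(g$gene_id, g$chromosome, g$start,
                                    250000)
    oracle <- lapply(oracle, sort)
    oracle <- oracle[order(vapply(oracle, `[`, character(1), 1))]
    expect_equal(unname(got), unname(oracle))
  }
})

test_that("cluster assignment is invariant to input order", {
  set.seed(32)
  g <- random_gene_positions(30)
  a1 <- assign_clusters(g)
  a2 <- assign_clusters(g[sample.int(nrow(g)), ])
  expect_equal(a1$clusters, a2$clusters)
  expect_equal(a1$singletons, a2$singletons)
})

test_that("wider gaps never fragment the partition further", {
  set.seed(33)
  for (rep in 1:10) {
    g <- random_gene_positions(25)
    parts <- vapply(c(50000, 150000, 400000), function(gap) {
      a <- assign_clusters(g, cluster_config(max_gap = gap))
      length(a$clusters) + length(a$singletons)
    }, numeric(1))
    expect_true(all(diff(parts) <= 0))
  }
})

test_that("organization statistics reproduce the printed ratios", {
  s <- organization_summary("potato", clustered_genes = 367,
                            singleton_genes = 80, n_clusters = 79)
  expect_equal(s$clustered_singleton_ratio, 4.59)
  expect_equal(s$mean_cluster_size, 4.65)
  # no singletons: infinity sentinel rather than an error
  s2 <- organization_summary("x", clustered_genes = 10,
                             singleton_genes = 0, n_clusters = 2)
  expect_true(is.infinite(s2$clustered_singleton_ratio))
  # no genes at all
  empty <- assign_clusters(gene_table())
  s3 <- organization_stats(empty, species = "x")
  expect_equal(s3$anchored_genes, 0)
  expect_equal(s3$clustered_loci, 0)
})

test_that("largest cluster is reported with its chromosome", {
  starts <- c(seq(0, 12 * 20000, by = 20000),        # 13 genes on Chr04
              c(0, 100000))                          # 2 genes on Chr07
  g <- gene_table(gene_id = sprintf("g%02d", seq_along(starts)),
                  species = "tomato",
                  chromosome = rep(c("Chr04", "Chr07"), c(13, 2)),
                  start = starts + 1, end = starts + 1000,
                  domains = "NBS", nbs_len = 290)
  s <- organization_stats(assign_clusters(g))
  expect_equal(s$largest_cluster_size, 13)
  expect_equal(s$largest_cluster_chrom, "Chr04")
  expect_equal(s$clusters_ge10, 1)
})

test_that("chromosome distribution matches the simulator's placement log", {
  cfg <- sim_config(seed = 35, ancestral_counts = c(CNL = 25, TNL = 8,
                                                    RNL = 3))
  sim <- simulate_all(cfg)
  genes <- sim$genes
  genes$subclass <- sim$truth$genes$subclass[
    match(genes$gene_id, sim$truth$genes$gene_id)]
  d <- chromosome_distribution(genes)
  expect_equal(sum(d$n), nrow(genes))
  by_hand <- table(paste(genes$species, genes$chromosome, genes$subclass))
  for (i in seq_len(nrow(d))) {
    key <- paste(d$species[i], d$chromosome[i], d$subclass[i])
    expect_equal(d$n[i], unname(by_hand[[key]]))
  }
  # empty input
  expect_equal(nrow(chromosome_distribution(gene_table())), 0)
})
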