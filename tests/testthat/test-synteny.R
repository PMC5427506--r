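mk_orders <- function(n_a, n_b, genome = c("tomato", "tomato"),
                      chrom = c("Chr01", "Chr02")) {
  data.frame(
    gene_id = c(sprintf("a%02d", seq_len(n_a)),
                sprintf("b%02d", seq_len(n_b))),
    genome = rep(genome, c(n_a, n_b)),
    chromosome = rep(chrom, c(n_a, n_b)),
    idx = c(seq_len(n_a), seq_len(n_b)))
}

mk_anchors <- function(ia, ib, genome = c("tomato", "tomato")) {
  data.frame(gene_a = sprintf("a%02d", ia), gene_b = sprintf("b%02d", ib),
             genome_a = genome[1], genome_b = genome[2], score = 1)
}

test_that("monotone anchor runs become blocks, shuffles do not", {
  orders <- mk_orders(20, 20)
  b1 <- find_collinear_blocks(mk_anchors(1:5, 11:15), orders)
  expect_equal(length(b1), 1)
  expect_equal(nrow(b1[[1]]$anchors), 5)
  expect_equal(b1[[1]]$orientation, "same")

  # descending right side: one inverted block
  b2 <- find_collinear_blocks(mk_anchors(1:5, 15:11), orders)
  expect_equal(length(b2), 1)
  expect_equal(b2[[1]]$orientation, "inverted")

  # a shuffle with no monotone run of 5 (longest is 3; oracle-checked)
  shuffled <- c(13, 11, 15, 12, 14)
  expect_equal(oracle_longest_chain_len(1:5, shuffled, 25), 3)
  b3 <- find_collinear_blocks(mk_anchors(1:5, shuffled), orders,
                              min_anchors = 5)
  expect_equal(length(b3), 0)
})

test_that("block extraction matches the exhaustive longest-chain search", {
  set.seed(51)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    ia <- sample(1:20, n)
    ib <- sample(1:20, n)
    gap <- sample(c(5, 10, 25), 1)
    orders <- mk_orders(20, 20)
    blocks <- find_collinear_blocks(mk_anchors(sort(ia), ib), orders,
                                    min_anchors = 2, max_gap_genes = gap)
    got <- if (length(blocks) > 0) nrow(blocks[[1]]$anchors) else 1
    want <- oracle_longest_chain_len(sort(ia), ib, gap)
    expect_equal(max(got, 2), max(want, 2),
                 info = paste(sort(ia), collapse = ","))
  }
})

test_that("each anchor is used by at most one block", {
  orders <- mk_orders(30, 70)
  # second chain too far on the b side to merge with the first (gap > 25)
  anchors <- rbind(mk_anchors(1:6, 1:6), mk_anchors(10:15, 60:65))
  blocks <- find_collinear_blocks(anchors, orders, min_anchors = 5)
  expect_equal(length(blocks), 2)
  used <- unlist(lapply(blocks, function(b)
    paste(b$anchors$gene_a, b$anchors$gene_b)))
  expect_equal(anyDuplicated(used), 0)
})

test_that("duplication typing follows the positional precedence", {
  genes <- gene_table(
    gene_id = c("p", "q", "r", "s"), species = "tomato",
    chromosome = c("Chr01", "Chr01", "Chr02", NA),
    start = c(100000, 200000, 500000, 1),
    end = c(101000, 201000, 501000, 1000),
    domains = "NBS", nbs_len = 290)
  asg <- assign_clusters(genes)
  # same 250-kb cluster: tandem
  expect_equal(classify_duplication("p", "q", genes, asg), "tandem")
  # different chromosomes, no blocks: ectopic
  expect_equal(classify_duplication("p", "r", genes, asg), "ectopic")
  # one copy unanchored: unanchored wins over everything
  expect_equal(classify_duplication("p", "s", genes, asg), "unanchored")

  # pair that is an anchor inside a 6-anchor within-genome block: segmental
  orders <- mk_orders(30, 30)
  orders <- rbind(orders,
                  data.frame(gene_id = c("x", "y"), genome = "tomato",
                             chromosome = c("Chr01", "Chr02"),
                             idx = c(25, 25)))
  anchors <- rbind(mk_anchors(1:5, 1:5),
                   data.frame(gene_a = "x", gene_b = "y",
                              genome_a = "tomato", genome_b = "tomato",
                              score = 1))
  genes2 <- gene_table(gene_id = c("x", "y"), species = "tomato",
                       chromosome = c("Chr01", "Chr02"),
                       start = c(1e6, 2e6), end = c(1e6, 2e6) + 999,
                       domains = "NBS", nbs_len = 290)
  orders_all <- orders
  blocks <- find_collinear_blocks(anchors, orders_all, min_anchors = 5,
                                  max_gap_genes = 25)
  expect_equal(length(blocks), 1)  # the 6-anchor chain absorbs x-y
  expect_equal(
    classify_duplication("x", "y", genes2, assign_clusters(genes2),
                         blocks, orders_all), "segmental")
})

test_that("duplication-type summary reports printed-style percentages", {
  ev <- data.frame(
    species = c(rep("potato", 194), rep("tomato", 70)),
    mechanism = c(rep("tandem", 118), rep("ectopic", 76),
                  rep("unanchored", 0), rep("segmental", 0),
                  rep("tandem", 42), rep("ectopic", 27),
                  rep("unanchored", 1)))
  s <- duplication_type_summary(ev)
  expect_equal(s$pct[s$species == "potato" & s$mechanism == "tandem"], 60.8)
  expect_equal(s$pct[s$species == "tomato" & s$mechanism == "ectopic"], 38.6)
  # counts conserve within each species
  for (sp in c("potato", "tomato")) {
    tot <- s$n[s$species == sp & s$mechanism == "total"]
    expect_equal(sum(s$n[s$species == sp & s$mechanism != "total"]), tot)
  }
  expect_equal(nrow(duplication_type_summary(
    data.frame(species = character(0), mechanism = character(0)))), 0)
})

test_that("locus conservation classes partition loci into groups", {
  mk_sp <- function(sp, n, chrom = "Chr01") {
    st <- seq_len(n) * 1e6
    gene_table(gene_id = sprintf("%s_g%02d", sp, seq_len(n)), species = sp,
               chromosome = chrom, start = st, end = st + 999,
               domains = "NBS", nbs_len = 290)
  }
  gt <- list(tomato = mk_sp("tomato", 6), potato = mk_sp("potato", 6),
             pepper = mk_sp("pepper", 6))
  loci <- lapply(gt, assign_clusters)
  orders <- gene_order_index(do.call(rbind, gt))
  cross <- function(a, b, n) data.frame(
    gene_a = sprintf("%s_g%02d", a, seq_len(n)),
    gene_b = sprintf("%s_g%02d", b, seq_len(n)),
    genome_a = a, genome_b = b, score = 1)
  # tomato-potato and tomato-pepper fully collinear: all loci all-three
  anchors <- rbind(cross("tomato", "potato", 6),
                   cross("tomato", "pepper", 6))
  blocks <- find_collinear_blocks(anchors, orders, min_anchors = 5)
  cons <- locus_conservation(loci, blocks)
  expect_equal(cons$venn$n_groups[cons$venn$class == "all-three"], 6)
  # no anchors: everything species-specific
  cons0 <- locus_conservation(loci, list())
  expect_equal(cons0$venn$class, "species-specific")
  expect_equal(cons0$venn$n_groups, 18)
  # group accounting: per-genome loci = sum over groups of genomes spanned
  expect_equal(nrow(cons$loci), 18)
})
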