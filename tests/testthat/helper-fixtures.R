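# Programmatic fixtures shared across test files.

SPECIES_NWK <- "((tomato:1,potato:1):1,pepper:2);"

species_tree_fixture <- function() ape::read.tree(text = SPECIES_NWK)

# Random rooted binary gene tree over n leaves with random species labels:
# recursively split the leaf set.
random_gene_tree <- function(n, species = c("tomato", "potato", "pepper")) {
  labs <- sprintf("g%02d_%s", seq_len(n),
                  sample(species, n, replace = TRUE))
  build <- function(leaves) {
    if (length(leaves) == 1) return(leaves)
    k <- sample(seq_len(length(leaves) - 1), 1)
    pick <- sample(leaves, k)
    paste0("(", build(pick), ",", build(setdiff(leaves, pick)), ")")
  }
  txt <- if (n == 1) paste0("(", labs, ");") else paste0(build(labs), ";")
  ape::read.tree(text = txt)
}

# Random single-species gene table for cluster tests.
random_gene_positions <- function(n, n_chrom = 3, span = 3e6) {
  st <- round(runif(n, 1, span))
  gene_table(
    gene_id = sprintf("g%03d", seq_len(n)),
    species = "tomato",
    chromosome = sprintf("Chr%02d", sample.int(n_chrom, n, replace = TRUE)),
    start = st, end = st + 999,
    domains = "NBS", nbs_len = 290
  )
}

# all permutations of 1..n (tiny n only)
gtools_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], n,
                 sub[, seq(i, n - 1)[seq_len(n - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# graft one new leaf next to an existing tip, keeping the original tip
graft_leaf <- function(tree, tip_label, new_label) {
  txt <- ape::write.tree(tree)
  txt <- sub(paste0("(?<![A-Za-z0-9_])", tip_label, "(?![A-Za-z0-9_])"),
             paste0("(", tip_label, ",", new_label, ")"), txt, perl = TRUE)
  ape::read.tree(text = txt)
}

write_gene_call_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tspecies\tchromosome\tstart\tend\tstrand\tdomain\tdom_start\tdom_end",
               lines), path)
  path
}
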