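## File formats
##
## All genomic coordinates handled by this package are 1-based inclusive
## (GFF3 convention): a gene of length 1 has start == end.  Domain
## coordinates (dom_start/dom_end) are 1-based inclusive positions in the
## translated protein, so nbs_len = dom_end - dom_start + 1 for the NBS call.

#' Construct a gene table
#'
#' A gene table is the package's central container: one row per gene with its
#' species, chromosomal position, ordered domain architecture and NBS-domain
#' length. It is a plain `data.frame` with class `"gene_table"`.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param species species name per gene.
#' @param chromosome chromosome name, or `NA`/`"UN"` for unanchored genes.
#' @param start,end 1-based inclusive coordinates in base pairs.
#' @param strand one of `"+"`, `"-"`, `"?"`.
#' @param domains list of character vectors (N-to-C ordered domain labels
#'   from TIR, CC, RPW8, NBS, LRR) or a `";"`-collapsed character vector.
#' @param nbs_len NBS (NB-ARC) domain length in amino acids; may be `NA`.
#' @param subclass optional subclass label (`TNL`/`CNL`/`RNL`) or `NA`.
#' @return a `gene_table` data.frame.
#' @export
gene_table <- function(gene_id = character(), species = character(),
                       chromosome = character(), start = integer(),
                       end = integer(), strand = "?", domains = character(),
                       nbs_len = NA_real_, subclass = NA_character_) {
  if (is.list(domains)) domains <- vapply(domains, join_domains, character(1))
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    species = rep_len(as.character(species), n),
    chromosome = rep_len(as.character(chromosome), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    domains = rep_len(as.character(domains), n),
    nbs_len = rep_len(as.numeric(nbs_len), n),
    subclass = rep_len(as.character(subclass), n),
    stringsAsFactors = FALSE
  )
  if (n > 0 && anyDuplicated(df$gene_id))
    stop("gene_id values must be unique within a gene table")
  if (n > 0 && any(df$start > df$end, na.rm = TRUE))
    stop("gene start must not exceed end (coordinates are 1-based inclusive)")
  class(df) <- c("gene_table", "data.frame")
  df
}

#' Read a gene coordinate + domain-call table
#'
#' Reads a tab-separated file with one row per domain call (hmmscan-style)
#' and assembles one record per gene. Required columns: `gene_id`, `species`,
#' `chromosome`, `start`, `end`, `strand`, `domain`; optional `dom_start`,
#' `dom_end` (protein coordinates of the call) and `subclass`. Domain calls
#' sharing a `gene_id` are merged into one record with domains ordered N-to-C
#' by `dom_start`; the NBS-domain length is taken from the NBS call's span.
#'
#' Rows with malformed coordinates are rejected with a logged line number.
#' Unknown domain labels are dropped with a warning. Duplicate `gene_id`s
#' with conflicting gene coordinates are a hard error. When isoform-tagged
#' identifiers (`gene.1`, `gene.2`, ...) are detected, only the longest
#' transcript per gene is kept and the collapse is logged.
#'
#' @param path file path.
#' @param collapse_isoforms collapse isoform-tagged ids to the longest model.
#' @param verbose log dropped rows and isoform collapses.
#' @return a [gene_table()].
#' @export
read_gene_table <- function(path, collapse_isoforms = TRUE, verbose = TRUE) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  if (nrow(raw) == 0) return(gene_table())
  needed <- c("gene_id", "species", "chromosome", "start", "end",
              "strand", "domain")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0)
    stop("gene table is missing columns: ", paste(missing_cols, collapse = ", "))

  raw$start <- suppressWarnings(as.numeric(raw$start))
  raw$end <- suppressWarnings(as.numeric(raw$end))
  bad <- is.na(raw$start) | is.na(raw$end) | raw$start > raw$end |
    raw$start < 1
  if (any(bad)) {
    nbs_log("rejected ", sum(bad), " malformed coordinate row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "), verbose = verbose)
    raw <- raw[!bad, , drop = FALSE]
  }
  unknown <- !(raw$domain %in% DOMAIN_LABELS)
  if (any(unknown)) {
    warning("dropping ", sum(unknown), " domain call(s) with unknown label(s): ",
            paste(unique(raw$domain[unknown]), collapse = ", "))
    raw <- raw[!unknown, , drop = FALSE]
  }
  if (nrow(raw) == 0) return(gene_table())

  if (!"dom_start" %in% names(raw)) raw$dom_start <- seq_len(nrow(raw))
  if (!"dom_end" %in% names(raw)) raw$dom_end <- raw$dom_start
  raw$dom_start <- suppressWarnings(as.numeric(raw$dom_start))
  raw$dom_end <- suppressWarnings(as.numeric(raw$dom_end))
  if (!"subclass" %in% names(raw)) raw$subclass <- NA_character_

  ## conflicting gene-level coordinates for one id are unrecoverable
  per_id <- split(raw, raw$gene_id)
  conflict <- vapply(per_id, function(d) {
    length(unique(d$start)) > 1 || length(unique(d$end)) > 1 ||
      length(unique(d$chromosome)) > 1
  }, logical(1))
  if (any(conflict))
    stop("duplicate gene_id with conflicting coordinates: ",
         paste(names(per_id)[conflict], collapse = ", "))

  recs <- lapply(per_id, function(d) {
    d <- d[order(d$dom_start, d$domain), , drop = FALSE]
    nbs <- d[d$domain == "NBS", , drop = FALSE]
    nbs_len <- if (nrow(nbs) > 0) nbs$dom_end[1] - nbs$dom_start[1] + 1 else NA_real_
    data.frame(
      gene_id = d$gene_id[1], species = d$species[1],
      chromosome = d$chromosome[1], start = d$start[1], end = d$end[1],
      strand = d$strand[1], domains = join_domains(d$domain),
      nbs_len = nbs_len, subclass = d$subclass[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL

  if (collapse_isoforms) {
    iso <- grepl("^(.+)\\.\\d+$", out$gene_id)
    base_id <- ifelse(iso, sub("\\.\\d+$", "", out$gene_id), out$gene_id)
    if (anyDuplicated(base_id)) {
      keep <- unlist(lapply(split(seq_len(nrow(out)), base_id), function(i) {
        i[which.max(out$end[i] - out$start[i])]
      }))
      nbs_log("collapsed ", nrow(out) - length(keep),
              " isoform model(s) to the longest transcript", verbose = verbose)
      out <- out[sort(keep), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Write a gene table as a domain-call file
#'
#' Inverse of [read_gene_table()]: emits one row per domain call. Domain
#' protein coordinates are synthesised as consecutive blocks (the NBS block
#' spans `nbs_len` residues) so that reading the file back reproduces every
#' gene-level field, including domain order and `nbs_len`.
#'
#' @param genes a [gene_table()].
#' @param path output file path.
#' @export
write_gene_table <- function(genes, path) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    doms <- split_domains(genes$domains[i])
    if (length(doms) == 0 || all(doms == "")) doms <- character(0)
    len <- ifelse(doms == "NBS",
                  ifelse(is.na(genes$nbs_len[i]), 290, genes$nbs_len[i]), 100)
    dom_end <- cumsum(len)
    dom_start <- dom_end - len + 1
    if (length(doms) == 0) return(NULL)
    data.frame(
      gene_id = genes$gene_id[i], species = genes$species[i],
      chromosome = ifelse(is_unanchored(genes$chromosome[i]), UNANCHORED,
                          genes$chromosome[i]),
      start = genes$start[i], end = genes$end[i], strand = genes$strand[i],
      domain = doms, dom_start = dom_start, dom_end = dom_end,
      subclass = genes$subclass[i], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), species = character(),
                      chromosome = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      domain = character(), dom_start = numeric(),
                      dom_end = numeric(), subclass = character())
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted tree from a Newick file or string
#'
#' Leaf labels encode the species; by default the species name follows the
#' last underscore (`geneX_tomato`). Polytomies are preserved and flagged via
#' the `"has_polytomy"` attribute; downstream reconciliation decides whether
#' to resolve or reject them.
#'
#' @param path path to a Newick file, or (with `text=`) a Newick string.
#' @param text optional Newick string instead of a file.
#' @param species_pattern regex with one capture group extracting the species
#'   from a leaf label.
#' @return an `ape::phylo` with attributes `leaf_species` (named character
#'   vector) and `has_polytomy` (logical).
#' @export
read_newick <- function(path = NULL, text = NULL,
                        species_pattern = "_([^_]+)$") {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error in: ", substr(text, 1, 60))
  attr(tree, "leaf_species") <- leaf_species(tree$tip.label, species_pattern)
  attr(tree, "has_polytomy") <- !ape::is.binary(tree)
  tree
}

#' Extract species names from gene-tree leaf labels
#'
#' @param labels leaf labels.
#' @param species_pattern regex with one capture group.
#' @return named character vector (names = labels).
#' @export
leaf_species <- function(labels, species_pattern = "_([^_]+)$") {
  m <- regmatches(labels, regexec(species_pattern, labels))
  sp <- vapply(m, function(x) if (length(x) >= 2) x[2] else NA_character_,
               character(1))
  if (anyNA(sp))
    stop("cannot parse species from leaf label(s): ",
         paste(labels[is.na(sp)], collapse = ", "))
  setNames(sp, labels)
}

#' Read / write anchor-pair tables
#'
#' Anchor pairs are putative homologous gene pairs (within or across genomes)
#' used as collinearity evidence. Columns: `gene_a`, `gene_b`, `genome_a`,
#' `genome_b`, optional `score`.
#'
#' @param path file path.
#' @return data.frame of anchor pairs.
#' @export
read_anchor_table <- function(path) {
  a <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_a", "gene_b", "genome_a", "genome_b")
  if (!all(needed %in% names(a)))
    stop("anchor table needs columns: ", paste(needed, collapse = ", "))
  if (!"score" %in% names(a)) a$score <- NA_real_
  if (any(a$gene_a == a$gene_b))
    stop("anchor pair with gene_a == gene_b")
  a
}

#' @rdname read_anchor_table
#' @param anchors anchor-pair data.frame.
#' @export
write_anchor_table <- function(anchors, path) {
  write.table(anchors, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif-profile table
#'
#' Tab-separated, one row per gene: `gene_id` plus aligned residue strings
#' for the six conserved NBS-domain motifs `p_loop`, `kinase_2`, `kinase_3`,
#' `rnbs_c`, `glpl`, `rnbs_d`. Missing motifs are empty strings or NA.
#'
#' @param path file path.
#' @return data.frame with `gene_id` and the six motif columns.
#' @export
read_motif_table <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(m)) stop("motif table needs a gene_id column")
  for (mm in MOTIF_NAMES) if (!mm %in% names(m)) m[[mm]] <- NA_character_
  extra <- setdiff(names(m), c("gene_id", MOTIF_NAMES))
  if (length(extra) > 0)
    warning("ignoring unknown motif column(s): ", paste(extra, collapse = ", "))
  m[, c("gene_id", MOTIF_NAMES)]
}

#' @rdname read_motif_table
#' @param motifs motif-profile data.frame.
#' @export
write_motif_table <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write report tables
#'
#' Writes the three summary reports (classification, organization,
#' duplication types) as TSVs with fixed rounding: ratios to 2 decimals,
#' percentages to 1 decimal. Empty results produce header-only files.
#'
#' @param results list with any of `classification` (from
#'   [summarize_classification()]), `organization` (from
#'   [organization_stats()]), `duplication` (from
#'   [duplication_type_summary()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_summary_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(results$classification)) {
    cs <- results$classification
    tab <- cs$counts
    tot <- cs$subclass_totals
    tab <- merge(tab, tot[, c("species", "subclass", "pct")],
                 by = c("species", "subclass"), sort = FALSE)
    names(tab)[names(tab) == "pct"] <- "subclass_pct"
    tab$subclass_pct <- fmt_pct(tab$subclass_pct)
    p <- file.path(dir, "table1_classification.tsv")
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$organization)) {
    org <- results$organization
    org$clustered_singleton_ratio <- fmt_ratio(org$clustered_singleton_ratio)
    org$mean_cluster_size <- fmt_ratio(org$mean_cluster_size)
    p <- file.path(dir, "table2_organization.tsv")
    write.table(org, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$duplication)) {
    dup <- results$duplication
    dup$pct <- fmt_pct(dup$pct)
    p <- file.path(dir, "table3_duplication_types.tsv")
    write.table(dup, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
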