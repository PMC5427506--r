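#' @keywords internal
"_PACKAGE"

#' @importFrom stats rexp runif rnorm setNames aggregate
#' @importFrom utils read.delim write.table head tail
NULL

## Recognised structural domain labels (N-terminal signalling domains,
## the central NB-ARC ("NBS") domain and the LRR sensor domain).
DOMAIN_LABELS <- c("TIR", "CC", "RPW8", "NBS", "LRR")
NTERM_DOMAINS <- c("TIR", "CC", "RPW8")
SUBCLASSES <- c("TNL", "CNL", "RNL")
ARCH_CATEGORIES <- c("intact", "TN", "NL", "N")
MOTIF_NAMES <- c("p_loop", "kinase_2", "kinase_3", "rnbs_c", "glpl", "rnbs_d")
MECHANISMS <- c("tandem", "ectopic", "segmental", "unanchored")

## Sentinel written to files for genes that are not placed on a chromosome.
UNANCHORED <- "UN"

is_unanchored <- function(chromosome) {
  is.na(chromosome) | chromosome == "" | chromosome == UNANCHORED
}

## Split a ";"-collapsed domain string into an ordered character vector.
split_domains <- function(x) {
  if (length(x) == 1L) return(strsplit(x, ";", fixed = TRUE)[[1]])
  strsplit(x, ";", fixed = TRUE)
}

join_domains <- function(x) paste(x, collapse = ";")

## Fixed report rounding: ratios to 2 decimals, percentages to 1 decimal,
## matching the precision used throughout the printed summary tables.
round_ratio <- function(x) round(x, 2)
round_pct <- function(x) round(x, 1)

fmt_ratio <- function(x) {
  ifelse(is.finite(x), formatC(x, format = "f", digits = 2), "Inf")
}
fmt_pct <- function(x) formatC(x, format = "f", digits = 1)

## Natural sort for chromosome names: "Chr2" before "Chr10".
natural_sort <- function(x) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", x)))
  pre <- gsub("[0-9]+", "", x)
  x[order(pre, num, x, na.last = TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Lightweight logging used by readers and the pipeline driver.
nbs_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[nbsevol] ", ...)
  invisible(NULL)
}
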