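## Internal helpers shared across modules.

#' Normalize gene symbols for comparison
#'
#' Uppercases and strips surrounding whitespace.  Mouse symbol casing is
#' inconsistent across databases, so all identity comparisons use the
#' normalized form while the first-seen original casing is preserved for
#' output.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @keywords internal
norm_gene <- function(x) toupper(trimws(as.character(x)))

## Composite node key "<GENE>|<layer>"; (gene, layer) pairs are the node
## identities of the two-layer interactome.
node_key <- function(gene, layer) paste(norm_gene(gene), layer, sep = "|")

#' Derive a child seed from a global seed
#'
#' One global seed fans out to per-generator child seeds so modules can be
#' exercised independently while a whole scenario stays reproducible.
#' Result is kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream small integer identifying the consumer.
#' @return integer child seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(seed) * 7919 + stream * 104729) %% 2147483647)
}

stop_malformed <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
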