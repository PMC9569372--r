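## Differential-expression tables, node prizes, and closed-form assay
## quantifications (RPM, delta-delta-Ct, percent of input).

#' Read a differential-expression results table
#'
#' Accepts the column dialect exported by common DE tools: \code{gene},
#' \code{log2FoldChange}, \code{padj} (extra columns ignored, matching is
#' case-insensitive).
#'
#' @param path TSV file (gzip transparent) or data.frame.
#' @param contrast label stored on the table, e.g. \code{"day3_vs_3h"}.
#' @return data.frame of class \code{de_table} with columns \code{gene},
#'   \code{log2fc}, \code{padj} and attribute \code{contrast}.
#' @export
read_de_table <- function(path, contrast = "") {
  tab <- if (is.character(path)) utils::read.delim(path, stringsAsFactors = FALSE) else path
  nm <- tolower(names(tab))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1L]
    if (is.na(i)) stop_malformed("DE table lacks a column among: %s",
                                 paste(cands, collapse = ", "))
    tab[[i]]
  }
  de <- data.frame(gene = norm_gene(pick(c("gene", "symbol", "gene_symbol"))),
                   log2fc = as.numeric(pick(c("log2foldchange", "log2fc", "lfc"))),
                   padj = as.numeric(pick(c("padj", "fdr", "adj.p.val", "qvalue"))),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(de$gene))
    stop_malformed("duplicate gene symbols in DE table")
  if (any(!is.finite(de$log2fc)))
    stop_malformed("non-finite log2 fold changes in DE table")
  if (any(!is.na(de$padj) & (de$padj < 0 | de$padj > 1)))
    stop_malformed("adjusted p values outside [0, 1]")
  attr(de, "contrast") <- contrast
  class(de) <- c("de_table", class(de))
  de
}

#' Reads-per-million normalization
#'
#' \code{rpm[g, s] = counts[g, s] / sum(counts[, s]) * 1e6}; every column
#' of the result sums to one million.
#'
#' @param counts non-negative gene x sample count matrix.
#' @return RPM matrix of the same shape.
#' @export
compute_rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_malformed("negative counts")
  tot <- colSums(counts)
  zero <- which(tot == 0)
  if (length(zero))
    stop_malformed("sample '%s' has zero total count",
                   colnames(counts)[zero[1L]] %||% as.character(zero[1L]))
  sweep(counts, 2L, tot, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select significantly up-regulated genes
#'
#' Genes with \code{padj < fdr_max} and \code{log2fc > min_log2fc}
#' (default FDR 0.01, any positive fold change).  Missing adjusted p
#' values are treated as non-significant.
#'
#' @param de de_table (or data.frame with gene/log2fc/padj).
#' @param fdr_max adjusted-p cutoff (strict).
#' @param min_log2fc lower bound on log2 fold change (strict).
#' @return character vector of normalized gene symbols.
#' @export
select_up_genes <- function(de, fdr_max = 0.01, min_log2fc = 0) {
  keep <- !is.na(de$padj) & de$padj < fdr_max & de$log2fc > min_log2fc
  sort(unique(de$gene[keep]))
}

#' Select differentially expressed genes (either direction)
#'
#' Genes with \code{padj < fdr_max} and \code{|log2fc| > min_abs_log2fc};
#' both inequalities strict.
#'
#' @inheritParams select_up_genes
#' @param min_abs_log2fc lower bound on |log2 fold change| (strict).
#' @return character vector of normalized gene symbols.
#' @export
select_de_genes <- function(de, fdr_max = 0.01, min_abs_log2fc = 2) {
  keep <- !is.na(de$padj) & de$padj < fdr_max & abs(de$log2fc) > min_abs_log2fc
  sort(unique(de$gene[keep]))
}

#' Assign node prizes from two DE contrasts
#'
#' Protein-layer nodes are prized with the early contrast (significantly
#' up-regulated genes get \code{beta * log2fc}); RNA-layer nodes with the
#' late contrast.  Everything else has prize zero and is a Steiner
#' candidate.  Genes significant in a contrast but absent from the
#' corresponding interactome layer are reported via message.
#'
#' @param interactome assembled interactome.
#' @param de_early DE table for the early contrast (prizes protein nodes).
#' @param de_late DE table for the late contrast (prizes RNA nodes).
#' @param beta positive prize scaling.
#' @param fdr_max significance cutoff passed to [select_up_genes()].
#' @return object of class \code{prize_assignment}: data.frame
#'   (gene, layer, prize) for positive prizes, with attributes
#'   \code{beta} and \code{provenance}.
#' @export
assign_prizes <- function(interactome, de_early, de_late,
                          beta = 1.0, fdr_max = 0.01) {
  if (!is.numeric(beta) || beta <= 0)
    stop_malformed("beta must be a positive number")
  up_e <- select_up_genes(de_early, fdr_max = fdr_max)
  up_l <- select_up_genes(de_late, fdr_max = fdr_max)
  prot <- interactome$nodes$gene[interactome$nodes$layer == "protein"]
  rna <- interactome$nodes$gene[interactome$nodes$layer == "rna"]

  pe <- intersect(up_e, prot); pl <- intersect(up_l, rna)
  miss_e <- setdiff(up_e, prot); miss_l <- setdiff(up_l, rna)
  if (length(miss_e))
    message(sprintf("%d early-up genes not on the protein layer (unmapped)",
                    length(miss_e)))
  if (length(miss_l))
    message(sprintf("%d late-up genes not on the rna layer (unmapped)",
                    length(miss_l)))

  lfc_e <- stats::setNames(de_early$log2fc, de_early$gene)
  lfc_l <- stats::setNames(de_late$log2fc, de_late$gene)
  out <- rbind(
    data.frame(gene = pe, layer = rep("protein", length(pe)),
               prize = beta * unname(lfc_e[pe]), stringsAsFactors = FALSE),
    data.frame(gene = pl, layer = rep("rna", length(pl)),
               prize = beta * unname(lfc_l[pl]), stringsAsFactors = FALSE))
  out <- out[order(out$layer, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, beta = beta,
            provenance = c(protein = attr(de_early, "contrast") %||% "early",
                           rna = attr(de_late, "contrast") %||% "late"),
            unmapped = list(early = miss_e, late = miss_l),
            class = c("prize_assignment", class(out)))
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' Fold change \code{2^-(ddCt)} with
#' \code{ddCt = (ct_gene_sample - ct_ref_sample) -
#'              (ct_gene_control - ct_ref_control)},
#' the reference gene playing the role of, e.g., Polr2a.
#'
#' @param ct_gene_sample,ct_ref_sample,ct_gene_control,ct_ref_control
#'   threshold cycles; vectors recycle.
#' @return fold change(s) relative to the control sample.
#' @export
ddct_fold_change <- function(ct_gene_sample, ct_ref_sample,
                             ct_gene_control, ct_ref_control) {
  stopifnot(is.finite(ct_gene_sample), is.finite(ct_ref_sample),
            is.finite(ct_gene_control), is.finite(ct_ref_control))
  ddct <- (ct_gene_sample - ct_ref_sample) -
    (ct_gene_control - ct_ref_control)
  2^(-ddct)
}

#' ChIP-qPCR recovery as percent of input
#'
#' The input Ct is first adjusted for its dilution
#' (\code{ct_input - log2(1 / input_fraction)}), then
#' \code{100 * 2^(adjusted_input_ct - ct_ip)}.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the diluted input sample.
#' @param input_fraction fraction of chromatin used as input, in (0, 1).
#' @return percent of input (100 = full recovery).
#' @export
percent_of_input <- function(ct_ip, ct_input, input_fraction) {
  if (!is.numeric(input_fraction) || any(input_fraction <= 0) ||
      any(input_fraction >= 1))
    stop_malformed("input_fraction must lie strictly inside (0, 1)")
  stopifnot(is.finite(ct_ip), is.finite(ct_input))
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
}

#' Write a prize assignment as TSV
#' @param prizes prize_assignment.
#' @param path output file.
#' @export
write_prizes <- function(prizes, path) {
  utils::write.table(as.data.frame(prizes)[, c("gene", "layer", "prize")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
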