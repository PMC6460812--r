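#' Threshold a differential-expression table
#'
#' Keeps genes with at least a \code{min_change} relative difference in
#' expression (\code{|log2fc| >= log2(1 + min_change)}) at
#' \code{fdr <= max_fdr}; both boundaries are inclusive.
#'
#' @param de data frame with columns \code{gene, log2fc, fdr}.
#' @param min_change minimum relative expression change (default 0.25, i.e.
#'   25%).
#' @param max_fdr FDR ceiling (default 0.05).
#' @return The significant subset, same columns and order.
#' @export
de_threshold_filter <- function(de, min_change = 0.25, max_fdr = 0.05) {
  assert_that(all(c("gene", "log2fc", "fdr") %in% names(de)),
              "DE table needs columns gene, log2fc, fdr")
  assert_that(all(is.na(de$fdr) | (de$fdr >= 0 & de$fdr <= 1)),
              "fdr must lie in [0, 1]")
  assert_that(min_change >= 0, "min_change must be >= 0")
  keep <- !is.na(de$log2fc) & !is.na(de$fdr) &
    abs(de$log2fc) >= log2(1 + min_change) & de$fdr <= max_fdr
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' qPCR relative expression by the 2^-ddCT method
#'
#' Per sample, the target CT is normalised against the reference gene
#' (\code{dCT = CT_target - CT_reference}); per target gene, \code{ddCT} is
#' the DE-minus-FA difference of group mean dCTs and the fold change is
#' \code{2^-ddCT}. Group comparison is a Welch two-sided t-test on the
#' per-sample dCT values.
#'
#' @param ct data frame with columns \code{sample, group, gene, ct}; every
#'   sample must include the reference gene.
#' @param reference_gene normaliser gene id (default \code{"18S"}).
#' @return Data frame per target gene: \code{gene, n_FA, n_DE, ddct,
#'   fold_change, p}, with the per-sample dCT table attached as attribute
#'   \code{"dct"}.
#' @export
ddct <- function(ct, reference_gene = "18S") {
  assert_that(all(c("sample", "group", "gene", "ct") %in% names(ct)),
              "CT table needs columns sample, group, gene, ct")
  assert_that(all(ct$group %in% c("FA", "DE")), "group must be 'FA' or 'DE'")
  ref <- ct[ct$gene == reference_gene, ]
  assert_that(nrow(ref) > 0, paste("reference gene absent:", reference_gene))
  assert_that(!any(duplicated(ref$sample)),
              "one reference CT per sample expected")
  targets <- ct[ct$gene != reference_gene, ]
  ix <- match(targets$sample, ref$sample)
  assert_that(!anyNA(ix), "every sample needs a reference-gene CT")
  dct <- data.frame(sample = targets$sample, group = targets$group,
                    gene = targets$gene, dct = targets$ct - ref$ct[ix],
                    stringsAsFactors = FALSE)
  out <- lapply(split(dct, dct$gene), function(d) {
    x <- d$dct[d$group == "FA"]; y <- d$dct[d$group == "DE"]
    assert_that(length(x) >= 2 && length(y) >= 2,
                sprintf("gene %s: need >= 2 samples per group", d$gene[1]))
    dd <- mean(y) - mean(x)
    tp <- .welch(x, y)
    data.frame(gene = d$gene[1], n_FA = length(x), n_DE = length(y),
               ddct = dd, fold_change = 2^(-dd), p = tp[["p"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dct") <- dct
  res
}

#' Link DMRs to differentially expressed genes
#'
#' Emits a (gene, DMR) pair when the gene lies within \code{window} bp of the
#' DMR on the same chromosome (distance between closest edges, 0 for
#' overlap; the boundary at exactly \code{window} is inclusive), the gene is
#' in the significant DE set, and -- when \code{require_inverse} -- the
#' expression change opposes the methylation change
#' (\code{sign(log2fc) == -sign(mean_diff)}, both nonzero).
#'
#' @param dmrs a DMR data frame (needs \code{chrom, start, end, mean_diff}).
#' @param de_sig significant DE records (\code{gene, log2fc, fdr}), e.g. from
#'   [de_threshold_filter()].
#' @param annotation a \code{gene_model}; DE genes absent from it are
#'   skipped with a warning.
#' @param window maximum gene-DMR distance in bp (default 1e6).
#' @param require_inverse require opposite signs (default TRUE).
#' @param anchor measure distance from the gene's transcript \code{"span"}
#'   (default) or its \code{"tss"} only.
#' @return Data frame of linked pairs: \code{gene, chrom, dmr_start,
#'   dmr_end, distance, log2fc, mean_diff}.
#' @export
link_dmrs_to_genes <- function(dmrs, de_sig, annotation, window = 1e6,
                               require_inverse = TRUE,
                               anchor = c("span", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(annotation, "gene_model"))
  empty <- data.frame(gene = character(0), chrom = character(0),
                      dmr_start = integer(0), dmr_end = integer(0),
                      distance = numeric(0), log2fc = numeric(0),
                      mean_diff = numeric(0), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0 || nrow(de_sig) == 0) return(empty)

  known <- de_sig$gene %in% annotation$genes$gene_id
  if (any(!known)) {
    warning(sprintf("link_dmrs_to_genes: %d DE gene(s) absent from annotation skipped: %s",
                    sum(!known),
                    paste(utils::head(de_sig$gene[!known], 5), collapse = ", ")))
    de_sig <- de_sig[known, , drop = FALSE]
  }
  if (nrow(de_sig) == 0) return(empty)

  gm <- annotation$genes[match(de_sig$gene, annotation$genes$gene_id), ]
  if (anchor == "tss") {
    tss <- ifelse(gm$strand == "+", gm$start, gm$end)
    gene_gr <- GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(tss, tss))
  } else {
    gene_gr <- GenomicRanges::GRanges(gm$chrom,
                                      IRanges::IRanges(gm$start, gm$end))
  }
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start, dmrs$end))
  hits <- GenomicRanges::findOverlaps(dmr_gr, gene_gr, maxgap = window + 1,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(dmr_gr[qi], gene_gr[si], ignore.strand = TRUE)
  keep <- !is.na(d) & d <= window
  if (require_inverse) {
    keep <- keep & sign(de_sig$log2fc[si]) != 0 &
      sign(dmrs$mean_diff[qi]) != 0 &
      sign(de_sig$log2fc[si]) == -sign(dmrs$mean_diff[qi])
  }
  out <- data.frame(gene = de_sig$gene[si][keep],
                    chrom = dmrs$chrom[qi][keep],
                    dmr_start = dmrs$start[qi][keep],
                    dmr_end = dmrs$end[qi][keep],
                    distance = d[keep],
                    log2fc = de_sig$log2fc[si][keep],
                    mean_diff = dmrs$mean_diff[qi][keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$chrom, out$dmr_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a DE table / CT table from disk
#'
#' DE tables are TSV with columns \code{gene, log2fc, fdr}; CT tables are CSV
#' with columns \code{sample, group, gene, ct}.
#'
#' @param path file path.
#' @return The parsed data frame.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  assert_that(all(c("gene", "log2fc", "fdr") %in% names(de)),
              "DE table needs columns gene, log2fc, fdr")
  de
}

#' @rdname read_de_table
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a DE table as TSV
#'
#' @param de data frame \code{gene, log2fc, fdr}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
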