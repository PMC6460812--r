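#' Gene model container
#'
#' A light single-transcript gene model: one span per gene plus its exon
#' intervals. This is the annotation consumed by [annotate_location()] and
#' [link_dmrs_to_genes()].
#'
#' @param genes data frame with columns \code{gene_id, chrom, start, end,
#'   strand} (1-based inclusive; strand "+" or "-").
#' @param exons data frame with columns \code{gene_id, chrom, start, end};
#'   every exon must belong to a gene and lie within its span.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(genes, exons) {
  need_g <- c("gene_id", "chrom", "start", "end", "strand")
  need_e <- c("gene_id", "chrom", "start", "end")
  assert_that(all(need_g %in% names(genes)), "genes needs gene_id, chrom, start, end, strand")
  assert_that(all(need_e %in% names(exons)), "exons needs gene_id, chrom, start, end")
  assert_that(all(genes$strand %in% c("+", "-")), "strand must be '+' or '-'")
  assert_that(all(genes$start <= genes$end), "gene start must be <= end")
  assert_that(!any(duplicated(genes$gene_id)), "gene ids must be unique")
  assert_that(all(exons$gene_id %in% genes$gene_id),
              "every exon must reference a known gene")
  structure(list(genes = genes[need_g], exons = exons[need_e]),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

# GRanges views of a gene model.
.genes_gr <- function(model) {
  GenomicRanges::GRanges(model$genes$chrom,
                         IRanges::IRanges(model$genes$start, model$genes$end),
                         strand = model$genes$strand,
                         gene_id = model$genes$gene_id)
}

.exons_gr <- function(model) {
  GenomicRanges::GRanges(model$exons$chrom,
                         IRanges::IRanges(model$exons$start, model$exons$end),
                         gene_id = model$exons$gene_id)
}

#' Write / read a gene model as GFF3
#'
#' Genes are written as \code{gene} features (attribute \code{ID}) and exons
#' as \code{exon} features whose \code{Parent} is the gene id (a simplified
#' single-transcript convention). Reading accepts any GFF3 whose gene and
#' exon features follow that convention.
#'
#' @param model a \code{gene_model}.
#' @param path GFF3 file path.
#' @return Invisibly \code{path}; for the reader, a \code{gene_model}.
#' @export
write_gff3 <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  g <- model$genes; e <- model$exons
  gr <- GenomicRanges::GRanges(
    c(g$chrom, e$chrom),
    IRanges::IRanges(c(g$start, e$start), c(g$end, e$end)),
    strand = c(g$strand, g$strand[match(e$gene_id, g$gene_id)])
  )
  gr$source <- "dmrflux"
  gr$type <- c(rep("gene", nrow(g)), rep("exon", nrow(e)))
  gr$ID <- c(g$gene_id, paste0(e$gene_id, ".exon", stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along)))
  gr$Parent <- c(rep(NA_character_, nrow(g)), e$gene_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  is_exon <- gr$type == "exon"
  assert_that(any(is_gene), "GFF3 contains no gene features")
  gg <- gr[is_gene]
  genes <- data.frame(gene_id = as.character(gg$ID),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  ge <- gr[is_exon]
  parent <- vapply(as.list(ge$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  exons <- data.frame(gene_id = parent,
                      chrom = as.character(GenomicRanges::seqnames(ge)),
                      start = GenomicRanges::start(ge),
                      end = GenomicRanges::end(ge),
                      stringsAsFactors = FALSE)
  exons <- exons[!is.na(exons$gene_id) & exons$gene_id %in% genes$gene_id, ,
                 drop = FALSE]
  gene_model(genes, exons)
}
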