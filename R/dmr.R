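#' Flag significant CpGs for region formation
#'
#' A CpG is flagged when its p-value is strictly below \code{p_max} and its
#' absolute methylation difference is at least \code{min_abs_diff}. Missing
#' p-values or differences are never flagged.
#'
#' @param results a \code{cpg_test_result} data frame.
#' @param p_max p-value cutoff (strict \code{<}; default 0.001).
#' @param min_abs_diff minimum absolute methylation difference (inclusive
#'   \code{>=}; default 0.10).
#' @return Logical vector, one flag per CpG.
#' @export
flag_significant <- function(results, p_max = 0.001, min_abs_diff = 0.10) {
  stopifnot(all(c("p", "diff") %in% names(results)))
  !is.na(results$p) & !is.na(results$diff) &
    results$p < p_max & abs(results$diff) >= min_abs_diff
}

# Validate that a results table is sorted by chromosome block then position.
.check_sorted <- function(results) {
  chrom_f <- factor(results$chrom, levels = unique(results$chrom))
  assert_that(identical(order(chrom_f, results$pos), seq_len(nrow(results))),
              "results must be sorted by chromosome then position")
}

#' Seed candidate regions from flagged CpGs
#'
#' Candidates are maximal chains of flagged CpGs on one chromosome in which
#' consecutive flagged CpGs are at most \code{join_gap} bp apart. Each
#' candidate spans its first to last flagged CpG and absorbs every
#' intervening unflagged CpG.
#'
#' @param results a \code{cpg_test_result}, sorted by chromosome and
#'   position (as [per_cpg_test()] emits).
#' @param flags logical vector from [flag_significant()].
#' @param join_gap maximum bp between consecutive flagged CpGs in a chain
#'   (default 100).
#' @return Data frame of candidates: \code{chrom, start, end, first, last},
#'   where \code{first}/\code{last} index the member CpG rows of
#'   \code{results} (all CpGs in the span are members).
#' @export
seed_regions <- function(results, flags, join_gap = 100) {
  stopifnot(length(flags) == nrow(results))
  .check_sorted(results)
  out <- list()
  for (ch in unique(results$chrom)) {
    on_ch <- which(results$chrom == ch)
    f <- on_ch[flags[on_ch]]
    if (length(f) == 0) next
    brk <- c(0, which(diff(results$pos[f]) > join_gap), length(f))
    for (i in seq_len(length(brk) - 1)) {
      members <- f[(brk[i] + 1):brk[i + 1]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start = results$pos[members[1]],
        end = results$pos[members[length(members)]],
        first = members[1], last = members[length(members)])
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), first = integer(0), last = integer(0)))
  }
  do.call(rbind, out)
}

# Region statistics over the member CpG rows first..last of `results`.
# CpGs with missing statistics contribute nothing to area_stat/mean_diff but
# count toward n_cpgs.
.region_stats <- function(results, flags, first, last) {
  idx <- seq.int(first, last)
  area <- sum(results$stat[idx], na.rm = TRUE)
  data.frame(n_cpgs = length(idx), n_sig = sum(flags[idx]),
             area_stat = area,
             mean_diff = mean(results$diff[idx], na.rm = TRUE),
             direction = if (area < 0) "hypo" else "hyper",
             stringsAsFactors = FALSE)
}

#' Apply the DMR qualification criteria to candidate regions
#'
#' A candidate qualifies as a DMR when its genomic span (\code{end - start +
#' 1}) is at least \code{min_len} bp, it contains at least \code{min_cpgs}
#' CpGs, and at least \code{min_frac_sig} of its CpGs are flagged. Region
#' statistics (CpG counts, AreaStat = sum of member-CpG test statistics, mean
#' difference, direction) are computed for the survivors.
#'
#' @param candidates output of [seed_regions()].
#' @param results,flags the per-CpG results and flags the candidates index.
#' @param min_len minimum span in bp (default 50).
#' @param min_cpgs minimum CpG count (default 3).
#' @param min_frac_sig minimum flagged fraction (default 0.5).
#' @return A DMR data frame: \code{chrom, start, end, n_cpgs, n_sig,
#'   area_stat, mean_diff, direction, first, last}.
#' @export
apply_dmr_criteria <- function(candidates, results, flags,
                               min_len = 50, min_cpgs = 3, min_frac_sig = 0.5) {
  assert_that(min_cpgs >= 1, "min_cpgs must be >= 1")
  stats_list <- lapply(seq_len(nrow(candidates)), function(i) {
    .region_stats(results, flags, candidates$first[i], candidates$last[i])
  })
  st <- if (length(stats_list)) do.call(rbind, stats_list) else
    data.frame(n_cpgs = integer(0), n_sig = integer(0), area_stat = numeric(0),
               mean_diff = numeric(0), direction = character(0))
  dmrs <- cbind(candidates[c("chrom", "start", "end")], st,
                candidates[c("first", "last")])
  keep <- (dmrs$end - dmrs$start + 1) >= min_len &
    dmrs$n_cpgs >= min_cpgs &
    dmrs$n_sig / dmrs$n_cpgs >= min_frac_sig
  dmrs <- dmrs[keep, , drop = FALSE]
  rownames(dmrs) <- NULL
  dmrs
}

#' Merge nearby DMRs
#'
#' Consecutive DMRs on the same chromosome whose inter-region gap
#' (\code{start2 - end1 - 1}) is at most \code{merge_dist} bp are replaced by
#' a single DMR spanning both; statistics are recomputed over all CpGs in the
#' merged span (including any CpGs lying between the original regions).
#' Merging is transitive and idempotent; merged regions are not re-checked
#' against the qualification criteria.
#'
#' @param dmrs DMR data frame from [apply_dmr_criteria()] (sorted,
#'   non-overlapping).
#' @param results,flags the per-CpG results and flags the DMRs index.
#' @param merge_dist maximum gap in bp (default 100).
#' @return The merged DMR data frame.
#' @export
merge_dmrs <- function(dmrs, results, flags, merge_dist = 100) {
  if (nrow(dmrs) <= 1) return(dmrs)
  out <- list()
  cur <- dmrs[1, ]
  for (i in 2:nrow(dmrs)) {
    nxt <- dmrs[i, ]
    gap <- nxt$start - cur$end - 1
    if (nxt$chrom == cur$chrom && gap <= merge_dist) {
      cur$end <- nxt$end
      cur$last <- nxt$last
      st <- .region_stats(results, flags, cur$first, cur$last)
      cur[names(st)] <- st
    } else {
      out[[length(out) + 1]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call DMRs from per-CpG results
#'
#' The full region pipeline: flag significant CpGs, chain them into candidate
#' regions, apply the qualification criteria, and merge nearby survivors.
#'
#' @param results a \code{cpg_test_result}, sorted by chromosome/position.
#' @inheritParams flag_significant
#' @inheritParams seed_regions
#' @inheritParams apply_dmr_criteria
#' @inheritParams merge_dmrs
#' @return A sorted, non-overlapping DMR data frame (see
#'   [apply_dmr_criteria()] for columns).
#' @export
call_dmrs <- function(results, p_max = 0.001, min_abs_diff = 0.10,
                      join_gap = 100, min_len = 50, min_cpgs = 3,
                      min_frac_sig = 0.5, merge_dist = 100) {
  flags <- flag_significant(results, p_max = p_max, min_abs_diff = min_abs_diff)
  cand <- seed_regions(results, flags, join_gap = join_gap)
  dmrs <- apply_dmr_criteria(cand, results, flags, min_len = min_len,
                             min_cpgs = min_cpgs, min_frac_sig = min_frac_sig)
  merge_dmrs(dmrs, results, flags, merge_dist = merge_dist)
}

#' Annotate DMRs with their genomic context
#'
#' Classifies each DMR's midpoint by precedence promoter > exon > intron >
#' intergenic: promoter means within \code{promoter_upstream} bp upstream of
#' any gene's transcription start site (strand-aware, the TSS itself
#' excluded); exon/intron mean containment in any gene's exon, respectively
#' in a gene span outside its exons. Ties between overlapping genes are
#' resolved by the precedence order, then alphabetically by gene id. A
#' \code{gene} column records the assigning (or nearest same-chromosome)
#' gene.
#'
#' @param dmrs a DMR data frame.
#' @param annotation a \code{gene_model}.
#' @param promoter_upstream promoter window upstream of the TSS in bp
#'   (default 3000).
#' @return \code{dmrs} with added \code{location} and \code{gene} columns.
#' @export
annotate_location <- function(dmrs, annotation, promoter_upstream = 3000) {
  stopifnot(inherits(annotation, "gene_model"))
  dmrs$location <- character(nrow(dmrs))
  dmrs$gene <- rep(NA_character_, nrow(dmrs))
  if (nrow(dmrs) == 0) return(dmrs)

  genes <- .genes_gr(annotation)
  exons <- .exons_gr(annotation)
  prom <- GenomicRanges::promoters(genes, upstream = promoter_upstream,
                                   downstream = 0)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  midp <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(mid, mid))

  pick <- function(hits, ids) {
    # earliest alphabetical gene id among hits, per query
    ans <- rep(NA_character_, nrow(dmrs))
    if (length(hits) == 0) return(ans)
    q <- S4Vectors::queryHits(hits)
    g <- ids[S4Vectors::subjectHits(hits)]
    for (qq in unique(q)) ans[qq] <- min(g[q == qq])
    ans
  }
  hit_prom <- pick(GenomicRanges::findOverlaps(midp, prom, ignore.strand = TRUE),
                   prom$gene_id)
  hit_exon <- pick(GenomicRanges::findOverlaps(midp, exons, ignore.strand = TRUE),
                   exons$gene_id)
  hit_gene <- pick(GenomicRanges::findOverlaps(midp, genes, ignore.strand = TRUE),
                   genes$gene_id)

  dmrs$location <- ifelse(!is.na(hit_prom), "promoter",
                   ifelse(!is.na(hit_exon), "exon",
                   ifelse(!is.na(hit_gene), "intron", "intergenic")))
  dmrs$gene <- ifelse(!is.na(hit_prom), hit_prom,
               ifelse(!is.na(hit_exon), hit_exon,
               ifelse(!is.na(hit_gene), hit_gene, NA_character_)))

  # for intergenic DMRs record the nearest gene on the same chromosome
  inter <- which(is.na(dmrs$gene))
  if (length(inter) > 0) {
    nn <- GenomicRanges::distanceToNearest(midp[inter], genes,
                                           ignore.strand = TRUE)
    dmrs$gene[inter[S4Vectors::queryHits(nn)]] <-
      genes$gene_id[S4Vectors::subjectHits(nn)]
  }
  dmrs
}

#' Write / read DMRs as BED6+
#'
#' BED uses half-open 0-based coordinates; the internal model is 1-based
#' inclusive, so \code{start0 = start - 1}. Columns: chrom, start0, end,
#' name (assigned/nearest gene or "."), score (\code{|area_stat|}), strand
#' ("."), then n_cpgs, n_sig, area_stat, mean_diff, direction, location.
#'
#' @param dmrs an annotated DMR data frame.
#' @param path BED file path.
#' @return Invisibly \code{path}; the reader returns the DMR data frame.
#' @export
write_dmrs_bed <- function(dmrs, path) {
  gene <- if ("gene" %in% names(dmrs)) ifelse(is.na(dmrs$gene), ".", dmrs$gene)
          else rep(".", nrow(dmrs))
  loc <- if ("location" %in% names(dmrs)) dmrs$location else rep(".", nrow(dmrs))
  bed <- data.frame(chrom = dmrs$chrom, start0 = dmrs$start - 1, end = dmrs$end,
                    name = gene, score = abs(dmrs$area_stat), strand = ".",
                    n_cpgs = dmrs$n_cpgs, n_sig = dmrs$n_sig,
                    area_stat = dmrs$area_stat, mean_diff = dmrs$mean_diff,
                    direction = dmrs$direction, location = loc)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmrs_bed
#' @export
read_dmrs_bed <- function(path) {
  cols <- c("chrom", "start0", "end", "name", "score", "strand",
            "n_cpgs", "n_sig", "area_stat", "mean_diff", "direction",
            "location")
  bed <- utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  data.frame(chrom = bed$chrom, start = bed$start0 + 1, end = bed$end,
             n_cpgs = bed$n_cpgs, n_sig = bed$n_sig,
             area_stat = bed$area_stat, mean_diff = bed$mean_diff,
             direction = bed$direction, location = bed$location,
             gene = ifelse(bed$name == ".", NA_character_, bed$name),
             stringsAsFactors = FALSE)
}
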