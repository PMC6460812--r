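#' Per-CpG, per-sample bisulfite count matrix
#'
#' The substrate of all methylation stages: for every CpG a chromosome and
#' 1-based position, and for every sample a read coverage and a methylated
#' read count, together with a two-level exposure group label per sample
#' (\code{"FA"} filtered air, \code{"DE"} diesel exhaust).
#'
#' @param chrom character vector of chromosome ids, one per CpG.
#' @param pos integer vector of 1-based CpG positions.
#' @param cov integer matrix (CpGs x samples) of read coverages.
#' @param meth integer matrix (CpGs x samples) of methylated read counts.
#' @param group character or factor of length \code{ncol(cov)} with values
#'   in \code{c("FA", "DE")}.
#' @param samples sample ids; defaults to \code{colnames(cov)} or
#'   \code{s1, s2, ...}.
#'
#' @return An object of class \code{CpgCountMatrix}: a list with elements
#'   \code{chrom}, \code{pos}, \code{cov}, \code{meth}, \code{group},
#'   \code{samples}. Rows are sorted by chromosome (order of first
#'   appearance) then position; positions are strictly increasing within
#'   each chromosome.
#' @export
cpg_count_matrix <- function(chrom, pos, cov, meth, group, samples = NULL) {
  cov <- as.matrix(cov)
  meth <- as.matrix(meth)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  n <- length(chrom)
  assert_that(length(pos) == n && nrow(cov) == n && nrow(meth) == n,
              "chrom, pos, cov, meth must agree on the number of CpGs")
  assert_that(all(dim(cov) == dim(meth)), "cov and meth must have equal dims")
  if (is.null(samples)) samples <- colnames(cov) %||% paste0("s", seq_len(ncol(cov)))
  group <- as.character(group)
  assert_that(length(group) == ncol(cov), "one group label per sample required")
  assert_that(all(group %in% c("FA", "DE")),
              "group labels must be 'FA' or 'DE'")
  assert_that(sum(group == "FA") >= 2 && sum(group == "DE") >= 2,
              "at least 2 samples per group are required")
  storage.mode(cov) <- "integer"
  storage.mode(meth) <- "integer"
  assert_that(!anyNA(cov) && !anyNA(meth), "counts must not contain NA")
  assert_that(all(cov >= 0) && all(meth >= 0) && all(meth <= cov),
              "0 <= methylated <= coverage must hold for every cell")

  # canonical order: chromosome blocks in order of first appearance, then pos
  chrom_f <- factor(chrom, levels = unique(chrom))
  o <- order(chrom_f, pos)
  chrom <- chrom[o]; pos <- pos[o]
  cov <- cov[o, , drop = FALSE]; meth <- meth[o, , drop = FALSE]
  dup <- duplicated(paste(chrom, pos))
  assert_that(!any(dup), "positions must be unique within a chromosome")
  colnames(cov) <- colnames(meth) <- samples

  structure(
    list(chrom = chrom, pos = pos, cov = cov, meth = meth,
         group = group, samples = samples),
    class = "CpgCountMatrix"
  )
}

#' @export
print.CpgCountMatrix <- function(x, ...) {
  cat(sprintf("CpgCountMatrix: %d CpGs x %d samples (%d FA, %d DE) on %d chromosome(s)\n",
              length(x$pos), length(x$samples),
              sum(x$group == "FA"), sum(x$group == "DE"),
              length(unique(x$chrom))))
  invisible(x)
}

#' @export
dim.CpgCountMatrix <- function(x) c(length(x$pos), length(x$samples))

# Row-subset a CpgCountMatrix, preserving sample metadata.
subset_cpgs <- function(mat, keep) {
  structure(
    list(chrom = mat$chrom[keep], pos = mat$pos[keep],
         cov = mat$cov[keep, , drop = FALSE],
         meth = mat$meth[keep, , drop = FALSE],
         group = mat$group, samples = mat$samples),
    class = "CpgCountMatrix"
  )
}

#' Write a count matrix as per-sample Bismark-coverage TSVs plus a samplesheet
#'
#' One file per sample in the Bismark coverage dialect (chrom, start, end =
#' start, methylation percentage, methylated count, unmethylated count),
#' tab-separated, no header. CpGs with zero coverage in a sample are omitted
#' from that sample's file, as an aligner would. A samplesheet CSV
#' (\code{file, sample, group}) is written alongside.
#'
#' @param mat a \code{CpgCountMatrix}.
#' @param dir output directory (created if needed).
#' @param samplesheet path of the samplesheet CSV; default
#'   \code{file.path(dir, "samples.csv")}.
#' @return Invisibly, the samplesheet path.
#' @export
write_bismark_cov <- function(mat, dir, samplesheet = file.path(dir, "samples.csv")) {
  stopifnot(inherits(mat, "CpgCountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(mat$samples))
  for (j in seq_along(mat$samples)) {
    keep <- mat$cov[, j] > 0L
    m <- mat$meth[keep, j]
    u <- mat$cov[keep, j] - m
    df <- data.frame(chrom = mat$chrom[keep],
                     start = mat$pos[keep],
                     end = mat$pos[keep],
                     pct = ifelse(m + u > 0, 100 * m / (m + u), 0),
                     meth = m, unmeth = u)
    f <- file.path(dir, paste0(mat$samples[j], ".cov"))
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[j] <- f
  }
  sheet <- data.frame(file = basename(files), sample = mat$samples,
                      group = mat$group)
  utils::write.csv(sheet, samplesheet, row.names = FALSE, quote = FALSE)
  invisible(samplesheet)
}

#' Read per-sample Bismark-coverage TSVs into a count matrix
#'
#' Reads the samplesheet CSV (\code{file, sample, group}; file paths relative
#' to the samplesheet's directory) and assembles the union of CpG positions
#' across samples; a CpG absent from a sample's file gets coverage 0 there.
#'
#' @param samplesheet path to the samplesheet CSV.
#' @return A \code{CpgCountMatrix}.
#' @export
read_bismark_cov <- function(samplesheet) {
  sheet <- utils::read.csv(samplesheet, stringsAsFactors = FALSE)
  assert_that(all(c("file", "sample", "group") %in% names(sheet)),
              "samplesheet needs columns file, sample, group")
  base <- dirname(samplesheet)
  per <- lapply(seq_len(nrow(sheet)), function(i) {
    f <- sheet$file[i]
    if (!file.exists(f)) f <- file.path(base, f)
    assert_that(file.exists(f), paste("missing coverage file:", f))
    d <- utils::read.table(f, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "pct",
                                         "meth", "unmeth"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric", "integer", "integer"))
    d
  })
  keys <- unique(do.call(rbind, lapply(per, function(d) d[c("chrom", "start")])))
  chrom_f <- factor(keys$chrom, levels = unique(keys$chrom))
  keys <- keys[order(chrom_f, keys$start), , drop = FALSE]
  id <- paste(keys$chrom, keys$start)
  n <- nrow(keys); k <- nrow(sheet)
  cov <- matrix(0L, n, k); meth <- matrix(0L, n, k)
  for (i in seq_len(k)) {
    d <- per[[i]]
    ix <- match(paste(d$chrom, d$start), id)
    cov[ix, i] <- d$meth + d$unmeth
    meth[ix, i] <- d$meth
  }
  cpg_count_matrix(keys$chrom, keys$start, cov, meth,
                   group = sheet$group, samples = sheet$sample)
}
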