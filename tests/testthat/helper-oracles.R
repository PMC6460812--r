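# Fixtures and independent oracles used across the suite.

# Build a small CpgCountMatrix from explicit per-sample counts.
# cov/meth: matrices (CpGs x samples); groups default 2 FA + 2 DE.
make_matrix <- function(cov, meth, pos = NULL, chrom = "chr1", group = NULL) {
  cov <- as.matrix(cov); meth <- as.matrix(meth)
  if (is.null(pos)) pos <- seq_len(nrow(cov)) * 100L
  if (is.null(group)) group <- rep(c("FA", "DE"), each = ncol(cov) / 2)
  cpg_count_matrix(rep(chrom, nrow(cov)), pos, cov, meth, group)
}

# Brute-force Benjamini-Hochberg: sort, scale by m/rank, cumulative min from
# the largest rank, cap at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Classical pooled two-proportion z statistic (the dispersion-0 reference
# for the per-CpG test): totals (m1, w1) vs (m2, w2), sign = p2 - p1.
pooled_z <- function(m1, w1, m2, w2) {
  p1 <- m1 / w1; p2 <- m2 / w2
  pp <- (m1 + m2) / (w1 + w2)
  (p2 - p1) / sqrt(pp * (1 - pp) * (1 / w1 + 1 / w2))
}

# Exhaustive DMR oracle, independent of the package's linear scan:
# enumerates every pair of flagged CpGs as potential chain endpoints,
# checks by brute force that all consecutive flagged CpGs inside are within
# join_gap and that the chain is not extendable (maximality), applies the
# three qualification criteria, then merges transitively by repeated
# pairwise passes until a fixed point.
dmr_oracle <- function(results, flags, join_gap = 100, min_len = 50,
                       min_cpgs = 3, min_frac_sig = 0.5, merge_dist = 100) {
  regions <- list()
  for (ch in unique(results$chrom)) {
    on_ch <- which(results$chrom == ch)
    f <- on_ch[flags[on_ch]]
    if (length(f) == 0) next
    pos <- results$pos
    for (a in seq_along(f)) for (b in a:length(f)) {
      chain <- f[a:b]
      gaps_ok <- all(diff(pos[chain]) <= join_gap)
      left_ext <- a > 1 && (pos[f[a]] - pos[f[a - 1]]) <= join_gap
      right_ext <- b < length(f) && (pos[f[b + 1]] - pos[f[b]]) <= join_gap
      if (gaps_ok && !left_ext && !right_ext) {
        regions[[length(regions) + 1]] <-
          list(chrom = ch, first = f[a], last = f[b])
      }
    }
  }
  mkstats <- function(r) {
    idx <- seq(r$first, r$last)
    area <- sum(results$stat[idx], na.rm = TRUE)
    data.frame(chrom = r$chrom, start = results$pos[r$first],
               end = results$pos[r$last], n_cpgs = length(idx),
               n_sig = sum(flags[idx]), area_stat = area,
               mean_diff = mean(results$diff[idx], na.rm = TRUE),
               direction = if (area < 0) "hypo" else "hyper",
               first = r$first, last = r$last, stringsAsFactors = FALSE)
  }
  dmrs <- do.call(rbind, lapply(regions, mkstats))
  if (is.null(dmrs)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpgs = integer(0),
                      n_sig = integer(0), area_stat = numeric(0),
                      mean_diff = numeric(0), direction = character(0)))
  }
  dmrs <- dmrs[(dmrs$end - dmrs$start + 1) >= min_len &
                 dmrs$n_cpgs >= min_cpgs &
                 dmrs$n_sig / dmrs$n_cpgs >= min_frac_sig, , drop = FALSE]
  dmrs <- dmrs[order(match(dmrs$chrom, unique(results$chrom)), dmrs$start), ,
               drop = FALSE]
  # transitive merge to a fixed point
  repeat {
    merged <- FALSE
    if (nrow(dmrs) >= 2) {
      for (i in 1:(nrow(dmrs) - 1)) {
        if (dmrs$chrom[i] == dmrs$chrom[i + 1] &&
            dmrs$start[i + 1] - dmrs$end[i] - 1 <= merge_dist) {
          r <- list(chrom = dmrs$chrom[i], first = dmrs$first[i],
                    last = dmrs$last[i + 1])
          dmrs <- rbind(if (i > 1) dmrs[1:(i - 1), ], mkstats(r),
                        if (i + 1 < nrow(dmrs)) dmrs[(i + 2):nrow(dmrs), ])
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  rownames(dmrs) <- NULL
  dmrs[c("chrom", "start", "end", "n_cpgs", "n_sig", "area_stat",
         "mean_diff", "direction")]
}

# Random per-CpG results fixture for oracle comparisons.
random_results <- function(n, seed, flag_prob = 0.4, max_gap = 200) {
  set.seed(seed)
  pos <- cumsum(sample(1:max_gap, n, replace = TRUE))
  stat <- rnorm(n, 0, 3)
  res <- data.frame(chrom = "chr1", pos = pos,
                    mean_FA = 0.5, mean_DE = 0.5,
                    diff = sign(stat) * runif(n, 0, 0.5),
                    stat = stat, p = runif(n), fdr = NA_real_)
  flags <- runif(n) < flag_prob
  list(results = res, flags = flags)
}

# A tiny deterministic gene model for annotation tests: one + strand gene
# with two exons, one - strand gene, on chr1.
tiny_model <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB"),
    chrom = "chr1",
    start = c(10000L, 50000L),
    end = c(20000L, 60000L),
    strand = c("+", "-"))
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneB"),
    chrom = "chr1",
    start = c(10000L, 18000L, 50000L),
    end = c(12000L, 20000L, 52000L))
  gene_model(genes, exons)
}
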