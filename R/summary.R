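#' Global methylation histogram in 5% bins
#'
#' For every sample and CpG with nonzero coverage, the percent methylation
#' \code{100 * methylated / coverage} is placed into one of twenty 5% bins:
#' bin b holds values in \code{[5b, 5(b+1))}, with the final bin closed at
#' 100. Per-bin group means and sample standard deviations are attached.
#'
#' @param mat a \code{CpgCountMatrix} (conventionally after coverage
#'   filtering; pass the unfiltered matrix to summarise raw data).
#' @return A data frame of class \code{methylation_histogram} with columns
#'   \code{bin_low, bin_high}, one count column per sample, and
#'   \code{mean_FA, sd_FA, mean_DE, sd_DE}.
#' @export
methylation_histogram <- function(mat) {
  stopifnot(inherits(mat, "CpgCountMatrix"))
  edges <- seq(0, 100, by = 5)
  k <- length(mat$samples)
  counts <- matrix(0L, 20, k, dimnames = list(NULL, mat$samples))
  for (j in seq_len(k)) {
    nz <- mat$cov[, j] > 0
    pct <- 100 * mat$meth[nz, j] / mat$cov[nz, j]
    bin <- pmin(floor(pct / 5), 19) + 1L
    counts[, j] <- tabulate(bin, nbins = 20)
  }
  fa <- mat$group == "FA"; de <- mat$group == "DE"
  out <- data.frame(bin_low = edges[-21], bin_high = edges[-1])
  out <- cbind(out, counts)
  out$mean_FA <- rowMeans(counts[, fa, drop = FALSE])
  out$sd_FA <- apply(counts[, fa, drop = FALSE], 1, stats::sd)
  out$mean_DE <- rowMeans(counts[, de, drop = FALSE])
  out$sd_DE <- apply(counts[, de, drop = FALSE], 1, stats::sd)
  class(out) <- c("methylation_histogram", "data.frame")
  out
}

#' Exact binomial test for directional skew
#'
#' Tests whether hyper- and hypomethylated loci are equally likely
#' (probability \code{p0} of a locus being hypermethylated) with an exact
#' two-sided binomial test: the p-value sums all outcome probabilities not
#' exceeding that of the observed count (minimum-likelihood two-sided
#' method, as in \code{stats::binom.test}). The mass is accumulated in log
#' space, so extremely skewed counts that underflow a double still report a
#' finite \code{log10_p} attribute.
#'
#' @param n_hyper observed hypermethylated count.
#' @param n_total total directional loci (>= 1).
#' @param p0 null probability of hypermethylation (default 0.5).
#' @return The two-sided p-value (may underflow to 0 for extreme skews),
#'   with attribute \code{log10_p} carrying the exact base-10 log p-value.
#' @export
direction_skew_test <- function(n_hyper, n_total, p0 = 0.5) {
  assert_that(length(n_total) == 1 && n_total >= 1, "n_total must be >= 1")
  assert_that(n_hyper >= 0 && n_hyper <= n_total,
              "need 0 <= n_hyper <= n_total")
  assert_that(p0 > 0 && p0 < 1, "p0 must be in (0, 1)")
  lf <- stats::dbinom(0:n_total, n_total, p0, log = TRUE)
  lobs <- lf[n_hyper + 1L]
  # same relative tolerance as binom.test's relErr = 1 + 1e-7
  sel <- lf <= lobs + log1p(1e-7)
  lp <- min(logsumexp(lf[sel]), 0)
  structure(exp(lp), log10_p = lp / log(10))
}

#' Composition of DMR genomic locations
#'
#' Fractions of DMRs per location label (promoter, exon, intron,
#' intergenic). Fractions sum to 1; an empty DMR set yields an empty result.
#'
#' @param dmrs an annotated DMR data frame (with a \code{location} column).
#' @return Named numeric vector of fractions, or \code{numeric(0)} when no
#'   DMRs are given.
#' @export
location_composition <- function(dmrs) {
  if (nrow(dmrs) == 0) return(numeric(0))
  stopifnot("location" %in% names(dmrs))
  labs <- c("promoter", "exon", "intron", "intergenic")
  assert_that(all(dmrs$location %in% labs), "unknown location label")
  tab <- table(factor(dmrs$location, levels = labs))
  frac <- as.numeric(tab) / nrow(dmrs)
  names(frac) <- labs
  frac
}

#' Write the methylation histogram / location composition as TSV
#'
#' @param x a \code{methylation_histogram} or composition vector.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_histogram <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
write_composition <- function(x, path) {
  df <- data.frame(location = names(x), fraction = as.numeric(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
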