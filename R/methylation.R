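#' Coverage-filter CpGs
#'
#' Retains the CpGs whose read coverage is strictly greater than
#' \code{min_cov} in at least \code{ceiling(min_frac_samples * n_samples)}
#' samples (counted over all samples, not per group). Row order is preserved.
#'
#' @param mat a \code{CpgCountMatrix}.
#' @param min_cov coverage must exceed this value (strict \code{>}).
#' @param min_frac_samples minimum fraction of samples meeting the coverage
#'   requirement.
#' @return The filtered \code{CpgCountMatrix}.
#' @export
filter_cpgs <- function(mat, min_cov = 5, min_frac_samples = 0.5) {
  stopifnot(inherits(mat, "CpgCountMatrix"))
  assert_that(min_cov >= 0, "min_cov must be >= 0")
  assert_that(min_frac_samples >= 0 && min_frac_samples <= 1,
              "min_frac_samples must be in [0, 1]")
  need <- ceiling(min_frac_samples * length(mat$samples))
  keep <- rowSums(mat$cov > min_cov) >= need
  subset_cpgs(mat, keep)
}

# Per-group sufficient statistics for the Wald test, vectorised over CpGs.
# Returns coverage-weighted proportion, and the method-of-moments pieces
# S, A, B such that E[S] = p(1-p) (A + phi * B) under a beta-binomial with
# mean p and overdispersion phi (samples with zero coverage contribute
# nothing).
.group_suffstats <- function(cov, meth) {
  W <- rowSums(cov)
  M <- rowSums(meth)
  npos <- rowSums(cov > 0)
  sumN2 <- rowSums(cov^2)
  phat <- ifelse(W > 0, M / W, NA_real_)
  ps <- matrix(0, nrow(cov), ncol(cov))
  nz <- cov > 0
  ps[nz] <- meth[nz] / cov[nz]
  dev <- (ps - phat)^2
  dev[!nz] <- 0              # zero-coverage samples carry zero weight
  S <- rowSums(cov * dev)
  A <- npos - 1
  B <- (W - npos) - ifelse(W > 0, (sumN2 - W) / W, 0)
  list(W = W, M = M, npos = npos, phat = phat, S = S, A = A, B = B)
}

#' Per-CpG differential methylation test
#'
#' For each CpG, group methylation levels are the coverage-weighted
#' proportions \eqn{\hat p_g = \sum_s m_s / \sum_s N_s} over the samples with
#' nonzero coverage, and the signed test statistic is
#' \eqn{(\hat p_{DE} - \hat p_{FA}) / SE} with a beta-binomial sampling
#' variance evaluated at the pooled proportion \eqn{\tilde p} (score-type
#' standardisation, which is well calibrated under the null):
#' \eqn{Var(\hat p_g) = \tilde p (1-\tilde p)
#' \sum_s N_s (1 + (N_s - 1)\phi) / W_g^2}. The overdispersion \eqn{\phi} is
#' a per-CpG method-of-moments estimate shrunk 50/50 toward a genome-wide
#' pooled method-of-moments estimate (no smoothing across neighbouring CpGs
#' is applied). Two-sided p-values come from the standard normal reference
#' and are BH-adjusted.
#'
#' A CpG needs at least 2 samples with nonzero coverage per group to be
#' tested; otherwise its statistic and p-value are \code{NA} (group means are
#' still reported when any coverage exists). When the pooled proportion is
#' exactly 0 or 1, the variance uses the shrunken proportion
#' \eqn{(M + 0.5)/(W + 1)} so the statistic stays finite.
#'
#' @param mat a \code{CpgCountMatrix} (typically after [filter_cpgs()]).
#' @param dispersion optional fixed overdispersion in \[0, 1): bypasses
#'   estimation (0 gives the classical pooled two-proportion z-test).
#' @param shrink weight of the genome-wide pooled estimate in the per-CpG
#'   dispersion (default 0.5).
#' @return A data frame of class \code{cpg_test_result} with columns
#'   \code{chrom, pos, mean_FA, mean_DE, diff, stat, p, fdr}; \code{diff} is
#'   DE minus FA.
#' @export
per_cpg_test <- function(mat, dispersion = NULL, shrink = 0.5) {
  stopifnot(inherits(mat, "CpgCountMatrix"))
  fa <- mat$group == "FA"
  de <- mat$group == "DE"
  gf <- .group_suffstats(mat$cov[, fa, drop = FALSE], mat$meth[, fa, drop = FALSE])
  gd <- .group_suffstats(mat$cov[, de, drop = FALSE], mat$meth[, de, drop = FALSE])

  if (is.null(dispersion)) {
    num <- rep(0, length(gf$W)); den <- rep(0, length(gf$W)); any_ok <- rep(FALSE, length(gf$W))
    for (g in list(gf, gd)) {
      ok <- g$npos >= 2 & !is.na(g$phat) & g$phat > 0 & g$phat < 1 & g$B > 0
      num[ok] <- num[ok] + g$S[ok] / (g$phat[ok] * (1 - g$phat[ok])) - g$A[ok]
      den[ok] <- den[ok] + g$B[ok]
      any_ok <- any_ok | ok
    }
    phi_raw <- ifelse(any_ok & den > 0, pmin(pmax(num / den, 0), 0.99), NA_real_)
    # genome-wide centre: pooled method-of-moments over all CpGs (the median
    # of the clamped per-CpG estimates is biased toward 0 at small n)
    ok_all <- any_ok & den > 0
    phi_glob <- if (any(ok_all)) {
      min(max(sum(num[ok_all]) / sum(den[ok_all]), 0), 0.99)
    } else 0
    phi <- (1 - shrink) * phi_raw + shrink * phi_glob
    phi[is.na(phi)] <- phi_glob
  } else {
    assert_that(dispersion >= 0 && dispersion < 1, "dispersion must be in [0, 1)")
    phi <- rep(dispersion, length(gf$W))
  }

  # score-type null variance: both groups share the pooled proportion
  # (better calibrated under the null than unpooled plug-ins); pooled
  # boundary proportions are shrunk away from 0/1 for the variance only
  pp <- ifelse(gf$W + gd$W > 0, (gf$M + gd$M) / (gf$W + gd$W), NA_real_)
  bd <- !is.na(pp) & (pp == 0 | pp == 1)
  pp[bd] <- (gf$M[bd] + gd$M[bd] + 0.5) / (gf$W[bd] + gd$W[bd] + 1)
  gvar <- function(g, cov_g) {
    eff <- rowSums(cov_g * (1 + (cov_g - 1) * phi))
    ifelse(g$W > 0, pp * (1 - pp) * eff / g$W^2, NA_real_)
  }
  vf <- gvar(gf, mat$cov[, fa, drop = FALSE])
  vd <- gvar(gd, mat$cov[, de, drop = FALSE])

  tested <- gf$npos >= 2 & gd$npos >= 2
  diff <- gd$phat - gf$phat
  se <- sqrt(vf + vd)
  stat <- ifelse(tested, ifelse(diff == 0, 0, diff / se), NA_real_)
  p <- ifelse(tested, 2 * stats::pnorm(-abs(stat)), NA_real_)

  n_skipped <- sum(!tested)
  if (n_skipped > 0) {
    message(sprintf("per_cpg_test: %d CpG(s) lack >=2 covered samples per group; stat/p set NA",
                    n_skipped))
  }

  res <- data.frame(chrom = mat$chrom, pos = mat$pos,
                    mean_FA = gf$phat, mean_DE = gd$phat,
                    diff = diff, stat = stat, p = p,
                    fdr = adjust_fdr(p),
                    stringsAsFactors = FALSE)
  class(res) <- c("cpg_test_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment; a thin wrapper over
#' \code{stats::p.adjust(method = "BH")} that validates its input. \code{NA}
#' p-values stay \code{NA} and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return The adjusted values, same length and order as \code{p}.
#' @export
adjust_fdr <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Count significant CpGs and their direction
#'
#' Among CpGs with \code{fdr <= fdr_threshold}, counts hypermethylated
#' (\code{diff > 0}, higher methylation in DE) and hypomethylated
#' (\code{diff < 0}) loci. Exact ties (\code{diff == 0}) are excluded from
#' both directional counts and reported separately.
#'
#' @param results a \code{cpg_test_result} data frame.
#' @param fdr_threshold FDR cutoff (default 0.1).
#' @return A list with \code{n_total}, \code{n_hyper}, \code{n_hypo},
#'   \code{n_ties}; \code{n_total = n_hyper + n_hypo} (ties reported apart).
#' @export
count_significant <- function(results, fdr_threshold = 0.1) {
  stopifnot(is.data.frame(results), all(c("fdr", "diff") %in% names(results)))
  sig <- !is.na(results$fdr) & results$fdr <= fdr_threshold
  n_hyper <- sum(sig & results$diff > 0, na.rm = TRUE)
  n_hypo <- sum(sig & results$diff < 0, na.rm = TRUE)
  n_ties <- sum(sig & results$diff == 0, na.rm = TRUE)
  if (n_ties > 0) {
    message(sprintf("count_significant: %d significant CpG(s) with diff == 0 excluded from directional counts",
                    n_ties))
  }
  list(n_total = n_hyper + n_hypo, n_hyper = n_hyper,
       n_hypo = n_hypo, n_ties = n_ties)
}

#' Write / read per-CpG test results as TSV
#'
#' Columns: chrom, pos, mean_FA, mean_DE, diff, stat, p, fdr.
#'
#' @param results a \code{cpg_test_result}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_cpg_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cpg_results
#' @export
read_cpg_results <- function(path) {
  res <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(res) <- c("cpg_test_result", "data.frame")
  res
}
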