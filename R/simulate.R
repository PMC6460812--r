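#' Parameters for the methylome simulator
#'
#' Bundles and validates everything [simulate_methylome()] needs. Defaults
#' emulate an RRBS two-group design: 4 methylomes per exposure group,
#' CpG-dense fragments (mean spacing 30 bp, minimum gap 2 bp), a shifted
#' Poisson coverage model with mean 15, baseline methylation 0.5 and a
#' modest beta-binomial overdispersion of 0.02 across biological replicates.
#'
#' Regions of differential methylation can be planted either explicitly
#' (\code{planted_dmrs}: data frame \code{chrom, start, end, delta}, where
#' \code{delta} is the DE-minus-FA methylation-proportion difference applied
#' to every CpG in the interval) or automatically (\code{n_planted} blocks of
#' \code{planted_n_cpgs} consecutive CpGs, each given \code{planted_delta}).
#' An optional \code{global_shift} is added to all DE CpGs.
#'
#' @param n_cpgs number of CpGs to simulate.
#' @param n_per_group samples per group (>= 2; default 4).
#' @param baseline_methylation baseline methylation proportion in \[0, 1\].
#' @param dispersion beta-binomial overdispersion phi in \[0, 1); 0 degrades
#'   to a plain binomial. Parameterisation: mean p, shapes
#'   \code{alpha = p (1 - phi) / phi}, \code{beta = (1 - p)(1 - phi) / phi}.
#' @param mean_coverage mean read coverage (>= 1); coverage is drawn as
#'   \code{1 + Poisson(mean_coverage - 1)} so it is always positive.
#' @param planted_dmrs optional data frame \code{chrom, start, end, delta}.
#' @param n_planted,planted_n_cpgs,planted_delta automatic planting: number
#'   of blocks, CpGs per block, and their delta.
#' @param global_shift methylation offset applied to every DE CpG.
#' @param mean_spacing,min_gap CpG spacing model: positions are sorted
#'   uniform integers over \code{n_cpgs * mean_spacing} bp with at least
#'   \code{min_gap} bp between consecutive CpGs.
#' @param chrom chromosome name for all simulated CpGs.
#' @param clamp if \code{TRUE} (default) per-CpG proportions are clamped to
#'   \[0, 1\] after shifts; if \code{FALSE}, out-of-range proportions raise
#'   an error.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{MethylomeSimParams}.
#' @export
methylome_sim_params <- function(n_cpgs,
                                 n_per_group = 4,
                                 baseline_methylation = 0.5,
                                 dispersion = 0.02,
                                 mean_coverage = 15,
                                 planted_dmrs = NULL,
                                 n_planted = 0,
                                 planted_n_cpgs = 10,
                                 planted_delta = -0.3,
                                 global_shift = 0,
                                 mean_spacing = 30,
                                 min_gap = 2,
                                 chrom = "chr1",
                                 clamp = TRUE,
                                 seed = 1) {
  assert_that(n_cpgs >= 1, "n_cpgs must be >= 1")
  assert_that(n_per_group >= 2, "n_per_group must be >= 2")
  assert_that(baseline_methylation >= 0 && baseline_methylation <= 1,
              "baseline_methylation must be in [0, 1]")
  assert_that(dispersion >= 0 && dispersion < 1, "dispersion must be in [0, 1)")
  assert_that(mean_coverage >= 1, "mean_coverage must be >= 1")
  assert_that(mean_spacing >= min_gap && min_gap >= 1,
              "need mean_spacing >= min_gap >= 1")
  assert_that(abs(global_shift) <= 1, "global_shift must be in [-1, 1]")
  if (!is.null(planted_dmrs)) {
    assert_that(all(c("chrom", "start", "end", "delta") %in% names(planted_dmrs)),
                "planted_dmrs needs columns chrom, start, end, delta")
  }
  structure(list(n_cpgs = as.integer(n_cpgs), n_per_group = as.integer(n_per_group),
                 baseline_methylation = baseline_methylation,
                 dispersion = dispersion, mean_coverage = mean_coverage,
                 planted_dmrs = planted_dmrs, n_planted = as.integer(n_planted),
                 planted_n_cpgs = as.integer(planted_n_cpgs),
                 planted_delta = planted_delta, global_shift = global_shift,
                 mean_spacing = mean_spacing, min_gap = as.integer(min_gap),
                 chrom = chrom, clamp = clamp, seed = as.integer(seed)),
            class = "MethylomeSimParams")
}

# beta-binomial draws with mean p and overdispersion phi (vectorised);
# phi = 0 is plain binomial, p = 0/1 are handled exactly.
.rbetabinom <- function(n, size, p, phi) {
  out <- integer(n)
  if (phi == 0) {
    out <- stats::rbinom(n, size, p)
  } else {
    fixed <- p <= 0 | p >= 1
    if (any(!fixed)) {
      a <- p[!fixed] * (1 - phi) / phi
      b <- (1 - p[!fixed]) * (1 - phi) / phi
      pp <- stats::rbeta(sum(!fixed), a, b)
      out[!fixed] <- stats::rbinom(sum(!fixed), size[!fixed], pp)
    }
    out[fixed] <- ifelse(p[fixed] >= 1, size[fixed], 0L)
  }
  as.integer(out)
}

#' Simulate a two-group RRBS methylome with known ground truth
#'
#' Draws CpG positions, per-cell coverages, and beta-binomial methylated
#' counts under the design in \code{params}, optionally planting DMRs and a
#' global DE methylation shift. Deterministic given \code{params$seed}; the
#' caller's RNG state is left untouched.
#'
#' @param params a \code{MethylomeSimParams} from [methylome_sim_params()].
#' @return A list with \code{counts} (a \code{CpgCountMatrix}) and
#'   \code{truth}: a data frame of the planted intervals
#'   (\code{chrom, start, end, delta, n_cpgs}), empty when nothing was
#'   planted.
#' @export
simulate_methylome <- function(params) {
  stopifnot(inherits(params, "MethylomeSimParams"))
  with_seed(params$seed, {
    n <- params$n_cpgs
    L <- max(n * params$mean_spacing, n * params$min_gap + 1)
    slack <- L - (n - 1L) * params$min_gap
    pos <- sort(sample.int(slack, n)) + (seq_len(n) - 1L) * params$min_gap

    # resolve planted intervals
    if (!is.null(params$planted_dmrs)) {
      truth <- params$planted_dmrs
      truth$n_cpgs <- vapply(seq_len(nrow(truth)), function(i) {
        sum(params$chrom == truth$chrom[i] & pos >= truth$start[i] & pos <= truth$end[i])
      }, integer(1))
    } else if (params$n_planted > 0) {
      k <- params$planted_n_cpgs
      assert_that(params$n_planted * (k + 2) <= n,
                  "not enough CpGs to place the requested planted blocks")
      # non-overlapping blocks of k consecutive CpGs, spaced >= 2 CpGs apart
      stride <- floor(n / params$n_planted)
      offs <- sample.int(max(stride - k - 2L, 1L), params$n_planted, replace = TRUE)
      firsts <- (seq_len(params$n_planted) - 1L) * stride + offs
      truth <- data.frame(chrom = params$chrom,
                          start = pos[firsts], end = pos[firsts + k - 1L],
                          delta = params$planted_delta, n_cpgs = k)
    } else {
      truth <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), delta = numeric(0),
                          n_cpgs = integer(0))
    }

    delta_per_cpg <- rep(0, n)
    for (i in seq_len(nrow(truth))) {
      inside <- params$chrom == truth$chrom[i] & pos >= truth$start[i] & pos <= truth$end[i]
      delta_per_cpg[inside] <- delta_per_cpg[inside] + truth$delta[i]
    }

    p_fa <- rep(params$baseline_methylation, n)
    p_de <- params$baseline_methylation + delta_per_cpg + params$global_shift
    if (params$clamp) {
      p_fa <- pmin(pmax(p_fa, 0), 1)
      p_de <- pmin(pmax(p_de, 0), 1)
    } else {
      assert_that(all(p_de >= 0 & p_de <= 1) && all(p_fa >= 0 & p_fa <= 1),
                  "methylation proportions fall outside [0, 1] and clamp = FALSE")
    }

    k <- params$n_per_group
    groups <- rep(c("FA", "DE"), each = k)
    probs <- cbind(matrix(p_fa, n, k), matrix(p_de, n, k))
    cov <- matrix(1L + stats::rpois(n * 2L * k, params$mean_coverage - 1),
                  n, 2L * k)
    meth <- matrix(0L, n, 2L * k)
    for (j in seq_len(2L * k)) {
      meth[, j] <- .rbetabinom(n, cov[, j], probs[, j], params$dispersion)
    }
    counts <- cpg_count_matrix(rep(params$chrom, n), pos, cov, meth,
                               group = groups,
                               samples = paste0(rep(c("FA", "DE"), each = k),
                                                rep(seq_len(k), 2)))
    list(counts = counts, truth = truth)
  })
}

#' Parameters for the extracellular-flux plate simulator
#'
#' Defaults follow the study design: 8 FA and 7 DE biological samples, 3-5
#' replicate wells per sample, 3 rate measurements per injection phase, and
#' DNA-normalised phase means (pmol O2/min/ug DNA) of FA (10, 4, 15, 2) vs
#' DE (8, 4, 11, 2) across the four phases baseline, oligomycin, FCCP,
#' rotenone/antimycin A -- i.e. every respiration metric lower in DE.
#' Pathological phase means (e.g. FCCP below baseline) are deliberately
#' allowed so downstream formulas can be exercised on signed outputs.
#'
#' @param n_fa,n_de samples per group (>= 2 each).
#' @param wells_per_sample integer vector of allowed replicate-well counts;
#'   each sample's count is drawn uniformly from it (default \code{3:5}).
#' @param phase_means list with numeric length-4 elements \code{FA} and
#'   \code{DE}: true normalised OCR level per phase.
#' @param noise_sd Gaussian noise SD on the normalised OCR scale (>= 0).
#' @param ug_dna_range range (length 2, positive) of per-well ug DNA drawn
#'   uniformly; raw well OCR is \code{ug_dna * (phase mean + noise)}.
#' @param measurements_per_phase rate measurements per phase (>= 2).
#' @param seed integer RNG seed.
#' @return A validated list of class \code{OcrSimParams}.
#' @export
ocr_sim_params <- function(n_fa = 8, n_de = 7,
                           wells_per_sample = 3:5,
                           phase_means = list(FA = c(10, 4, 15, 2),
                                              DE = c(8, 4, 11, 2)),
                           noise_sd = 0.5,
                           ug_dna_range = c(0.5, 2),
                           measurements_per_phase = 3,
                           seed = 1) {
  assert_that(n_fa >= 2 && n_de >= 2, "need >= 2 samples per group")
  assert_that(all(wells_per_sample >= 1), "wells_per_sample must be >= 1")
  assert_that(is.list(phase_means) && all(c("FA", "DE") %in% names(phase_means)) &&
                length(phase_means$FA) == 4 && length(phase_means$DE) == 4,
              "phase_means must list 4 values for each of FA and DE")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(length(ug_dna_range) == 2 && all(ug_dna_range > 0) &&
                ug_dna_range[1] <= ug_dna_range[2],
              "ug_dna_range must be a positive interval")
  assert_that(measurements_per_phase >= 2,
              "measurements_per_phase must be >= 2 (phase extrema undefined otherwise)")
  structure(list(n_fa = as.integer(n_fa), n_de = as.integer(n_de),
                 wells_per_sample = as.integer(wells_per_sample),
                 phase_means = phase_means, noise_sd = noise_sd,
                 ug_dna_range = ug_dna_range,
                 measurements_per_phase = as.integer(measurements_per_phase),
                 seed = as.integer(seed)),
            class = "OcrSimParams")
}

.OCR_PHASES <- c("baseline", "oligomycin", "fccp", "rot_ama")

# Flux formulas applied to the four noise-free phase levels
# (baseline, oligomycin, FCCP, rot/AMA), already DNA-normalised.
.flux_from_levels <- function(levels) {
  nmoc <- levels[4]
  basal <- levels[1] - nmoc
  maximal <- levels[3] - nmoc
  atp <- levels[1] - levels[2]
  data.frame(nmoc = nmoc, basal = basal, maximal = maximal,
             atp_production = atp, spare_capacity = maximal - basal,
             coupling_efficiency = if (basal != 0) 100 * atp / basal else NA_real_)
}

#' Simulate a mitochondrial stress-test plate with known truth
#'
#' Each well receives \code{measurements_per_phase} rate measurements in each
#' of the four injection phases; the normalised rate is the group's phase
#' mean plus Gaussian noise, multiplied by the well's ug DNA to give the raw
#' instrument-scale OCR (so [normalize_plate()] exactly recovers the
#' normalised trace). Truth metrics are computed from the noise-free phase
#' means by the flux formulas.
#'
#' @param params an \code{OcrSimParams} from [ocr_sim_params()].
#' @return A list with \code{plate} (long-format data frame: well, sample,
#'   group, measurement_index, phase, ocr, ug_dna) and \code{truth}: one row
#'   of flux metrics per group.
#' @export
simulate_ocr_plate <- function(params) {
  stopifnot(inherits(params, "OcrSimParams"))
  with_seed(params$seed, {
    samples <- data.frame(
      sample = c(paste0("FA", seq_len(params$n_fa)),
                 paste0("DE", seq_len(params$n_de))),
      group = rep(c("FA", "DE"), c(params$n_fa, params$n_de))
    )
    mpp <- params$measurements_per_phase
    rows <- list()
    for (i in seq_len(nrow(samples))) {
      nw <- if (length(params$wells_per_sample) == 1) params$wells_per_sample
            else sample(params$wells_per_sample, 1)
      means <- params$phase_means[[samples$group[i]]]
      for (w in seq_len(nw)) {
        ug <- stats::runif(1, params$ug_dna_range[1], params$ug_dna_range[2])
        norm_trace <- rep(means, each = mpp) +
          stats::rnorm(4 * mpp, 0, params$noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          well = sprintf("%s_w%d", samples$sample[i], w),
          sample = samples$sample[i], group = samples$group[i],
          measurement_index = seq_len(4 * mpp),
          phase = rep(.OCR_PHASES, each = mpp),
          ocr = ug * norm_trace, ug_dna = ug,
          stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, rows)
    class(plate) <- c("OcrPlate", "data.frame")
    truth <- do.call(rbind, lapply(c("FA", "DE"), function(g) {
      cbind(group = g, .flux_from_levels(params$phase_means[[g]]))
    }))
    list(plate = plate, truth = truth)
  })
}

#' Simulate a differential-expression results table
#'
#' Unplanted genes receive a small-noise null log2 fold change and a
#' Uniform(0, 1) FDR; planted rows are inserted verbatim.
#'
#' @param annotation a \code{gene_model} supplying gene ids.
#' @param n_genes number of genes in the table (default: all genes in the
#'   annotation; the first \code{n_genes} are used otherwise). 0 with no
#'   planted rows yields an empty table.
#' @param planted optional data frame \code{gene, log2fc, fdr}; every planted
#'   gene must exist in the annotation.
#' @param null_log2fc_sd SD of the null log2 fold changes (default 0.1).
#' @param seed integer RNG seed.
#' @return A data frame \code{gene, log2fc, fdr}.
#' @export
simulate_de_table <- function(annotation, n_genes = NULL, planted = NULL,
                              null_log2fc_sd = 0.1, seed = 1) {
  stopifnot(inherits(annotation, "gene_model"))
  ids <- annotation$genes$gene_id
  if (is.null(n_genes)) n_genes <- length(ids)
  assert_that(n_genes <= length(ids), "n_genes exceeds genes in annotation")
  ids <- ids[seq_len(n_genes)]
  if (!is.null(planted)) {
    assert_that(all(c("gene", "log2fc", "fdr") %in% names(planted)),
                "planted needs columns gene, log2fc, fdr")
    assert_that(all(planted$gene %in% annotation$genes$gene_id),
                "planted genes must exist in the annotation")
    ids <- union(ids, planted$gene)
  }
  with_seed(seed, {
    de <- data.frame(gene = ids,
                     log2fc = stats::rnorm(length(ids), 0, null_log2fc_sd),
                     fdr = stats::runif(length(ids)),
                     stringsAsFactors = FALSE)
    if (!is.null(planted) && nrow(planted) > 0) {
      ix <- match(planted$gene, de$gene)
      de$log2fc[ix] <- planted$log2fc
      de$fdr[ix] <- planted$fdr
    }
    de
  })
}

#' Simulate a single-transcript gene annotation
#'
#' Genes are placed uniformly (without overlap is not enforced), each with
#' 1-4 exons inside its span and a random strand.
#'
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param gene_length_range range of gene span lengths.
#' @param seed integer RNG seed.
#' @return A \code{gene_model}.
#' @export
simulate_gene_annotation <- function(n_genes = 50, chrom = "chr1",
                                     chrom_length = 2e6,
                                     gene_length_range = c(2000, 20000),
                                     seed = 1) {
  assert_that(n_genes >= 1, "n_genes must be >= 1")
  with_seed(seed, {
    len <- round(stats::runif(n_genes, gene_length_range[1], gene_length_range[2]))
    # genes must fit the chromosome with room to place n_genes start points
    len <- pmin(len, max(floor(chrom_length / 4), 100))
    start <- sort(sample.int(max(chrom_length - max(len), n_genes), n_genes))
    genes <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                        chrom = chrom, start = start, end = start + len - 1,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      ne <- sample(1:4, 1)
      # partition the span into 2*ne alternating exon/intron chunks
      cuts <- sort(sample(seq(genes$start[i], genes$end[i]), 2 * ne - 1))
      bounds <- c(genes$start[i], cuts, genes$end[i])
      data.frame(gene_id = genes$gene_id[i], chrom = chrom,
                 start = bounds[seq(1, 2 * ne, by = 2)],
                 end = bounds[seq(2, 2 * ne + 1, by = 2)],
                 stringsAsFactors = FALSE)
    }))
    gene_model(genes, exons)
  })
}

#' Time-weighted average exposure concentration
#'
#' Converts an exposure-chamber concentration and a weekly schedule into the
#' time-weighted hourly average over a full 168-hour week:
#' \code{concentration * hours_per_day * days_per_week / 168}. Linear in the
#' concentration and in the scheduled hours.
#'
#' @param concentration chamber concentration (ug/m^3).
#' @param hours_per_day exposure hours per day, in \[0, 24\].
#' @param days_per_week exposure days per week, in \[0, 7\].
#' @return The weekly time-weighted average, same units as
#'   \code{concentration}.
#' @examples
#' compute_twa(300, 6, 5) # ~53.6 ug/m^3
#' @export
compute_twa <- function(concentration, hours_per_day, days_per_week) {
  assert_that(all(hours_per_day >= 0 & hours_per_day <= 24),
              "hours_per_day must be in [0, 24]")
  assert_that(all(days_per_week >= 0 & days_per_week <= 7),
              "days_per_week must be in [0, 7]")
  assert_that(all(concentration >= 0), "concentration must be >= 0")
  concentration * hours_per_day * days_per_week / 168
}
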