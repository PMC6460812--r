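#' Read / validate an OCR plate from long-format CSV
#'
#' Expected columns: \code{well, sample, group, measurement_index, phase,
#' ocr, ug_dna}. Phases must be among \code{baseline, oligomycin, fccp,
#' rot_ama} and appear in that order within each well; \code{ug_dna} must be
#' constant and positive per well.
#'
#' @param path CSV path, or a data frame with the same columns.
#' @return A validated data frame of class \code{OcrPlate}.
#' @export
read_ocr_plate <- function(path) {
  plate <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "sample", "group", "measurement_index", "phase", "ocr",
            "ug_dna")
  assert_that(all(need %in% names(plate)),
              paste("plate needs columns:", paste(need, collapse = ", ")))
  assert_that(all(plate$phase %in% .OCR_PHASES),
              paste("phase must be one of:", paste(.OCR_PHASES, collapse = ", ")))
  assert_that(all(plate$group %in% c("FA", "DE")),
              "group must be 'FA' or 'DE'")
  for (w in unique(plate$well)) {
    rows <- plate[plate$well == w, ]
    rows <- rows[order(rows$measurement_index), ]
    ph <- as.integer(factor(rows$phase, levels = .OCR_PHASES))
    assert_that(!is.unsorted(ph),
                sprintf("well %s: phases out of order (baseline -> oligomycin -> fccp -> rot_ama)", w))
    assert_that(all(.OCR_PHASES %in% rows$phase),
                sprintf("well %s: missing a phase", w))
    assert_that(length(unique(rows$ug_dna)) == 1,
                sprintf("well %s: ug_dna must be constant per well", w))
  }
  assert_that(all(plate$ug_dna > 0), "ug_dna must be > 0 for every well")
  class(plate) <- c("OcrPlate", "data.frame")
  plate
}

#' DNA-normalise an OCR plate
#'
#' Divides each well's OCR values by that well's micrograms of DNA; the
#' \code{ug_dna} column is set to 1 afterwards so normalisation is
#' idempotent.
#'
#' @param plate an \code{OcrPlate}.
#' @return The normalised plate.
#' @export
normalize_plate <- function(plate) {
  assert_that(all(plate$ug_dna > 0), "ug_dna must be > 0 for every well")
  plate$ocr <- plate$ocr / plate$ug_dna
  plate$ug_dna <- 1
  plate
}

#' Per-well phase summaries
#'
#' Extracts, for each well, the four quantities the flux formulas use: the
#' last rate measured in the baseline phase (before the oligomycin
#' injection), the minimum rate after oligomycin, the maximum rate after
#' FCCP, and the minimum rate after rotenone/antimycin A.
#'
#' @param plate an \code{OcrPlate} (normalised or raw).
#' @return Data frame: \code{well, sample, group, last_baseline, min_oligo,
#'   max_fccp, min_rot_ama}.
#' @export
well_phase_summary <- function(plate) {
  wells <- unique(plate$well)
  out <- lapply(wells, function(w) {
    rows <- plate[plate$well == w, ]
    rows <- rows[order(rows$measurement_index), ]
    byph <- split(rows$ocr, factor(rows$phase, levels = .OCR_PHASES))
    assert_that(all(lengths(byph) >= 1),
                sprintf("well %s: every phase needs >= 1 measurement", w))
    data.frame(well = w, sample = rows$sample[1], group = rows$group[1],
               last_baseline = byph$baseline[length(byph$baseline)],
               min_oligo = min(byph$oligomycin),
               max_fccp = max(byph$fccp),
               min_rot_ama = min(byph$rot_ama),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mitochondrial stress-test metrics per well
#'
#' Applies the standard formulas to the per-well phase summaries:
#' \itemize{
#'   \item NMOC (non-mitochondrial oxygen consumption) = minimum rate after
#'     rotenone/antimycin A;
#'   \item basal respiration = last rate before oligomycin - NMOC;
#'   \item maximal respiration = maximum rate after FCCP - NMOC;
#'   \item ATP production = last rate before oligomycin - minimum rate after
#'     oligomycin;
#'   \item spare respiratory capacity = maximal - basal;
#'   \item coupling efficiency = 100 * ATP production / basal respiration.
#' }
#' Values are signed and never clamped; a well with basal exactly 0 gets a
#' missing coupling efficiency (logged).
#'
#' @param summary output of [well_phase_summary()].
#' @return Data frame: \code{well, sample, group, nmoc, basal, maximal,
#'   atp_production, spare_capacity, coupling_efficiency}.
#' @export
compute_metrics <- function(summary) {
  nmoc <- summary$min_rot_ama
  basal <- summary$last_baseline - nmoc
  maximal <- summary$max_fccp - nmoc
  atp <- summary$last_baseline - summary$min_oligo
  coupling <- ifelse(basal != 0, 100 * atp / basal, NA_real_)
  if (any(basal == 0)) {
    message(sprintf("compute_metrics: %d well(s) with basal = 0; coupling efficiency set NA",
                    sum(basal == 0)))
  }
  data.frame(well = summary$well, sample = summary$sample,
             group = summary$group, nmoc = nmoc, basal = basal,
             maximal = maximal, atp_production = atp,
             spare_capacity = maximal - basal,
             coupling_efficiency = coupling, stringsAsFactors = FALSE)
}

#' Average replicate wells into per-sample metrics
#'
#' Unweighted mean across a sample's replicate wells for each metric.
#' Coupling efficiency is, by default, recomputed from the sample-averaged
#' ATP production and basal respiration (a ratio of means, which is stabler
#' at small basal rates than averaging per-well ratios); set
#' \code{coupling = "mean_of_ratios"} for the alternative.
#'
#' @param well_metrics output of [compute_metrics()].
#' @param coupling \code{"ratio_of_means"} (default) or
#'   \code{"mean_of_ratios"}.
#' @return Data frame of per-sample metrics (one row per sample), columns as
#'   in [compute_metrics()] minus \code{well}, plus \code{n_wells}.
#' @export
aggregate_sample <- function(well_metrics,
                             coupling = c("ratio_of_means", "mean_of_ratios")) {
  coupling <- match.arg(coupling)
  out <- lapply(split(well_metrics, well_metrics$sample), function(d) {
    ce <- if (coupling == "ratio_of_means") {
      b <- mean(d$basal); a <- mean(d$atp_production)
      if (b != 0) 100 * a / b else NA_real_
    } else {
      mean(d$coupling_efficiency, na.rm = TRUE)
    }
    if (anyNA(d$coupling_efficiency)) {
      message(sprintf("aggregate_sample: sample %s has well(s) with undefined coupling",
                      d$sample[1]))
    }
    data.frame(sample = d$sample[1], group = d$group[1],
               n_wells = nrow(d), nmoc = mean(d$nmoc), basal = mean(d$basal),
               maximal = mean(d$maximal),
               atp_production = mean(d$atp_production),
               spare_capacity = mean(d$spare_capacity),
               coupling_efficiency = ce, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Welch t-test that tolerates zero-variance groups.
.welch <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(c(t = 0, p = 1))
    return(c(t = sign(mean(y) - mean(x)) * Inf, p = 0))
  }
  tt <- stats::t.test(y, x)   # DE vs FA orientation decided by caller
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Compare flux metrics between exposure groups
#'
#' Welch two-sample t-test (two-sided) per metric, DE versus FA; the sign of
#' \code{t} follows \code{mean_DE - mean_FA}.
#'
#' @param sample_metrics output of [aggregate_sample()].
#' @return Data frame: \code{metric, mean_FA, mean_DE, t, p}.
#' @export
group_compare <- function(sample_metrics) {
  fa <- sample_metrics[sample_metrics$group == "FA", ]
  de <- sample_metrics[sample_metrics$group == "DE", ]
  assert_that(nrow(fa) >= 2 && nrow(de) >= 2,
              "need >= 2 samples per group for a t-test")
  metrics <- c("nmoc", "basal", "maximal", "atp_production",
               "spare_capacity", "coupling_efficiency")
  rows <- lapply(metrics, function(m) {
    x <- fa[[m]][!is.na(fa[[m]])]
    y <- de[[m]][!is.na(de[[m]])]
    tp <- if (length(x) >= 2 && length(y) >= 2) .welch(x, y)
          else c(t = NA_real_, p = NA_real_)
    data.frame(metric = m, mean_FA = mean(x), mean_DE = mean(y),
               t = tp[["t"]], p = tp[["p"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full flux pipeline on a plate
#'
#' Normalise, summarise phases, compute per-well metrics, average replicate
#' wells, and compare groups.
#'
#' @param plate an \code{OcrPlate} (raw instrument scale).
#' @inheritParams aggregate_sample
#' @return List with \code{well_metrics}, \code{sample_metrics},
#'   \code{comparison}.
#' @export
flux_pipeline <- function(plate, coupling = c("ratio_of_means", "mean_of_ratios")) {
  plate <- normalize_plate(plate)
  wm <- compute_metrics(well_phase_summary(plate))
  sm <- aggregate_sample(wm, coupling = match.arg(coupling))
  list(well_metrics = wm, sample_metrics = sm, comparison = group_compare(sm))
}

#' Write an OCR plate as CSV
#'
#' @param plate an \code{OcrPlate}.
#' @param path CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_ocr_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
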