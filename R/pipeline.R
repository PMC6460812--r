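#' Pipeline configuration
#'
#' Bundles input paths, output directory and every stage threshold (defaults
#' as documented in the stage functions). Validation checks threshold ranges
#' and that every referenced input path resolves.
#'
#' @param samplesheet samplesheet CSV for the per-sample coverage files.
#' @param gff gene-model GFF3 path.
#' @param de_table DE results TSV (\code{gene, log2fc, fdr}).
#' @param out_dir output directory (created if needed).
#' @param ocr_plate optional OCR plate CSV; the flux stage runs when given.
#' @param min_cov,min_frac_samples coverage filter (see [filter_cpgs()]).
#' @param fdr_dml FDR threshold for counting differentially methylated CpGs.
#' @param p_max,min_abs_diff,join_gap,min_len,min_cpgs,min_frac_sig,merge_dist
#'   DMR-calling thresholds (see [call_dmrs()]).
#' @param promoter_upstream promoter window (see [annotate_location()]).
#' @param de_min_change,de_max_fdr DE thresholds (see
#'   [de_threshold_filter()]).
#' @param window DMR-gene linkage window in bp.
#' @param seed integer seed echoed into the run report.
#' @return A validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(samplesheet, gff, de_table, out_dir,
                            ocr_plate = NULL,
                            min_cov = 5, min_frac_samples = 0.5,
                            fdr_dml = 0.1,
                            p_max = 0.001, min_abs_diff = 0.10,
                            join_gap = 100, min_len = 50, min_cpgs = 3,
                            min_frac_sig = 0.5, merge_dist = 100,
                            promoter_upstream = 3000,
                            de_min_change = 0.25, de_max_fdr = 0.05,
                            window = 1e6, seed = 1) {
  cfg <- list(samplesheet = samplesheet, gff = gff, de_table = de_table,
              out_dir = out_dir, ocr_plate = ocr_plate,
              min_cov = min_cov, min_frac_samples = min_frac_samples,
              fdr_dml = fdr_dml, p_max = p_max, min_abs_diff = min_abs_diff,
              join_gap = join_gap, min_len = min_len, min_cpgs = min_cpgs,
              min_frac_sig = min_frac_sig, merge_dist = merge_dist,
              promoter_upstream = promoter_upstream,
              de_min_change = de_min_change, de_max_fdr = de_max_fdr,
              window = window, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg a \code{PipelineConfig}.
#' @export
validate_pipeline_config <- function(cfg) {
  chk <- function(cond, what) assert_that(cond, paste("config:", what))
  chk(cfg$min_cov >= 0, "min_cov must be >= 0")
  chk(cfg$min_frac_samples >= 0 && cfg$min_frac_samples <= 1,
      "min_frac_samples must be in [0, 1]")
  chk(cfg$fdr_dml > 0 && cfg$fdr_dml <= 1, "fdr_dml must be in (0, 1]")
  chk(cfg$p_max > 0 && cfg$p_max <= 1, "p_max must be in (0, 1]")
  chk(cfg$min_abs_diff >= 0 && cfg$min_abs_diff <= 1,
      "min_abs_diff must be in [0, 1]")
  chk(cfg$join_gap >= 0, "join_gap must be >= 0")
  chk(cfg$min_len >= 1, "min_len must be >= 1")
  chk(cfg$min_cpgs >= 1, "min_cpgs must be >= 1")
  chk(cfg$min_frac_sig > 0 && cfg$min_frac_sig <= 1,
      "min_frac_sig must be in (0, 1]")
  chk(cfg$merge_dist >= 0, "merge_dist must be >= 0")
  chk(cfg$promoter_upstream >= 0, "promoter_upstream must be >= 0")
  chk(cfg$de_min_change >= 0, "de_min_change must be >= 0")
  chk(cfg$de_max_fdr > 0 && cfg$de_max_fdr <= 1,
      "de_max_fdr must be in (0, 1]")
  chk(cfg$window >= 0, "window must be >= 0")
  for (p in c(cfg$samplesheet, cfg$gff, cfg$de_table, cfg$ocr_plate)) {
    chk(file.exists(p), paste("input path not found:", p))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds the same keys as [pipeline_config()] arguments.
#'
#' @param path YAML file path.
#' @return A validated \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes: read and coverage-filter the counts, per-CpG tests, DMR calling
#' and annotation, global methylation summary with the directional-skew
#' test, DMR-to-expression linkage, and (when a plate is configured) the
#' flux stage. All stage outputs are written under \code{cfg$out_dir}
#' together with a JSON run report (input digests, thresholds, stage counts,
#' skew-test p-value) and a YAML echo of the configuration. Identical
#' configuration and inputs produce identical outputs. Any stage failure
#' removes the partial outputs and aborts with the stage name.
#'
#' @param cfg a \code{PipelineConfig}.
#' @return The run report, invisibly (a list; also written as
#'   \code{report.json}).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(p) { written <<- c(written, p); p }
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    set.seed(cfg$seed)
    inputs <- c(cfg$samplesheet, cfg$gff, cfg$de_table, cfg$ocr_plate)
    report <- list(
      package = "dmrflux",
      version = as.character(utils::packageVersion("dmrflux")),
      seed = cfg$seed,
      config = unclass(cfg),
      input_md5 = as.list(tools::md5sum(inputs))
    )

    stage <- "dml"
    counts <- read_bismark_cov(cfg$samplesheet)
    n_raw <- nrow(counts$cov)
    filtered <- filter_cpgs(counts, cfg$min_cov, cfg$min_frac_samples)
    results <- per_cpg_test(filtered)
    write_cpg_results(results, note(file.path(cfg$out_dir, "dml.tsv")))
    sig <- count_significant(results, cfg$fdr_dml)

    stage <- "calldmr"
    annotation <- read_gff3(cfg$gff)
    dmrs <- call_dmrs(results, p_max = cfg$p_max,
                      min_abs_diff = cfg$min_abs_diff,
                      join_gap = cfg$join_gap, min_len = cfg$min_len,
                      min_cpgs = cfg$min_cpgs,
                      min_frac_sig = cfg$min_frac_sig,
                      merge_dist = cfg$merge_dist)
    dmrs <- annotate_location(dmrs, annotation,
                              promoter_upstream = cfg$promoter_upstream)
    write_dmrs_bed(dmrs, note(file.path(cfg$out_dir, "dmrs.bed")))

    stage <- "summary"
    hist <- methylation_histogram(filtered)
    write_histogram(hist, note(file.path(cfg$out_dir, "histogram.tsv")))
    comp <- location_composition(dmrs)
    write_composition(comp, note(file.path(cfg$out_dir, "composition.tsv")))
    skew <- if (sig$n_total >= 1) {
      direction_skew_test(sig$n_hyper, sig$n_total)
    } else NA_real_

    stage <- "integrate"
    de <- read_de_table(cfg$de_table)
    de_sig <- de_threshold_filter(de, cfg$de_min_change, cfg$de_max_fdr)
    linked <- link_dmrs_to_genes(dmrs, de_sig, annotation,
                                 window = cfg$window)
    utils::write.table(linked,
                       note(file.path(cfg$out_dir, "linked_genes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    flux_counts <- NULL
    if (!is.null(cfg$ocr_plate)) {
      stage <- "flux"
      plate <- read_ocr_plate(cfg$ocr_plate)
      flux <- flux_pipeline(plate)
      utils::write.table(flux$sample_metrics,
                         note(file.path(cfg$out_dir, "flux_samples.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(flux$comparison,
                         note(file.path(cfg$out_dir, "flux_comparison.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      flux_counts <- list(n_samples = nrow(flux$sample_metrics),
                          n_wells = nrow(flux$well_metrics))
    }

    stage <- "report"
    report$counts <- list(
      cpgs_raw = n_raw,
      cpgs_retained = nrow(filtered$cov),
      dml_total = sig$n_total, dml_hyper = sig$n_hyper,
      dml_hypo = sig$n_hypo, dml_ties = sig$n_ties,
      dmrs = nrow(dmrs),
      dmr_hypo = sum(dmrs$direction == "hypo"),
      dmr_hyper = sum(dmrs$direction == "hyper"),
      de_significant = nrow(de_sig),
      linked_pairs = nrow(linked),
      linked_genes = length(unique(linked$gene))
    )
    report$skew_p <- as.numeric(skew)
    report$skew_log10_p <- if (!is.na(skew)) attr(skew, "log10_p") else NA_real_
    report$location_composition <- as.list(comp)
    report$flux <- flux_counts
    jsonlite::write_json(report, note(file.path(cfg$out_dir, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    yaml::write_yaml(unclass(cfg), note(file.path(cfg$out_dir, "config_echo.yaml")))
    invisible(report)
  }, error = on_fail)
}
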