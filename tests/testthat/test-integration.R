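test_that("DE thresholds are inclusive at both boundaries", {
  de <- data.frame(
    gene = c("exact", "weak", "acot1", "highfdr", "strongup"),
    log2fc = c(log2(1.25), 0.20, -2.25, 1.5, 0.9),
    fdr = c(0.05, 0.001, 2.30e-50, 0.051, 0.01))
  sig <- de_threshold_filter(de)
  expect_true("exact" %in% sig$gene)     # both boundaries exactly met
  expect_false("weak" %in% sig$gene)     # 0.20 < log2(1.25) ~ 0.3219
  expect_true("acot1" %in% sig$gene)     # strong down-regulation retained
  expect_false("highfdr" %in% sig$gene)
  expect_true("strongup" %in% sig$gene)

  # loosening either threshold never removes a gene
  for (mc in c(0.1, 0.25, 0.5)) for (mf in c(0.01, 0.05, 0.2)) {
    a <- de_threshold_filter(de, mc, mf)$gene
    b <- de_threshold_filter(de, mc / 2, mf)$gene
    c2 <- de_threshold_filter(de, mc, min(2 * mf, 1))$gene
    expect_true(all(a %in% b) && all(a %in% c2))
  }
})

test_that("ddct computes 2^-ddCT with reference normalisation", {
  mk_ct <- function(target_fa, target_de, ref = 15) {
    rbind(
      data.frame(sample = paste0("F", seq_along(target_fa)), group = "FA",
                 gene = "tgt", ct = target_fa),
      data.frame(sample = paste0("D", seq_along(target_de)), group = "DE",
                 gene = "tgt", ct = target_de),
      data.frame(sample = c(paste0("F", seq_along(target_fa)),
                            paste0("D", seq_along(target_de))),
                 group = rep(c("FA", "DE"), c(length(target_fa), length(target_de))),
                 gene = "18S", ct = ref))
  }
  # identical dCT in both groups: ddCT 0, fold change 1
  r0 <- ddct(mk_ct(c(20, 20), c(20, 20)))
  expect_equal(r0$ddct, 0)
  expect_equal(r0$fold_change, 1)
  # one-cycle increase in DE dCT halves expression
  r1 <- ddct(mk_ct(c(20, 20), c(21, 21)))
  expect_equal(r1$ddct, 1)
  expect_equal(r1$fold_change, 0.5)
  # ddCT -2 quadruples expression
  r2 <- ddct(mk_ct(c(20, 20), c(18, 18)))
  expect_equal(r2$fold_change, 4)
  # shifting every CT (target and reference alike) changes nothing
  ct <- mk_ct(c(20.4, 21.0, 20.1), c(22.2, 21.8, 22.5))
  shifted <- ct; shifted$ct <- shifted$ct + 3.7
  expect_equal(ddct(ct)$fold_change, ddct(shifted)$fold_change)
  expect_equal(ddct(ct)$p, ddct(shifted)$p)
  # missing reference CT is an error
  expect_error(ddct(ct[ct$gene != "18S", ]), "reference")
})

test_that("DMR-gene links respect window, chromosome and inverse-sign rules", {
  genes <- data.frame(
    gene_id = c("near_up", "near_dn", "far_up", "otherchr"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(600000L, 700000L, 2000000L, 600000L),
    end = c(610000L, 710000L, 2010000L, 610000L),
    strand = "+")
  exons <- genes[c("gene_id", "chrom", "start", "end")]
  model <- gene_model(genes, exons)
  # hypomethylated DMR at 100000-100500
  dmrs <- data.frame(chrom = "chr1", start = 100000L, end = 100500L,
                     n_cpgs = 5L, n_sig = 4L, area_stat = -12,
                     mean_diff = -0.25, direction = "hypo")
  de_sig <- data.frame(gene = c("near_up", "near_dn", "far_up", "otherchr"),
                       log2fc = c(1.2, -1.2, 1.2, 1.2),
                       fdr = rep(1e-4, 4))
  linked <- link_dmrs_to_genes(dmrs, de_sig, model)
  expect_equal(linked$gene, "near_up")      # ~0.5 Mb, inverse sign
  expect_equal(linked$distance, 600000 - 100500 - 1)

  # without the inverse-sign requirement the near downregulated gene joins
  all_near <- link_dmrs_to_genes(dmrs, de_sig, model, require_inverse = FALSE)
  expect_setequal(all_near$gene, c("near_up", "near_dn"))
  expect_gte(nrow(all_near), nrow(linked))

  # the boundary at exactly 1 Mb is inclusive
  gap <- 600000 - 100500 - 1
  at_edge <- link_dmrs_to_genes(dmrs, de_sig, model, window = gap)
  expect_equal(at_edge$gene, "near_up")
  beyond <- link_dmrs_to_genes(dmrs, de_sig, model, window = gap - 1)
  expect_equal(nrow(beyond), 0L)

  # unknown DE genes are skipped with a warning
  de_bad <- rbind(de_sig, data.frame(gene = "ghost", log2fc = 2, fdr = 1e-5))
  expect_warning(link_dmrs_to_genes(dmrs, de_bad, model), "absent")
})

test_that("planted links are fully recovered with zero false links", {
  # deterministic construction: genes at known offsets around planted DMRs
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:6),
    chrom = "chr1",
    start = c(200000L, 1500000L, 3200000L, 4800000L, 6100000L, 8000000L),
    end = c(210000L, 1510000L, 3210000L, 4810000L, 6110000L, 8010000L),
    strand = "+")
  model <- gene_model(genes, genes[c("gene_id", "chrom", "start", "end")])
  dmrs <- data.frame(chrom = "chr1",
                     start = c(150000L, 3150000L, 6050000L),
                     end = c(150400L, 3150400L, 6050400L),
                     n_cpgs = 4L, n_sig = 3L,
                     area_stat = c(-10, -8, 9),
                     mean_diff = c(-0.2, -0.3, 0.25),
                     direction = c("hypo", "hypo", "hyper"))
  de_sig <- data.frame(gene = c("g01", "g03", "g05", "g02", "g06"),
                       log2fc = c(1.5, 2.0, -1.1, 1.5, 1.5),
                       fdr = 1e-6)
  # expected: g01 (inverse, 49.6 kb), g03 (inverse, near), g05 (hyper DMR,
  # down gene); g02 is 1.35 Mb from the nearest DMR, g06 ~2 Mb: excluded
  linked <- link_dmrs_to_genes(dmrs, de_sig, model)
  expect_setequal(linked$gene, c("g01", "g03", "g05"))
  expect_equal(nrow(linked), 3L)
})

test_that("DE table TSV round-trips", {
  de <- data.frame(gene = c("a", "b"), log2fc = c(0.5, -2.25),
                   fdr = c(0.2, 2.3e-50))
  path <- tempfile(fileext = ".tsv")
  write_de_table(de, path)
  expect_equal(read_de_table(path), de)
  unlink(path)
})
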