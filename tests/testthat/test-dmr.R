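test_that("significance flags respect both boundaries", {
  res <- data.frame(p = c(0.0009, 0.001, 1e-8, NA),
                    diff = c(0.10, 0.5, 0.09, 0.5))
  expect_equal(flag_significant(res), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("candidate chains follow the gap rule and absorb unflagged CpGs", {
  res <- data.frame(chrom = "chr1", pos = c(100L, 150L, 400L),
                    diff = 0.2, stat = 1, p = 0.0001)
  cand <- seed_regions(res, c(TRUE, TRUE, TRUE), join_gap = 100)
  expect_equal(cand$start, c(100L, 400L))
  expect_equal(cand$end, c(150L, 400L))

  expect_equal(nrow(seed_regions(res, rep(FALSE, 3))), 0L)

  # unflagged CpG inside a chain is absorbed
  res2 <- data.frame(chrom = "chr1", pos = c(100L, 130L, 160L, 220L),
                     diff = 0.2, stat = 1, p = 0.0001)
  flags2 <- c(TRUE, FALSE, TRUE, TRUE)
  cand2 <- seed_regions(res2, flags2, join_gap = 100)
  expect_equal(nrow(cand2), 1L)
  expect_equal(c(cand2$start, cand2$end), c(100L, 220L))
  d <- apply_dmr_criteria(cand2, res2, flags2)
  expect_equal(d$n_cpgs, 4L)
  expect_equal(d$n_sig, 3L)
})

test_that("qualification criteria reject short, sparse or weakly flagged regions", {
  mk <- function(pos, flags, stat = -3) {
    res <- data.frame(chrom = "chr1", pos = pos, diff = sign(stat) * 0.2,
                      stat = stat, p = ifelse(flags, 1e-4, 0.5))
    apply_dmr_criteria(seed_regions(res, flags), res, flags)
  }
  # 60 bp span, 3 flagged CpGs, known AreaStat
  res <- data.frame(chrom = "chr1", pos = c(100L, 130L, 160L),
                    diff = -0.2, stat = c(-3.1, -2.8, -4.0), p = 1e-4)
  flags <- rep(TRUE, 3)
  d <- apply_dmr_criteria(seed_regions(res, flags), res, flags)
  expect_equal(d$area_stat, -9.9)
  expect_equal(d$direction, "hypo")
  expect_equal(d$mean_diff, -0.2)
  # too short (span 40 bp)
  expect_equal(nrow(mk(c(100L, 120L, 140L), rep(TRUE, 3))), 0L)
  # too few CpGs
  expect_equal(nrow(mk(c(100L, 180L), rep(TRUE, 2))), 0L)
  # candidate spanning 7 CpGs with 3 flagged: 3/7 < 50%
  pos7 <- seq(100L, 100L + 6L * 15L, by = 15L)
  expect_equal(nrow(mk(pos7, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))), 0L)
})

test_that("merging joins regions within 100 bp, transitively and idempotently", {
  # two qualifying chains separated by a 79 bp gap merge into one region
  res <- data.frame(chrom = "chr1",
                    pos = c(100L, 130L, 160L, 240L, 270L, 300L),
                    diff = -0.2, stat = -2, p = 1e-4)
  flags <- rep(TRUE, 6)
  cand <- seed_regions(res, flags, join_gap = 70)
  dmrs <- apply_dmr_criteria(cand, res, flags)
  expect_equal(nrow(dmrs), 2L)
  merged <- merge_dmrs(dmrs, res, flags, merge_dist = 100)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 300L))
  expect_equal(merged$area_stat, -12)
  expect_identical(merge_dmrs(merged, res, flags), merged)

  # gap of 101 bp stays apart
  res2 <- res; res2$pos <- c(100L, 130L, 160L, 262L, 292L, 322L)
  dmrs2 <- apply_dmr_criteria(seed_regions(res2, flags, join_gap = 70),
                              res2, flags)
  expect_equal(nrow(merge_dmrs(dmrs2, res2, flags, merge_dist = 100)), 2L)

  # three regions pairwise within 100 bp collapse and AreaStat sums all CpGs
  res3 <- data.frame(chrom = "chr1",
                     pos = c(100L, 130L, 160L, 240L, 270L, 300L, 380L, 410L, 440L),
                     diff = 0.3, stat = 2, p = 1e-4)
  flags3 <- rep(TRUE, 9)
  dmrs3 <- apply_dmr_criteria(seed_regions(res3, flags3, join_gap = 70),
                              res3, flags3)
  expect_equal(nrow(dmrs3), 3L)
  m3 <- merge_dmrs(dmrs3, res3, flags3)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$area_stat, sum(res3$stat))
  expect_equal(m3$direction, "hyper")
})

test_that("call_dmrs equals the exhaustive oracle on randomized fixtures", {
  n_fix <- 250
  for (seed in seq_len(n_fix)) {
    fx <- random_results(n = sample(5:30, 1), seed = seed,
                         flag_prob = runif(1, 0.2, 0.8))
    got <- call_dmrs(transform(fx$results, p = ifelse(fx$flags, 1e-5, 0.5),
                               diff = ifelse(fx$flags, pmax(abs(fx$results$diff), 0.1),
                                             fx$results$diff) * sign(fx$results$stat)))
    # recompute flags exactly as call_dmrs saw them
    res <- transform(fx$results, p = ifelse(fx$flags, 1e-5, 0.5),
                     diff = ifelse(fx$flags, pmax(abs(fx$results$diff), 0.1),
                                   fx$results$diff) * sign(fx$results$stat))
    flags <- flag_significant(res)
    want <- dmr_oracle(res, flags)
    cols <- c("chrom", "start", "end", "n_cpgs", "n_sig", "area_stat",
              "mean_diff", "direction")
    expect_equal(got[cols], want[cols], info = paste("fixture", seed))
  }
})

test_that("every called DMR satisfies the region invariants", {
  sim <- simulate_methylome(methylome_sim_params(
    n_cpgs = 8000, mean_coverage = 30, n_planted = 6, seed = 31))
  res <- per_cpg_test(filter_cpgs(sim$counts))
  dmrs <- call_dmrs(res)
  expect_gt(nrow(dmrs), 0)
  expect_true(all(dmrs$end - dmrs$start + 1 >= 50))
  expect_true(all(dmrs$n_cpgs >= 3))
  expect_true(all(dmrs$n_sig / dmrs$n_cpgs >= 0.5))
  expect_true(all(ifelse(dmrs$area_stat < 0, "hypo", "hyper") == dmrs$direction))
  expect_true(!is.unsorted(dmrs$start))
  if (nrow(dmrs) > 1) {
    expect_true(all(dmrs$start[-1] > dmrs$end[-nrow(dmrs)]))
  }
})

test_that("genomic-context labels follow promoter > exon > intron > intergenic", {
  model <- tiny_model()
  mk_dmr <- function(start, end) {
    data.frame(chrom = "chr1", start = start, end = end, n_cpgs = 3L,
               n_sig = 3L, area_stat = -5, mean_diff = -0.2,
               direction = "hypo")
  }
  # midpoint 500 bp upstream of geneA's + strand TSS (10000)
  d <- annotate_location(mk_dmr(9400L, 9600L), model)
  expect_equal(d$location, "promoter")
  expect_equal(d$gene, "geneA")
  # midpoint inside geneA's first exon
  expect_equal(annotate_location(mk_dmr(11000L, 11100L), model)$location, "exon")
  # midpoint between geneA's exons
  expect_equal(annotate_location(mk_dmr(15000L, 15100L), model)$location, "intron")
  # far from anything
  d4 <- annotate_location(mk_dmr(200000L, 200100L), model)
  expect_equal(d4$location, "intergenic")
  expect_equal(d4$gene, "geneB")   # nearest gene recorded
  # - strand promoter sits downstream in genome coordinates (TSS = end)
  expect_equal(annotate_location(mk_dmr(60500L, 60600L), model)$location,
               "promoter")
  # empty input passes through
  expect_equal(nrow(annotate_location(mk_dmr(1L, 1L)[0, ], model)), 0L)
})

test_that("DMR BED output round-trips with 0-based half-open conversion", {
  model <- tiny_model()
  dmrs <- data.frame(chrom = "chr1", start = c(9400L, 11000L),
                     end = c(9600L, 11100L), n_cpgs = c(4L, 3L),
                     n_sig = c(3L, 3L), area_stat = c(-8.2, 6.1),
                     mean_diff = c(-0.25, 0.2),
                     direction = c("hypo", "hyper"))
  dmrs <- annotate_location(dmrs, model)
  path <- tempfile(fileext = ".bed")
  write_dmrs_bed(dmrs, path)
  raw <- read.table(path, sep = "\t")
  expect_equal(raw$V2, dmrs$start - 1)   # BED start is 0-based
  expect_equal(raw$V3, dmrs$end)
  back <- read_dmrs_bed(path)
  expect_equal(back$start, dmrs$start)
  expect_equal(back$area_stat, dmrs$area_stat)
  expect_equal(back$location, dmrs$location)
  unlink(path)
})
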