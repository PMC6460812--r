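# A hand-built two-well plate: known trace per phase.
toy_plate <- function(traces = list(w1 = c(10, 9.5, 9, 4.2, 3.8, 4.0,
                                           15, 14, 14.5, 2, 1.8, 2.1)),
                      ug = 1, sample = "FA1", group = "FA") {
  rows <- lapply(names(traces), function(w) {
    data.frame(well = w, sample = sample, group = group,
               measurement_index = 1:12,
               phase = rep(c("baseline", "oligomycin", "fccp", "rot_ama"),
                           each = 3),
               ocr = traces[[w]], ug_dna = ug)
  })
  read_ocr_plate(do.call(rbind, rows))
}

test_that("normalisation divides by per-well DNA and is idempotent", {
  p <- toy_plate(ug = 2)
  n <- normalize_plate(p)
  expect_equal(n$ocr, p$ocr / 2)
  expect_equal(normalize_plate(n)$ocr, n$ocr)
  p1 <- toy_plate(ug = 1)
  expect_equal(normalize_plate(p1)$ocr, p1$ocr)
  bad <- toy_plate(); bad$ug_dna <- 0
  expect_error(normalize_plate(bad), "ug_dna")
})

test_that("phase summaries take the documented extrema", {
  ws <- well_phase_summary(toy_plate())
  expect_equal(ws$last_baseline, 9)    # last rate before oligomycin
  expect_equal(ws$min_oligo, 3.8)
  expect_equal(ws$max_fccp, 15)        # max rate after FCCP
  expect_equal(ws$min_rot_ama, 1.8)    # min rate after rot/AMA
})

test_that("metric formulas match hand evaluation and stay signed", {
  m <- compute_metrics(well_phase_summary(toy_plate()))
  expect_equal(m$nmoc, 1.8)
  expect_equal(m$basal, 7.2)
  expect_equal(m$maximal, 13.2)
  expect_equal(m$atp_production, 5.2)
  expect_equal(m$spare_capacity, 6.0)
  expect_equal(m$coupling_efficiency, 100 * 5.2 / 7.2)

  # flat trace: every derived rate is 0 and coupling undefined
  flat <- toy_plate(traces = list(w1 = rep(4, 12)))
  expect_message(mf <- compute_metrics(well_phase_summary(flat)), "basal = 0")
  expect_equal(mf$basal, 0)
  expect_equal(mf$maximal, 0)
  expect_equal(mf$atp_production, 0)
  expect_equal(mf$spare_capacity, 0)
  expect_true(is.na(mf$coupling_efficiency))

  # FCCP maximum below baseline: spare capacity is negative, unclamped
  low <- toy_plate(traces = list(w1 = c(10, 10, 10, 4, 4, 4, 8, 8, 8, 2, 2, 2)))
  ml <- compute_metrics(well_phase_summary(low))
  expect_lt(ml$spare_capacity, 0)
})

test_that("identities and the scale contract hold on every output row", {
  sim <- simulate_ocr_plate(ocr_sim_params(seed = 44))
  wm <- compute_metrics(well_phase_summary(normalize_plate(sim$plate)))
  expect_equal(wm$spare_capacity, wm$maximal - wm$basal)
  ok <- !is.na(wm$coupling_efficiency)
  expect_equal(wm$coupling_efficiency[ok],
               100 * wm$atp_production[ok] / wm$basal[ok])

  # scaling one well's OCR by c scales the rate metrics and fixes coupling
  p <- toy_plate()
  m1 <- compute_metrics(well_phase_summary(p))
  p$ocr <- p$ocr * 3
  m3 <- compute_metrics(well_phase_summary(p))
  for (col in c("nmoc", "basal", "maximal", "atp_production", "spare_capacity")) {
    expect_equal(m3[[col]], 3 * m1[[col]])
  }
  expect_equal(m3$coupling_efficiency, m1$coupling_efficiency)
})

test_that("replicate wells average into per-sample metrics", {
  tr <- c(10, 10, 9, 4, 4, 4, 15, 15, 15, 2, 2, 2)
  p <- toy_plate(traces = list(w1 = tr, w2 = tr))
  wm <- compute_metrics(well_phase_summary(p))
  sm <- aggregate_sample(wm)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$basal, wm$basal[1])   # identical wells = any single well
  expect_equal(sm$n_wells, 2L)

  wm2 <- wm
  wm2$basal <- c(6, 8)
  expect_equal(aggregate_sample(wm2)$basal, 7)
  # coupling from averaged atp and basal (ratio of means)
  wm3 <- wm
  wm3$basal <- c(4, 8); wm3$atp_production <- c(2, 6)
  expect_equal(aggregate_sample(wm3)$coupling_efficiency, 100 * 4 / 6)
  # mean_of_ratios averages the per-well coupling column instead
  expect_equal(aggregate_sample(wm3, coupling = "mean_of_ratios")$coupling_efficiency,
               mean(wm3$coupling_efficiency))
})

test_that("group comparison handles identical groups and rejects n = 1", {
  sm <- data.frame(sample = c("a", "b", "c", "d"),
                   group = c("FA", "FA", "DE", "DE"),
                   nmoc = 1, basal = 5, maximal = 9, atp_production = 3,
                   spare_capacity = 4, coupling_efficiency = 60)
  cmp <- group_compare(sm)
  expect_equal(cmp$t, rep(0, 6))
  expect_equal(cmp$p, rep(1, 6))
  expect_error(group_compare(sm[c(1, 3, 4), ]), "2 samples per group")
})

test_that("a planted group difference is detected at moderate noise", {
  sim <- simulate_ocr_plate(ocr_sim_params(noise_sd = 0.4, seed = 77))
  out <- flux_pipeline(sim$plate)
  cmp <- out$comparison
  basal <- cmp[cmp$metric == "basal", ]
  expect_lt(basal$p, 0.05)
  expect_lt(basal$mean_DE, basal$mean_FA)  # planted direction
  maximal <- cmp[cmp$metric == "maximal", ]
  expect_lt(maximal$p, 0.05)
})

test_that("plate CSV round-trips and phase-order violations are caught", {
  sim <- simulate_ocr_plate(ocr_sim_params(seed = 2))
  path <- tempfile(fileext = ".csv")
  write_ocr_plate(sim$plate, path)
  back <- read_ocr_plate(path)
  expect_equal(back$ocr, sim$plate$ocr, tolerance = 1e-12)
  unlink(path)

  bad <- toy_plate()
  bad$phase[1:3] <- "fccp"; bad$phase[7:9] <- "baseline"
  expect_error(read_ocr_plate(bad), "out of order|missing")
})
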