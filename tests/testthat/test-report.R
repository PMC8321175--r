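test_that("randomized-run summaries use empirical quantiles", {
  s <- summarizeRandomized(rep(4.2, 10))
  expect_equal(s$min, 4.2); expect_equal(s$max, 4.2)
  expect_equal(s$mean, 4.2); expect_equal(s$median, 4.2)
  expect_equal(s$ciHigh - s$ciLow, 0)

  s2 <- summarizeRandomized(as.numeric(1:500), ciLevel = 0.99)
  expect_equal(s2$median, 250.5)
  # order-statistic interpolation: 1 + 0.005 * 499 and 1 + 0.995 * 499
  expect_equal(s2$ciLow, 3.495)
  expect_equal(s2$ciHigh, 497.505)

  s0 <- summarizeRandomized(as.numeric(1:500), ciLevel = 0)
  expect_equal(s0$ciLow, s0$median)
  expect_equal(s0$ciHigh, s0$median)

  expect_error(summarizeRandomized(1), "at least 2")
})

test_that("verdicts apply each limit with its comparison direction", {
  metrics <- list(
    psg = list(A7 = 0.74),
    piu = list(A7 = 96.7),
    snr = list(single_LR = 130),
    ratios = list(single_7_over_6 = 1.25),
    snru = list(single_7 = 4),
    snruRatios = list(single_7_over_6 = 1.0))

  acr <- evaluateMetrics(metrics, protocolLimits("acr"), 1.5)
  expect_true(acr$pass[acr$metric == "PSG"])
  expect_true(acr$pass[acr$metric == "PIU"])
  expect_true(acr$pass[acr$metric == "SNR"])     # 130 >= 80 * 1.5
  expect_false(acr$pass[acr$metric == "SNR ratio"])

  greek <- evaluateMetrics(metrics, protocolLimits("greek"), 1.5)
  expect_true(greek$pass[greek$metric == "PSG"])  # 0.74 <= 1

  # SNR limit scales with field strength: 130 < 80 * 3
  at3T <- evaluateMetrics(metrics, protocolLimits("acr"), 3)
  expect_false(at3T$pass[at3T$metric == "SNR"])

  expect_error(evaluateMetrics(list(psg = list(A7 = 1)),
                               protocolLimits("acr"), 1.5), "must include")
})

test_that("flipping one metric across its limit flips exactly that verdict", {
  base <- list(psg = list(A7 = 0.5), piu = list(A7 = 95),
               snr = list(single_LR = 130),
               ratios = list(r1 = 1.0), snru = list(s7 = 4),
               snruRatios = list(q1 = 1.0))
  limits <- protocolLimits("acr")
  v0 <- evaluateMetrics(base, limits, 1.5)
  expect_true(all(v0$pass))

  flips <- list(
    list(psg = list(A7 = 3.0)),        # above 2.5
    list(piu = list(A7 = 80)),         # below 87.5
    list(snr = list(single_LR = 100)), # below 120
    list(ratios = list(r1 = 1.2)),
    list(snru = list(s7 = 12)),
    list(snruRatios = list(q1 = 0.8)))
  for (k in seq_along(flips)) {
    m <- utils::modifyList(base, flips[[k]])
    v <- evaluateMetrics(m, limits, 1.5)
    expect_equal(sum(!v$pass), 1)
    expect_false(v$pass[k])
  }
})

test_that("runQc on a well-behaved pair passes all checks, PSG ~ 0, PIU ~ 100", {
  # mild non-uniformity as on real scanners: with a perfectly flat phantom
  # the SNRU values of both slices are pure noise and their ratio is
  # ill-conditioned; any realistic deterministic spatial pattern stabilizes it
  spec <- noisyScene(noiseSd = 5, seed = 41L, nonuniformityAmplitude = 0.04)
  pair <- pairSeries(renderSeries(spec, 2),
                     renderSeries(spec, 1, sliceIndices = 7L,
                                  seriesLabel = "B", acquisitionTime = 120))
  rep <- runQc(pair, list(nRuns = 100L, seed = 1L))
  expect_true(reportPasses(rep))
  m <- reportMetrics(rep)
  expect_lt(m$psg$A7, 0.1)
  expect_gt(m$piu$A7, 97)
  expect_true(all(c("diff_AB_num7A", "diff_AB_num7B", "diff_AB_avg",
                    "diff_76_num7", "single_LR", "single_UD") %in%
                  names(m$snr)))
  expect_length(reportNotes(rep), 0)
})

test_that("missing series B is reported as not computed", {
  series <- renderSeries(noisyScene(noiseSd = 5, seed = 43L), 2)
  rep <- runQc(series, list(nRuns = 20L))
  expect_match(reportNotes(rep), "series B absent", all = FALSE)
  expect_false(any(grepl("^diff_AB", names(reportMetrics(rep)$snr))))
  expect_true(all(c("diff_76_num7", "single_LR") %in%
                  names(reportMetrics(rep)$snr)))
})

test_that("reports are byte-identical for a fixed seed and round-trip JSON", {
  spec <- noisyScene(noiseSd = 5, seed = 47L)
  pair <- pairSeries(renderSeries(spec, 2),
                     renderSeries(spec, 1, sliceIndices = 7L,
                                  seriesLabel = "B"))
  cfg <- list(nRuns = 50L, seed = 8L, timestamp = "2026-01-01T00:00:00Z")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeReport(runQc(pair, cfg), f1)
  writeReport(runQc(pair, cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  rep <- runQc(pair, cfg)
  writeReport(rep, f1)
  back <- readReport(f1)
  expect_equal(back$metrics$psg$A7, reportMetrics(rep)$psg$A7)
  expect_equal(back$metrics$snr, reportMetrics(rep)$snr,
               ignore_attr = TRUE)
  expect_equal(as.data.frame(back$verdicts), reportVerdicts(rep))
  expect_equal(back$randomization$psg_A7$median,
               rep@randomization$psg_A7$median)
})

test_that("a ghosted study fails the Greek PSG limit but passes ACR", {
  spec <- noisyScene(noiseSd = 2, seed = 53L, ghostFraction = 0.02,
                     nonuniformityAmplitude = 0.04)
  series <- renderSeries(spec, 2)
  repAcr <- runQc(series, list(nRuns = 20L, protocol = "acr"))
  repGreek <- runQc(series, list(nRuns = 20L, protocol = "greek"))
  vA <- reportVerdicts(repAcr); vG <- reportVerdicts(repGreek)
  expect_true(vA$pass[vA$metric == "PSG" & vA$variant == "A7"])
  expect_false(vG$pass[vG$metric == "PSG" & vG$variant == "A7"])
  # the Rayleigh noise floor in the ghost-free bars offsets part of the
  # injected 2% ghost, so the measured PSG sits between the two limits
  psgA7 <- reportMetrics(repAcr)$psg$A7
  expect_gt(psgA7, 1.0); expect_lt(psgA7, 2.5)
})
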