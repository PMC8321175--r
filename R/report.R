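#' Pass/fail limits for a named protocol
#'
#' "acr": PSG <= 2.5 percent, PIU >= 87.5 percent. "greek" (= AAPM):
#' PSG <= 1 percent, PIU >= 90 percent. Both use SNR >= 80 x T, ratio
#' interval [0.9, 1.1] and SNRU references 5 / 10 percent.
#'
#' @param protocol "acr" or "greek".
#' @return a [ProtocolLimits-class].
#' @export
protocolLimits <- function(protocol = c("acr", "greek")) {
  protocol <- match.arg(protocol)
  if (protocol == "acr")
    new("ProtocolLimits", name = "acr", psgMax = 2.5, piuMin = 87.5,
        snrMinPerTesla = 80, ratioLow = 0.9, ratioHigh = 1.1,
        snruAchievable = 5, snruMax = 10)
  else
    new("ProtocolLimits", name = "greek", psgMax = 1.0, piuMin = 90,
        snrMinPerTesla = 80, ratioLow = 0.9, ratioHigh = 1.1,
        snruAchievable = 5, snruMax = 10)
}

#' Summarize a randomized-run distribution
#'
#' Empirical summary of the metric values obtained across randomized ROI
#' layouts. The confidence interval is formed from the empirical quantiles
#' at (1 - ci)/2 and 1 - (1 - ci)/2 (no normality assumption).
#'
#' @param values numeric vector (>= 2 values).
#' @param ciLevel confidence level (default 0.99).
#' @return list: n, min, max, mean, median, q1, q3, ciLow, ciHigh, ciLevel.
#' @export
summarizeRandomized <- function(values, ciLevel = 0.99) {
  if (length(values) < 2L)
    stopQc("report", "need at least 2 values to summarize")
  probs <- c((1 - ciLevel) / 2, 1 - (1 - ciLevel) / 2)
  ci <- unname(stats::quantile(values, probs))
  q <- unname(stats::quantile(values, c(0.25, 0.75)))
  list(n = length(values), min = min(values), max = max(values),
       mean = mean(values), median = stats::median(values),
       q1 = q[1], q3 = q[2], ciLow = ci[1], ciHigh = ci[2],
       ciLevel = ciLevel)
}

verdictRow <- function(metric, variant, value, limit, pass) {
  data.frame(metric = metric, variant = variant, value = value,
             limit = limit, pass = pass, stringsAsFactors = FALSE)
}

#' Judge computed metrics against protocol limits
#'
#' Applies the comparison direction proper to each metric: PSG below its
#' maximum, PIU and SNR above their minima (SNR limit scales with field
#' strength as 80 x T), ratios inside [0.9, 1.1], SNRU below the maximum
#' acceptable level.
#'
#' @param metrics named list as assembled by [runQc()] (entries: psg, piu,
#'   snr, ratios, snru, snruRatios; each a named list of numeric values).
#' @param limits a [ProtocolLimits-class].
#' @param fieldStrengthT field strength in Tesla.
#' @return data.frame of verdicts (metric, variant, value, limit, pass).
#' @export
evaluateMetrics <- function(metrics, limits, fieldStrengthT) {
  if (is.null(metrics$psg) || is.null(metrics$piu) || is.null(metrics$snr))
    stopQc("report", "metrics must include psg, piu and snr")
  rows <- list()
  for (nm in names(metrics$psg))
    rows[[length(rows) + 1L]] <- verdictRow(
      "PSG", nm, metrics$psg[[nm]],
      sprintf("<= %.1f%%", limits@psgMax),
      metrics$psg[[nm]] <= limits@psgMax)
  for (nm in names(metrics$piu))
    rows[[length(rows) + 1L]] <- verdictRow(
      "PIU", nm, metrics$piu[[nm]],
      sprintf(">= %.1f%%", limits@piuMin),
      metrics$piu[[nm]] >= limits@piuMin)
  snrLimit <- limits@snrMinPerTesla * fieldStrengthT
  for (nm in names(metrics$snr))
    rows[[length(rows) + 1L]] <- verdictRow(
      "SNR", nm, metrics$snr[[nm]],
      sprintf(">= %.0f (80 x %.1f T)", snrLimit, fieldStrengthT),
      metrics$snr[[nm]] >= snrLimit)
  for (nm in names(metrics$ratios %||% list()))
    rows[[length(rows) + 1L]] <- verdictRow(
      "SNR ratio", nm, metrics$ratios[[nm]],
      sprintf("[%.1f, %.1f]", limits@ratioLow, limits@ratioHigh),
      metrics$ratios[[nm]] >= limits@ratioLow &&
        metrics$ratios[[nm]] <= limits@ratioHigh)
  for (nm in names(metrics$snru %||% list()))
    rows[[length(rows) + 1L]] <- verdictRow(
      "SNRU", nm, metrics$snru[[nm]],
      sprintf("<= %.0f%%", limits@snruMax),
      metrics$snru[[nm]] <= limits@snruMax)
  for (nm in names(metrics$snruRatios %||% list()))
    rows[[length(rows) + 1L]] <- verdictRow(
      "SNRU ratio", nm, metrics$snruRatios[[nm]],
      sprintf("[%.1f, %.1f]", limits@ratioLow, limits@ratioHigh),
      metrics$snruRatios[[nm]] >= limits@ratioLow &&
        metrics$snruRatios[[nm]] <= limits@ratioHigh)
  do.call(rbind, rows)
}

defaultQcConfig <- function() {
  list(protocol = "acr", nRuns = 500L, seed = 1L,
       rayleighFactor = 0.655, sqrt2Factor = 1.41,
       ufovFraction = 0.8, slice7Index = 7L, slice6Index = 6L,
       snruRadiusMm = 10, timestamp = NULL)
}

#' Run the full QC pipeline on a study
#'
#' Detection, ROI placement, all PSG / PIU / SNR / SNRU variants on slices
#' #6 and #7 of series A (plus the A/B two-image variants when series B is
#' present), the randomized PSG distribution, and the verdict table.
#' Deterministic for a fixed seed.
#'
#' @param study a [StudyPair-class], or a plain list of
#'   [AcquisitionSlice-class] (series A only; A/B variants are then
#'   reported as not computed).
#' @param config named list overriding any of: protocol, nRuns, seed,
#'   rayleighFactor, sqrt2Factor, ufovFraction, slice7Index, slice6Index,
#'   snruRadiusMm, timestamp.
#' @return a [QCReport-class].
#' @export
runQc <- function(study, config = list()) {
  cfg <- utils::modifyList(defaultQcConfig(), config)
  limits <- protocolLimits(cfg$protocol)
  notes <- character()

  if (is(study, "StudyPair")) {
    seriesA <- study@seriesA; seriesB <- study@seriesB
  } else {
    seriesA <- study; seriesB <- NULL
  }
  a7 <- selectSlice(seriesA, cfg$slice7Index)
  a6 <- tryCatch(selectSlice(seriesA, cfg$slice6Index),
                 error = function(e) NULL)
  b7 <- if (!is.null(seriesB))
    tryCatch(selectSlice(seriesB, cfg$slice7Index), error = function(e) NULL)
  if (is.null(a6))
    notes <- c(notes, "slice #6 absent: same-acquisition two-image variants not computed")
  if (is.null(b7))
    notes <- c(notes, "series B absent: A/B two-image variants not computed")

  px <- a7@px; py <- a7@py
  geom <- detectPhantom(a7)
  ufov <- placeUfov(geom, cfg$ufovFraction)
  bars <- placeBackgroundBars(geom, dim(a7@pixels), px, py)
  barStats7 <- lapply(bars, function(b) roiStats(a7@pixels, b))
  sP7 <- roiStats(a7@pixels, ufov)

  metrics <- list(psg = list(), piu = list(), snr = list(),
                  ratios = list(), snru = list(), snruRatios = list())

  ## --- PSG: deterministic + randomized, slice #7 of A (and of B) ---
  psgA <- computePsg(sP7, barStats7$U, barStats7$D, barStats7$L, barStats7$R)
  metrics$psg[["A7"]] <- psgA$value
  rcfg <- randomizationConfig(nRuns = cfg$nRuns, seed = cfg$seed)
  psgRandom <- randomizedPsg(a7@pixels, geom, rcfg, px, py, cfg$ufovFraction)
  randomization <- list(
    psg_A7 = c(list(deterministic = psgA$value),
               summarizeRandomized(psgRandom, 0.99)))
  if (!is.null(b7)) {
    geomB <- detectPhantom(b7)
    barsB <- placeBackgroundBars(geomB, dim(b7@pixels), px, py)
    sPB <- roiStats(b7@pixels, placeUfov(geomB, cfg$ufovFraction))
    psgB <- computePsg(sPB,
                       roiStats(b7@pixels, barsB$U), roiStats(b7@pixels, barsB$D),
                       roiStats(b7@pixels, barsB$L), roiStats(b7@pixels, barsB$R))
    metrics$psg[["B7"]] <- psgB$value
  }

  ## --- PIU ---
  metrics$piu[["A7"]] <- computePiu(a7@pixels, geom, px, py,
                                    cfg$ufovFraction)$value
  if (!is.null(b7))
    metrics$piu[["B7"]] <- computePiu(b7@pixels, geomB, px, py,
                                      cfg$ufovFraction)$value

  ## --- single-image SNR: all bar combinations on slice #7 of A ---
  combos <- list(LR = c("L", "R"), UD = c("U", "D"), UL = c("U", "L"),
                 UR = c("U", "R"), DL = c("D", "L"), DR = c("D", "R"),
                 U = "U", D = "D", L = "L", R = "R")
  for (nm in names(combos)) {
    v <- computeSnrSingle(sP7, barStats7[combos[[nm]]],
                          factor = cfg$rayleighFactor,
                          tag = paste0("single_", nm))
    metrics$snr[[variantTag(v)]] <- variantValue(v)
  }

  ## --- slices #7 vs #6, single-image method + ratio ---
  if (!is.null(a6)) {
    barStats6 <- lapply(bars, function(b) roiStats(a6@pixels, b))
    sP6 <- roiStats(a6@pixels, ufov)
    snr1 <- computeSnrSingle(sP7, barStats7[c("L", "R")],
                             factor = cfg$rayleighFactor, tag = "single_7_LR")
    snr2 <- computeSnrSingle(sP6, barStats6[c("L", "R")],
                             factor = cfg$rayleighFactor, tag = "single_6_LR")
    metrics$snr[["single_6_LR"]] <- variantValue(snr2)
    metrics$ratios[["single_7_over_6"]] <- snrRatio(snr1, snr2)$ratio

    ## --- two-image method, #7 - #6 of the same acquisition ---
    sdD76 <- ufovDiffSd(a7@pixels, a6@pixels, ufov)
    for (mode in c("first", "second", "average")) {
      tag <- paste0("diff_76_",
                    switch(mode, first = "num7", second = "num6",
                           average = "avg"))
      v <- computeSnrDiff(sP7, sP6, sdD76, mode, cfg$sqrt2Factor, tag)
      metrics$snr[[tag]] <- variantValue(v)
    }
  }

  ## --- two-image method across acquisitions, #7A - #7B ---
  if (!is.null(b7)) {
    sPB_onA <- roiStats(b7@pixels, ufov)  # common UFOV from series A geometry
    sdDAB <- ufovDiffSd(a7@pixels, b7@pixels, ufov)
    for (mode in c("first", "second", "average")) {
      tag <- paste0("diff_AB_",
                    switch(mode, first = "num7A", second = "num7B",
                           average = "avg"))
      v <- computeSnrDiff(sP7, sPB_onA, sdDAB, mode, cfg$sqrt2Factor, tag)
      metrics$snr[[tag]] <- variantValue(v)
    }
    if (!is.null(a6))
      metrics$ratios[["diff_76_over_diff_AB"]] <-
        snrRatio(metrics$snr[["diff_76_num7"]],
                 metrics$snr[["diff_AB_num7A"]])$ratio
  }

  ## --- SNRU ---
  snruRois <- placeSnruRois(geom, px, cfg$snruRadiusMm)
  means7 <- vapply(snruRois, function(r) roiMean(roiStats(a7@pixels, r)),
                   numeric(1))
  barSds7 <- c(roiSd(barStats7$L), roiSd(barStats7$R))
  metrics$snru[["single_7"]] <-
    computeSnru(means7, barSds = barSds7, factor = cfg$rayleighFactor)$value
  if (!is.null(a6)) {
    means6 <- vapply(snruRois, function(r) roiMean(roiStats(a6@pixels, r)),
                     numeric(1))
    barSds6 <- c(roiSd(barStats6$L), roiSd(barStats6$R))
    metrics$snru[["single_6"]] <-
      computeSnru(means6, barSds = barSds6, factor = cfg$rayleighFactor)$value
    metrics$snruRatios[["single_7_over_6"]] <-
      metrics$snru[["single_7"]] / metrics$snru[["single_6"]]

    diffImg <- a7@pixels - a6@pixels
    diffSds <- vapply(snruRois, function(r) popSd(roiPixelValues(diffImg, r)),
                      numeric(1))
    metrics$snru[["diff_1"]] <-
      computeSnru(means7, diffSds = diffSds, factor = cfg$sqrt2Factor)$value
    metrics$snru[["diff_2"]] <-
      computeSnru(means6, diffSds = diffSds, factor = cfg$sqrt2Factor)$value
    metrics$snruRatios[["diff_1_over_2"]] <-
      metrics$snru[["diff_1"]] / metrics$snru[["diff_2"]]
  }

  verdicts <- evaluateMetrics(metrics, limits, a7@fieldStrengthT)
  provenance <- list(
    protocol = cfg$protocol, seed = cfg$seed, nRuns = cfg$nRuns,
    rayleighFactor = cfg$rayleighFactor, sqrt2Factor = cfg$sqrt2Factor,
    ufovFraction = cfg$ufovFraction,
    ciMethod = "empirical quantiles",
    softwareVersion = as.character(utils::packageVersion("acrqc")),
    inputs = c(a7@sourceId, if (!is.null(a6)) a6@sourceId,
               if (!is.null(b7)) b7@sourceId),
    timestamp = cfg$timestamp %||% format(Sys.time(), tz = "UTC"))

  new("QCReport", metrics = metrics, verdicts = verdicts,
      randomization = randomization, provenance = provenance, notes = notes)
}

#' Flatten a report to a plain serializable list
#'
#' @param report a [QCReport-class].
#' @return nested list of plain vectors (round-trips through JSON).
#' @export
reportToList <- function(report) {
  list(metrics = report@metrics,
       verdicts = report@verdicts,
       randomization = report@randomization,
       provenance = report@provenance,
       notes = as.list(report@notes))
}

#' Write a report to JSON (canonical) or CSV (flat verdict rows)
#'
#' @param report a [QCReport-class].
#' @param path output file.
#' @param format "json" or "csv".
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(reportToList(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    utils::write.csv(report@verdicts, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [writeReport()].
#' @return the report as a plain list (same shape as [reportToList()]).
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Overall pass of a report
#'
#' @param report a [QCReport-class].
#' @return logical: TRUE when every checked limit passes.
#' @export
reportPasses <- function(report) {
  all(report@verdicts$pass)
}
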