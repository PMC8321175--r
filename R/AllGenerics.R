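#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slicePixels", function(x) standardGeneric("slicePixels"))
#' @rdname accessors
#' @export
setMethod("slicePixels", "AcquisitionSlice", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "AcquisitionSlice",
          function(x) c(px = x@px, py = x@py))

#' @rdname accessors
#' @export
setGeneric("sliceIndex", function(x) standardGeneric("sliceIndex"))
#' @rdname accessors
#' @export
setMethod("sliceIndex", "AcquisitionSlice", function(x) x@sliceIndex)

#' @rdname accessors
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))
#' @rdname accessors
#' @export
setMethod("seriesLabel", "AcquisitionSlice", function(x) x@seriesLabel)

#' @rdname accessors
#' @export
setGeneric("fieldStrength", function(x) standardGeneric("fieldStrength"))
#' @rdname accessors
#' @export
setMethod("fieldStrength", "AcquisitionSlice", function(x) x@fieldStrengthT)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "AcquisitionSlice", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("phantomCenter", function(x) standardGeneric("phantomCenter"))
#' @rdname accessors
#' @export
setMethod("phantomCenter", "PhantomGeometry",
          function(x) c(row = x@centerRow, col = x@centerCol))

#' @rdname accessors
#' @export
setGeneric("phantomRadiusPx", function(x) standardGeneric("phantomRadiusPx"))
#' @rdname accessors
#' @export
setMethod("phantomRadiusPx", "PhantomGeometry", function(x) x@r0Px)

#' @rdname accessors
#' @export
setGeneric("phantomMask", function(x) standardGeneric("phantomMask"))
#' @rdname accessors
#' @export
setMethod("phantomMask", "PhantomGeometry", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("roiMean", function(x) standardGeneric("roiMean"))
#' @rdname accessors
#' @export
setMethod("roiMean", "ROIStats", function(x) x@mean)

#' @rdname accessors
#' @export
setGeneric("roiSd", function(x) standardGeneric("roiSd"))
#' @rdname accessors
#' @export
setMethod("roiSd", "ROIStats", function(x) x@sd)

#' @rdname accessors
#' @export
setGeneric("roiPixelCount", function(x) standardGeneric("roiPixelCount"))
#' @rdname accessors
#' @export
setMethod("roiPixelCount", "ROIStats", function(x) x@nPixels)

#' @rdname accessors
#' @export
setGeneric("variantTag", function(x) standardGeneric("variantTag"))
#' @rdname accessors
#' @export
setMethod("variantTag", "SNRVariant", function(x) x@tag)

#' @rdname accessors
#' @export
setGeneric("variantValue", function(x) standardGeneric("variantValue"))
#' @rdname accessors
#' @export
setMethod("variantValue", "SNRVariant", function(x) x@value)

#' @rdname accessors
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
#' @rdname accessors
#' @export
setMethod("reportMetrics", "QCReport", function(x) x@metrics)

#' @rdname accessors
#' @export
setGeneric("reportVerdicts", function(x) standardGeneric("reportVerdicts"))
#' @rdname accessors
#' @export
setMethod("reportVerdicts", "QCReport", function(x) x@verdicts)

#' @rdname accessors
#' @export
setGeneric("reportNotes", function(x) standardGeneric("reportNotes"))
#' @rdname accessors
#' @export
setMethod("reportNotes", "QCReport", function(x) x@notes)

setMethod("show", "AcquisitionSlice", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "AcquisitionSlice: %dx%d, slice #%d series %s, spacing %.4f x %.4f mm\n",
    d[1], d[2], object@sliceIndex, object@seriesLabel, object@px, object@py))
})

setMethod("show", "PhantomGeometry", function(object) {
  cat(sprintf(
    "PhantomGeometry: center (%.2f, %.2f), r0 = %.2f px (%.1f mm), quality %.3f\n",
    object@centerRow, object@centerCol, object@r0Px, 2 * object@r0Mm / 2,
    object@quality))
})

setMethod("show", "CircularROI", function(object) {
  cat(sprintf("CircularROI [%s]: center (%.2f, %.2f), radius %.2f px\n",
              object@label, object@centerRow, object@centerCol,
              object@radiusPx))
})

setMethod("show", "RectROI", function(object) {
  cat(sprintf("RectROI [%s]: corner (%d, %d), w = %d, H = %d px\n",
              object@side, object@topRow, object@leftCol,
              object@widthW, object@heightH))
})

setMethod("show", "ROIStats", function(object) {
  cat(sprintf("ROIStats: mean %.4g, sd %.4g, n = %d\n",
              object@mean, object@sd, object@nPixels))
})

setMethod("show", "SNRVariant", function(object) {
  cat(sprintf("SNRVariant [%s]: %.2f (factor %.3f)\n",
              object@tag, object@value, object@factorUsed))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport\n")
  cat(sprintf("  protocol: %s\n", object@provenance$protocol %||% "?"))
  v <- object@verdicts
  if (nrow(v)) {
    cat(sprintf("  checks: %d (%d pass, %d fail)\n",
                nrow(v), sum(v$pass), sum(!v$pass)))
    cat(sprintf("  overall: %s\n", if (all(v$pass)) "PASS" else "FAIL"))
  }
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
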