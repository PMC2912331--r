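#' Accessors for leukoProfiler result objects
#'
#' Small accessor layer so downstream code never reaches into slots:
#' \code{populationId()} / \code{classLabel()} / \code{nSignatures()} /
#' \code{signatureTranscripts()} for [SignatureSet-class] objects, and
#' \code{profileRows()} / \code{profileBackground()} / \code{profileAlpha()}
#' for [InflammationProfile-class] objects.
#'
#' @param x a leukoProfiler object.
#' @return the corresponding component; \code{profileRows()} and
#'   \code{signatureTranscripts()} return a \link[S4Vectors]{DataFrame}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("populationId", function(x) standardGeneric("populationId"))

#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("nSignatures", function(x) standardGeneric("nSignatures"))

#' @rdname accessors
#' @export
setGeneric("signatureTranscripts",
           function(x) standardGeneric("signatureTranscripts"))

#' @rdname accessors
#' @export
setGeneric("profileRows", function(x) standardGeneric("profileRows"))

#' @rdname accessors
#' @export
setGeneric("profileBackground", function(x) standardGeneric("profileBackground"))

#' @rdname accessors
#' @export
setGeneric("profileAlpha", function(x) standardGeneric("profileAlpha"))

#' @rdname accessors
#' @export
setMethod("populationId", "SignatureSet", function(x) x@populationId)

#' @rdname accessors
#' @export
setMethod("classLabel", "SignatureSet", function(x) x@classLabel)

#' @rdname accessors
#' @export
setMethod("nSignatures", "SignatureSet", function(x) nrow(x@transcripts))

#' @rdname accessors
#' @export
setMethod("signatureTranscripts", "SignatureSet", function(x) x@transcripts)

#' @rdname accessors
#' @export
setMethod("profileRows", "InflammationProfile", function(x) x@rows)

#' @rdname accessors
#' @export
setMethod("profileBackground", "InflammationProfile", function(x) x@background)

#' @rdname accessors
#' @export
setMethod("profileAlpha", "InflammationProfile", function(x) x@alpha)

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet '%s' (%s): %d signature transcripts\n",
              object@populationId, object@classLabel,
              nrow(object@transcripts)))
  cat(sprintf("  gate: adjusted p < %g, fold change >= %g\n",
              object@thresholds[["p_adj_max"]],
              object@thresholds[["fc_min"]]))
  if (nrow(object@transcripts)) {
    top <- utils::head(object@transcripts, 3L)
    cat(sprintf("  top markers: %s\n",
                paste(sprintf("%s (%.1fx)", top$probe_id, top$fc),
                      collapse = ", ")))
  }
})

setMethod("show", "InflammationProfile", function(object) {
  r <- object@rows
  cat(sprintf("InflammationProfile '%s': %d populations, %d significant\n",
              object@contrastLabel, nrow(r), sum(r$significant)))
  cat(sprintf("  background: %d / %d probes increased (%.2f%%)\n",
              object@background[["k_increased"]],
              object@background[["m_total"]],
              100 * object@background[["k_increased"]] /
                object@background[["m_total"]]))
  if (nrow(r)) {
    top <- r[1L, ]
    cat(sprintf("  top-ranked: %s (n1/n2 = %d/%d = %s)\n",
                top$population_id, top$n1, top$n2,
                formatRatio(top$ratio)))
  }
})

setMethod("show", "SpikeInTruth", function(object) {
  cat(sprintf("SpikeInTruth: %d spiked population(s), sigma = %g, seed = %d\n",
              length(object@spiked), object@noiseSigma, object@seed))
  if (length(object@spiked))
    cat(sprintf("  fractions: %s\n",
                paste(sprintf("%s = %.2f", names(object@spiked),
                              object@spiked), collapse = ", ")))
})

setMethod("show", "AttributionResult", function(object) {
  cat(sprintf("AttributionResult: top %d induced transcripts, %.1f%% explained\n",
              object@K, sum(object@classFractions)))
  for (cl in names(object@classFractions))
    cat(sprintf("  %s: %.1f%%\n", cl, object@classFractions[[cl]]))
})

# "Inf" for the n2 = 0 sentinel, "NA" for the empty case, else 2 decimals
formatRatio <- function(r) {
  if (is.na(r)) "NA" else if (is.infinite(r)) "Inf" else sprintf("%.2f", r)
}
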