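#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' SignatureSet: signature transcripts of one reference population
#'
#' A \code{SignatureSet} holds, for one reference cell population, the
#' transcripts whose expression is far higher in that population than in the
#' baseline tissue: adjusted p below \code{pAdjMax} and linear fold change of
#' at least \code{fcMin} (defaults 1e-4 and 16). Transcripts are stored in
#' descending fold-change order.
#'
#' @slot populationId single character identifier of the population.
#' @slot classLabel cell-type class (e.g. "macrophage", "dendritic cell").
#' @slot transcripts a \link[S4Vectors]{DataFrame} with columns
#'   \code{probe_id}, \code{fc} (linear fold change population/reference) and
#'   \code{p_adj} (BH-adjusted p from the population-vs-reference contrast).
#' @slot thresholds named numeric vector with elements \code{p_adj_max} and
#'   \code{fc_min} used for the gate.
#'
#' @seealso [identifySignatures()], [signatureOverlap()]
#' @exportClass SignatureSet
setClass("SignatureSet",
  slots = c(
    populationId = "character",
    classLabel   = "character",
    transcripts  = "DataFrame",
    thresholds   = "numeric"
  )
)

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (length(object@populationId) != 1L || is.na(object@populationId))
    msg <- c(msg, "populationId must be a single non-NA string")
  if (length(object@classLabel) != 1L)
    msg <- c(msg, "classLabel must be a single string")
  tr <- object@transcripts
  need <- c("probe_id", "fc", "p_adj")
  if (!all(need %in% colnames(tr)))
    msg <- c(msg, sprintf("transcripts must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tr$probe_id))
      msg <- c(msg, "duplicate probe_id in transcripts")
    if (!all(c("p_adj_max", "fc_min") %in% names(object@thresholds)))
      msg <- c(msg, "thresholds must name p_adj_max and fc_min")
    else if (nrow(tr) > 0L) {
      if (any(tr$fc < object@thresholds[["fc_min"]]))
        msg <- c(msg, "transcript below the fc_min gate")
      if (any(tr$p_adj >= object@thresholds[["p_adj_max"]]))
        msg <- c(msg, "transcript at or above the p_adj_max gate")
    }
  }
  if (length(msg)) msg else TRUE
})

#' InflammationProfile: ranked per-population infiltration scores
#'
#' The result of [buildProfile()]: one row per candidate population with the
#' signature counts split by contrast direction (\code{n1} increased,
#' \code{n2} decreased), the \code{n1/n2} ratio, the redundancy-filtered
#' counterparts (\code{n_star}, \code{n1_star}, \code{n2_star},
#' \code{ratio_star}), hypergeometric p-values for both counts
#' (Hochberg-adjusted across populations), and the joint significance flag.
#' Rows are ordered by the ranking rule (descending ratio; infinite ratios
#' first, larger n1 breaking ties).
#'
#' @slot rows a \link[S4Vectors]{DataFrame}, one row per population.
#' @slot background named numeric: \code{m_total}, \code{k_increased},
#'   \code{k_decreased} from the case/control contrast over the full platform.
#' @slot alpha significance level applied to both adjusted p-value families.
#' @slot contrastLabel free-text label of the case/control contrast.
#'
#' @seealso [buildProfile()], [classSummary()], [attributeTranscripts()]
#' @exportClass InflammationProfile
setClass("InflammationProfile",
  slots = c(
    rows          = "DataFrame",
    background    = "numeric",
    alpha         = "numeric",
    contrastLabel = "character"
  )
)

setValidity("InflammationProfile", function(object) {
  msg <- character()
  need <- c("population_id", "class_label", "n", "n1", "n2", "ratio",
            "pct_increased", "n_star", "n1_star", "n2_star", "ratio_star",
            "p1_raw", "p1_adj", "p2_raw", "p2_adj", "significant")
  r <- object@rows
  if (!all(need %in% colnames(r)))
    msg <- c(msg, sprintf("rows missing columns: %s",
                          paste(setdiff(need, colnames(r)), collapse = ", ")))
  else if (nrow(r) > 0L) {
    if (any(r$n1 + r$n2 > r$n)) msg <- c(msg, "n1 + n2 exceeds n")
    if (any(r$n_star > r$n) || any(r$n1_star > r$n1) || any(r$n2_star > r$n2))
      msg <- c(msg, "starred counts exceed unfiltered counts")
    if (anyDuplicated(r$population_id))
      msg <- c(msg, "duplicate population_id")
  }
  bg <- object@background
  if (!all(c("m_total", "k_increased", "k_decreased") %in% names(bg)))
    msg <- c(msg, "background must name m_total, k_increased, k_decreased")
  else if (bg[["k_increased"]] + bg[["k_decreased"]] > bg[["m_total"]])
    msg <- c(msg, "background counts exceed platform size")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' SpikeInTruth: ground truth for a simulated infiltration experiment
#'
#' Records which populations were spiked into the simulated case samples and
#' at what linear-scale mixing fraction, any intrinsic (cell-autonomous)
#' differential-expression effects planted in cases, the noise level, and the
#' seed, so simulation results can be checked against a known answer.
#'
#' @slot spiked named numeric; mixing fraction per spiked population id,
#'   each in [0,1) and summing to less than 1.
#' @slot intrinsicDe named numeric; planted log2 effect per probe id
#'   (added to case samples on top of the mixture).
#' @slot noiseSigma log2-scale Gaussian noise SD per sample.
#' @slot seed integer seed driving the experiment generator.
#'
#' @seealso [simulatePanel()], [simulateExperiment()]
#' @exportClass SpikeInTruth
setClass("SpikeInTruth",
  slots = c(
    spiked      = "numeric",
    intrinsicDe = "numeric",
    noiseSigma  = "numeric",
    seed        = "integer"
  )
)

setValidity("SpikeInTruth", function(object) {
  msg <- character()
  f <- object@spiked
  if (length(f) && is.null(names(f)))
    msg <- c(msg, "spiked fractions must be named by population id")
  if (any(f < 0)) msg <- c(msg, "negative mixing fraction")
  if (sum(f) >= 1) msg <- c(msg, "mixing fractions must sum to < 1")
  if (length(object@intrinsicDe) && is.null(names(object@intrinsicDe)))
    msg <- c(msg, "intrinsicDe must be named by probe id")
  if (length(object@noiseSigma) != 1L || object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' AttributionResult: explanation of top induced transcripts
#'
#' Produced by [attributeTranscripts()]: the K most strongly induced
#' transcripts of a contrast, each assigned (where possible) to the
#' highest-ranked significant population whose signature set contains it,
#' plus the per-class explained fractions.
#'
#' @slot assignments a \link[S4Vectors]{DataFrame} with columns
#'   \code{probe_id}, \code{log2fc}, \code{rank}, \code{assigned_population},
#'   \code{assigned_class} (NA where unexplained).
#' @slot classFractions named numeric, percent of the K transcripts explained
#'   per class.
#' @slot K number of top transcripts considered.
#'
#' @exportClass AttributionResult
setClass("AttributionResult",
  slots = c(
    assignments    = "DataFrame",
    classFractions = "numeric",
    K              = "integer"
  )
)

setValidity("AttributionResult", function(object) {
  msg <- character()
  a <- object@assignments
  if (nrow(a) && anyDuplicated(a$rank))
    msg <- c(msg, "ranks must be unique")
  if (sum(object@classFractions) > 100 + 1e-8)
    msg <- c(msg, "explained fractions exceed 100%")
  if (length(msg)) msg else TRUE
})
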