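#' Identify a population's signature transcripts
#'
#' Contrasts a reference cell population against the baseline tissue and
#' keeps the probes expressed significantly and strongly higher in the
#' population: BH-adjusted p below \code{pAdjMax} (default 1e-4) and linear
#' fold change of at least \code{fcMin} (default 16, inclusive at the
#' boundary). The BH adjustment is computed within this single
#' population-vs-reference contrast. Transcripts are returned sorted by
#' descending fold change.
#'
#' @param population expression container for the population's replicate
#'   arrays (>= 2 samples).
#' @param reference expression container for the baseline tissue arrays,
#'   same probe universe.
#' @param pAdjMax adjusted-p gate, in (0,1).
#' @param fcMin linear fold-change gate, > 1.
#' @param classLabel cell-type class stored on the result (default
#'   \code{"unknown"}).
#' @param populationId identifier; defaults to the population's group label
#'   if unambiguous, else \code{"population"}.
#' @param method contrast method, see [probeContrast()].
#' @return a [SignatureSet-class].
#' @export
identifySignatures <- function(population, reference,
                               pAdjMax = 1e-4, fcMin = 16,
                               classLabel = "unknown",
                               populationId = NULL,
                               method = "moderated") {
  if (!(pAdjMax > 0 && pAdjMax < 1)) stop("pAdjMax must be in (0,1)")
  if (!(fcMin > 1)) stop("fcMin must exceed 1")
  if (ncol(population) < 2L)
    stop("population needs at least 2 replicate samples (got ",
         ncol(population), ")")
  if (is.null(populationId)) {
    cd <- SummarizedExperiment::colData(population)
    populationId <- if ("group" %in% colnames(cd) &&
                        length(unique(cd$group)) == 1L)
      unique(cd$group) else "population"
  }
  joined <- joinMatrices(reference, population)
  cc <- probeContrast(joined, group1 = colnames(reference),
                      group2 = colnames(population), method = method)
  keep <- cc$p_bh < pAdjMax & cc$fc >= fcMin
  hits <- cc[keep, c("probe_id", "fc", "p_bh"), drop = FALSE]
  names(hits)[3L] <- "p_adj"
  hits <- hits[order(-hits$fc, hits$probe_id), , drop = FALSE]
  new("SignatureSet",
      populationId = populationId,
      classLabel = classLabel,
      transcripts = S4Vectors::DataFrame(hits, row.names = NULL),
      thresholds = c(p_adj_max = pAdjMax, fc_min = fcMin))
}

#' Pairwise overlap between signature sets
#'
#' For each unordered pair of populations, the percentage of shared
#' signature transcripts. The default metric divides the intersection by the
#' smaller set (\code{"min"}); \code{"jaccard"} divides by the union. Pairs
#' involving an empty set are reported as NA and excluded from the summary.
#'
#' @param sets list of [SignatureSet-class] objects.
#' @param metric \code{"min"} or \code{"jaccard"}.
#' @return list with \code{overlap} (symmetric percent matrix, NA diagonal)
#'   and \code{summary} (median and quartiles over unordered pairs).
#' @export
signatureOverlap <- function(sets, metric = c("min", "jaccard")) {
  metric <- match.arg(metric)
  if (length(sets) < 2L) stop("need at least 2 signature sets")
  ids <- vapply(sets, populationId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate population ids")
  probes <- lapply(sets, function(s) signatureTranscripts(s)$probe_id)
  n <- length(sets)
  ov <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!length(probes[[i]]) || !length(probes[[j]])) next
    inter <- length(intersect(probes[[i]], probes[[j]]))
    den <- switch(metric,
      min = min(length(probes[[i]]), length(probes[[j]])),
      jaccard = length(union(probes[[i]], probes[[j]])))
    ov[i, j] <- ov[j, i] <- 100 * inter / den
  }
  pairs <- ov[upper.tri(ov)]
  pairs <- pairs[!is.na(pairs)]
  list(overlap = ov,
       summary = if (length(pairs))
         c(median = stats::median(pairs),
           q1 = unname(stats::quantile(pairs, 0.25)),
           q3 = unname(stats::quantile(pairs, 0.75)))
       else c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
}

#' Collapse probe-level signatures to genes
#'
#' For gene-level reporting, keeps the best probe per gene (smallest
#' adjusted p, ties by larger fold change).
#'
#' @param set a [SignatureSet-class].
#' @param annotation probe-to-gene data.frame from [readAnnotation()].
#' @return data.frame with one row per gene (\code{gene, probe_id, fc,
#'   p_adj}).
#' @export
collapseToGenes <- function(set, annotation) {
  tr <- as.data.frame(signatureTranscripts(set))
  tr$gene <- annotation$gene[match(tr$probe_id, annotation$probe_id)]
  tr <- tr[!is.na(tr$gene), , drop = FALSE]
  tr <- tr[order(tr$p_adj, -tr$fc), , drop = FALSE]
  tr <- tr[!duplicated(tr$gene), c("gene", "probe_id", "fc", "p_adj")]
  rownames(tr) <- NULL
  tr
}

#' Serialize a signature set
#'
#' @param set a [SignatureSet-class].
#' @param path output file; \code{.json} extension selects JSON, anything
#'   else TSV (\code{population_id, probe_id, fc, p_adj}).
#' @return \code{path}, invisibly.
#' @export
writeSignatureSet <- function(set, path) {
  tr <- as.data.frame(signatureTranscripts(set))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      population_id = populationId(set),
      class_label = classLabel(set),
      thresholds = as.list(set@thresholds),
      transcripts = tr), path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- cbind(population_id = populationId(set),
                 class_label = classLabel(set), tr)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
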