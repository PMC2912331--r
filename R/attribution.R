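#' Select the most strongly induced transcripts of a contrast
#'
#' Two-step selection mirroring a "top induced" ranking: among probes with
#' increased direction, take the K with the smallest BH-adjusted p (ties by
#' smaller raw p, then larger fold change), then order the selected K by
#' descending fold change for display.
#'
#' @param contrast a [probeContrast()] result.
#' @param K number of transcripts to select (default 500).
#' @return data.frame \code{probe_id, log2fc, fc, p_bh, rank} ordered by
#'   descending fold change; fewer than K rows (with a warning) when the
#'   contrast has fewer increased probes.
#' @export
topInduced <- function(contrast, K = 500L) {
  if (K < 1L) stop("K must be >= 1")
  inc <- contrast[contrast$direction == "increased", , drop = FALSE]
  if (nrow(inc) < K) {
    warning("only ", nrow(inc), " increased probes; returning all")
    K <- nrow(inc)
  }
  sel <- inc[order(inc$p_bh, inc$p_raw, -inc$fc), , drop = FALSE]
  sel <- sel[seq_len(K), , drop = FALSE]
  sel <- sel[order(-sel$fc, sel$probe_id), , drop = FALSE]
  out <- sel[, c("probe_id", "log2fc", "fc", "p_bh")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Attribute top induced transcripts to infiltrating populations
#'
#' Each top transcript that is a signature transcript of at least one
#' significant population is "explained" by infiltration of that cell type
#' and assigned to the highest-ranked such population (optionally restricted
#' to a set of classes, e.g. dendritic cells, macrophages and monocytes).
#' The per-class explained fraction is the assigned count over K, as a
#' percent.
#'
#' @param top output of [topInduced()].
#' @param profile an [InflammationProfile-class] built from the same
#'   contrast.
#' @param sets the signature sets the profile was built from.
#' @param classFilter optional character vector of classes eligible to
#'   explain transcripts.
#' @return an [AttributionResult-class].
#' @export
attributeTranscripts <- function(top, profile, sets, classFilter = NULL) {
  ids <- vapply(sets, populationId, character(1L))
  names(sets) <- ids
  r <- as.data.frame(profileRows(profile))
  sig <- r[r$significant, , drop = FALSE]          # already in rank order
  if (!is.null(classFilter))
    sig <- sig[sig$class_label %in% classFilter, , drop = FALSE]
  sigProbes <- lapply(sig$population_id,
                      function(j) signatureTranscripts(sets[[j]])$probe_id)
  assignedPop <- rep(NA_character_, nrow(top))
  assignedClass <- rep(NA_character_, nrow(top))
  for (i in seq_along(sigProbes)) {       # best-ranked population wins
    hit <- is.na(assignedPop) & top$probe_id %in% sigProbes[[i]]
    assignedPop[hit] <- sig$population_id[[i]]
    assignedClass[hit] <- sig$class_label[[i]]
  }
  K <- nrow(top)
  classes <- if (!is.null(classFilter)) classFilter
             else sort(unique(sig$class_label))
  fractions <- vapply(classes, function(cl)
    100 * sum(assignedClass == cl, na.rm = TRUE) / max(K, 1L), numeric(1L))
  new("AttributionResult",
      assignments = S4Vectors::DataFrame(
        probe_id = top$probe_id, log2fc = top$log2fc, rank = top$rank,
        assigned_population = assignedPop, assigned_class = assignedClass),
      classFractions = fractions,
      K = as.integer(K))
}

#' Serialize an attribution result
#'
#' @param result an [AttributionResult-class].
#' @param path output file; \code{.json} selects the per-class summary
#'   (pie-chart fractions), else the per-transcript TSV table.
#' @return \code{path}, invisibly.
#' @export
writeAttribution <- function(result, path) {
  if (grepl("\\.json$", path)) {
    fr <- as.list(result@classFractions)
    fr[["unexplained"]] <- 100 - sum(result@classFractions)
    jsonlite::write_json(list(K = result@K, explained_percent = fr),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(as.data.frame(result@assignments), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
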