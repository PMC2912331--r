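#' Score one population against a case/control contrast
#'
#' Counts how a population's signature transcripts respond in the contrast:
#' \code{n1} increased, \code{n2} decreased (probes with an exactly zero
#' fold change, or absent from the contrast, count as neither). The score is
#' the ratio \code{n1/n2}; when \code{n2 = 0} and \code{n1 > 0} the ratio is
#' \code{Inf}, and when both are 0 it is \code{NA}.
#'
#' @param set a [SignatureSet-class].
#' @param contrast a data.frame from [probeContrast()] on the case/control
#'   matrix.
#' @return named list: \code{n}, \code{n1}, \code{n2}, \code{ratio},
#'   \code{pct_increased} (= 100 n1/(n1+n2)), \code{n_absent} (signature
#'   probes missing from the contrast, excluded from the counts).
#' @export
scorePopulation <- function(set, contrast) {
  probes <- signatureTranscripts(set)$probe_id
  dir <- contrast$direction[match(probes, contrast$probe_id)]
  absent <- sum(is.na(dir))
  if (absent)
    message(absent, " signature probe(s) of '", populationId(set),
            "' absent from the contrast; excluded")
  n1 <- sum(dir == "increased", na.rm = TRUE)
  n2 <- sum(dir == "decreased", na.rm = TRUE)
  list(n = length(probes), n1 = n1, n2 = n2,
       ratio = scoreRatio(n1, n2),
       pct_increased = if (n1 + n2 > 0) 100 * n1 / (n1 + n2) else NA_real_,
       n_absent = absent)
}

scoreRatio <- function(n1, n2) {
  if (n2 > 0) n1 / n2 else if (n1 > 0) Inf else NA_real_
}

#' Rank populations by their n1/n2 score
#'
#' Descending ratio; infinite ratios sort first among themselves by larger
#' n1; finite ties broken by larger n1, then lexicographic population id;
#' NA ratios last.
#'
#' @param scores data.frame with columns \code{population_id}, \code{ratio},
#'   \code{n1}.
#' @return the data.frame reordered, with a \code{rank} column (1 = top).
#' @export
rankPopulations <- function(scores) {
  ord <- order(-scores$ratio, -scores$n1,
               as.character(scores$population_id),
               na.last = TRUE)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Redundancy filter: signatures unique below higher-ranked populations
#'
#' Removes from population \code{j}'s signature set every transcript that is
#' also a signature transcript of any population ranked strictly above
#' \code{j}. The top-ranked population is returned unchanged (n* = n). This
#' de-correlates the significance tests: a population that merely shares
#' markers with a truly infiltrating one loses those markers here.
#'
#' @param sets named list of [SignatureSet-class] objects (names =
#'   population ids).
#' @param ranking character vector of population ids, best first.
#' @param j population id to filter.
#' @return character vector of retained probe ids.
#' @export
filterUniqueSignatures <- function(sets, ranking, j) {
  if (!j %in% ranking) stop("population '", j, "' not in ranking")
  own <- signatureTranscripts(sets[[j]])$probe_id
  above <- ranking[seq_len(match(j, ranking) - 1L)]
  if (!length(above)) return(own)
  taken <- unique(unlist(lapply(sets[above],
                                function(s) signatureTranscripts(s)$probe_id)))
  setdiff(own, taken)
}

#' Build the inflammation profile
#'
#' The full scoring procedure over a panel of candidate populations:
#' (1) score each population's signature set against the case/control
#' contrast (n1 increased vs n2 decreased); (2) rank by the n1/n2 ratio;
#' (3) apply the redundancy filter to obtain n1*, n2* from each population's
#' unique signatures; (4) test both n1 (out of n1+n2 draws) and n1* (out of
#' n1*+n2* draws) against the platform-wide proportion of increased probes
#' with one-sided hypergeometric tests, each family Hochberg-adjusted across
#' all populations. A population is significant only if both adjusted
#' p-values fall below \code{alpha}.
#'
#' @param sets list of [SignatureSet-class] objects (unique population ids).
#' @param contrast case/control [probeContrast()] result over the full
#'   platform.
#' @param background optional direction counts (default
#'   [backgroundCounts()] of \code{contrast}).
#' @param alpha significance level for both adjusted families (default
#'   0.05).
#' @param contrastLabel label stored on the result.
#' @return an [InflammationProfile-class]; rows in rank order.
#' @export
buildProfile <- function(sets, contrast, background = NULL, alpha = 0.05,
                         contrastLabel = "case_vs_control") {
  if (!length(sets)) stop("need at least one signature set")
  ids <- vapply(sets, populationId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate population ids")
  names(sets) <- ids
  if (is.null(background)) background <- backgroundCounts(contrast)
  m_total <- background[["m_total"]]
  k_inc <- background[["k_increased"]]

  scores <- do.call(rbind, lapply(sets, function(s) {
    sc <- scorePopulation(s, contrast)
    data.frame(population_id = populationId(s),
               class_label = classLabel(s),
               n = sc$n, n1 = sc$n1, n2 = sc$n2, ratio = sc$ratio,
               pct_increased = sc$pct_increased,
               stringsAsFactors = FALSE)
  }))
  ranked <- rankPopulations(scores)
  ranking <- ranked$population_id

  dirById <- stats::setNames(contrast$direction, contrast$probe_id)
  starred <- do.call(rbind, lapply(ranking, function(j) {
    keep <- filterUniqueSignatures(sets, ranking, j)
    dir <- dirById[keep]
    n1s <- sum(dir == "increased", na.rm = TRUE)
    n2s <- sum(dir == "decreased", na.rm = TRUE)
    data.frame(n_star = length(keep), n1_star = n1s, n2_star = n2s,
               ratio_star = scoreRatio(n1s, n2s))
  }))

  tailP <- function(x, draws) {
    if (draws == 0L) 1 else hypergeomTail(x, draws, k_inc, m_total)
  }
  p1 <- mapply(tailP, ranked$n1, ranked$n1 + ranked$n2)
  p2 <- mapply(tailP, starred$n1_star, starred$n1_star + starred$n2_star)
  p1_adj <- adjustHochberg(p1)
  p2_adj <- adjustHochberg(p2)

  rows <- S4Vectors::DataFrame(
    ranked[, c("population_id", "class_label", "rank", "n", "n1", "n2",
               "ratio", "pct_increased")],
    starred,
    p1_raw = p1, p1_adj = p1_adj, p2_raw = p2, p2_adj = p2_adj,
    empty = (ranked$n1 + ranked$n2) == 0L,
    significant = p1_adj < alpha & p2_adj < alpha)
  new("InflammationProfile", rows = rows,
      background = background, alpha = alpha,
      contrastLabel = contrastLabel)
}

#' Class-level summary of a profile
#'
#' Collapses the profile to cell-type classes: per class the largest n1/n2
#' ratio among member populations and whether any member met both
#' significance criteria.
#'
#' @param profile an [InflammationProfile-class].
#' @param classMap optional named character vector population_id -> class;
#'   defaults to the class labels stored in the profile.
#' @return data.frame with \code{class_label}, \code{max_ratio},
#'   \code{any_significant}.
#' @export
classSummary <- function(profile, classMap = NULL) {
  r <- as.data.frame(profileRows(profile))
  if (!is.null(classMap)) {
    unmapped <- setdiff(r$population_id, names(classMap))
    if (length(unmapped))
      stop("unmapped populations: ", paste(unmapped, collapse = ", "))
    r$class_label <- unname(classMap[r$population_id])
  }
  out <- do.call(rbind, lapply(split(r, r$class_label), function(g) {
    data.frame(class_label = g$class_label[[1L]],
               max_ratio = if (all(is.na(g$ratio))) NA_real_
                           else max(g$ratio, na.rm = TRUE),
               any_significant = any(g$significant),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$max_ratio), , drop = FALSE]
}

#' Serialize an inflammation profile
#'
#' TSV writes one row per population with \code{Inf} ratios spelled
#' \code{"Inf"}; JSON carries infinite ratios as null with an
#' \code{infinite_ratio} flag plus the background and alpha metadata.
#'
#' @param profile an [InflammationProfile-class].
#' @param path output file; \code{.json} selects JSON, else TSV.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
  r <- as.data.frame(profileRows(profile))
  if (grepl("\\.json$", path)) {
    rows <- lapply(seq_len(nrow(r)), function(i) {
      x <- as.list(r[i, ])
      for (f in c("ratio", "ratio_star")) {
        x[[paste0("infinite_", f)]] <- is.infinite(x[[f]])
        if (!is.finite(x[[f]])) x[[f]] <- NULL
      }
      x
    })
    jsonlite::write_json(list(
      contrast = profile@contrastLabel,
      alpha = profileAlpha(profile),
      background = as.list(profileBackground(profile)),
      rows = rows), path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.table(r, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
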