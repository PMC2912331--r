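#' Ground truth for a spike-in experiment
#'
#' @param spiked named numeric vector of linear-scale mixing fractions per
#'   spiked population id (may be empty for an all-null experiment); must
#'   sum to less than 1.
#' @param intrinsicDe named numeric vector of planted log2 effects per probe
#'   (cell-autonomous case effects, added on top of the mixture).
#' @param noiseSigma log2-scale Gaussian noise SD (default 0.25).
#' @param seed integer seed for [simulateExperiment()].
#' @return a [SpikeInTruth-class].
#' @export
spikeInTruth <- function(spiked = numeric(), intrinsicDe = numeric(),
                         noiseSigma = 0.25, seed = 1L) {
  new("SpikeInTruth", spiked = spiked, intrinsicDe = intrinsicDe,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Simulate a reference panel with planted marker blocks
#'
#' Emulates a baseline tissue plus a panel of candidate cell populations on
#' a shared probe universe. Baseline log2 means are uniform on [4, 10]; each
#' population elevates its own block of marker probes by log2(markerFC)
#' (default 32-fold, comfortably above the 16-fold signature gate); samples
#' add i.i.d. Gaussian noise on the log2 scale. A population may share a
#' fraction of its markers with a designated earlier "parent" population to
#' exercise the redundancy filter.
#'
#' @param nProbes probe universe size.
#' @param nPopulations number of candidate populations.
#' @param markersPerPop planted markers per population.
#' @param markerFC linear fold elevation of markers over baseline
#'   (default 32).
#' @param sharedFrac fraction of a child population's markers taken from
#'   its parent's block (default 0).
#' @param parents integer vector (length nPopulations) of parent indices,
#'   NA for none; each parent index must be smaller than the child's.
#' @param nB replicate samples per population (default 3).
#' @param nA baseline reference samples (default 10).
#' @param noiseSigma log2 noise SD (default 0.25).
#' @param seed integer seed; same seed reproduces the panel exactly.
#' @return list: \code{reference} (expression container),
#'   \code{populations} (named list of containers, ids \code{pop01}, ...),
#'   \code{markers} (named list of planted marker probe ids),
#'   \code{baseline} (named vector of baseline log2 means).
#' @export
simulatePanel <- function(nProbes, nPopulations, markersPerPop,
                          markerFC = 32, sharedFrac = 0, parents = NULL,
                          nB = 3L, nA = 10L, noiseSigma = 0.25, seed = 1L) {
  if (markersPerPop * nPopulations > nProbes)
    stop("marker blocks do not fit: ", markersPerPop, " x ", nPopulations,
         " > ", nProbes)
  if (is.null(parents)) parents <- rep(NA_integer_, nPopulations)
  if (length(parents) != nPopulations)
    stop("parents must have one entry per population")
  if (any(!is.na(parents) & parents >= seq_len(nPopulations)))
    stop("a parent must precede its child")
  set.seed(seed)
  probes <- sprintf("probe%05d", seq_len(nProbes))
  popIds <- sprintf("pop%02d", seq_len(nPopulations))
  mu <- stats::runif(nProbes, 4, 10)
  names(mu) <- probes

  nShared <- if (sharedFrac > 0) round(sharedFrac * markersPerPop) else 0L
  markers <- vector("list", nPopulations)
  names(markers) <- popIds
  nextFree <- 1L
  for (j in seq_len(nPopulations)) {
    own <- markersPerPop
    shared <- character()
    if (!is.na(parents[[j]]) && nShared > 0L) {
      shared <- markers[[parents[[j]]]][seq_len(nShared)]
      own <- markersPerPop - nShared
    }
    if (nextFree + own - 1L > nProbes)
      stop("marker allocation exhausted the probe universe")
    fresh <- probes[seq(nextFree, length.out = own)]
    nextFree <- nextFree + own
    markers[[j]] <- c(fresh, shared)
  }

  noisy <- function(mean, n, prefix) {
    m <- matrix(mean, nrow = nProbes, ncol = n) +
      matrix(stats::rnorm(nProbes * n, sd = noiseSigma), nProbes, n)
    dimnames(m) <- list(probes, paste0(prefix, seq_len(n)))
    m
  }
  reference <- exprMatrix(noisy(mu, nA, "ref"),
                          groups = rep("reference", nA))
  populations <- lapply(seq_len(nPopulations), function(j) {
    muj <- mu
    muj[markers[[j]]] <- muj[markers[[j]]] + log2(markerFC)
    exprMatrix(noisy(muj, nB, paste0(popIds[[j]], "_s")),
               groups = rep(popIds[[j]], nB))
  })
  names(populations) <- popIds
  list(reference = reference, populations = populations,
       markers = markers, baseline = mu)
}

#' Simulate a case/control experiment with known infiltration
#'
#' Case samples are linear-scale convex mixtures of the baseline tissue and
#' the spiked populations: per probe, the case mean intensity is
#' \code{(1 - sum(f)) * 2^ref + sum_j f_j * 2^pop_j}, log2-transformed,
#' plus any planted intrinsic log2 effects, plus per-sample Gaussian log2
#' noise. Controls are the baseline mean plus noise. A probe at b-fold above
#' baseline in a population spiked at fraction f therefore shows an
#' expected case/control log2 fold change of \code{log2(1 - f + f*b)}.
#'
#' @param reference baseline expression container (from [simulatePanel()]
#'   or real data).
#' @param populations named list of population containers, probe-aligned
#'   with the reference.
#' @param truth a [SpikeInTruth-class]; spiked names must appear in
#'   \code{populations}.
#' @param nCase,nControl samples per arm (default 3 and 3).
#' @return expression container with groups \code{"case"} /
#'   \code{"control"}.
#' @export
simulateExperiment <- function(reference, populations, truth,
                               nCase = 3L, nControl = 3L) {
  f <- truth@spiked
  miss <- setdiff(names(f), names(populations))
  if (length(miss))
    stop("spiked populations not in panel: ", paste(miss, collapse = ", "))
  refMu <- rowMeans(exprValues(reference))
  caseLin <- (1 - sum(f)) * 2^refMu
  for (j in names(f)) {
    pop <- populations[[j]]
    if (!identical(rownames(pop), names(refMu)))
      pop <- pop[names(refMu), ]
    caseLin <- caseLin + f[[j]] * 2^rowMeans(exprValues(pop))
  }
  caseMu <- log2(caseLin)
  de <- truth@intrinsicDe
  if (length(de)) {
    idx <- match(names(de), names(refMu))
    if (anyNA(idx)) stop("intrinsicDe names absent from probe universe")
    caseMu[idx] <- caseMu[idx] + de
  }
  set.seed(truth@seed)
  nP <- length(refMu)
  sim <- function(mean, n, prefix) {
    m <- matrix(mean, nP, n) +
      matrix(stats::rnorm(nP * n, sd = truth@noiseSigma), nP, n)
    dimnames(m) <- list(names(refMu), paste0(prefix, seq_len(n)))
    m
  }
  exprMatrix(cbind(sim(caseMu, nCase, "case"),
                   sim(refMu, nControl, "ctrl")),
             groups = c(rep("case", nCase), rep("control", nControl)))
}

#' Run the full profiling procedure on a panel and an experiment
#'
#' Convenience wrapper tying the stages together: identifies signature
#' transcripts for every population against the reference, contrasts case
#' vs control, and builds the inflammation profile. This is the in-memory
#' core of the pipeline; [runPipeline()] adds file I/O around it.
#'
#' @param panel list with \code{reference} and \code{populations} (as from
#'   [simulatePanel()], or assembled from real matrices).
#' @param experiment case/control expression container with group labels.
#' @param caseGroup,controlGroup group labels in \code{experiment}.
#' @param pAdjMax,fcMin signature gate, see [identifySignatures()].
#' @param alpha profile significance level.
#' @param classLabels optional named character vector population id ->
#'   class.
#' @param method contrast method for both stages.
#' @return list: \code{profile} ([InflammationProfile-class]), \code{sets}
#'   (signature sets), \code{contrast} (case/control contrast data.frame).
#' @export
profileFromPanel <- function(panel, experiment,
                             caseGroup = "case", controlGroup = "control",
                             pAdjMax = 1e-4, fcMin = 16, alpha = 0.05,
                             classLabels = NULL, method = "moderated") {
  sets <- lapply(names(panel$populations), function(j) {
    identifySignatures(panel$populations[[j]], panel$reference,
                       pAdjMax = pAdjMax, fcMin = fcMin,
                       classLabel = if (!is.null(classLabels))
                         classLabels[[j]] else "unknown",
                       populationId = j, method = method)
  })
  cc <- probeContrast(experiment,
                      group1 = groupSamples(experiment, controlGroup),
                      group2 = groupSamples(experiment, caseGroup),
                      method = method)
  profile <- buildProfile(sets, cc, alpha = alpha,
                          contrastLabel = paste0(caseGroup, "_vs_",
                                                 controlGroup))
  list(profile = profile, sets = sets, contrast = cc)
}
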