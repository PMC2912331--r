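#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from a YAML file)
#' with either file inputs (\code{reference}, \code{populations} — a
#' directory or vector of matrix files — and \code{case_matrix} with
#' \code{case_group} / \code{control_group}) or a \code{simulate} block
#' (arguments for [simulatePanel()] plus \code{spiked} fractions for
#' [simulateExperiment()]). Optional fields with defaults:
#' \code{p_adj_max} (1e-4), \code{fc_min} (16), \code{alpha} (0.05),
#' \code{K_top} (500), \code{method} ("moderated"), \code{seed} (1),
#' \code{out} (output directory, required).
#'
#' @param config named list or path to a YAML file.
#' @return the completed configuration list (defaults filled in).
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(p_adj_max = 1e-4, fc_min = 16, alpha = 0.05,
                   K_top = 500L, method = "moderated", seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out)) stop("config must set an output directory 'out'")
  if (!(config$fc_min > 1)) stop("fc_min must exceed 1")
  if (!(config$p_adj_max > 0 && config$p_adj_max < 1))
    stop("p_adj_max must be in (0,1)")
  if (!(config$alpha > 0 && config$alpha < 1))
    stop("alpha must be in (0,1)")
  if (!config$method %in% c("moderated", "ordinary"))
    stop("method must be 'moderated' or 'ordinary'")
  if (is.null(config$simulate)) {
    for (f in c("reference", "case_matrix"))
      if (is.null(config[[f]]) || !all(file.exists(config[[f]])))
        stop("config field '", f, "' missing or file not found")
    if (is.null(config$populations))
      stop("config must list population matrices (file(s) or directory)")
    pops <- config$populations
    if (length(pops) == 1L && dir.exists(pops))
      pops <- list.files(pops, pattern = "\\.(tsv|gct)$", full.names = TRUE)
    if (!length(pops) || !all(file.exists(pops)))
      stop("population matrix files not found")
    config$populations <- pops
    if (is.null(config$case_group) || is.null(config$control_group))
      stop("config must set case_group and control_group")
  }
  config
}

#' Run the profiling pipeline end to end
#'
#' Loads (or simulates) the inputs, identifies signatures for every
#' population, contrasts case vs control, builds the inflammation profile,
#' attributes the top induced transcripts, and writes all reports plus a
#' machine-readable manifest (parameters, input checksums, session
#' versions) to the output directory. Deterministic given the same inputs
#' and seed.
#'
#' @param config run configuration, see [validateRunConfig()].
#' @return invisibly, a list with the in-memory results (\code{profile},
#'   \code{sets}, \code{contrast}, \code{attribution}, \code{manifest}).
#' @export
runPipeline <- function(config) {
  config <- validateRunConfig(config)
  out <- config$out
  for (d in c("", "signatures", "profile", "attribution", "reports"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  checksums <- list()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    panel <- simulatePanel(
      nProbes = sim$n_probes, nPopulations = sim$n_populations,
      markersPerPop = sim$markers_per_pop,
      markerFC = sim$marker_fc %||% 32,
      sharedFrac = sim$shared_frac %||% 0,
      parents = if (!is.null(sim$parents)) as.integer(sim$parents),
      nB = sim$n_B %||% 3L, nA = sim$n_A %||% 10L,
      noiseSigma = sim$noise_sigma %||% 0.25, seed = config$seed)
    spiked <- unlist(sim$spiked) %||% numeric()
    truth <- spikeInTruth(spiked = spiked,
                          noiseSigma = sim$noise_sigma %||% 0.25,
                          seed = config$seed)
    experiment <- simulateExperiment(panel$reference, panel$populations,
                                     truth,
                                     nCase = sim$n_case %||% 3L,
                                     nControl = sim$n_control %||% 3L)
    caseGroup <- "case"; controlGroup <- "control"
    jsonlite::write_json(
      list(spiked = as.list(truth@spiked), seed = config$seed,
           noise_sigma = truth@noiseSigma, markers = panel$markers),
      file.path(out, "reports", "truth.json"),
      auto_unbox = TRUE, digits = NA)
  } else {
    dialect <- function(p) if (grepl("\\.gct$", p)) "gct" else "tsv"
    reference <- readExprMatrix(config$reference,
                                dialect = dialect(config$reference))
    pops <- lapply(config$populations,
                   function(p) readExprMatrix(p, dialect = dialect(p)))
    names(pops) <- sub("\\.(tsv|gct)$", "", basename(config$populations))
    panel <- list(reference = reference, populations = pops)
    experiment <- readExprMatrix(config$case_matrix,
                                 dialect = dialect(config$case_matrix))
    if (!is.null(config$sample_groups)) {
      gr <- utils::read.delim(config$sample_groups)
      SummarizedExperiment::colData(experiment)$group <-
        gr[[2L]][match(colnames(experiment), gr[[1L]])]
    }
    caseGroup <- config$case_group; controlGroup <- config$control_group
    checksums <- as.list(tools::md5sum(
      c(config$reference, config$populations, config$case_matrix)))
  }

  res <- profileFromPanel(panel, experiment,
                          caseGroup = caseGroup,
                          controlGroup = controlGroup,
                          pAdjMax = config$p_adj_max,
                          fcMin = config$fc_min, alpha = config$alpha,
                          classLabels = config$class_labels,
                          method = config$method)
  for (s in res$sets)
    writeSignatureSet(s, file.path(out, "signatures",
                                   paste0(populationId(s), ".tsv")))
  writeProfile(res$profile, file.path(out, "profile", "profile.tsv"))
  writeProfile(res$profile, file.path(out, "profile", "profile.json"))
  utils::write.table(res$contrast,
                     file.path(out, "profile", "contrast.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- withCallingHandlers(
    topInduced(res$contrast, K = config$K_top),
    warning = function(w) invokeRestart("muffleWarning"))
  attribution <- attributeTranscripts(top, res$profile, res$sets)
  writeAttribution(attribution,
                   file.path(out, "attribution", "assignments.tsv"))
  writeAttribution(attribution,
                   file.path(out, "attribution", "summary.json"))

  manifest <- list(
    package = "leukoProfiler",
    version = as.character(utils::packageVersion("leukoProfiler")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = config[c("p_adj_max", "fc_min", "alpha", "K_top",
                          "method", "seed")],
    input_checksums = checksums,
    n_populations = length(res$sets),
    n_significant = sum(profileRows(res$profile)$significant))
  jsonlite::write_json(manifest,
                       file.path(out, "reports", "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(attribution = attribution, manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
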