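# Shared fixtures and independent oracles for the suite.

# tiny deterministic 3x2 matrix
tinyMatrix <- function() {
  m <- matrix(c(1.5, 2.25, -0.5, 3, 4.125, 0.875), nrow = 3,
              dimnames = list(c("pA", "pB", "pC"), c("s1", "s2")))
  exprMatrix(m)
}

randomExpr <- function(nProbes, samples, mu = 8, sigma = 0.3,
                       groups = NULL) {
  m <- matrix(rnorm(nProbes * length(samples), mu, sigma), nProbes,
              dimnames = list(sprintf("p%04d", seq_len(nProbes)), samples))
  exprMatrix(m, groups = groups)
}

# hand-coded step-up adjustments, evaluated directly from the formulas;
# the package routes through stats::p.adjust, so these are independent
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m / seq(i, m)) * ps[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj
  out
}

bruteHochberg <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min((m - seq(i, m) + 1) * ps[seq(i, m)]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive enumeration of all C(m_total, n_draw) unordered draws
bruteHyperTail <- function(x, n_draw, k_bg, m_total) {
  if (n_draw == 0) return(as.numeric(x <= 0))
  draws <- combn(m_total, n_draw)
  succ <- colSums(draws <= k_bg)   # balls 1..k_bg are the successes
  mean(succ >= x)
}

# direct transcription of the moderated t formulas, independent of the
# package implementation: ordinary pooled variances, moment-matched prior
# on log s^2, shrunken variance, t with d0 + d df
bruteModeratedP <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  d <- n1 + n2 - 2
  s2 <- (rowSums((x1 - rowMeans(x1))^2) +
         rowSums((x2 - rowMeans(x2))^2)) / d
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    # invert trigamma by uniroot on a wide bracket
    d0 <- 2 * uniroot(function(v) trigamma(v) - evar,
                      c(1e-6, 1e8), tol = 1e-12)$root
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf; s02 <- mean(s2)
  }
  s2mod <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  tt <- (rowMeans(x2) - rowMeans(x1)) / sqrt(s2mod * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df = d0 + d)
}

# a SignatureSet built directly from a probe list (for set-arithmetic tests)
makeSet <- function(id, probes, class = "unknown", fc = 20, p = 1e-6) {
  new("SignatureSet", populationId = id, classLabel = class,
      transcripts = S4Vectors::DataFrame(
        probe_id = probes,
        fc = rep(fc, length(probes)),
        p_adj = rep(p, length(probes))),
      thresholds = c(p_adj_max = 1e-4, fc_min = 16))
}

# a minimal contrast table with prescribed directions
makeContrast <- function(probes, directions, lfc = NULL) {
  if (is.null(lfc))
    lfc <- ifelse(directions == "increased", 1,
                  ifelse(directions == "decreased", -1, 0))
  data.frame(probe_id = probes, log2fc = lfc, fc = 2^lfc,
             t = lfc, df = 4, p_raw = 0.5, p_bh = 0.5,
             direction = directions, flag = "",
             stringsAsFactors = FALSE)
}

# the benchmark spike-in scenario shared by several files: 5,000 probes,
# 20 populations, populations 1 and 2 spiked at f = 0.2, population 3 an
# 80%-marker-sharing decoy child of population 1; computed once per run
.scenarioCache <- new.env(parent = emptyenv())
spikeScenario <- function() {
  if (!exists("res", envir = .scenarioCache)) {
    parents <- rep(NA_integer_, 20); parents[3] <- 1L
    panel <- simulatePanel(nProbes = 5000, nPopulations = 20,
                           markersPerPop = 100, markerFC = 32,
                           sharedFrac = 0.8, parents = parents,
                           nB = 3, nA = 10, noiseSigma = 0.25, seed = 42)
    truth <- spikeInTruth(spiked = c(pop01 = 0.2, pop02 = 0.2),
                          noiseSigma = 0.25, seed = 42)
    experiment <- simulateExperiment(panel$reference, panel$populations,
                                     truth, nCase = 3, nControl = 3)
    res <- c(profileFromPanel(panel, experiment),
             list(panel = panel, truth = truth, experiment = experiment))
    assign("res", res, envir = .scenarioCache)
  }
  get("res", envir = .scenarioCache)
}
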