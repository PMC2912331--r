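#' Two-group differential expression contrast
#'
#' Per-probe comparison of two sample groups on the log2 scale. The fold
#' change is the ratio of geometric means, \code{2^(mean(group2) -
#' mean(group1))}. The \code{"moderated"} method shrinks each probe's pooled
#' variance toward a common prior fitted across all probes by empirical
#' Bayes: the prior degrees of freedom \code{d0} and variance \code{s0^2}
#' are obtained by moment-matching the scaled-F distribution of the sample
#' variances on the log scale, and the moderated variance is
#' \code{(d0*s0^2 + d*s^2) / (d0 + d)} with the t statistic referred to
#' \code{d0 + d} degrees of freedom. \code{"ordinary"} is the classical
#' pooled-variance two-sample t.
#'
#' @param se expression container (see [exprMatrix()]).
#' @param group1,group2 character vectors of sample ids (each of length
#'   >= 2, disjoint), or group labels if \code{se} carries groups.
#' @param method \code{"moderated"} (default) or \code{"ordinary"}.
#' @return a data.frame with one row per probe: \code{probe_id},
#'   \code{log2fc} (mean2 - mean1), \code{fc} (= 2^log2fc), \code{t},
#'   \code{df}, \code{p_raw}, \code{p_bh} (BH-adjusted), \code{direction}
#'   (\code{"increased"} / \code{"decreased"} / \code{"unchanged"} by strict
#'   sign of log2fc) and \code{flag} (\code{"zero_variance"} where both the
#'   within- and between-group variance vanish; there t = 0 and p = 1).
#' @export
probeContrast <- function(se, group1, group2,
                          method = c("moderated", "ordinary")) {
  method <- match.arg(method)
  x <- exprValues(se)
  resolve <- function(g) {
    if (all(g %in% colnames(x))) return(g)
    cd <- SummarizedExperiment::colData(se)
    if ("group" %in% colnames(cd) && all(g %in% cd$group))
      return(colnames(x)[cd$group %in% g])
    stop("unknown samples or groups: ",
         paste(setdiff(g, c(colnames(x),
                            SummarizedExperiment::colData(se)$group)),
               collapse = ", "))
  }
  g1 <- resolve(group1); g2 <- resolve(group2)
  if (length(intersect(g1, g2))) stop("groups must be disjoint")
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs at least 2 samples (got ",
         length(g1), " and ", length(g2), ")")
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m2 - m1
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df_res <- n1 + n2 - 2L
  s2 <- ss / df_res
  sem2 <- 1 / n1 + 1 / n2

  zerovar <- s2 <= 0 & lfc == 0
  if (method == "moderated") {
    fit <- fitVariancePrior(s2, df_res)
    d0 <- fit$d0; s02 <- fit$s02
    if (is.finite(d0)) {
      s2mod <- (d0 * s02 + df_res * s2) / (d0 + df_res)
      dft <- d0 + df_res
    } else {
      s2mod <- rep(s02, length(s2))
      dft <- Inf
    }
    tt <- lfc / sqrt(s2mod * sem2)
    pp <- 2 * stats::pt(-abs(tt), df = dft)
    dfv <- rep(dft, length(tt))
  } else {
    tt <- ifelse(s2 > 0, lfc / sqrt(s2 * sem2),
                 ifelse(lfc == 0, 0, sign(lfc) * Inf))
    pp <- 2 * stats::pt(-abs(tt), df = df_res)
    dfv <- rep(df_res, length(tt))
  }
  tt[zerovar] <- 0
  pp[zerovar] <- 1
  pp <- pmin(pp, 1)
  direction <- ifelse(lfc > 0, "increased",
                      ifelse(lfc < 0, "decreased", "unchanged"))
  data.frame(
    probe_id = rownames(x),
    log2fc = lfc, fc = 2^lfc,
    t = tt, df = dfv,
    p_raw = pp, p_bh = adjustBH(pp),
    direction = direction,
    flag = ifelse(zerovar, "zero_variance", ""),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Empirical-Bayes fit of the variance prior (d0, s0^2) by moment matching
# on log s^2. Probes with zero sample variance are excluded from the fit.
# With fewer than 10 informative probes the fit is unstable; fall back to
# the ordinary t (d0 = 0, with a warning).
fitVariancePrior <- function(s2, df_res) {
  s2pos <- s2[s2 > 0]
  if (length(s2pos) < 10L) {
    warning("fewer than 10 probes with positive variance; ",
            "falling back to ordinary t (no moderation)")
    return(list(d0 = 0, s02 = 0))
  }
  z <- log(s2pos)
  e <- z - digamma(df_res / 2) + log(df_res / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(df_res / 2)
  if (evar > 0) {
    d0 <- 2 * trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variance dispersion within chi-square expectation: infinite prior
    # df, every variance shrunk fully to the mean sample variance
    d0 <- Inf
    s02 <- mean(s2pos)
  }
  list(d0 = d0, s02 = s02)
}

# Newton solve of trigamma(x) = y; monotone decreasing so the iteration
# converges from x0 = 0.5 + 1/y.
trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR-controlling step-up adjustment, returned in input order:
#' \code{q(i) = min_{j >= i} (m/j) p(j)} over the ascending order
#' statistics, clipped at 1.
#'
#' @param p numeric vector of p-values in [0,1].
#' @return adjusted p-values, same length and order.
#' @export
adjustBH <- function(p) {
  checkPValues(p)
  stats::p.adjust(p, method = "BH")
}

#' Hochberg step-up adjustment
#'
#' Family-wise step-up adjustment, valid under non-negative dependence:
#' \code{adj(i) = min_{j >= i} (m - j + 1) p(j)} over the ascending order
#' statistics, clipped at 1, returned in input order. Used to adjust the
#' hypergeometric profile tests across candidate populations.
#'
#' @inheritParams adjustBH
#' @return adjusted p-values, same length and order.
#' @export
adjustHochberg <- function(p) {
  checkPValues(p)
  stats::p.adjust(p, method = "hochberg")
}

checkPValues <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0,1] with no missing values")
  invisible(p)
}

#' Upper tail of the hypergeometric distribution
#'
#' \code{P(X >= x)} when \code{n_draw} balls are drawn without replacement
#' from an urn of \code{m_total} balls of which \code{k_bg} are successes.
#' Computed in log space so that extreme tails (down to the smallest
#' representable double) remain accurate; \code{log.p = TRUE} returns the
#' natural-log tail for tails beyond double range.
#'
#' @param x observed successes in the sample.
#' @param n_draw sample size.
#' @param k_bg successes in the background.
#' @param m_total background size.
#' @param log.p return the natural logarithm of the tail.
#' @return the tail probability (or its log).
#' @export
hypergeomTail <- function(x, n_draw, k_bg, m_total, log.p = FALSE) {
  stopifnot(length(x) == 1L, length(n_draw) == 1L,
            length(k_bg) == 1L, length(m_total) == 1L)
  if (x < 0 || x > n_draw || n_draw > m_total || k_bg > m_total || k_bg < 0)
    stop("hypergeometric bounds violated: need 0 <= x <= n_draw <= m_total ",
         "and 0 <= k_bg <= m_total")
  lp <- stats::phyper(x - 1, m = k_bg, n = m_total - k_bg, k = n_draw,
                      lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Platform-wide direction counts from a contrast
#'
#' The hypergeometric null for the profile tests: how many probes on the
#' whole platform are increased and decreased in the case/control contrast
#' (all probes, significant or not; exact-zero fold changes count as
#' neither).
#'
#' @param contrast a data.frame from [probeContrast()].
#' @return named numeric: \code{m_total}, \code{k_increased},
#'   \code{k_decreased}.
#' @export
backgroundCounts <- function(contrast) {
  c(m_total = nrow(contrast),
    k_increased = sum(contrast$direction == "increased"),
    k_decreased = sum(contrast$direction == "decreased"))
}

#' Cluster contrasts by fold-change correlation
#'
#' Pairwise Pearson correlation between log2 fold-change vectors of several
#' contrasts (restricted to a probe filter, e.g. probes significant in at
#' least one contrast), converted to the distance 1 - r and clustered
#' agglomeratively.
#'
#' @param contrasts named list of [probeContrast()] results over a shared
#'   probe universe.
#' @param probeFilter character vector of probe ids to correlate over.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default \code{"average"}).
#' @return a list with \code{correlation} (matrix), \code{hclust}, and
#'   \code{newick} (tree with merge-height branch lengths).
#' @export
clusterContrasts <- function(contrasts, probeFilter, linkage = "average") {
  if (length(contrasts) < 2L) stop("need at least 2 contrasts")
  if (is.null(names(contrasts))) stop("contrasts must be named")
  if (!length(probeFilter)) stop("probeFilter is empty")
  fcm <- vapply(contrasts, function(cc) {
    v <- cc$log2fc[match(probeFilter, cc$probe_id)]
    if (anyNA(v)) stop("probeFilter contains probes absent from a contrast")
    v
  }, numeric(length(probeFilter)))
  const <- apply(fcm, 2L, function(v) stats::sd(v) == 0)
  if (any(const))
    stop("constant fold-change vector, correlation undefined: ",
         paste(names(contrasts)[const], collapse = ", "))
  r <- stats::cor(fcm)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  list(correlation = r, hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)))
}
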