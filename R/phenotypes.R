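#' Correlate probe expression with a phenotype
#'
#' Per-probe Pearson correlation between expression across study samples and
#' a numeric phenotype (e.g. total cholesterol), then a comparison of the
#' mean correlation inside a probe set of interest against the background of
#' all other probes (Welch two-sample t-test on the correlation values).
#' Background excludes set members.
#'
#' @param se expression container over the study samples.
#' @param phenotype named numeric vector (names = sample ids) or a
#'   single-column selection from [readPhenotypes()].
#' @param probeSet character vector of probes of interest.
#' @return list: \code{r} (named per-probe correlations),
#'   \code{set_mean_r}, \code{background_mean_r}, \code{t_test_p}
#'   (NA with a warning when the background is empty), \code{n_samples}.
#' @export
phenotypeCorrelations <- function(se, phenotype, probeSet) {
  if (is.null(names(phenotype))) stop("phenotype must be named by sample id")
  phenotype <- phenotype[!is.na(phenotype)]
  shared <- intersect(colnames(se), names(phenotype))
  if (length(shared) < 3L)
    stop("need >= 3 samples with both expression and phenotype (got ",
         length(shared), ")")
  ph <- phenotype[shared]
  if (stats::sd(ph) == 0) stop("phenotype is constant across samples")
  x <- exprValues(se)[, shared, drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(x), ph)))
  names(r) <- rownames(x)
  inset <- names(r) %in% probeSet
  rs <- r[inset & !is.na(r)]
  rb <- r[!inset & !is.na(r)]
  if (!length(rb)) {
    warning("background is empty; t-test not performed")
    tp <- NA_real_
  } else if (length(rs) < 2L || length(rb) < 2L) {
    tp <- NA_real_   # too few correlations on one side for a t-test
  } else {
    tp <- stats::t.test(rs, rb, var.equal = FALSE)$p.value
  }
  list(r = r,
       set_mean_r = mean(rs),
       background_mean_r = if (length(rb)) mean(rb) else NA_real_,
       t_test_p = tp,
       n_samples = length(shared))
}

#' Screen for transcripts predicting population scores
#'
#' Correlates each probe's expression across the reference-panel samples
#' with the log2 infiltration score (n1/n2 ratio) of the population each
#' sample belongs to, and reports the top-k positively correlated probes
#' with their least-squares slope and regression p-value. Populations with
#' an infinite ratio enter at a capped score (twice the largest finite
#' ratio) so the log is defined; probes with constant expression are
#' excluded with a flag.
#'
#' @param panel expression container of all population samples, with a
#'   \code{group} column naming each sample's population.
#' @param profile the [InflammationProfile-class] providing ratios.
#' @param k number of top predictors (default 200).
#' @return list: \code{table} (per-probe \code{r}, \code{slope}, \code{p},
#'   descending r), \code{top} (first k probe ids), \code{excluded}
#'   (constant probes), \code{scores} (per-sample log2 score used).
#' @export
scorePredictorScreen <- function(panel, profile, k = 200L) {
  cd <- SummarizedExperiment::colData(panel)
  if (!"group" %in% colnames(cd))
    stop("panel must carry a group column mapping samples to populations")
  r <- as.data.frame(profileRows(profile))
  ratio <- stats::setNames(r$ratio, r$population_id)
  miss <- setdiff(unique(cd$group), names(ratio))
  if (length(miss))
    stop("panel populations absent from profile: ",
         paste(miss, collapse = ", "))
  fin <- ratio[is.finite(ratio)]
  if (length(fin) < 3L)
    stop("need >= 3 populations with a finite ratio (got ",
         length(fin), ")")
  cap <- 2 * max(fin)
  ratio[is.infinite(ratio)] <- cap
  score <- log2(ratio[cd$group])
  if (anyNA(score)) stop("NA population score in panel")
  x <- exprValues(panel)
  constant <- apply(x, 1L, function(v) stats::sd(v) == 0)
  xs <- x[!constant, , drop = FALSE]
  m <- ncol(xs)
  sc <- as.vector(scale(score))
  rr <- as.vector(stats::cor(t(xs), score))
  slope <- as.vector(stats::cov(t(xs), score)) / stats::var(score)
  tstat <- rr * sqrt((m - 2) / pmax(1 - rr^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = m - 2)
  tab <- data.frame(probe_id = rownames(xs), r = rr, slope = slope, p = pv,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r, tab$probe_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       top = utils::head(tab$probe_id, k),
       excluded = rownames(x)[constant],
       scores = stats::setNames(score, colnames(x)))
}

#' Term over-representation in a gene set
#'
#' One-sided hypergeometric over-representation of annotation terms (e.g.
#' pathway membership) within a gene set, against an annotated universe.
#' Raw p-values are flagged at p < 0.05 (unadjusted); a BH column is
#' provided alongside.
#'
#' @param geneSet character vector of genes of interest (subset of
#'   \code{universe}).
#' @param annotation gene-to-term data.frame from [readAnnotation()]
#'   (columns \code{gene}, \code{term_id}, optionally \code{term_name}).
#' @param universe character vector of all candidate genes.
#' @return data.frame per term: \code{term_id, term_name, x, n_draw, k_bg,
#'   m_total, p_raw, p_bh, significant}, ascending p.
#' @export
termOverrepresentation <- function(geneSet, annotation, universe) {
  if (!length(geneSet)) stop("geneSet is empty")
  if (length(setdiff(geneSet, universe)))
    stop("geneSet must be a subset of the universe")
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  annotated <- unique(ann$gene)
  m_total <- length(annotated)
  n_draw <- length(intersect(geneSet, annotated))
  terms <- split(ann$gene, ann$term_id)
  res <- do.call(rbind, lapply(names(terms), function(tid) {
    genes <- unique(terms[[tid]])
    x <- length(intersect(geneSet, genes))
    data.frame(term_id = tid,
               term_name = if ("term_name" %in% names(ann))
                 ann$term_name[match(tid, ann$term_id)] else tid,
               x = x, n_draw = n_draw, k_bg = length(genes),
               m_total = m_total,
               p_raw = hypergeomTail(x, n_draw, length(genes), m_total),
               stringsAsFactors = FALSE)
  }))
  res$p_bh <- adjustBH(res$p_raw)
  res$significant <- res$p_raw < 0.05
  res <- res[order(res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
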