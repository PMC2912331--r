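#' Construct a log2 expression matrix container
#'
#' Wraps a probes-by-samples matrix of log2 intensities in a
#' \link[SummarizedExperiment]{SummarizedExperiment} (assay \code{"log2expr"},
#' optional \code{group} column in \code{colData}). All downstream functions
#' take and return this container. Values must be finite; probe and sample
#' ids unique.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids), log2 intensity units.
#' @param groups optional character vector of group labels, one per sample
#'   (named by sample id or in column order).
#' @param linearScale if TRUE, \code{values} are linear intensities and are
#'   clipped at \code{pseudoFloor} then log2-transformed.
#' @param pseudoFloor lower clip applied before the log2 transform of
#'   linear-scale input (default 1, i.e. log2 values are non-negative).
#' @return a \code{SummarizedExperiment} with one assay \code{"log2expr"}.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' se <- exprMatrix(m, groups = c("ctl", "ctl"))
#' @export
exprMatrix <- function(values, groups = NULL, linearScale = FALSE,
                       pseudoFloor = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have probe rownames and sample colnames")
  if (linearScale)
    values <- log2(pmax(values, pseudoFloor))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) {
      if (!setequal(names(groups), colnames(values)))
        stop("group names do not match sample ids")
      groups <- groups[colnames(values)]
    } else if (length(groups) != ncol(values)) {
      stop("groups must have one label per sample")
    }
    SummarizedExperiment::colData(se)$group <- unname(groups)
  }
  validateExprMatrix(se)
  se
}

# Invariant checks shared by the constructor and the readers.
validateExprMatrix <- function(se) {
  x <- exprValues(se)
  if (anyDuplicated(rownames(x)))
    stop("duplicate probe ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (!all(is.finite(x)))
    stop("non-finite values in expression matrix (",
         sum(!is.finite(x)), " cells)")
  invisible(se)
}

#' Extract the log2 expression assay
#'
#' @param se a \code{SummarizedExperiment} built by [exprMatrix()] or
#'   [readExprMatrix()].
#' @return the probes-by-samples numeric matrix.
#' @export
exprValues <- function(se) {
  SummarizedExperiment::assay(se, "log2expr")
}

#' Sample ids belonging to a group
#'
#' @param se an expression container with a \code{group} column.
#' @param group group label to select.
#' @return character vector of sample ids.
#' @export
groupSamples <- function(se, group) {
  cd <- SummarizedExperiment::colData(se)
  if (!"group" %in% colnames(cd))
    stop("expression matrix carries no group labels")
  colnames(se)[cd$group == group]
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' TSV dialect: header \code{probe_id<TAB>sample1<TAB>...}, one probe per
#' row. GCT dialect: \code{#1.2} preamble, dimensions line, then
#' \code{Name<TAB>Description<TAB>samples...}. Duplicate probe rows, missing
#' and non-numeric cells are rejected with the offending location named.
#'
#' @param path file to read.
#' @param dialect \code{"tsv"} or \code{"gct"}.
#' @inheritParams exprMatrix
#' @return a \code{SummarizedExperiment} (assay \code{"log2expr"}).
#' @export
readExprMatrix <- function(path, dialect = c("tsv", "gct"),
                           linearScale = FALSE, pseudoFloor = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  skip <- 0L
  if (dialect == "gct") {
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("malformed GCT preamble at line 1 (expected '#1.2'): ", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions at line 2: ", path)
    skip <- 2L
  }
  if (length(lines) <= skip + 1L)
    stop("no data rows in ", path)
  header <- strsplit(lines[[skip + 1L]], "\t", fixed = TRUE)[[1L]]
  nmeta <- if (dialect == "gct") 2L else 1L
  if (length(header) < nmeta + 1L)
    stop("malformed header at line ", skip + 1L, " in ", path)
  samples <- header[-seq_len(nmeta)]
  body <- lines[-seq_len(skip + 1L)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("row at line ", skip + 1L + bad[[1L]], " has ",
         lengths(cells)[bad[[1L]]], " fields, expected ", length(header))
  probes <- vapply(cells, `[[`, character(1L), 1L)
  if (anyDuplicated(probes))
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  vals <- matrix(NA_real_, length(probes), length(samples),
                 dimnames = list(probes, samples))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]][-seq_len(nmeta)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[[1L]]
      stop("non-numeric cell at probe '", probes[[i]], "', sample '",
           samples[[j]], "' (line ", skip + 1L + i, ")")
    }
    vals[i, ] <- v
  }
  if (dialect == "gct" && (dims[[1L]] != nrow(vals) || dims[[2L]] != ncol(vals)))
    stop("GCT dimensions line says ", dims[[1L]], "x", dims[[2L]],
         " but body is ", nrow(vals), "x", ncol(vals))
  exprMatrix(vals, linearScale = linearScale, pseudoFloor = pseudoFloor)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' Values are serialized with full double precision, so
#' \code{readExprMatrix(writeExprMatrix(se))} reproduces the matrix exactly.
#'
#' @param se the expression container.
#' @param path output file.
#' @param dialect \code{"tsv"} or \code{"gct"}.
#' @return \code{path}, invisibly.
#' @export
writeExprMatrix <- function(se, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  x <- exprValues(se)
  if (ncol(x) == 0L || nrow(x) == 0L)
    stop("refusing to write a degenerate matrix (",
         nrow(x), " probes x ", ncol(x), " samples)")
  fmt <- function(v) sprintf("%.17g", v)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    if (dialect == "gct")
      paste(c(rownames(x)[i], "na", fmt(x[i, ])), collapse = "\t")
    else
      paste(c(rownames(x)[i], fmt(x[i, ])), collapse = "\t")
  }, character(1L))
  header <- if (dialect == "gct")
    paste(c("Name", "Description", colnames(x)), collapse = "\t")
  else
    paste(c("probe_id", colnames(x)), collapse = "\t")
  lines <- c(
    if (dialect == "gct") c("#1.2", paste(nrow(x), ncol(x), sep = "\t")),
    header, rows)
  writeLines(lines, path)
  invisible(path)
}

#' Column-concatenate two probe-aligned expression matrices
#'
#' Joins a reference matrix and a population matrix measured on the same
#' probe universe (mirroring joint handling of reference and population
#' arrays before a contrast). Probe order follows \code{a}; sample ids must
#' be disjoint; group labels are preserved.
#'
#' @param a,b expression containers over identical probe sets.
#' @return a joined \code{SummarizedExperiment}.
#' @export
joinMatrices <- function(a, b) {
  pa <- rownames(a); pb <- rownames(b)
  if (!setequal(pa, pb)) {
    diff <- c(setdiff(pa, pb), setdiff(pb, pa))
    stop("probe universes differ (", length(diff), " probes): ",
         paste(utils::head(diff, 10L), collapse = ", "))
  }
  if (length(intersect(colnames(a), colnames(b))))
    stop("sample ids overlap: ",
         paste(utils::head(intersect(colnames(a), colnames(b)), 10L),
               collapse = ", "))
  b <- b[pa, ]
  ga <- SummarizedExperiment::colData(a)
  gb <- SummarizedExperiment::colData(b)
  groups <- NULL
  if ("group" %in% colnames(ga) || "group" %in% colnames(gb)) {
    groups <- c(
      if ("group" %in% colnames(ga)) ga$group else rep(NA_character_, ncol(a)),
      if ("group" %in% colnames(gb)) gb$group else rep(NA_character_, ncol(b)))
  }
  exprMatrix(cbind(exprValues(a), exprValues(b)), groups = groups)
}

#' Read a 2- or 3-column annotation table
#'
#' Two columns map probes to gene symbols; three columns map genes to terms
#' (\code{gene, term_id, term_name}). Duplicate (key, value) pairs are
#' dropped with a warning.
#'
#' @param path TSV file with a header row.
#' @return a data.frame with standardized column names
#'   (\code{probe_id, gene} or \code{gene, term_id, term_name}).
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) == 2L) names(df) <- c("probe_id", "gene")
  else if (ncol(df) == 3L) names(df) <- c("gene", "term_id", "term_name")
  else stop("annotation table must have 2 or 3 columns, found ", ncol(df))
  dup <- duplicated(df[, 1:2])
  if (any(dup)) {
    warning(sum(dup), " duplicate annotation pairs dropped")
    df <- df[!dup, , drop = FALSE]
  }
  df
}

#' Read a per-sample phenotype table
#'
#' @param path TSV file: first column \code{sample_id}, remaining columns
#'   numeric phenotype measurements (empty cells = missing).
#' @return a data.frame with rownames = sample ids and numeric columns.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample ids in phenotype table")
  rownames(df) <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  notnum <- !vapply(df, is.numeric, logical(1L))
  if (any(notnum))
    stop("non-numeric phenotype columns: ",
         paste(names(df)[notnum], collapse = ", "))
  df
}
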