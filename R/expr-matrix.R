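#' Construct an expression matrix object
#'
#' A thin S3 container for a genes-by-samples matrix of normalized expression
#' values, with optional binary group labels. Gene and sample identifiers are
#' the dimnames and must be unique; values must be numeric and complete.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param labels optional per-sample group labels: a vector with exactly two
#'   distinct values, either named by sample id or in column order. Stored as
#'   a factor; the second level is treated as the positive (case) class.
#' @return an object of class `expr_matrix` with elements `values`,
#'   `gene_ids`, `sample_ids`, `labels`.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(x, labels = c(0, 0, 1, 1))
#' em
expression_matrix <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers; collapse before constructing")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (anyNA(values))
    stop("missing values present; apply a missing-value policy first")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      if (!setequal(names(labels), colnames(values)))
        stop("label names do not cover the samples")
      labels <- labels[colnames(values)]
    } else if (length(labels) != ncol(values)) {
      stop("labels must have one entry per sample")
    }
    labels <- if (is.factor(labels)) droplevels(labels)
              else factor(as.vector(labels))
    if (nlevels(labels) != 2L)
      stop("labels must have exactly 2 classes, got ", nlevels(labels))
    names(labels) <- colnames(values)
  }
  structure(
    list(values = values, gene_ids = rownames(values),
         sample_ids = colnames(values), labels = labels),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("Labels: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Load an expression matrix from delimited text
#'
#' Reads a TSV/CSV table with one header row and the identifiers in the first
#' column, normalizes orientation to genes x samples, mean-collapses duplicate
#' gene rows, and applies a missing-value policy.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param orientation `"genes"` if genes are in rows (default) or `"samples"`
#'   if samples are in rows.
#' @param missing_policy `"drop-gene"` (default) removes genes with any
#'   missing value; `"mean-impute"` replaces missing values with the gene
#'   mean.
#' @param labels optional labels passed through to [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
load_expression_matrix <- function(path,
                                   orientation = c("genes", "samples"),
                                   missing_policy = c("drop-gene", "mean-impute"),
                                   labels = NULL) {
  orientation <- match.arg(orientation)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("cannot read expression file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an identifier column plus data columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cell found after the identifier column")
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers in ", path)
  if (anyDuplicated(rownames(m))) {
    # deduplication rule: duplicate gene rows are collapsed by their mean
    key <- rownames(m)
    first <- !duplicated(key)
    collapsed <- rowsum(m, key, reorder = FALSE)
    counts <- as.vector(table(key)[rownames(collapsed)])
    m <- collapsed / counts
    m <- m[unique(key[first]), , drop = FALSE]
  }
  if (anyNA(m)) {
    if (missing_policy == "drop-gene") {
      keep <- rowSums(is.na(m)) == 0L
      m <- m[keep, , drop = FALSE]
    } else {
      for (i in which(rowSums(is.na(m)) > 0L)) {
        mu <- mean(m[i, ], na.rm = TRUE)
        m[i, is.na(m[i, ])] <- mu
      }
    }
  }
  expression_matrix(m, labels = labels)
}

#' Load sample labels from a two-column table
#'
#' @param path TSV with header and columns sample id, label.
#' @return named vector of labels.
#' @export
load_labels <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("labels file needs (sample_id, label) columns")
  setNames(df[[2L]], as.character(df[[1L]]))
}

#' Filter genes by mean and coefficient of variation
#'
#' Retains genes whose mean exceeds `mean_min` and whose coefficient of
#' variation (sample sd / mean, n-1 denominator) exceeds `cv_min`. Order is
#' preserved; the operation is idempotent.
#'
#' @param em an [expression_matrix()].
#' @param cv_min minimum coefficient of variation (default 0.2, the
#'   conventional low-variability cutoff for expression QC).
#' @param mean_min minimum mean expression (default 0; no published numeric
#'   intensity floor, so the cutoff is exposed rather than fixed).
#' @return the filtered [expression_matrix()].
#' @export
filter_genes <- function(em, cv_min = 0.2, mean_min = 0) {
  stopifnot(inherits(em, "expr_matrix"), cv_min >= 0)
  mu <- rowMeans(em$values)
  s <- apply(em$values, 1L, sd)
  cv <- ifelse(mu == 0, Inf * sign(s), s / mu)
  cv[s == 0] <- 0
  keep <- mu > mean_min & cv > cv_min
  if (!any(keep)) {
    stop(sprintf(
      "gene filter removed all %d genes (mean_min=%g, cv_min=%g)",
      nrow(em$values), mean_min, cv_min))
  }
  message(sprintf("filter_genes: kept %d of %d genes (cv_min=%g, mean_min=%g)",
                  sum(keep), length(keep), cv_min, mean_min))
  expression_matrix(em$values[keep, , drop = FALSE], labels = em$labels)
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene_id = em$gene_ids, em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
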