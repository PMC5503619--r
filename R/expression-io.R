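#' Construct an expression matrix
#'
#' A gene-by-sample matrix of expression intensities with unique gene and
#' sample identifiers and an explicit scale flag. Linear-scale matrices must
#' be nonnegative (NMF-admissible after flooring); log2-scale matrices may
#' contain negative values.
#'
#' @param values numeric matrix, genes as rows and samples as columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param scale `"linear"` or `"log2"`.
#' @return An `expr_matrix`: the numeric matrix with a `scale` attribute.
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  if (anyNA(values))
    stop("missing values are not supported")
  if (scale == "linear" && any(values < 0))
    stop("linear-scale expression must be nonnegative")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Scale flag of an expression matrix
#' @param m an `expr_matrix`.
#' @return `"linear"` or `"log2"`.
#' @export
expr_scale <- function(m) attr(m, "scale")

# internal: strip class, keep plain matrix
expr_values <- function(m) {
  attr(m, "scale") <- NULL
  unclass(m)
}

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be fully numeric.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param scale scale flag to attach, `"linear"` by default.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "csv"),
                            scale = c("linear", "log2")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected gene-id column plus >= 1 sample column")
  gene_ids <- df[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5),
               collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) vals <- matrix(vals, nrow = 1L,
                                       dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 gene_ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  if (anyNA(vals)) stop("missing values are not supported")
  rownames(vals) <- gene_ids
  expr_matrix(vals, scale = scale)
}

#' Write an expression matrix to a delimited text file
#'
#' Exact inverse of [read_expression()]: the round trip reproduces values to
#' full printed precision (15 significant digits).
#'
#' @param m an [expr_matrix()].
#' @param path output file path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(m), expr_values(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Requires columns `sample_id` and `tissue` (values `tumor`/`normal`);
#' optional columns such as `external_label`, `group`, `time_months`,
#' `event` and arbitrary covariates pass through.
#'
#' @param path file path to a TSV/CSV annotation table.
#' @param format `"tsv"` or `"csv"`.
#' @return A data frame.
#' @export
read_annotation <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  ann <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "tissue")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation lacks required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotation")
  bad <- setdiff(unique(ann$tissue), c("tumor", "normal"))
  if (length(bad)) stop("tissue must be 'tumor' or 'normal'; found: ",
                        paste(bad, collapse = ", "))
  ann
}

#' Quantile-normalize a linear-scale expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-column mean of order statistics; within-column ranks are preserved
#' and tied values receive the mean of the tied reference quantiles.
#'
#' @param m a linear-scale [expr_matrix()] with no missing values.
#' @return A quantile-normalized linear-scale [expr_matrix()].
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "linear")
    stop("quantile normalization operates on linear-scale intensities")
  x <- expr_values(m)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  expr_matrix(out, scale = "linear")
}

#' Convert between linear and log2 expression scales
#'
#' `to_linear()` maps `x -> 2^x` elementwise; `to_log2()` maps
#' `x -> log2(x + pseudo)`. Composing the two with `pseudo = 0` on positive
#' data is the identity to within 1e-9.
#'
#' @param m an [expr_matrix()].
#' @param pseudo small nonnegative pseudo-count added before the log.
#' @return An [expr_matrix()] on the other scale.
#' @export
to_linear <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") stop("to_linear expects a log2-scale matrix")
  expr_matrix(2^expr_values(m), scale = "linear")
}

#' @rdname to_linear
#' @export
to_log2 <- function(m, pseudo = 0) {
  stopifnot(inherits(m, "expr_matrix"), pseudo >= 0)
  if (expr_scale(m) != "linear") stop("to_log2 expects a linear-scale matrix")
  x <- expr_values(m)
  if (any(x <= -pseudo)) stop("matrix contains values <= -pseudo")
  expr_matrix(log2(x + pseudo), scale = "log2")
}

#' Median-center genes of a log2 matrix
#'
#' Subtracts each gene's across-sample median, the convention used for
#' correlation-based sample clustering displays (values above/below the
#' gene's sample median).
#'
#' @param m a log2-scale [expr_matrix()].
#' @return A centered log2-scale [expr_matrix()].
#' @export
center_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (expr_scale(m) != "log2") stop("center_genes expects a log2-scale matrix")
  x <- expr_values(m)
  expr_matrix(x - matrixStats::rowMedians(x), scale = "log2")
}
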