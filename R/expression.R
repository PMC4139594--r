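#' Construct an expression set
#'
#' The pipeline's expression container: a genes x samples matrix of
#' non-negative values (ISH expression energy, microarray intensity or
#' RPKM-like units) plus a sample sheet describing each column. Modelled on
#' the values-plus-targets layout used by microarray analysis packages.
#'
#' Validation enforces: numeric, finite, non-negative values; unique gene
#' symbols in rownames; a bijection between matrix columns and sample-sheet
#' rows keyed by `sample_id`.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `structure`, `age`,
#'   `species` and optionally `zone`.
#' @return an object of class `expr_set` with elements `values` and `samples`.
#' @export
expr_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", rownames(values)[bad[1]],
         "', sample '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("gene symbols (rownames) must be present and unique", call. = FALSE)
  }
  req <- c("sample_id", "structure", "age", "species")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  missing <- setdiff(colnames(values), samples$sample_id)
  if (length(missing)) {
    stop("sample(s) missing from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set: ", nrow(x$values), " genes x ", ncol(x$values), " samples (",
      x$samples$species[1], ")\n", sep = "")
  cat("  structures: ", paste(unique(x$samples$structure), collapse = ", "), "\n",
      sep = "")
  cat("  ages: ", paste(unique(x$samples$age), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read an expression matrix and sample sheet from TSV files
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column named `gene`; the sample sheet has one row per sample id.
#' Lines beginning with `#` are ignored in both files.
#'
#' @param matrix_path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return a validated [expr_set()].
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path) {
  raw <- read.delim(matrix_path, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(raw) || names(raw)[1] != "gene") {
    stop("expression matrix must have a first column named 'gene'", call. = FALSE)
  }
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbol in expression matrix: '",
         genes[duplicated(genes)][1], "'", call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    stop("non-numeric expression value in column '", names(raw)[-1][bad], "'",
         call. = FALSE)
  }
  rownames(vals) <- genes
  samples <- read.delim(sample_sheet_path, sep = "\t", comment.char = "#",
                        stringsAsFactors = FALSE)
  expr_set(vals, samples)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression_matrix()]; the round trip preserves values
#' and metadata.
#'
#' @param x an [expr_set()].
#' @param matrix_path output path for the expression TSV.
#' @param sample_sheet_path output path for the sample sheet TSV.
#' @return invisibly, a character vector of the two paths.
#' @export
write_expression_matrix <- function(x, matrix_path, sample_sheet_path) {
  stopifnot(inherits(x, "expr_set"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, sample_sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}
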