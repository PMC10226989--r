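#' Read an expression matrix and survival table and align them
#'
#' Loads a genes-by-samples expression matrix and a per-sample survival table,
#' restricts both to the samples they share (in a common order), and drops
#' genes whose expression is constant across the retained samples. Constant
#' genes carry no grouping information: both the PCA split and the SAM pooled
#' standard error are degenerate for them.
#'
#' The expression file is tab-separated with the gene identifier in the first
#' column and one column per sample (header row = sample identifiers). The
#' survival file is tab-separated with header `sample_id`, `time`, `event`;
#' `time` must be positive and `event` must be 0 (censored) or 1 (event).
#'
#' @param expr_path Path to the expression TSV.
#' @param surv_path Path to the survival TSV.
#' @param log_transform If `TRUE`, values are replaced by `log2(value + 1)`
#'   before the zero-variance filter. Off by default: microarray matrices are
#'   usually already on a log scale, RSEM-style abundances are not.
#' @return A list with `expr` (numeric matrix, genes in rows, samples in
#'   columns, dimnames set) and `surv` (data frame with columns `sample_id`,
#'   `time`, `event`, rows aligned to the expression columns).
#' @export
load_dataset <- function(expr_path, surv_path, log_transform = FALSE) {
  expr <- read_expression(expr_path)
  surv <- read_survival(surv_path)

  shared <- intersect(colnames(expr), surv$sample_id)
  if (length(shared) < 2L) {
    stop("no shared samples between expression and survival inputs")
  }
  expr <- expr[, shared, drop = FALSE]
  surv <- surv[match(shared, surv$sample_id), , drop = FALSE]
  rownames(surv) <- NULL

  if (log_transform) {
    if (any(expr < -1)) stop("log2(x+1) transform requires values > -1")
    expr <- log2(expr + 1)
  }

  keep <- matrixStats_row_var(expr) > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance gene(s) dropped at load time")
    expr <- expr[keep, , drop = FALSE]
  }
  if (nrow(expr) == 0L) stop("no genes with nonzero variance remain")

  list(expr = expr, surv = surv)
}

# Row variances without a matrixStats dependency.
matrixStats_row_var <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

#' Read an expression TSV (genes in rows, samples in columns)
#'
#' @param path File path.
#' @return Numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression file needs a gene column plus samples")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression value(s) in ", path)
  if (anyNA(vals)) stop("missing expression value(s) in ", path)
  samples <- colnames(vals)
  if (anyDuplicated(samples)) stop("duplicate sample id(s) in expression header")
  dimnames(vals) <- list(genes, samples)
  vals
}

#' Read a survival table TSV
#'
#' @param path File path to a TSV with columns `sample_id`, `time`, `event`.
#' @return Data frame with those three columns.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% colnames(tab))) {
    stop("survival file must have columns: ", paste(need, collapse = ", "))
  }
  surv <- data.frame(sample_id = as.character(tab$sample_id),
                     time = as.numeric(tab$time),
                     event = as.integer(tab$event),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(surv$sample_id)) stop("duplicate sample id(s) in survival table")
  if (anyNA(surv$time) || any(surv$time <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0L, 1L))) stop("event indicator must be 0 or 1")
  surv
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene`, then one column per
#' sample.
#'
#' @param expr Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a survival table as TSV
#'
#' @param surv Data frame with columns `sample_id`, `time`, `event`.
#' @param path Output path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv[, c("sample_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene scores as a two-column TSV
#'
#' Rows are ordered by descending score, ties broken by ascending gene id, so
#' the file doubles as a ranked gene list. An empty score map yields a
#' header-only file.
#'
#' @param scores Named integer/numeric vector mapping gene id to score.
#' @param path Output path.
#' @export
write_gene_scores <- function(scores, path) {
  if (length(scores)) {
    ord <- order(-as.numeric(scores), names(scores), method = "radix")
    tab <- data.frame(gene = names(scores)[ord],
                      score = as.numeric(scores)[ord],
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(gene = character(0), score = numeric(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene scores written by [write_gene_scores()]
#'
#' @param path File path.
#' @return Named numeric vector of scores.
#' @export
read_gene_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$score), as.character(tab$gene))
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines are skipped; duplicate symbols are collapsed with a warning.
#'
#' @param path File path.
#' @return Character vector of distinct gene symbols.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty gene set: ", path)
  if (anyDuplicated(lines)) {
    warning("duplicate gene symbol(s) collapsed in ", path)
    lines <- unique(lines)
  }
  lines
}
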