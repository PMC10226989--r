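#' SAM two-class unpaired d-statistics
#'
#' For each gene computes the Tusher-style moderated statistic
#' `d = (mean_A - mean_B) / (s + s0)`, where `s` is the pooled standard error
#' `sqrt((1/nA + 1/nB) * (SS_A + SS_B) / (nA + nB - 2))` and the fudge factor
#' `s0` is the median of the per-gene `s` values. The fudge factor damps the
#' statistic for genes whose pooled error is near zero, which would otherwise
#' top the ranking on noise alone. Only the ranking by `|d|` feeds downstream
#' steps, so no permutation-based false-discovery estimation is attached.
#'
#' @param expr Numeric expression matrix (genes x samples).
#' @param labels Character vector in `c("A","B")` per sample (aligned to
#'   columns).
#' @return A list with `gene_ids`, `d`, `s` (named numeric vectors) and the
#'   scalar `s0`.
#' @export
sam_statistics <- function(expr, labels) {
  stopifnot(ncol(expr) == length(labels))
  in_a <- labels == "A"
  n_a <- sum(in_a)
  n_b <- sum(!in_a)
  if (n_a < 2L || n_b < 2L) stop("both groups need at least 2 samples")

  xa <- expr[, in_a, drop = FALSE]
  xb <- expr[, !in_a, drop = FALSE]
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  ss_a <- rowSums((xa - ma)^2)
  ss_b <- rowSums((xb - mb)^2)
  s <- sqrt((1 / n_a + 1 / n_b) * (ss_a + ss_b) / (n_a + n_b - 2L))
  if (all(s == 0)) stop("degenerate matrix: all pooled standard errors are zero")
  s0 <- stats::median(s)

  d <- (ma - mb) / (s + s0)
  list(gene_ids = rownames(expr),
       d = stats::setNames(d, rownames(expr)),
       s = stats::setNames(s, rownames(expr)),
       s0 = s0)
}

#' Top m genes by absolute SAM statistic
#'
#' Ranks genes by `|d|` (two-sided differential expression, direction not
#' used); exact ties are broken by ascending gene id so the selection is a
#' deterministic total order.
#'
#' @param stats A result of [sam_statistics()].
#' @param m Number of genes to return.
#' @return Character vector of `m` gene ids.
#' @export
top_m_genes <- function(stats, m) {
  n <- length(stats$d)
  if (m > n) stop("m (", m, ") exceeds the number of genes (", n, ")")
  ord <- order(-abs(stats$d), names(stats$d), method = "radix")
  names(stats$d)[ord[seq_len(m)]]
}
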