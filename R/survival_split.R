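#' Split samples at the median of the first principal component
#'
#' Standardizes each gene row of the submatrix (mean 0, sd 1 across samples),
#' takes the leading principal component of the samples, ranks samples by
#' their PC1 score, and labels the lower ceiling(n/2) ranks "A" and the rest
#' "B". Standardizing first keeps a single high-variance gene from dominating
#' PC1, which matters when inputs mix measurement platforms. The partition is
#' invariant (up to swapping the A/B labels) under the arbitrary sign of the
#' eigenvector; a deterministic sign convention and sample-id tie-break make
#' repeated calls identical.
#'
#' @param expr Numeric expression matrix (genes x samples, dimnames set).
#' @param genes Character vector of gene ids to use; all must be rows of
#'   `expr`.
#' @return A list with `labels` (named factor-free character vector in
#'   `c("A","B")`, one per sample) and `pc1_scores` (named numeric vector).
#' @export
pc1_median_split <- function(expr, genes) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("unknown gene(s): ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  n <- ncol(expr)
  if (n < 2L) stop("need at least 2 samples")
  x <- expr[genes, , drop = FALSE]

  # per-gene standardization; zero-variance rows become all-zero
  mu <- rowMeans(x)
  x <- x - mu
  sdev <- sqrt(rowSums(x^2) / (n - 1L))
  nz <- sdev > 0
  if (!any(nz)) stop("degenerate input: gene submatrix has zero total variance")
  x[nz, ] <- x[nz, , drop = FALSE] / sdev[nz]

  scores <- pc1_scores(x)
  names(scores) <- colnames(expr)

  # sign convention: the largest-magnitude score is positive (first such
  # sample on exact magnitude ties)
  peak <- which.max(abs(scores))
  if (scores[peak] < 0) scores <- -scores

  ord <- order(scores, colnames(expr), method = "radix")
  labels <- rep("B", n)
  labels[ord[seq_len(ceiling(n / 2))]] <- "A"
  names(labels) <- colnames(expr)

  list(labels = labels, pc1_scores = scores)
}

# PC1 sample scores of a row-centered matrix x (genes x samples): the leading
# left singular vector is taken from the smaller-dimension crossproduct.
pc1_scores <- function(x) {
  g <- nrow(x)
  n <- ncol(x)
  if (g <= n) {
    e <- eigen(tcrossprod(x), symmetric = TRUE)
    u1 <- e$vectors[, 1L]
    drop(crossprod(x, u1))
  } else {
    e <- eigen(crossprod(x), symmetric = TRUE)
    v1 <- e$vectors[, 1L]
    # scale to D * v1 so magnitudes match the g <= n branch
    v1 * sqrt(max(e$values[1L], 0))
  }
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time the observed minus expected number of events in
#' group A is accumulated, with the hypergeometric variance of the 2x2 risk
#' table; ties are handled by the standard multi-event hypergeometric formula.
#' Censored samples contribute to risk sets only. The statistic
#' `(sum(O-E))^2 / sum(V)` is referred to a chi-square distribution with 1
#' degree of freedom (two-sided).
#'
#' @param labels Character vector of group labels in `c("A","B")`, one per
#'   sample, aligned to `surv`.
#' @param surv Survival data frame with columns `time` and `event`.
#' @return A list with `chi_square` and `p_value`.
#' @export
logrank_test <- function(labels, surv) {
  stopifnot(length(labels) == nrow(surv))
  in_a <- labels == "A"
  if (!any(in_a) || all(in_a)) stop("both groups must be non-empty")
  if (any(surv$time <= 0)) stop("survival times must be positive")

  if (sum(surv$event) == 0L) {
    warning("no events observed; log-rank test is undefined, returning p = 1")
    return(list(chi_square = 0, p_value = 1))
  }

  time <- surv$time
  event <- surv$event

  # risk sets and event counts at each distinct time, via reverse cumulative
  # tallies (avoids an explicit loop over event times)
  ut <- sort(unique(time))
  idx <- match(time, ut)
  nb <- length(ut)
  n_at_all <- rev(cumsum(rev(tabulate(idx, nbins = nb))))
  n_a_all <- rev(cumsum(rev(tabulate(idx[in_a], nbins = nb))))
  d_all <- tabulate(idx[event == 1L], nbins = nb)
  d_a_all <- tabulate(idx[event == 1L & in_a], nbins = nb)

  keep <- d_all > 0L
  n_at <- n_at_all[keep]
  n_a_at <- n_a_all[keep]
  d_at <- d_all[keep]
  d_a_at <- d_a_all[keep]

  e_a <- d_at * n_a_at / n_at
  v <- ifelse(n_at > 1,
              d_at * (n_a_at / n_at) * (1 - n_a_at / n_at) *
                (n_at - d_at) / (n_at - 1),
              0)

  vsum <- sum(v)
  if (vsum == 0) {
    return(list(chi_square = 0, p_value = 1))
  }
  chi <- sum(d_a_at - e_a)^2 / vsum
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1L, lower.tail = FALSE))
}

#' Split by PC1 median and test the survival difference
#'
#' Composition of [pc1_median_split()] and [logrank_test()]; this is the unit
#' operation applied to every random gene set, both inside the fixed-point
#' iteration and in SSAR estimation. A gene set is called significantly
#' survival-associated when `p_value < alpha` (0.05 throughout).
#'
#' @inheritParams pc1_median_split
#' @param surv Survival data frame aligned to the columns of `expr`.
#' @return A list with `labels`, `pc1_scores`, `chi_square`, `p_value`.
#' @export
split_and_test <- function(expr, genes, surv) {
  stopifnot(ncol(expr) == nrow(surv),
            identical(colnames(expr), surv$sample_id) || is.null(surv$sample_id))
  sp <- pc1_median_split(expr, genes)
  lr <- logrank_test(sp$labels, surv)
  c(sp, lr)
}
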