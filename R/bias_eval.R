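#' Estimate the proportion of significant survival-associated random sets
#'
#' Monte-Carlo estimate of random bias: draws `n_sets` random gene sets of
#' size `cfg$set_size`, splits the cohort at the PC1 median of each, and
#' reports the fraction whose log-rank p-value falls below `cfg$alpha`. In an
#' unbiased cohort this proportion sits at the nominal level (0.05); a
#' clearly larger value is positive random bias. Draw `i` uses an RNG
#' substream derived from `cfg$seed`, so the estimate is reproducible and
#' order-independent.
#'
#' @param expr Expression matrix (genes x samples).
#' @param surv Aligned survival data frame.
#' @param cfg An [fpgi_config()]; `set_size`, `alpha` and `seed` are used.
#' @param n_sets Number of random sets to test.
#' @return A list of class `ssar_report` with `n_sets`, `set_size`, `alpha`,
#'   `p_values`, `n_significant`, `proportion`, `seed`.
#' @export
estimate_ssar <- function(expr, surv, cfg = fpgi_config(), n_sets = 1000L) {
  stopifnot(n_sets >= 1L)
  universe <- rownames(expr)
  if (cfg$set_size > length(universe)) stop("set_size exceeds the number of genes")

  set.seed(cfg$seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_sets)

  p_values <- numeric(n_sets)
  for (i in seq_len(n_sets)) {
    set.seed(draw_seeds[i])
    genes <- draw_random_set(universe, cfg$set_size)
    p_values[i] <- split_and_test(expr, genes, surv)$p_value
  }

  n_sig <- sum(p_values < cfg$alpha)
  structure(list(n_sets = as.integer(n_sets), set_size = cfg$set_size,
                 alpha = cfg$alpha, p_values = p_values,
                 n_significant = as.integer(n_sig),
                 proportion = n_sig / n_sets, seed = cfg$seed),
            class = "ssar_report")
}

#' @export
print.ssar_report <- function(x, ...) {
  cat(sprintf("SSAR estimate: %d / %d random %d-gene sets significant (%.1f%%) at alpha = %g\n",
              x$n_significant, x$n_sets, x$set_size,
              100 * x$proportion, x$alpha))
  invisible(x)
}

#' Regress a signature's metagene out of every gene
#'
#' Summarizes the signature as a metagene — the per-sample mean of the
#' signature genes after each is z-scored across samples — and replaces every
#' gene row (signature rows included) by its residual from an ordinary
#' least-squares fit on an intercept and the metagene. After correction no
#' gene retains linear association with the signature's activity, which is
#' the operation used to test whether a signature is responsible for random
#' bias.
#'
#' @param expr Expression matrix (genes x samples).
#' @param signature Character vector of gene ids present in `expr`.
#' @return A corrected matrix with identical dimensions and dimnames.
#' @export
remove_signature_effect <- function(expr, signature) {
  if (!length(signature)) stop("empty signature")
  missing <- setdiff(signature, rownames(expr))
  if (length(missing)) {
    stop("signature gene(s) absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  n <- ncol(expr)
  sig <- expr[signature, , drop = FALSE]
  mu <- rowMeans(sig)
  sdev <- sqrt(rowSums((sig - mu)^2) / (n - 1L))
  if (any(sdev == 0)) stop("degenerate signature: zero-variance signature gene")
  metagene <- colMeans((sig - mu) / sdev)
  if (stats::var(metagene) == 0) stop("degenerate signature: metagene has zero variance")

  # per-gene OLS on (intercept, metagene), vectorized over genes
  mg <- metagene - mean(metagene)
  beta <- (expr %*% mg) / sum(mg^2)
  centered <- expr - rowMeans(expr)
  resid <- centered - tcrossprod(drop(beta), mg)
  dimnames(resid) <- dimnames(expr)
  resid
}

#' Distance of an SSAR proportion from the nominal level
#'
#' A bias-removal procedure is perfect when random sets are significant at
#' exactly the nominal rate; this reports `|proportion - nominal|` as the
#' scalar figure of merit.
#'
#' @param report An [estimate_ssar()] report.
#' @param nominal Nominal significance level (default 0.05).
#' @return A list with `proportion`, `nominal`, `distance`.
#' @export
distance_to_nominal <- function(report, nominal = 0.05) {
  stopifnot(nominal >= 0, nominal <= 1)
  list(proportion = report$proportion, nominal = nominal,
       distance = abs(report$proportion - nominal))
}

#' Overlap fraction of two gene sets
#'
#' `|a intersect b| / min(|a|, |b|)`: the share of the smaller set that the
#' two sets have in common. Normalizing by the smaller set lets sets of
#' different sizes be compared on one scale.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return A number in [0, 1].
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) stop("gene sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Write an SSAR report as JSON
#'
#' @param report An [estimate_ssar()] report.
#' @param path Output path.
#' @param include_p_values Keep the full p-value vector in the file.
#' @export
write_ssar_report <- function(report, path, include_p_values = TRUE) {
  out <- unclass(report)
  if (!include_p_values) out$p_values <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
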