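#' Configuration for the fixed-point search
#'
#' Bundles the tunable parameters of the fixed-point gene-set search. The
#' defaults are the headline settings of the method: random sets of 50 genes,
#' 6000 restarts, a 0.05 log-rank significance screen, and the top 10% of
#' fixed-point genes used for bias correction. `max_iter` is a safety cap
#' only; in practice convergence takes at most on the order of 20 iterations.
#'
#' @param set_size Size m of each random gene set (>= 2).
#' @param n_runs Number of random restarts.
#' @param alpha Log-rank significance level in (0, 1).
#' @param max_iter Iteration cap per restart.
#' @param seed Master seed; every random draw derives from it.
#' @param top_frac Fraction of highest-scoring fixed-point genes selected for
#'   signature-removal, in (0, 1].
#' @return A list of class `fpgi_config`.
#' @export
fpgi_config <- function(set_size = 50L, n_runs = 6000L, alpha = 0.05,
                        max_iter = 100L, seed = 1L, top_frac = 0.10) {
  stopifnot(set_size >= 2L, n_runs >= 0L, alpha > 0, alpha < 1,
            max_iter >= 1L, top_frac > 0, top_frac <= 1)
  structure(list(set_size = as.integer(set_size), n_runs = as.integer(n_runs),
                 alpha = alpha, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), top_frac = top_frac),
            class = "fpgi_config")
}

#' Draw a random gene set
#'
#' Samples `m` distinct genes uniformly without replacement from the current
#' RNG stream (seed it with [set.seed()] for reproducibility).
#'
#' @param universe Character vector of available gene ids.
#' @param m Set size.
#' @return Character vector of `m` gene ids.
#' @export
draw_random_set <- function(universe, m) {
  if (m > length(universe)) {
    stop("m (", m, ") exceeds the gene universe size (", length(universe), ")")
  }
  universe[sample.int(length(universe), m)]
}

set_key <- function(genes) paste(sort(genes), collapse = "\r")

#' Iterate one random start to a fixed point
#'
#' Repeats the map (PC1-median split, log-rank screen, SAM top-m) from a
#' starting gene set until the SAM top-m equals its own input set. Each
#' iteration re-derives the patient split from the current set, so the map is
#' genuinely iterated rather than a single reranking on frozen groups. A run
#' is discarded as `not_significant` when the log-rank p-value is at or above
#' `cfg$alpha` — at the first pass (the initial screen, `iterations = 0`) or
#' at any later pass (a fixed point that is not survival-associated cannot
#' contribute to the fixed-point set). Revisiting a previously seen set
#' without immediate repetition is a cycle and also discards the run; the cap
#' `cfg$max_iter` bounds worst-case work.
#'
#' @param expr Expression matrix (genes x samples).
#' @param surv Aligned survival data frame.
#' @param start Character vector of `cfg$set_size` gene ids.
#' @param cfg An [fpgi_config()].
#' @return A list of class `fixed_point_run` with `status` (one of
#'   `"not_significant"`, `"converged"`, `"cycled"`, `"max_iter_exceeded"`),
#'   `iterations`, `trajectory` (list of visited sets), `final_set` (only
#'   when converged) and the last `p_value`.
#' @export
fixed_point_iterate <- function(expr, surv, start, cfg = fpgi_config()) {
  m <- cfg$set_size
  if (length(start) != m) stop("start set must have size ", m)

  current <- sort(start)
  trajectory <- list(current)
  seen <- set_key(current)
  iterations <- 0L
  status <- NA_character_
  final_set <- NULL
  p_value <- NA_real_

  repeat {
    st <- split_and_test(expr, current, surv)
    p_value <- st$p_value
    if (p_value >= cfg$alpha) {
      status <- "not_significant"
      break
    }
    stats <- sam_statistics(expr, st$labels)
    nxt <- sort(top_m_genes(stats, m))
    iterations <- iterations + 1L
    trajectory[[length(trajectory) + 1L]] <- nxt
    if (identical(nxt, current)) {
      status <- "converged"
      final_set <- current
      break
    }
    key <- set_key(nxt)
    if (key %in% seen) {
      status <- "cycled"
      break
    }
    if (iterations >= cfg$max_iter) {
      status <- "max_iter_exceeded"
      break
    }
    seen <- c(seen, key)
    current <- nxt
  }

  structure(list(start_set = sort(start), status = status,
                 iterations = iterations, trajectory = trajectory,
                 final_set = final_set, p_value = p_value),
            class = "fixed_point_run")
}

#' Run the full fixed-point search
#'
#' Draws `cfg$n_runs` random gene sets; each set that passes the log-rank
#' screen is iterated to a fixed point with [fixed_point_iterate()]. The
#' converged fixed sets are pooled as a multiset X: each gene's score `w(g)`
#' counts the converged runs whose fixed set contains it, and the fixed-point
#' gene set Z is the distinct genes of X. Restart `j` uses an RNG substream
#' derived from the master seed, so results do not depend on execution order
#' and identical seeds give identical results.
#'
#' @inheritParams fixed_point_iterate
#' @param cfg An [fpgi_config()]; `cfg$n_runs` indexes every draw, including
#'   those that fail the initial screen.
#' @return A list of class `fpgi_result` with `config`, `runs` (data frame:
#'   run index, status, iterations), `scores` (named integer vector `w`),
#'   and `fixed_point_set` (Z, the names of `scores`).
#' @export
run_fpgi <- function(expr, surv, cfg = fpgi_config()) {
  universe <- rownames(expr)
  if (cfg$set_size > length(universe)) {
    stop("set_size exceeds the number of genes")
  }

  set.seed(cfg$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, max(cfg$n_runs, 1L))

  status <- character(cfg$n_runs)
  iterations <- integer(cfg$n_runs)
  converged_sets <- vector("list", cfg$n_runs)

  for (j in seq_len(cfg$n_runs)) {
    set.seed(run_seeds[j])
    g_j <- draw_random_set(universe, cfg$set_size)
    run <- fixed_point_iterate(expr, surv, g_j, cfg)
    status[j] <- run$status
    iterations[j] <- run$iterations
    if (run$status == "converged") converged_sets[[j]] <- run$final_set
  }

  pooled <- unlist(converged_sets, use.names = FALSE)
  if (length(pooled)) {
    tab <- table(pooled)
    scores <- stats::setNames(as.integer(tab), names(tab))
    scores <- scores[order(-scores, names(scores), method = "radix")]
  } else {
    if (cfg$n_runs > 0L) {
      warning("no run converged to a significant fixed point; ",
              "the fixed-point set is empty")
    }
    scores <- stats::setNames(integer(0), character(0))
  }

  structure(list(config = cfg,
                 runs = data.frame(run = seq_len(cfg$n_runs),
                                   status = status,
                                   iterations = iterations,
                                   stringsAsFactors = FALSE),
                 scores = scores,
                 fixed_point_set = names(scores)),
            class = "fpgi_result")
}

#' @export
print.fpgi_result <- function(x, ...) {
  cat("Fixed-point gene set search\n")
  cat("  restarts:", x$config$n_runs, " set size:", x$config$set_size, "\n")
  if (nrow(x$runs)) {
    tab <- table(factor(x$runs$status,
                        levels = c("not_significant", "converged", "cycled",
                                   "max_iter_exceeded")))
    cat("  status: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  |Z| =", length(x$fixed_point_set), "distinct genes")
  if (length(x$scores)) {
    cat("; top score", max(x$scores), "(", names(x$scores)[1L], ")")
  }
  cat("\n")
  invisible(x)
}

#' Highest-scoring fraction of the fixed-point set
#'
#' Returns the `ceiling(frac * |Z|)` genes with the highest fixed-point
#' scores, ties broken by ascending gene id. With the default `frac = 0.10`
#' this is the subset used for bias correction.
#'
#' @param result An [run_fpgi()] result.
#' @param frac Fraction in (0, 1].
#' @return Character vector of gene ids.
#' @export
top_fraction <- function(result, frac = result$config$top_frac) {
  stopifnot(frac > 0, frac <= 1)
  if (!length(result$scores)) stop("no fixed-point genes")
  k <- ceiling(frac * length(result$scores))
  ord <- order(-as.numeric(result$scores), names(result$scores),
               method = "radix")
  names(result$scores)[ord[seq_len(k)]]
}

#' Write a JSON run report
#'
#' Serializes the configuration, run-status counts, iteration histogram of
#' converged runs, and the scored fixed-point set.
#'
#' @param result An [run_fpgi()] result.
#' @param path Output path.
#' @export
write_fpgi_report <- function(result, path) {
  conv <- result$runs$iterations[result$runs$status == "converged"]
  report <- list(
    config = unclass(result$config),
    status_counts = as.list(table(result$runs$status)),
    iteration_histogram = as.list(table(conv)),
    fixed_point_set = as.list(result$scores)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
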