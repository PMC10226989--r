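test_that("a single monotone gene splits at its median", {
  expr <- matrix(c(1, 2, 3, 4), nrow = 1,
                 dimnames = list("g1", c("s1", "s2", "s3", "s4")))
  sp <- pc1_median_split(expr, "g1")
  expect_setequal(names(sp$labels)[sp$labels == sp$labels["s1"]], c("s1", "s2"))
  expect_setequal(names(sp$labels)[sp$labels == sp$labels["s3"]], c("s3", "s4"))

  # duplicating the gene as an identical second row changes nothing
  expr2 <- rbind(expr, g2 = expr[1, ])
  rownames(expr2) <- c("g1", "g2")
  sp2 <- pc1_median_split(expr2, c("g1", "g2"))
  expect_true(same_partition(sp$labels, sp2$labels))
})

test_that("PC1 split matches an eigen-decomposition oracle on random fixtures", {
  for (i in 1:50) {
    g <- sample(3:12, 1)
    n <- sample(6:20, 1)
    expr <- make_expr(g = g, n = n, seed = 1000 + i)
    sp <- pc1_median_split(expr, rownames(expr))
    v1 <- pc1_oracle(expr, rownames(expr))
    ord <- order(if (sum(v1 * sp$pc1_scores) < 0) -v1 else v1,
                 colnames(expr), method = "radix")
    ref <- rep("B", n)
    ref[ord[seq_len(ceiling(n / 2))]] <- "A"
    names(ref) <- colnames(expr)
    expect_true(same_partition(sp$labels, ref))
    # scores proportional to the oracle eigenvector
    expect_gt(abs(cor(sp$pc1_scores, v1)), 1 - 1e-8)
  }
})

test_that("PC1 split is invariant to affine rescaling of one gene and balanced for odd n", {
  expr <- make_expr(g = 5, n = 9, seed = 77)
  sp <- pc1_median_split(expr, rownames(expr))
  expect_equal(abs(sum(sp$labels == "A") - sum(sp$labels == "B")), 1)
  expect_equal(sum(sp$labels == "A"), 5L)  # A gets the extra sample

  scaled <- expr
  scaled["g03", ] <- 100 * expr["g03", ] - 42
  sp_scaled <- pc1_median_split(scaled, rownames(scaled))
  expect_true(same_partition(sp$labels, sp_scaled$labels))

  expect_error(pc1_median_split(expr, c("g01", "nope")), "unknown gene")
  flat <- matrix(5, nrow = 2, ncol = 4,
                 dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(pc1_median_split(flat, c("a", "b")), "degenerate")
})

test_that("log-rank is symmetric in the labels and null on identical groups", {
  surv <- make_surv(n = 12, seed = 3)
  labels <- rep(c("A", "B"), 6)
  lr <- logrank_test(labels, surv)
  lr_swapped <- logrank_test(ifelse(labels == "A", "B", "A"), surv)
  expect_equal(lr$chi_square, lr_swapped$chi_square, tolerance = 1e-12)
  expect_equal(lr$p_value, lr_swapped$p_value, tolerance = 1e-12)

  # two groups with identical time/event multisets
  surv2 <- data.frame(time = c(1, 2, 3, 1, 2, 3),
                      event = c(1L, 1L, 0L, 1L, 1L, 0L))
  lr2 <- logrank_test(rep(c("A", "B"), each = 3), surv2)
  expect_equal(lr2$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr2$p_value, 1, tolerance = 1e-12)

  expect_warning(
    lr3 <- logrank_test(rep(c("A", "B"), 3),
                        data.frame(time = 1:6, event = rep(0L, 6))),
    "no events")
  expect_equal(lr3$p_value, 1)
})

test_that("log-rank matches the hand-computed risk-table oracle, ties included", {
  # fully separated groups
  surv <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = rep(1L, 6))
  labels <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(labels, surv)
  ref <- logrank_oracle(labels, surv$time, surv$event)
  expect_equal(lr$chi_square, ref$chi_square, tolerance = 1e-10)
  expect_equal(lr$p_value, ref$p_value, tolerance = 1e-10)

  # tied event times across groups plus censoring
  surv_t <- data.frame(time = c(2, 2, 2, 5, 5, 7, 7, 9),
                       event = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L))
  labels_t <- c("A", "B", "A", "A", "B", "B", "A", "B")
  lr_t <- logrank_test(labels_t, surv_t)
  ref_t <- logrank_oracle(labels_t, surv_t$time, surv_t$event)
  expect_equal(lr_t$chi_square, ref_t$chi_square, tolerance = 1e-10)
})

test_that("log-rank agrees with the survival package on 100 random fixtures", {
  for (i in 1:100) {
    set.seed(2000 + i)
    n <- sample(10:60, 1)
    time <- rexp(n, 0.2)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1L
    labels <- rep("B", n)
    labels[sample.int(n, floor(n / 2))] <- "A"
    if (all(labels == "A") || all(labels == "B")) next
    lr <- logrank_test(labels, data.frame(time = time, event = event))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ labels)
    expect_equal(lr$chi_square, sd_$chisq, tolerance = 1e-8)
    expect_equal(lr$p_value,
                 pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("split_and_test is deterministic and calibrated under permuted survival", {
  expr <- make_expr(g = 20, n = 60, seed = 5)
  surv <- make_surv(n = 60, seed = 5)

  r1 <- split_and_test(expr, rownames(expr)[1:8], surv)
  r2 <- split_and_test(expr, rownames(expr)[1:8], surv)
  expect_identical(r1, r2)

  # permuting survival against the expression: p < 0.05 at roughly the
  # nominal rate (pure-noise expression, so the permutation draws are
  # essentially independent)
  set.seed(99)
  hits <- 0L
  reps <- 500L
  for (i in seq_len(reps)) {
    perm <- surv
    shuffle <- sample.int(nrow(surv))
    perm$time <- surv$time[shuffle]
    perm$event <- surv$event[shuffle]
    hits <- hits + (split_and_test(expr, rownames(expr)[1:8], perm)$p_value < 0.05)
  }
  ci <- binom_interval(reps, 0.05)
  expect_gte(hits / reps, ci[1])
  expect_lte(hits / reps, ci[2])
})
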