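test_that("a constant fully detected gene gives LRT ~ 0 and p ~ 1", {
  y <- rep(3, 20)
  cond <- factor(rep(c("A", "B"), each = 10))
  fit <- fit_hurdle(y, cond)
  expect_equal(fit$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(fit$p_value, 1)
})

test_that("all-or-nothing detection matches the closed-form binomial LRT", {
  # detection 6/6 vs 0/6, no covariates: discrete-only LRT; the continuous
  # part is degenerate (condition constant among detected cells) so df = 1
  y <- c(rep(2, 6), rep(0, 6))
  cond <- factor(rep(c("A", "B"), each = 6))
  fit <- fit_hurdle(y, cond)
  # full model fits each group's detection perfectly (loglik -> 0);
  # null model: p_hat = 1/2 over 12 cells
  lrt_closed <- 2 * (0 - 12 * log(0.5))
  expect_equal(fit$df, 1L)
  expect_false(fit$converged)  # separation -> ridge-stabilized refit
  expect_equal(fit$lrt_stat, lrt_closed, tolerance = 1e-2)
  expect_equal(fit$p_value, pchisq(lrt_closed, 1, lower.tail = FALSE),
               tolerance = 1e-3)
})

test_that("partial detection shift matches closed-form binomial log-likelihoods", {
  # detection 5/6 vs 1/6; detected values all equal so the continuous part
  # contributes 0 to the statistic but keeps its df
  y <- c(2, 2, 2, 2, 2, 0, 2, 0, 0, 0, 0, 0)
  cond <- factor(rep(c("A", "B"), each = 6))
  fit <- fit_hurdle(y, cond)
  ll <- function(x, n) {
    p <- x / n
    x * log(p) + (n - x) * log(1 - p)
  }
  lrt_closed <- 2 * ((ll(5, 6) + ll(1, 6)) - ll(6, 12))
  expect_equal(fit$df, 2L)
  expect_true(fit$converged)
  expect_equal(fit$lrt_stat, lrt_closed, tolerance = 1e-6)
})

test_that("on all-detected genes the hurdle p equals the Gaussian-only LRT p", {
  set.seed(21)
  n <- 40
  cond <- factor(rep(c("A", "B"), each = n / 2))
  y <- rnorm(n, mean = ifelse(cond == "B", 1.5, 1.0), sd = 0.5) + 3
  fit <- fit_hurdle(y, cond)
  ll_full <- as.numeric(logLik(lm(y ~ cond)))
  ll_null <- as.numeric(logLik(lm(y ~ 1)))
  lrt <- 2 * (ll_full - ll_null)
  expect_equal(fit$df, 1L)
  expect_equal(fit$lrt_stat, lrt, tolerance = 1e-8)
  expect_equal(fit$p_value, pchisq(lrt, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("the LRT is invariant to affine rescaling of numeric covariates", {
  set.seed(33)
  n <- 120
  cond <- factor(rep(c("A", "B"), each = n / 2))
  covs <- data.frame(sex = factor(sample(c("F", "M"), n, TRUE)),
                     age = runif(n, 35, 70), rin = runif(n, 5, 9))
  y <- ifelse(runif(n) < 0.6, rlnorm(n, 1, 0.4), 0)
  f1 <- fit_hurdle(y, cond, covs)
  covs2 <- covs
  covs2$age <- covs2$age * 12 + 100
  covs2$rin <- covs2$rin / 3 - 5
  f2 <- fit_hurdle(y, cond, covs2)
  expect_equal(f1$lrt_stat, f2$lrt_stat, tolerance = 1e-6)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-6)
})

test_that("log2 fold change is the difference of group means, B minus A", {
  g <- factor(rep(c("A", "B"), each = 4))
  expect_equal(estimate_log2fc(rep(1, 8), g), 0)
  expect_equal(estimate_log2fc(c(rep(3, 4), rep(1, 4)), g), -2)  # up in A
  set.seed(4)
  y <- rnorm(8)
  expect_equal(estimate_log2fc(y, g), mean(y[5:8]) - mean(y[1:4]),
               tolerance = 1e-12)
  expect_error(estimate_log2fc(y[1:4], factor(rep("A", 4), levels = c("A", "B"))),
               "two levels|non-empty")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(6)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-15)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_dge recovers strong planted effects and skips tiny clusters", {
  set.seed(55)
  n <- 160; ng <- 200
  cond <- rep(c("RRMS", "SPMS"), each = n / 2)
  counts <- matrix(rnbinom(n * ng, mu = 2, size = 1), n, ng)
  # balanced planting (5 up, 5 down in SPMS) keeps library sizes comparable
  planted <- 1:10
  counts[cond == "SPMS", 1:5] <-
    matrix(rnbinom((n / 2) * 5, mu = 16, size = 1), n / 2, 5)
  counts[cond == "RRMS", 6:10] <-
    matrix(rnbinom((n / 2) * 5, mu = 16, size = 1), n / 2, 5)
  counts[rowSums(counts) == 0, 1] <- 1
  m <- toy_matrix(counts)
  meta <- toy_metadata(m$barcodes,
                       sample = rep(sprintf("s%d", 1:8), each = n / 8),
                       condition = rep(c("RRMS", "SPMS"), each = n / 2),
                       cluster = "OL",
                       sex = rep(c("F", "M", "F", "M", "M", "F", "M", "F"),
                                 each = n / 8),
                       age = rep(c(50, 60, 44, 66, 55, 65, 47, 58), each = n / 8),
                       rin = rep(c(7, 8, 6.2, 8.8, 6, 7.5, 8.1, 6.6),
                                 each = n / 8))
  x <- log_normalize(m)
  d <- run_dge(x, meta, "OL")
  expect_s3_class(d, "DgeTable")
  expect_gte(sum(d$is_deg[planted]), 8)
  expect_true(all(d$log2fc[1:5][d$is_deg[1:5]] > 0))   # up in SPMS
  expect_true(all(d$log2fc[6:10][d$is_deg[6:10]] < 0)) # up in RRMS
  expect_lte(sum(d$is_deg[-planted]), ceiling(0.05 * (ng - 10)) + 3)
  # fdr >= p elementwise, in [0, 1]
  ok <- !is.na(d$fdr)
  expect_true(all(d$fdr[ok] >= d$p_value[ok] & d$fdr[ok] <= 1))

  # a cluster below the per-condition cell floor is skipped with a message
  meta2 <- meta
  meta2$cluster[meta2$condition == "RRMS"][1:4] <- "rare"
  meta2$cluster[meta2$condition == "SPMS"][1:4] <- "rare"
  expect_message(out <- run_dge(x, meta2, "rare"), "skipped")
  expect_null(out)
})

test_that("genes below the detection floor are flagged untested", {
  set.seed(77)
  n <- 80
  counts <- matrix(rpois(n * 5, 3), n, 5)
  counts[, 5] <- 0
  counts[1, 5] <- 2  # detected in ~1% of cells only
  m <- toy_matrix(counts)
  meta <- toy_metadata(m$barcodes,
                       sample = rep(c("r1", "r2", "s1", "s2"), each = n / 4),
                       condition = rep(c("RRMS", "SPMS"), each = n / 2),
                       cluster = "OL")
  d <- run_dge(log_normalize(m), meta, "OL",
               dge_config(covariates = character(0)))
  expect_false(d$tested[5])
  expect_true(is.na(d$p_value[5]) && is.na(d$fdr[5]) && !d$is_deg[5])
  expect_true(all(d$tested[1:4]))
})
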