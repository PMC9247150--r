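# Two-part (hurdle) differential-expression test. The discrete part is a
# logistic regression of the detection indicator 1{y > 0} on condition +
# covariates; the continuous part is a Gaussian linear model of the
# log-expression among detected cells. Condition is tested by a
# likelihood-ratio test combining both parts, with chi-square reference
# distribution. Covariates (sex, age, RIN) are adjusted for in both parts.

# IRLS logistic fit with optional ridge penalty; returns the unpenalized
# binomial log-likelihood at the estimate. The ridge path stabilizes
# complete separation.
.logistic_fit <- function(X, z, ridge = 0, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(min(max(mean(z), 1e-3), 1 - 1e-3))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X, X * w)
    if (ridge > 0) XtWX <- XtWX + diag(ridge, p)
    rhs <- crossprod(X, w * eta + (z - mu))
    beta_new <- tryCatch(drop(solve(XtWX, rhs)), error = function(e) NULL)
    if (is.null(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  ll <- sum(z * log(mu) + (1 - z) * log(1 - mu))
  list(coef = beta, loglik = ll, converged = converged)
}

# OLS fit with Gaussian log-likelihood evaluated at the MLE variance
# (sigma2 = RSS / n); no variance shrinkage across genes.
.gaussian_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(coef = fit$coefficients, loglik = ll, rank = fit$rank)
}

# Drop columns that are constant or collinear within the given rows; the
# intercept (column 1) is always kept. Returns column indices to keep.
.estimable_cols <- function(X) {
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(v) {
    stats::var(v) > 0
  }))
  qr_x <- qr(X[, keep, drop = FALSE])
  if (qr_x$rank < sum(keep)) {
    piv_keep <- qr_x$pivot[seq_len(qr_x$rank)]
    idx <- which(keep)[sort(piv_keep)]
  } else {
    idx <- which(keep)
  }
  idx
}

.build_design <- function(condition, covariates = NULL) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2L) {
    stop("condition must have exactly two levels; got ", nlevels(condition))
  }
  df <- data.frame(condition = condition)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(condition))
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        # standardized internally: the LRT is invariant to affine
        # rescaling of numeric covariates, and conditioning improves
        s <- stats::sd(v)
        df[[nm]] <- if (is.na(s) || s == 0) v * 0 else (v - mean(v)) / s
      } else {
        df[[nm]] <- droplevels(as.factor(v))
      }
    }
  }
  X <- stats::model.matrix(~ ., data = df)
  cond_col <- which(startsWith(colnames(X), "condition"))
  list(X = X, cond_col = cond_col, levels = levels(condition))
}

#' Fit the hurdle model for one gene
#'
#' Fits the two-part model of `y` (per-cell log-expression within one
#' cluster) on condition plus covariates, and tests the condition term by
#' a likelihood-ratio test whose statistic is the sum of the discrete
#' (logistic, detection) and continuous (Gaussian, expression among
#' detected cells) contributions. Degenerate parts (all cells detected,
#' or fewer than 2 detected, or condition constant among detected cells)
#' contribute 0 to the statistic and nothing to the degrees of freedom.
#' If the unpenalized logistic fit fails to converge (e.g. complete
#' separation) both full and null discrete fits are redone with a small
#' ridge penalty and the `converged` flag is lowered.
#'
#' @param y numeric vector of log-expression values (zeros = undetected).
#' @param condition two-level factor (or coercible), one entry per cell.
#' @param covariates optional data.frame of per-cell covariates (e.g.
#'   sex, age, rin); numeric columns are standardized internally.
#' @param ridge ridge penalty used in the stabilized logistic refit.
#' @return an object of class `hurdle_fit` with the coefficients,
#'   log-likelihoods, `lrt_stat`, `df`, `p_value` and `converged` flag.
#' @export
fit_hurdle <- function(y, condition, covariates = NULL, ridge = 1e-4) {
  d <- .build_design(condition, covariates)
  X <- d$X
  z <- as.numeric(y > 0)

  ll_fd <- ll_nd <- 0
  df_d <- 0L
  coef_d <- NULL
  converged <- TRUE

  if (stats::var(z) > 0) {
    keep <- .estimable_cols(X)
    if (any(keep %in% d$cond_col)) {
      Xf <- X[, keep, drop = FALSE]
      Xn <- X[, setdiff(keep, d$cond_col), drop = FALSE]
      ff <- .logistic_fit(Xf, z)
      fn <- .logistic_fit(Xn, z)
      if (!ff$converged || !fn$converged) {
        ff <- .logistic_fit(Xf, z, ridge = ridge)
        fn <- .logistic_fit(Xn, z, ridge = ridge)
        converged <- FALSE
      }
      ll_fd <- ff$loglik; ll_nd <- fn$loglik
      df_d <- sum(keep %in% d$cond_col)
      coef_d <- ff$coef
      names(coef_d) <- colnames(Xf)
    }
  }

  ll_fc <- ll_nc <- 0
  df_c <- 0L
  coef_c <- NULL
  pos <- which(z > 0)
  if (length(pos) >= 2L) {
    Xp <- X[pos, , drop = FALSE]
    keep <- .estimable_cols(Xp)
    if (any(keep %in% d$cond_col) && length(pos) > length(keep)) {
      Xf <- Xp[, keep, drop = FALSE]
      Xn <- Xp[, setdiff(keep, d$cond_col), drop = FALSE]
      yf <- y[pos]
      df_c <- sum(keep %in% d$cond_col)
      if (stats::var(yf) > 0) {
        ff <- .gaussian_fit(Xf, yf)
        fn <- .gaussian_fit(Xn, yf)
        ll_fc <- ff$loglik; ll_nc <- fn$loglik
        coef_c <- ff$coef
        names(coef_c) <- colnames(Xf)
      }
      # zero-variance y among detected cells: full and null fit equally
      # well, LRT contribution 0 with the condition df retained (p -> 1)
    }
  }

  lrt <- max(0, 2 * ((ll_fd - ll_nd) + (ll_fc - ll_nc)))
  df <- df_d + df_c
  p <- if (df > 0L) stats::pchisq(lrt, df, lower.tail = FALSE) else NA_real_

  structure(
    list(
      discrete_coefs = coef_d,
      continuous_coefs = coef_c,
      loglik_full_d = ll_fd, loglik_null_d = ll_nd,
      loglik_full_c = ll_fc, loglik_null_c = ll_nc,
      lrt_stat = lrt, df = df, p_value = p,
      df_discrete = df_d, df_continuous = df_c,
      converged = converged,
      condition_levels = d$levels
    ),
    class = "hurdle_fit"
  )
}

#' Log2 fold change as a difference of group means
#'
#' Difference of group means of the log2-expression values with zeros
#' included: second condition level minus first (reference) level, so with
#' alphabetical RRMS/SPMS levels a positive value means higher in SPMS.
#' This mean-difference estimator is independent of the covariate coding
#' used by the hurdle fit.
#'
#' @param y per-cell log2-expression values.
#' @param groups two-level factor of condition labels.
#' @return scalar log2 fold change.
#' @export
estimate_log2fc <- function(y, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  n <- table(groups)
  if (any(n == 0)) stop("both groups must be non-empty")
  mm <- tapply(y, groups, mean)
  unname(mm[2L] - mm[1L])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement,
#' order-preserving on the input index.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed; NAs are returned
#'   as NA and excluded from the adjustment).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' DGE configuration
#'
#' @param fdr_threshold BH-adjusted p-value cutoff for the DEG flag.
#' @param fc_threshold fold-change cutoff; interpreted per `fc_scale`.
#' @param fc_scale `"ratio"` (default): a gene is fold-change-positive
#'   when `|log2fc| > log2(fc_threshold)` (so 1.1 means a 1.1-fold
#'   change); `"log2"`: when `|log2fc| > fc_threshold` directly.
#' @param min_cells_per_condition minimum cluster cells per condition for
#'   the cluster to be tested at all.
#' @param min_detection_frac detection floor: a gene is tested only when
#'   detected in at least this fraction of the cluster's cells in at
#'   least one condition; set 0 to disable.
#' @param covariates metadata columns adjusted for in the hurdle fit.
#' @return list of class `DgeConfig`.
#' @export
dge_config <- function(fdr_threshold = 0.05,
                       fc_threshold = 1.1,
                       fc_scale = c("ratio", "log2"),
                       min_cells_per_condition = 10,
                       min_detection_frac = 0.05,
                       covariates = c("sex", "age", "rin")) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1, fc_threshold >= 0,
            min_cells_per_condition >= 0, min_detection_frac >= 0,
            min_detection_frac < 1)
  structure(
    list(
      fdr_threshold = fdr_threshold,
      fc_threshold = fc_threshold,
      fc_scale = fc_scale,
      log2fc_cut = if (fc_scale == "ratio") log2(fc_threshold) else fc_threshold,
      min_cells_per_condition = min_cells_per_condition,
      min_detection_frac = min_detection_frac,
      covariates = covariates
    ),
    class = "DgeConfig"
  )
}

#' Hurdle differential expression within one cluster
#'
#' For every gene passing the detection floor, fits the covariate-adjusted
#' hurdle model within the cluster's cells, estimates the log2 fold change
#' as a difference of group means (zeros included), applies BH adjustment
#' over the tested genes of this cluster, and flags DEGs as
#' `fdr < fdr_threshold` and `|log2fc|` above the configured fold-change
#' cutoff. Genes below the floor are returned with `tested = FALSE` and NA
#' statistics.
#'
#' @param x a [log_normalize()] result.
#' @param meta `CellMetadata` covering the matrix's barcodes.
#' @param cluster cluster label to test.
#' @param config a [dge_config()].
#' @return a `data.frame` (DgeTable) with columns gene, cluster, log2fc,
#'   lrt_stat, df, p_value, fdr, is_deg, tested, converged; or `NULL`
#'   (with a message) when the cluster cannot be tested.
#' @export
run_dge <- function(x, meta, cluster, config = dge_config()) {
  stopifnot(inherits(x, "LogExpressionMatrix"), inherits(config, "DgeConfig"))
  meta <- as_cell_metadata(meta)
  idx <- match(x$barcodes, meta$barcode)
  if (anyNA(idx)) stop("metadata is missing ", sum(is.na(idx)), " barcode(s)")
  meta <- meta[idx, , drop = FALSE]

  in_cl <- which(meta$cluster == cluster)
  cond <- droplevels(meta$condition[in_cl])
  n_by_cond <- table(cond)
  if (nlevels(cond) < 2L ||
      any(n_by_cond < config$min_cells_per_condition)) {
    message("cluster '", cluster, "' skipped: needs >= ",
            config$min_cells_per_condition, " cells in each condition (",
            paste(names(n_by_cond), n_by_cond, sep = "=", collapse = ", "), ")")
    return(NULL)
  }

  V <- x$values[in_cl, , drop = FALSE]
  covs <- meta[in_cl, config$covariates, drop = FALSE]

  # detection floor per condition
  det <- vapply(levels(cond), function(l) {
    Matrix::colMeans(V[cond == l, , drop = FALSE] > 0)
  }, numeric(ncol(V)))
  tested <- apply(det, 1L, max) >= config$min_detection_frac & apply(det, 1L, max) > 0

  ng <- ncol(V)
  out <- data.frame(
    gene = x$gene_ids, cluster = cluster,
    log2fc = NA_real_, lrt_stat = NA_real_, df = NA_integer_,
    p_value = NA_real_, fdr = NA_real_,
    is_deg = FALSE, tested = tested, converged = NA,
    stringsAsFactors = FALSE
  )
  for (g in which(tested)) {
    y <- as.numeric(V[, g])
    fit <- fit_hurdle(y, cond, covariates = covs)
    out$log2fc[g] <- estimate_log2fc(y, cond)
    out$lrt_stat[g] <- fit$lrt_stat
    out$df[g] <- fit$df
    out$p_value[g] <- fit$p_value
    out$converged[g] <- fit$converged
  }
  out$fdr[tested] <- bh_adjust(out$p_value[tested])
  out$is_deg <- !is.na(out$fdr) & out$fdr < config$fdr_threshold &
    !is.na(out$log2fc) & abs(out$log2fc) > config$log2fc_cut
  attr(out, "condition_levels") <- levels(cond)
  attr(out, "config") <- config
  class(out) <- c("DgeTable", "data.frame")
  out
}
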