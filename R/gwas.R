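#' Mixed-linear-model association scan
#'
#' Per-marker test of `y = PCs alpha + x_j b_j + u + e` with polygenic
#' effect `u ~ N(0, sigma2_g K)`. Variance components are estimated once
#' by REML on the null (no-marker) model and reused for every marker
#' (the population-parameters-previously-determined approximation;
#' set `exact = TRUE` for per-marker REML). Principal components of the
#' dosage matrix enter as fixed covariates (default 6). Wald tests with
#' t reference distribution.
#'
#' @param g complete `n x m` dosage matrix.
#' @param y phenotype vector.
#' @param kinship `n x n` additive relationship matrix from
#'   [compute_kinship()], or `NULL` for independent residuals (plain
#'   fixed-effect regression).
#' @param n_pcs number of genotype principal components used as fixed
#'   effects (default 6; must be < n).
#' @param exact re-estimate variance components for every marker?
#' @param fdr_level FDR level for the significance call, default 0.05.
#' @return data frame of class `gwas_result`: `marker`, `effect`, `se`,
#'   `stat`, `p`, `q`, `significant`; attributes record the scan settings.
#' @export
mlm_scan <- function(g, y, kinship = NULL, n_pcs = 6, exact = FALSE,
                     fdr_level = 0.05) {
  g <- as.matrix(g)
  n <- nrow(g)
  stopifnot(length(y) == n)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of individuals")
  W <- matrix(1, n, 1)
  if (n_pcs > 0) {
    pcs <- prcomp(g, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                      drop = FALSE]
    W <- cbind(W, pcs)
  }
  p_fix <- ncol(W)
  if (is.null(kinship)) {
    U <- diag(n); d <- rep(0, n)
    v <- rep(1, n)
  } else {
    null_fit <- reml_kernel(y, kinship, W)
    U <- null_fit$U; d <- null_fit$d
    v <- null_fit$phi * d + 1
  }
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  m <- ncol(g)
  eff <- se <- stat <- pval <- rep(NA_real_, m)
  sw <- Ws / v
  for (j in seq_len(m)) {
    xj <- g[, j]
    if (var(xj) == 0) next
    if (exact && !is.null(kinship)) {
      fitj <- reml_kernel(y, kinship, cbind(W, xj))
      vj <- fitj$phi * fitj$d + 1
      ysj <- drop(crossprod(fitj$U, y))
      Dsj <- crossprod(fitj$U, cbind(W, xj))
      XtX <- crossprod(Dsj, Dsj / vj)
      Xty <- crossprod(Dsj, ysj / vj)
      cf <- solve(XtX, Xty)
      r <- ysj - drop(Dsj %*% cf)
      s2 <- sum(r^2 / vj) / (n - p_fix - 1L)
      covb <- solve(XtX)
    } else {
      xs <- drop(crossprod(U, xj))
      Ds <- cbind(Ws, xs)
      XtX <- crossprod(Ds, Ds / v)
      Xty <- crossprod(Ds, ys / v)
      cf <- tryCatch(solve(XtX, Xty), error = function(e) NULL)
      if (is.null(cf)) next
      r <- ys - drop(Ds %*% cf)
      s2 <- sum(r^2 / v) / (n - p_fix - 1L)
      covb <- tryCatch(solve(XtX), error = function(e) NULL)
      if (is.null(covb)) next
    }
    k <- p_fix + 1L
    eff[j] <- cf[k]
    se[j] <- sqrt(s2 * covb[k, k])
    stat[j] <- eff[j] / se[j]
    pval[j] <- 2 * pt(-abs(stat[j]), df = n - p_fix - 1L)
  }
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  sig <- fdr_significant(pval, fdr_level)
  out <- data.frame(marker = ids, effect = eff, se = se, stat = stat,
                    p = pval, q = sig$q, significant = sig$significant)
  attr(out, "n_pcs") <- n_pcs
  attr(out, "kinship") <- !is.null(kinship)
  attr(out, "fdr_level") <- fdr_level
  attr(out, "method") <- "mlm"
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Benjamini-Hochberg significance call
#'
#' Step-up false-discovery-rate control: q-values are `p.adjust(p, "BH")`
#' and markers with `q <= level` are significant. Also reports the
#' realized p-value cutoff (the largest significant raw p-value).
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed, left out of
#'   the adjustment).
#' @param level FDR level, default 0.05.
#' @return list with `significant` (logical), `q` (adjusted p-values),
#'   `threshold` (realized p cutoff, `NA` if nothing is significant).
#' @export
fdr_significant <- function(pvalues, level = 0.05) {
  q <- p.adjust(pvalues, method = "BH")
  sig <- !is.na(q) & q <= level
  thr <- if (any(sig)) max(pvalues[sig]) else NA_real_
  list(significant = sig, q = q, threshold = thr)
}

#' Extended-Bayesian-lasso association scan
#'
#' Fits the EBL whole-genome regression (shared code path with
#' [fit_shrinkage()]) and reports per-marker posterior-mean effects.
#' Associations are called where the absolute effect exceeds `k_sd`
#' standard deviations of all marker effects; this call threshold is a
#' configurable policy of this package (the scan itself only yields the
#' effect sizes). The default of 10 SD is conservative: posterior-mean
#' effects under this prior are heavy-tailed, and chance extremes on a
#' trait with no genetic signal routinely reach 5-8 SD.
#'
#' @inheritParams fit_shrinkage
#' @param theta EBL shrinkage hyperparameter, default 1e-4.
#' @param k_sd association call threshold in effect-SD units, default 10.
#' @return data frame of class `gwas_result` with `marker`, `effect`,
#'   `significant`; the fitted model is attached as attribute `model`.
#' @export
ebl_scan <- function(g, y, theta = 1e-4, k_sd = 10,
                     config = shrinkage_config()) {
  config$theta <- theta
  model <- fit_shrinkage(g, y, "ebl", config)
  eff <- model$beta
  thr <- k_sd * sd(eff)
  out <- data.frame(marker = model$marker_ids, effect = unname(eff),
                    significant = abs(eff) > thr)
  attr(out, "threshold") <- thr
  attr(out, "k_sd") <- k_sd
  attr(out, "method") <- "ebl"
  attr(out, "model") <- model
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Regression of a trait on significant markers with AIC selection
#'
#' Ordinary least squares of the trait on the candidate (GWAS-significant)
#' markers. With two or more candidates, bidirectional stepwise search
#' minimizing AIC prunes the model; collinear candidates are dropped
#' before the search. Reports the candidate count, the selected count and
#' the model r-squared, mirroring marker-assisted-selection predictability
#' summaries.
#'
#' @param y phenotype vector.
#' @param g_sig `n x k` dosage matrix of the candidate markers.
#' @return list of class `sig_marker_regression` with `candidates`,
#'   `selected`, `n_candidates`, `n_selected`, `coefficients`, `r2`.
#' @export
sig_marker_regression <- function(y, g_sig) {
  g_sig <- as.matrix(g_sig)
  if (ncol(g_sig) < 1L) stop("at least one candidate marker is required")
  ids <- colnames(g_sig)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(g_sig)))
  colnames(g_sig) <- make.names(ids)
  df <- data.frame(y = y, g_sig, check.names = FALSE)
  full <- lm(y ~ ., data = df)
  # drop aliased (collinear) candidates before the search
  alias <- names(which(is.na(coef(full))))
  if (length(alias)) {
    keepcols <- setdiff(colnames(g_sig), alias)
    df <- data.frame(y = y, g_sig[, keepcols, drop = FALSE],
                     check.names = FALSE)
    full <- lm(y ~ ., data = df)
  }
  fit <- if (ncol(df) > 2L) {
    step(full, direction = "both", trace = 0)
  } else full
  sel <- setdiff(names(coef(fit)), "(Intercept)")
  structure(list(candidates = ids,
                 selected = ids[match(sel, make.names(ids))],
                 n_candidates = length(ids),
                 n_selected = length(sel),
                 coefficients = coef(fit),
                 r2 = summary(fit)$r.squared),
            class = "sig_marker_regression")
}

#' @export
print.sig_marker_regression <- function(x, ...) {
  cat(sprintf("significant-marker regression: %d candidates, %d selected, r2 = %.3f\n",
              x$n_candidates, x$n_selected, x$r2))
  invisible(x)
}
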