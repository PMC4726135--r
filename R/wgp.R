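# Whole-genome prediction models. All fitters return a `marker_effect_model`
# whose GEBVs for new genotypes come from predict_gebv(); linear kinds store
# an intercept and per-marker additive effects, RKHS stores the training
# genotypes and dual weights.

# REML for y = W alpha + u + e, u ~ N(0, sigma2_g K), via spectral
# decomposition of K; profiles the variance ratio phi = sigma2_g / sigma2_e.
reml_kernel <- function(y, K, W = NULL, interval = c(-12, 12)) {
  n <- length(y)
  if (is.null(W)) W <- matrix(1, n, 1)
  p <- ncol(W)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  crit <- function(logphi) {
    phi <- exp(logphi)
    v <- phi * d + 1
    WtW <- crossprod(Ws, Ws / v)
    alpha <- solve(WtW, crossprod(Ws, ys / v))
    r <- ys - drop(Ws %*% alpha)
    s2e <- sum(r^2 / v) / (n - p)
    0.5 * ((n - p) * log(s2e) + sum(log(v)) +
             as.numeric(determinant(WtW)$modulus))
  }
  opt <- optimize(crit, interval)
  phi <- exp(opt$minimum)
  v <- phi * d + 1
  WtW <- crossprod(Ws, Ws / v)
  alpha <- drop(solve(WtW, crossprod(Ws, ys / v)))
  r <- ys - drop(Ws %*% alpha)
  s2e <- sum(r^2 / v) / (n - p)
  list(phi = phi, sigma2_g = phi * s2e, sigma2_e = s2e, alpha = alpha,
       U = U, d = d, v = v, resid_rot = r,
       converged = opt$minimum > interval[1] + 1e-6 &&
         opt$minimum < interval[2] - 1e-6)
}

new_marker_effect_model <- function(kind, mu, beta = NULL, center = NULL,
                                    marker_ids = NULL, extra = list()) {
  structure(c(list(kind = kind, mu = mu, beta = beta, center = center,
                   marker_ids = marker_ids), extra),
            class = "marker_effect_model")
}

#' @export
print.marker_effect_model <- function(x, ...) {
  cat(sprintf("marker_effect_model (%s): intercept %.4g, %d markers\n",
              x$kind, x$mu, length(x$marker_ids)))
  invisible(x)
}

#' Ridge-regression BLUP of marker effects
#'
#' Fits `y = mu + X beta + e` with `beta ~ N(0, sigma2_b I)`. Unless a
#' fixed ridge parameter is supplied, the variance components are
#' estimated by REML on the equivalent kinship (GBLUP) model using a
#' spectral decomposition of the centered cross-product, and the returned
#' effects are the BLUPs `sigma2_b X' V^-1 (y - mu)`.
#'
#' @param g complete `n x m` dosage matrix.
#' @param y numeric phenotype vector, length `n`, no missing values.
#' @param lambda optional fixed ridge parameter `sigma2_e / sigma2_b`;
#'   `NULL` (default) estimates it by REML.
#' @return a `marker_effect_model` of kind `"RR"` with fields `mu`, `beta`,
#'   variance components and a convergence flag.
#' @export
fit_rr <- function(g, y, lambda = NULL) {
  g <- as.matrix(g)
  n <- nrow(g)
  stopifnot(length(y) == n, !anyNA(y), n >= 2)
  if (anyNA(g)) stop("missing dosages; impute first")
  m <- ncol(g)
  if (m == 0L)
    return(new_marker_effect_model("RR", mean(y), numeric(0), numeric(0),
                                   character(0)))
  ctr <- colMeans(g)
  X <- sweep(g, 2L, ctr, "-")
  K <- tcrossprod(X)
  if (is.null(lambda)) {
    fit <- reml_kernel(y, K)
    phi <- fit$phi          # sigma2_b / sigma2_e
    sigma2_b <- fit$sigma2_g
    sigma2_e <- fit$sigma2_e
    conv <- fit$converged
    U <- fit$U; d <- fit$d
  } else {
    stopifnot(lambda > 0)
    phi <- 1 / lambda
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors; d <- pmax(eig$values, 0)
    sigma2_b <- NA_real_; sigma2_e <- NA_real_
    conv <- TRUE
  }
  v <- phi * d + 1
  ys <- drop(crossprod(U, y))
  ones <- drop(crossprod(U, rep(1, n)))
  mu <- sum(ones * ys / v) / sum(ones^2 / v)
  w <- (ys - mu * ones) / v            # V^-1 (y - mu) in rotated basis
  beta <- phi * drop(crossprod(X, U %*% w))
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  new_marker_effect_model(
    "RR", mu, beta, ctr, ids,
    list(sigma2_b = sigma2_b, sigma2_e = sigma2_e,
         lambda = if (is.null(lambda)) 1 / phi else lambda,
         converged = conv))
}

#' Sampler settings for the Bayesian-alphabet fitters
#'
#' @param niter,burnin Gibbs chain length and discarded burn-in
#'   (`niter > burnin`).
#' @param seed integer RNG seed; fits are bit-reproducible given the seed.
#' @param theta rate hyperparameter of the gamma prior on the EBL
#'   marker-specific shrinkage parameters; small values leave large
#'   effects nearly unshrunk. Default 1e-4.
#' @param phi,omega,psi EBL gamma hyperprior shape/rate parameters for the
#'   global (`phi`, `omega`) and marker-specific (`psi`, `theta`) terms.
#' @param r_lambda,delta_lambda gamma hyperprior on the BL global
#'   shrinkage parameter lambda^2.
#' @param pi prior inclusion probability for Bayes C.
#' @param estimate_pi update Bayes C's pi from the data (beta-binomial)?
#' @param nu_b Bayes C slab-variance prior degrees of freedom.
#' @param r2 prior guess of the fraction of phenotypic variance captured
#'   by markers, used to scale the residual and slab variance priors.
#' @return list of class `shrinkage_config`.
#' @export
shrinkage_config <- function(niter = 1500, burnin = 500, seed = 1,
                             theta = 1e-4, phi = 1, omega = 0.01, psi = 1,
                             r_lambda = 1, delta_lambda = 1e-4,
                             pi = 0.1, estimate_pi = TRUE, nu_b = 5,
                             r2 = 0.5) {
  stopifnot(niter > burnin, theta > 0, pi > 0, pi < 1)
  structure(list(niter = as.integer(niter), burnin = as.integer(burnin),
                 seed = as.integer(seed), theta = theta, phi = phi,
                 omega = omega, psi = psi, r_lambda = r_lambda,
                 delta_lambda = delta_lambda, pi = pi,
                 estimate_pi = isTRUE(estimate_pi), nu_b = nu_b, r2 = r2),
            class = "shrinkage_config")
}

#' Bayesian shrinkage regressions (BL, EBL, Bayes C)
#'
#' Posterior-mean marker effects by Gibbs sampling under the method's
#' prior: Bayesian lasso (double-exponential effects), extended Bayesian
#' lasso (marker-specific double-exponential scales, hyperparameter
#' `theta`), or Bayes C (spike-and-slab with common slab variance and
#' inclusion probability `pi`). Bayes C additionally returns per-marker
#' posterior inclusion probabilities.
#'
#' @inheritParams fit_rr
#' @param method one of `"bl"`, `"ebl"`, `"bayesc"`.
#' @param config a [shrinkage_config()].
#' @return a `marker_effect_model`; for Bayes C with an extra `pip` field.
#' @export
fit_shrinkage <- function(g, y, method = c("bl", "ebl", "bayesc"),
                          config = shrinkage_config()) {
  method <- match.arg(method)
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  n <- nrow(g)
  stopifnot(length(y) == n, !anyNA(y), n >= 2)
  if (anyNA(g)) stop("missing dosages; impute first")
  m <- ncol(g)
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  if (m == 0L)
    return(new_marker_effect_model(toupper(method), mean(y), numeric(0),
                                   numeric(0), character(0)))
  ctr <- colMeans(g)
  X <- sweep(g, 2L, ctr, "-")
  vy <- var(y)
  if (vy == 0) vy <- 1e-8
  nu_e <- 5
  S_e <- vy * (1 - config$r2)
  # seed the sampler reproducibly without disturbing the caller's stream
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(config$seed)
  fit <- switch(method,
    bl = .gibbs_bl(X, y, config$niter, config$burnin, config$r_lambda,
                   config$delta_lambda, nu_e, S_e),
    ebl = .gibbs_ebl(X, y, config$niter, config$burnin, config$phi,
                     config$omega, config$psi, config$theta, nu_e, S_e),
    bayesc = {
      msx <- sum(apply(X, 2L, var))
      if (msx == 0) msx <- 1
      S_b <- vy * config$r2 / (msx * config$pi)
      .gibbs_bayesc(X, y, config$niter, config$burnin, config$pi,
                    config$estimate_pi, config$nu_b, S_b, nu_e, S_e)
    })
  extra <- list(sigma2_e = fit$sigma2_e, config = config,
                n_samples = fit$n_samples, converged = TRUE)
  if (method == "bayesc") {
    extra$pip <- setNames(drop(fit$pip), ids)
    extra$pi <- fit$pi
  }
  kind <- c(bl = "BL", ebl = "EBL", bayesc = "BayesC")[[method]]
  new_marker_effect_model(kind, fit$mu, setNames(drop(fit$beta), ids),
                          ctr, ids, extra)
}

#' Gaussian-kernel RKHS regression
#'
#' Kernel mixed model `y = mu + u + e`, `u ~ N(0, sigma2_g K)` with
#' `K[i,k] = exp(-d2(i,k) / (bandwidth * m))` on squared Euclidean
#' distances between dosage rows; variance components by REML. Predictions
#' for new genotypes use the kernel against the training genotypes.
#'
#' @inheritParams fit_rr
#' @param bandwidth kernel bandwidth; `NULL` uses the median of the
#'   per-marker-scaled squared distances (median heuristic).
#' @return a `marker_effect_model` of kind `"RKHS"` storing the training
#'   genotypes and dual weights.
#' @export
fit_rkhs <- function(g, y, bandwidth = NULL) {
  g <- as.matrix(g)
  n <- nrow(g)
  stopifnot(length(y) == n, !anyNA(y), n >= 2)
  if (anyNA(g)) stop("missing dosages; impute first")
  m <- ncol(g)
  if (m == 0L)
    return(new_marker_effect_model("RKHS", mean(y), NULL, NULL, character(0)))
  d2 <- sq_dist(g, g)
  if (is.null(bandwidth)) {
    off <- d2[upper.tri(d2)] / m
    bandwidth <- stats::median(off[off > 0])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  K <- exp(-d2 / (bandwidth * m))
  jit <- 1e-8
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6 * n) stop("kernel matrix is not positive semidefinite")
  fit <- reml_kernel(y, K + jit * diag(n))
  mu <- fit$alpha[1L]
  # dual weights: sigma2_g * V^-1 (y - mu), so u(new) = K_new %*% weights
  w <- fit$sigma2_g * drop(fit$U %*% (fit$resid_rot / (fit$sigma2_g * fit$d + fit$sigma2_e)))
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  new_marker_effect_model(
    "RKHS", mu, NULL, NULL, ids,
    list(train = g, dual = w, bandwidth = bandwidth,
         sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
         converged = fit$converged))
}

sq_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Genomic estimated breeding values for new genotypes
#'
#' Deterministic prediction from a fitted model: `mu + X beta` for the
#' linear kinds, kernel regression against the training genotypes for
#' RKHS. The marker set and order of `g_new` must match the model.
#'
#' @param model a `marker_effect_model`.
#' @param g_new `n_new x m` dosage matrix with the model's markers.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, g_new) {
  stopifnot(inherits(model, "marker_effect_model"))
  g_new <- as.matrix(g_new)
  m <- length(model$marker_ids)
  if (ncol(g_new) != m)
    stop(sprintf("expected %d markers, got %d", m, ncol(g_new)))
  ids <- colnames(g_new)
  if (!is.null(ids) && length(model$marker_ids)) {
    mism <- which(ids != model$marker_ids)
    if (length(mism))
      stop("marker mismatch at ", ids[mism[1L]])
  }
  if (m == 0L) return(rep(model$mu, nrow(g_new)))
  if (model$kind == "RKHS") {
    K_new <- exp(-sq_dist(g_new, model$train) / (model$bandwidth * m))
    return(drop(model$mu + K_new %*% model$dual))
  }
  drop(model$mu + sweep(g_new, 2L, model$center, "-") %*% model$beta)
}

#' @export
predict.marker_effect_model <- function(object, newdata, ...) {
  predict_gebv(object, newdata)
}

fit_wgp <- function(g, y, method, config = shrinkage_config(), ...) {
  switch(method,
         rr = fit_rr(g, y, ...),
         rkhs = fit_rkhs(g, y, ...),
         bl = ,
         ebl = ,
         bayesc = fit_shrinkage(g, y, method, config),
         stop("unknown WGP method: ", method))
}

#' Leave-one-out cross-validation of prediction accuracy
#'
#' Each individual is held out in turn, the model refitted on the
#' remaining `n - 1`, and the held-out GEBV predicted; accuracy is the
#' Pearson correlation between observed phenotypes and the LOOCV GEBVs.
#' For the sampler-based methods each fold uses a seed derived from the
#' config seed, so the whole report is reproducible.
#'
#' @inheritParams fit_shrinkage
#' @param method `"rr"`, `"bl"`, `"ebl"`, `"bayesc"` or `"rkhs"`.
#' @param trait optional trait label recorded in the report.
#' @param ... further arguments passed to the fitter (e.g. a fixed
#'   `lambda` for `"rr"`, `bandwidth` for `"rkhs"`).
#' @return list of class `cv_report` with `accuracy`, `predicted`,
#'   `observed`, `method`, `trait`.
#' @export
loocv <- function(g, y, method = "rr", config = shrinkage_config(),
                  trait = NA_character_, ...) {
  g <- as.matrix(g)
  n <- nrow(g)
  stopifnot(n >= 3, length(y) == n)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fit <- fit_wgp(g[-i, , drop = FALSE], y[-i], method, cfg_i, ...)
    pred[i] <- predict_gebv(fit, g[i, , drop = FALSE])
  }
  acc <- if (sd(pred) == 0 || sd(y) == 0) NA_real_ else cor(y, pred)
  structure(list(accuracy = acc, predicted = pred, observed = y,
                 method = method, trait = trait, n = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV %s%s: accuracy %.3f over %d folds\n", x$method,
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$accuracy, x$n))
  invisible(x)
}

#' Pick the best prediction method per trait by LOOCV
#'
#' Runs [loocv()] for every trait/method combination and returns the
#' per-trait winner by accuracy, mirroring the practice of computing
#' GEBVs with the method of highest LOOCV predictability per trait.
#'
#' @param g complete dosage matrix.
#' @param phenotypes `n x t` matrix of trait values.
#' @param methods character vector of candidate methods.
#' @param config a [shrinkage_config()].
#' @return list with `table` (trait x method accuracies), `best` (named
#'   character vector), and `models` (refitted best model per trait).
#' @export
select_best_models <- function(g, phenotypes,
                               methods = c("rr", "bl", "ebl", "bayesc", "rkhs"),
                               config = shrinkage_config()) {
  phenotypes <- as.matrix(phenotypes)
  traits <- colnames(phenotypes)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(phenotypes)))
  acc <- matrix(NA_real_, length(traits), length(methods),
                dimnames = list(traits, methods))
  for (t in seq_along(traits)) {
    for (mth in methods) {
      acc[t, mth] <- loocv(g, phenotypes[, t], mth, config,
                           trait = traits[t])$accuracy
    }
  }
  best <- methods[apply(acc, 1L, which.max)]
  names(best) <- traits
  models <- lapply(seq_along(traits), function(t)
    fit_wgp(g, phenotypes[, t], best[t], config))
  names(models) <- traits
  list(table = acc, best = best, models = models)
}
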