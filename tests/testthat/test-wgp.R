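test_that("ridge with fixed lambda matches the closed-form solution", {
  set.seed(21)
  X <- matrix(rbinom(15, 2, 0.5), 5, 3)
  y <- rnorm(5)
  lambda <- 2.5
  fit <- fit_rr(X, y, lambda = lambda)
  # brute-force GLS oracle: V = Xc Xc' / lambda + I (sigma2_e = 1 scale)
  Xc <- sweep(X, 2, colMeans(X))
  V <- tcrossprod(Xc) / lambda + diag(5)
  one <- rep(1, 5)
  mu <- drop(solve(t(one) %*% solve(V) %*% one,
                   t(one) %*% solve(V) %*% y))
  beta <- drop(solve(crossprod(Xc) + lambda * diag(3),
                     crossprod(Xc, y - mu)))
  expect_equal(fit$mu, mu, tolerance = 1e-8)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-8)
})

test_that("marker-effect RR-BLUP equals GBLUP with matched variance components", {
  b <- tiny_bundle()
  g <- impute_mean(filter_markers(b$d)$genotypes)
  y <- b$phe$values[, 2]
  fit <- fit_rr(g, y)
  # independent GBLUP route: u = sigma2_b * K_X * V^-1 (y - mu) with
  # K_X = Xc Xc'
  Xc <- sweep(g, 2, colMeans(g))
  Kx <- tcrossprod(Xc)
  V <- fit$sigma2_b * Kx + fit$sigma2_e * diag(nrow(g))
  u_gblup <- drop(fit$sigma2_b * Kx %*% solve(V, y - fit$mu))
  gebv_marker <- predict_gebv(fit, g)
  expect_equal(gebv_marker, fit$mu + u_gblup, tolerance = 1e-6)
})

test_that("constant phenotypes give zero effects and intercept-only models", {
  g <- matrix(rbinom(60, 2, 0.5), 10, 6)
  y <- rep(3.2, 10)
  fit <- fit_rr(g, y)
  expect_equal(fit$mu, 3.2, tolerance = 1e-6)
  expect_equal(max(abs(fit$beta)), 0, tolerance = 1e-6)
  # zero markers: every kind predicts the intercept
  g0 <- matrix(numeric(0), 10, 0)
  y2 <- rnorm(10)
  for (mth in c("rr", "bl", "ebl", "bayesc", "rkhs")) {
    fit0 <- fit_wgp <- switch(mth,
      rr = fit_rr(g0, y2),
      rkhs = fit_rkhs(g0, y2),
      fit_shrinkage(g0, y2, mth, shrinkage_config(niter = 50, burnin = 10)))
    expect_equal(predict_gebv(fit0, g0), rep(mean(y2), 10))
  }
})

test_that("shrinkage fits shrink null effects far below QTL-signal effects", {
  set.seed(31)
  n <- 300; m <- 300; nq <- 100
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  qtl <- sort(sample.int(m, nq))
  gsig <- drop(X[, qtl] %*% sample(c(-1, 1), nq, replace = TRUE))
  y_sig <- gsig + rnorm(n, 0, sd(gsig) * 0.5)  # polygenic trait, h2 = 0.8
  y_null <- rnorm(n, 0, sd(y_sig))   # same scale, no genetic signal
  cfg <- shrinkage_config(niter = 800, burnin = 300, seed = 5)
  for (mth in c("bl", "ebl", "bayesc")) {
    f_sig <- fit_shrinkage(X, y_sig, mth, cfg)
    f_null <- fit_shrinkage(X, y_null, mth, cfg)
    expect_lt(mean(abs(f_null$beta)), 0.10 * mean(abs(f_sig$beta)))
  }
})

test_that("Bayes C inclusion probabilities rank planted QTLs on top", {
  set.seed(32)
  n <- 200; m <- 1000; nq <- 10
  X <- matrix(rbinom(n * m, 2, 0.4), n, m)
  qtl <- sort(sample.int(m, nq))
  bq <- sample(c(-1, 1), nq, replace = TRUE) * runif(nq, 0.8, 1.5)
  gval <- drop(X[, qtl] %*% bq)
  h2 <- 0.8
  y <- gval + rnorm(n, 0, sd(gval) * sqrt((1 - h2) / h2))
  fit <- fit_shrinkage(X, y, "bayesc",
                       shrinkage_config(niter = 1200, burnin = 400, seed = 6))
  top <- order(-fit$pip)[seq_len(2 * nq)]
  expect_gte(length(intersect(qtl, top)), 8)
})

test_that("shrinkage fits are bit-reproducible under a fixed seed", {
  b <- tiny_bundle()
  g <- impute_mean(b$d[, 1:60])
  y <- b$phe$values[, 1]
  cfg <- shrinkage_config(niter = 200, burnin = 50, seed = 77)
  f1 <- fit_shrinkage(g, y, "ebl", cfg)
  f2 <- fit_shrinkage(g, y, "ebl", cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$mu, f2$mu)
})

test_that("RKHS kernel entries match the Gaussian-kernel formula", {
  g <- matrix(c(0, 1, 2, 2,
                1, 1, 0, 2,
                2, 0, 0, 1,
                0, 2, 1, 1), 4, 4, byrow = TRUE)
  y <- c(1, 2, 3, 4)
  bw <- 0.7
  fit <- fit_rkhs(g, y, bandwidth = bw)
  d2 <- as.matrix(dist(g))^2
  K_hand <- exp(-d2 / (bw * ncol(g)))
  K_fit <- exp(-breedsim:::sq_dist(g, g) / (bw * ncol(g)))
  expect_equal(K_fit, K_hand, ignore_attr = TRUE, tolerance = 1e-12)
  # infinite-bandwidth limit: predictions collapse to a constant
  fit_inf <- fit_rkhs(g, y, bandwidth = 1e9)
  expect_lt(diff(range(predict_gebv(fit_inf, g))), 1e-3)
})

test_that("RKHS matches RR accuracy on a purely additive trait", {
  set.seed(41)
  n <- 80; m <- 150
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  bt <- rnorm(m, 0, 0.1)
  gval <- drop(X %*% bt)
  y <- gval + rnorm(n, 0, sd(gval) * 0.6)
  acc_rr <- loocv(X, y, "rr")$accuracy
  acc_rkhs <- loocv(X, y, "rkhs")$accuracy
  expect_lt(abs(acc_rr - acc_rkhs), 0.12)
})

test_that("GEBV prediction is deterministic, linear and checks marker ids", {
  b <- tiny_bundle()
  g <- impute_mean(b$d[, 1:50])
  y <- b$phe$values[, 3]
  fit <- fit_rr(g, y)
  # all-reference individual
  zero <- matrix(0, 1, 50, dimnames = list(NULL, colnames(g)))
  expect_equal(predict_gebv(fit, zero),
               fit$mu - sum(fit$center * fit$beta))
  # in-sample identity and linearity in a single marker dosage
  p0 <- predict_gebv(fit, g)
  expect_equal(p0, predict_gebv(fit, g))
  gp <- g; gp[, 7] <- gp[, 7] + 1
  expect_equal(unname(predict_gebv(fit, gp) - p0),
               rep(unname(fit$beta[7]), nrow(g)))
  # mismatched marker ids are named
  gbad <- g; colnames(gbad)[3] <- "nope"
  expect_error(predict_gebv(fit, gbad), "nope")
})

test_that("LOOCV approaches 1 in the noiseless limit and 0 under permutation", {
  set.seed(51)
  n <- 150
  x <- rbinom(n, 2, 0.5)
  X <- cbind(x, matrix(rbinom(n * 10, 2, 0.5), n, 10))
  y <- 2 * x + rnorm(n, 0, 0.05)
  expect_gt(loocv(X, y, "rr")$accuracy, 0.95)
  # permutation destroys the signal: no positive predictive ability
  # remains. (LOOCV correlation is negatively biased under the null --
  # each fold's prediction leans on the leave-one-out mean, which
  # anti-correlates with the held-out value -- so the null lands at or
  # below zero, never at positive accuracy.)
  yperm <- sample(y)
  expect_lt(loocv(X, yperm, "rr")$accuracy, 0.1)
  # the REML fit on permuted data indeed finds ~no genetic variance
  fit_perm <- fit_rr(X, yperm)
  expect_lt(fit_perm$sigma2_b * sum(apply(X, 2, var)),
            0.2 * var(yperm))
})

test_that("LOOCV accuracy increases with heritability and respects sqrt(h2)", {
  set.seed(61)
  n <- 100; m <- 200
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  bt <- rnorm(m, 0, 1)
  gval <- drop(X %*% bt)
  gval <- (gval - mean(gval)) / sd(gval)
  accs <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    y <- gval + rnorm(n, 0, sqrt((1 - h2) / h2))
    loocv(X, y, "rr")$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))  # monotone within Monte-Carlo error
  expect_lt(accs[3], sqrt(0.8) + 0.1)
})

test_that("best-model selection picks the highest-LOOCV method per trait", {
  b <- tiny_bundle()
  g <- impute_mean(b$d[, 1:60])
  phe <- b$phe$values[, 1:2]
  sel <- select_best_models(g, phe, methods = c("rr", "rkhs"),
                            config = shrinkage_config(niter = 100, burnin = 20))
  expect_equal(dim(sel$table), c(2L, 2L))
  for (tr in rownames(sel$table)) {
    expect_equal(unname(sel$best[tr]),
                 colnames(sel$table)[which.max(sel$table[tr, ])])
  }
  expect_s3_class(sel$models[[1]], "marker_effect_model")
})
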