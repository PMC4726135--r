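#' Broad-sense heritability from replicated trials
#'
#' One observation per individual per replicate year is decomposed by
#' one-way ANOVA with individual as the factor. From the expected mean
#' squares, the residual variance is the within-individual mean square and
#' the genetic variance is `(MS_between - MS_within) / y` for `y` replicate
#' years; negative genetic-variance estimates are truncated to zero.
#' Broad-sense heritability is `h2 = sigma2_G / (sigma2_G + sigma2_E)`
#' (0 when both variances are zero).
#'
#' @param replicates `n x y` numeric matrix, individuals by replicate years
#'   (`NA` allowed; unbalanced data are handled by the ANOVA fit).
#' @return list of class `h2_estimate` with `sigma2_G`, `sigma2_E`, `h2`,
#'   `n_replicates`.
#' @examples
#' y <- matrix(rnorm(40), 10, 4) + rnorm(10)
#' estimate_heritability(y)
#' @export
estimate_heritability <- function(replicates) {
  replicates <- as.matrix(replicates)
  y <- ncol(replicates)
  if (y < 2L) stop("at least two replicate years are required")
  long <- data.frame(
    value = as.vector(replicates),
    ind = factor(rep(seq_len(nrow(replicates)), y)))
  long <- long[!is.na(long$value), ]
  fit <- aov(value ~ ind, data = long)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  ms_between <- ms[1L]
  ms_within <- if (length(ms) > 1L) ms[2L] else 0
  if (!is.finite(ms_within)) ms_within <- 0
  # replicates per individual; with complete data this is y
  reps <- mean(table(long$ind))
  sigma2_E <- ms_within
  sigma2_G <- max((ms_between - ms_within) / reps, 0)
  denom <- sigma2_G + sigma2_E
  h2 <- if (denom > 0) sigma2_G / denom else 0
  structure(list(sigma2_G = sigma2_G, sigma2_E = sigma2_E, h2 = h2,
                 n_replicates = y),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.3f (sigma2_G = %.3g, sigma2_E = %.3g, %d replicates)\n",
              x$h2, x$sigma2_G, x$sigma2_E, x$n_replicates))
  invisible(x)
}
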