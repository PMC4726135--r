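#' Pairwise linkage disequilibrium (r-squared) from phased haplotypes
#'
#' For each marker pair, r^2 is the squared Pearson correlation between the
#' two markers' allele indicators over all `2n` haplotypes. Pairs involving
#' a monomorphic marker have undefined LD and are returned as `NA`.
#'
#' @param pop a [phased_population()].
#' @param pairs two-column matrix (or data frame) of marker indices or ids.
#' @param map optional `linkage_map` restricted to the same markers; if
#'   given, genetic and physical pair distances are reported.
#' @return data frame of class `ld_result` with columns `marker1`,
#'   `marker2`, `r2`, and when a map is supplied `dist_cm`, `dist_bp`
#'   (`NA` across chromosomes).
#' @export
compute_ld_r2 <- function(pop, pairs, map = NULL) {
  stopifnot(inherits(pop, "phased_pop"))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (is.character(pairs)) {
    idx <- matrix(match(pairs, pop$marker_ids), ncol = 2L)
    if (anyNA(idx)) stop("unknown marker id in pairs")
  } else {
    idx <- pairs
    storage.mode(idx) <- "integer"
  }
  h <- pop$hap
  freq <- colMeans(h, na.rm = TRUE)
  mono <- freq %in% c(0, 1) | is.na(freq)
  r2 <- vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (mono[i] || mono[j]) return(NA_real_)
    cor(h[, i], h[, j], use = "complete.obs")^2
  }, numeric(1))
  out <- data.frame(marker1 = pop$marker_ids[idx[, 1L]],
                    marker2 = pop$marker_ids[idx[, 2L]],
                    r2 = r2)
  if (!is.null(map)) {
    mi <- match(out$marker1, map$marker)
    mj <- match(out$marker2, map$marker)
    same <- map$chrom[mi] == map$chrom[mj]
    out$dist_cm <- ifelse(same, abs(map$pos_cm[mi] - map$pos_cm[mj]), NA_real_)
    if (!is.null(map$pos_bp))
      out$dist_bp <- ifelse(same, abs(map$pos_bp[mi] - map$pos_bp[mj]), NA_real_)
  }
  class(out) <- c("ld_result", "data.frame")
  out
}
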