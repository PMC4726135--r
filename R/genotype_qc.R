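#' Encode biallelic genotype calls as alternate-allele dosages
#'
#' Genotypes are scored 0 and 2 for the two homozygotes and 1 for the
#' heterozygote; the homozygote for the alternate allele scores 2, so the
#' code is the alternate-allele dosage and the mapping is deterministic
#' given the per-marker reference/alternate assignment.
#'
#' @param calls `n x m` character matrix of two-letter genotype calls
#'   (e.g. `"GG"`, `"GA"`, `"AG"`, `"AA"`); `NA` or `""` = missing.
#' @param ref,alt length-`m` character vectors of reference and alternate
#'   allele symbols per marker.
#' @return `n x m` integer dosage matrix in `{0,1,2}` with `NA` for missing,
#'   preserving dimnames.
#' @examples
#' calls <- matrix(c("GG", "GA", "AA"), ncol = 1)
#' encode_genotypes(calls, ref = "G", alt = "A")
#' @export
encode_genotypes <- function(calls, ref, alt) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (length(ref) != m || length(alt) != m)
    stop("ref/alt must have one entry per marker")
  out <- matrix(NA_integer_, nrow(calls), m, dimnames = dimnames(calls))
  ids <- colnames(calls)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  for (j in seq_len(m)) {
    cj <- calls[, j]
    miss <- is.na(cj) | cj == ""
    a1 <- substr(cj, 1L, 1L)
    a2 <- substr(cj, 2L, 2L)
    seen <- unique(c(a1[!miss], a2[!miss]))
    bad <- setdiff(seen, c(ref[j], alt[j]))
    if (length(bad) > 0L) {
      if (length(seen) > 2L)
        stop(sprintf("marker %s: more than two alleles observed", ids[j]))
      stop(sprintf("marker %s: unknown allele symbol '%s'", ids[j], bad[1L]))
    }
    out[, j] <- (a1 == alt[j]) + (a2 == alt[j])
    out[miss, j] <- NA_integer_
  }
  out
}

#' Filter markers on missing rate and minor allele frequency
#'
#' Retains markers whose missing-data fraction is at most `max_missing`
#' and whose minor allele frequency is strictly greater than `min_maf`
#' (a marker with MAF exactly at the threshold is removed). Marker order
#' is preserved.
#'
#' @param g `n x m` dosage matrix (`NA` = missing).
#' @param max_missing maximum tolerated missing fraction, default 0.05.
#' @param min_maf exclusive lower MAF bound, default 0.05.
#' @return list of class `marker_filter` with `genotypes` (retained
#'   columns), `keep` (logical length `m`), and `report` (data frame with
#'   per-marker maf, missing rate and retention flag).
#' @export
filter_markers <- function(g, max_missing = 0.05, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  maf <- marker_maf(g)
  miss <- marker_missing_rate(g)
  keep <- !is.na(maf) & miss <= max_missing & maf > min_maf
  if (!any(keep)) warning("no markers pass the filters")
  ids <- colnames(g)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(g)))
  structure(
    list(genotypes = g[, keep, drop = FALSE],
         keep = keep,
         report = data.frame(marker = ids, maf = maf, missing_rate = miss,
                             retained = keep, row.names = NULL)),
    class = "marker_filter")
}

#' @export
print.marker_filter <- function(x, ...) {
  cat(sprintf("marker_filter: %d / %d markers retained\n",
              sum(x$keep), length(x$keep)))
  invisible(x)
}

#' Mean-impute missing dosages per marker
#' @param g dosage matrix with `NA`s.
#' @return numeric matrix with each `NA` replaced by its marker mean.
#' @export
impute_mean <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  if (nrow(idx)) g[idx] <- mu[idx[, 2L]]
  g
}

#' Additive (VanRaden) kinship matrix
#'
#' Centered cross-product of dosages normalized by `2 * sum(p * (1 - p))`
#' over the allele frequencies `p`, the standard additive genomic
#' relationship matrix used as the polygenic covariance in mixed models.
#' Invariant to marker order, to duplicating markers, and to swapping the
#' reference/alternate labelling of any marker.
#'
#' @param g complete `n x m` dosage matrix (no missing values; impute
#'   first with [impute_mean()]).
#' @return symmetric positive semidefinite `n x n` matrix.
#' @export
compute_kinship <- function(g) {
  if (anyNA(g)) stop("kinship requires complete dosages; impute first")
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; kinship undefined")
  z <- sweep(g, 2L, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  tcrossprod(z) / denom
}
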