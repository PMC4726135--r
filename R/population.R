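#' Phased population container
#'
#' A phased diploid population is stored as a `2n x m` integer matrix of
#' allele codes (0 = reference, 1 = alternate), two consecutive rows per
#' individual (haplotype 1, haplotype 2). Missing alleles are `NA`.
#'
#' @param haplotypes `2n x m` matrix of 0/1 allele codes (`NA` allowed), or
#'   an `n x 2 x m` array which is flattened to the matrix layout.
#' @param individual_ids character vector of `n` unique identifiers.
#' @param marker_ids character vector of `m` unique marker identifiers.
#' @return An object of class `phased_pop` with elements `hap`,
#'   `individual_ids`, `marker_ids`.
#' @examples
#' h <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0), nrow = 4)
#' pop <- phased_population(h, c("a", "b"), c("m1", "m2"))
#' dosages(pop)
#' @export
phased_population <- function(haplotypes, individual_ids, marker_ids) {
  if (is.array(haplotypes) && length(dim(haplotypes)) == 3L) {
    n <- dim(haplotypes)[1L]
    m <- dim(haplotypes)[3L]
    hap <- matrix(NA_integer_, 2L * n, m)
    hap[seq(1L, 2L * n, 2L), ] <- haplotypes[, 1L, ]
    hap[seq(2L, 2L * n, 2L), ] <- haplotypes[, 2L, ]
    haplotypes <- hap
  }
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  n2 <- nrow(haplotypes)
  if (n2 %% 2L != 0L) stop("haplotype matrix must have an even number of rows")
  if (length(individual_ids) != n2 / 2L)
    stop("individual_ids length does not match haplotype rows / 2")
  if (anyDuplicated(individual_ids)) stop("individual_ids must be unique")
  if (length(marker_ids) != ncol(haplotypes))
    stop("marker_ids length does not match haplotype columns")
  ok <- haplotypes %in% c(0L, 1L, NA)
  if (!all(ok)) stop("allele codes must be 0, 1 or NA")
  structure(
    list(hap = haplotypes,
         individual_ids = as.character(individual_ids),
         marker_ids = as.character(marker_ids)),
    class = "phased_pop")
}

#' @export
print.phased_pop <- function(x, ...) {
  cat(sprintf("phased_pop: %d individuals x %d markers (%d haplotypes)\n",
              n_individuals(x), length(x$marker_ids), nrow(x$hap)))
  invisible(x)
}

#' Number of individuals in a phased population
#' @param pop a `phased_pop`.
#' @return integer count.
#' @export
n_individuals <- function(pop) nrow(pop$hap) / 2L

#' Allele dosage matrix from phased haplotypes
#'
#' @param pop a `phased_pop`.
#' @return `n x m` integer matrix of alternate-allele dosages in `{0,1,2}`
#'   (`NA` where either allele is missing), with individual and marker ids
#'   as dimnames.
#' @export
dosages <- function(pop) {
  stopifnot(inherits(pop, "phased_pop"))
  n <- n_individuals(pop)
  d <- pop$hap[seq(1L, 2L * n, 2L), , drop = FALSE] +
    pop$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  dimnames(d) <- list(pop$individual_ids, pop$marker_ids)
  d
}

#' Subset a phased population by markers
#' @param pop a `phased_pop`.
#' @param markers integer or character index of markers to keep.
#' @return a `phased_pop` restricted to the selected markers, order as given.
#' @export
subset_markers <- function(pop, markers) {
  if (is.character(markers)) markers <- match(markers, pop$marker_ids)
  if (anyNA(markers)) stop("unknown marker id")
  phased_population(pop$hap[, markers, drop = FALSE],
                    pop$individual_ids, pop$marker_ids[markers])
}

#' Per-marker minor allele frequency
#'
#' @param g `n x m` dosage matrix in `{0,1,2}` (`NA` allowed).
#' @return numeric vector of length `m`, values in `[0, 0.5]`.
#' @export
marker_maf <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Per-marker missing-data rate
#' @param g dosage matrix (`NA` = missing).
#' @return numeric vector of per-marker missing fractions in `[0, 1]`.
#' @export
marker_missing_rate <- function(g) colMeans(is.na(g))
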