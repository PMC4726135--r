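#' Linkage map constructor
#'
#' @param markers data frame with columns `marker`, `chrom`, `pos_cm`
#'   (genetic position, centimorgans) and optionally `pos_bp`.
#' @param chrom_length_cm optional named numeric vector of chromosome
#'   genetic lengths in cM; defaults to each chromosome's maximum marker
#'   position. The length in Morgans is the Poisson rate used for
#'   crossover counts in the meiosis simulator.
#' @return data frame of class `linkage_map`, markers sorted by chromosome
#'   then genetic position, with attribute `chrom_length_cm`.
#' @export
linkage_map <- function(markers, chrom_length_cm = NULL) {
  need <- c("marker", "chrom", "pos_cm")
  if (!all(need %in% names(markers)))
    stop("markers must have columns marker, chrom, pos_cm")
  markers$chrom <- as.character(markers$chrom)
  markers <- markers[order(markers$chrom, markers$pos_cm), , drop = FALSE]
  rownames(markers) <- NULL
  lens <- tapply(markers$pos_cm, markers$chrom, max)
  lens <- setNames(as.numeric(lens), names(lens))
  if (is.null(chrom_length_cm)) {
    chrom_length_cm <- lens
  } else {
    if (is.null(names(chrom_length_cm)))
      stop("chrom_length_cm must be named by chromosome")
    miss <- setdiff(names(lens), names(chrom_length_cm))
    if (length(miss)) stop("missing chromosome length for ", miss[1L])
    short <- chrom_length_cm[names(lens)] < lens - 1e-9
    if (any(short)) stop("chromosome length shorter than last marker on ",
                         names(lens)[short][1L])
    chrom_length_cm <- chrom_length_cm[names(lens)]
  }
  chrom_length_cm <- setNames(as.numeric(chrom_length_cm), names(lens))
  structure(markers, class = c("linkage_map", "data.frame"),
            chrom_length_cm = chrom_length_cm)
}

#' Chromosome genetic lengths of a linkage map
#' @param map a `linkage_map`.
#' @param unit `"cM"` or `"morgan"`.
#' @return named numeric vector of chromosome lengths.
#' @export
chrom_lengths <- function(map, unit = c("cM", "morgan")) {
  unit <- match.arg(unit)
  l <- attr(map, "chrom_length_cm")
  if (unit == "morgan") l / 100 else l
}

#' Fit a physical-to-genetic coordinate mapping
#'
#' Local polynomial (loess, degree 2, tricube weights) regression of
#' genetic position on physical position, fitted per chromosome on a table
#' of anchor pairs from a reference linkage map. The span controls the
#' smoothing neighbourhood fraction; 0.189 is the default.
#'
#' @param anchors data frame with columns `chrom`, `pos_bp`, `pos_cm`.
#' @param span loess span in (0, 1], default 0.189.
#' @param degree local polynomial degree, default 2.
#' @param min_anchors minimum anchors per chromosome (default 10); a
#'   chromosome with fewer is rejected.
#' @return object of class `genetic_map_fit`; use [project_markers()] or
#'   `predict(fit, chrom, pos_bp)` to project positions.
#' @export
fit_physical_to_genetic <- function(anchors, span = 0.189, degree = 2,
                                    min_anchors = 10) {
  stopifnot(span > 0, span <= 1)
  need <- c("chrom", "pos_bp", "pos_cm")
  if (!all(need %in% names(anchors)))
    stop("anchors must have columns chrom, pos_bp, pos_cm")
  fits <- lapply(split(anchors, anchors$chrom), function(a) {
    if (nrow(a) < min_anchors)
      stop(sprintf("chromosome %s has %d anchors; at least %d required",
                   a$chrom[1L], nrow(a), min_anchors))
    # bp rescaled to [0, 1] for numerical conditioning of the local
    # quadratic; the span is floored so each local fit has enough anchors
    scale <- max(abs(a$pos_bp))
    span_eff <- max(span, (degree + 2) / nrow(a))
    f <- loess(pos_cm ~ x, data = data.frame(pos_cm = a$pos_cm,
                                             x = a$pos_bp / scale),
               span = span_eff, degree = degree,
               control = loess.control(surface = "direct"))
    list(fit = f, scale = scale)
  })
  structure(list(fits = fits, span = span, degree = degree),
            class = "genetic_map_fit")
}

#' @export
predict.genetic_map_fit <- function(object, chrom, pos_bp, ...) {
  chrom <- as.character(chrom)
  out <- numeric(length(pos_bp))
  for (ch in unique(chrom)) {
    f <- object$fits[[ch]]
    if (is.null(f)) stop("no mapping fitted for chromosome ", ch)
    sel <- chrom == ch
    out[sel] <- predict(f$fit, data.frame(x = pos_bp[sel] / f$scale))
  }
  out
}

#' Repair non-increasing genetic positions
#'
#' Successive gaps that are zero or negative are replaced by 1e-6 cM and
#' positions re-accumulated from the first marker, so the output is
#' strictly increasing while positive gaps are preserved.
#'
#' @param pos_cm numeric vector of genetic positions, marker order by bp.
#' @return strictly increasing numeric vector of the same length.
#' @export
repair_gaps <- function(pos_cm) {
  if (length(pos_cm) < 2L) return(pos_cm)
  gaps <- diff(pos_cm)
  gaps[gaps <= 0] <- 1e-6
  c(pos_cm[1L], pos_cm[1L] + cumsum(gaps))
}

#' Project marker physical positions onto the genetic map
#'
#' Applies a fitted bp-to-cM mapping to markers sorted by physical
#' position within chromosome, then repairs any non-positive successive
#' genetic gap by replacing it with 1e-6 cM (cumulative re-accumulation),
#' so projected positions are strictly increasing in bp order.
#'
#' @param mapping a `genetic_map_fit` from [fit_physical_to_genetic()].
#' @param markers data frame with columns `marker`, `chrom`, `pos_bp`.
#' @return the input data frame with a `pos_cm` column added, sorted by
#'   chromosome and bp.
#' @export
project_markers <- function(mapping, markers) {
  markers <- markers[order(markers$chrom, markers$pos_bp), , drop = FALSE]
  rownames(markers) <- NULL
  raw <- predict(mapping, markers$chrom, markers$pos_bp)
  markers$pos_cm <- NA_real_
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    markers$pos_cm[sel] <- repair_gaps(raw[sel])
  }
  markers
}

#' Discretize a linkage map into fixed-width genetic bins
#'
#' Each chromosome is tiled by half-open bins `[lo, hi)` of `bin_size_cm`
#' centimorgans (`n_bins = ceiling(length_cm / bin_size_cm)`, at least 1).
#' Every marker is assigned to the bin whose midpoint is nearest its
#' genetic position; exact midpoint ties go to the lower-index bin. This
#' bin lattice is the genome representation used by the meiosis simulator.
#'
#' @param map a `linkage_map`.
#' @param bin_size_cm bin width in cM, default 0.1.
#' @return object of class `binned_genome`: per-chromosome bin counts and
#'   offsets, chromosome lengths in Morgans, the `bin_size_cm`, and
#'   `marker_bin`, the global bin index of every marker (map order).
#' @export
build_bins <- function(map, bin_size_cm = 0.1) {
  stopifnot(inherits(map, "linkage_map"), bin_size_cm > 0)
  len_cm <- chrom_lengths(map)
  chroms <- names(len_cm)
  n_bins <- setNames(pmax(as.integer(ceiling(len_cm / bin_size_cm - 1e-9)), 1L),
                     chroms)
  offset <- c(0L, cumsum(n_bins))[seq_along(chroms)]
  names(offset) <- chroms
  k <- map$pos_cm / bin_size_cm
  # containing bin, except exact boundaries tie to the lower bin
  local_bin <- ifelse(abs(k - round(k)) < 1e-9 & round(k) > 0,
                      round(k), floor(k) + 1L)
  local_bin <- pmin(as.integer(local_bin), n_bins[map$chrom])
  structure(list(chroms = chroms,
                 n_bins = setNames(n_bins, chroms),
                 offset = offset,
                 total_bins = sum(n_bins),
                 bin_size_cm = bin_size_cm,
                 length_morgan = setNames(len_cm / 100, chroms),
                 marker_bin = offset[map$chrom] + local_bin,
                 marker_ids = map$marker),
            class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosomes, %d bins of %.3g cM, %d markers\n",
              length(x$chroms), x$total_bins, x$bin_size_cm,
              length(x$marker_bin)))
  invisible(x)
}
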