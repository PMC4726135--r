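# Plain-text readers and writers for the exchanged formats: phased VCF,
# haplotype TSV (rows = markers, two columns per individual), marker map
# TSV, and wide/long phenotype CSV.

#' Write phased genotypes as VCF
#'
#' Minimal VCFv4.2 with phased `GT` (`0|1` style), one record per marker.
#' REF/ALT symbols are placeholders (`A`/`G`): the allele codes, not the
#' nucleotides, carry the information.
#'
#' @param pop a [phased_population()].
#' @param map a `linkage_map` covering the population's markers (used for
#'   CHROM/POS); marker order must match.
#' @param path output file path (`.vcf`, uncompressed).
#' @export
write_haplotype_vcf <- function(pop, map, path) {
  stopifnot(identical(as.character(map$marker), pop$marker_ids))
  n <- n_individuals(pop)
  h1 <- pop$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- pop$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(ifelse(is.na(h1), ".", h1), "|",
                      ifelse(is.na(h2), ".", h2)), nrow = n)
  pos <- if (!is.null(map$pos_bp)) map$pos_bp else seq_len(nrow(map))
  body <- cbind(map$chrom, pos, map$marker, "A", "G", ".", "PASS", ".",
                "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=breedsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", pop$individual_ids),
                     collapse = "\t")), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a phased population from VCF
#'
#' Requires phased `GT` fields (`|` separator). Alternate-allele codes
#' become haplotype alleles; `.` becomes `NA`.
#'
#' @param path VCF file path.
#' @return list with `pop` ([phased_population()]) and `map` (data frame
#'   marker/chrom/pos_bp).
#' @export
read_haplotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("unphased genotypes in VCF; phased GT (|) required")
  ids <- colnames(gt)
  m <- nrow(gt)
  n <- length(ids)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  to_int <- function(x) {
    x[x == "."] <- NA
    matrix(as.integer(x), nrow = m)
  }
  h1 <- t(to_int(a1)); h2 <- t(to_int(a2))
  hap <- matrix(NA_integer_, 2L * n, m)
  hap[seq(1L, 2L * n, 2L), ] <- h1
  hap[seq(2L, 2L * n, 2L), ] <- h2
  markers <- v@fix[, "ID"]
  list(pop = phased_population(hap, ids, markers),
       map = data.frame(marker = markers, chrom = v@fix[, "CHROM"],
                        pos_bp = as.numeric(v@fix[, "POS"])))
}

#' Write haplotypes as TSV (markers x haplotype columns)
#'
#' Columns `<id>_h1`, `<id>_h2` per individual, one row per marker.
#'
#' @inheritParams write_haplotype_vcf
#' @param path output path.
#' @export
write_haplotype_tsv <- function(pop, path) {
  tab <- data.table::as.data.table(t(pop$hap))
  data.table::setnames(tab, paste0(rep(pop$individual_ids, each = 2L),
                                   c("_h1", "_h2")))
  tab <- cbind(data.table::data.table(marker = pop$marker_ids), tab)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read haplotypes from TSV
#' @param path TSV written by [write_haplotype_tsv()] (first column
#'   `marker`, then `<id>_h1`/`<id>_h2` pairs).
#' @return a [phased_population()].
#' @export
read_haplotype_tsv <- function(path) {
  tab <- data.table::fread(path, sep = "\t")
  markers <- tab[[1L]]
  hap <- t(as.matrix(tab[, -1L]))
  ids <- unique(sub("_h[12]$", "", rownames(hap)))
  phased_population(hap, ids, markers)
}

#' Write / read a marker map TSV
#'
#' Columns `marker`, `chrom`, `pos_bp` (optional), `pos_cm` (optional when
#' an anchor table plus projection supplies genetic positions).
#'
#' @param map a `linkage_map`.
#' @param path file path.
#' @export
write_marker_map <- function(map, path) {
  df <- as.data.frame(map)
  lens <- chrom_lengths(map)
  df$chrom_length_cm <- lens[df$chrom]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_marker_map
#' @return `read_marker_map`: a `linkage_map`.
#' @export
read_marker_map <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  lens <- NULL
  if ("chrom_length_cm" %in% names(df)) {
    lens <- tapply(df$chrom_length_cm, df$chrom, max)
    df$chrom_length_cm <- NULL
  }
  linkage_map(df, lens)
}

#' Write phenotypes (wide means + long per-year replicates)
#' @param phe a `sim_phenotypes` (or list with `values` and optionally
#'   `replicates`).
#' @param path_means CSV path for the year-averaged wide table.
#' @param path_years optional CSV path for the long table with a `year`
#'   column.
#' @export
write_phenotypes <- function(phe, path_means, path_years = NULL) {
  wide <- data.frame(individual = rownames(phe$values), phe$values,
                     check.names = FALSE)
  data.table::fwrite(wide, path_means)
  if (!is.null(path_years) && !is.null(phe$replicates)) {
    reps <- phe$replicates
    long <- do.call(rbind, lapply(seq_len(dim(reps)[3L]), function(yy)
      data.frame(individual = rownames(phe$values), year = yy,
                 reps[, , yy], check.names = FALSE)))
    data.table::fwrite(long, path_years)
  }
  invisible(path_means)
}

#' Read phenotypes from CSV
#'
#' Wide format: first column individual id, remaining columns traits.
#' Long format (detected by a `year` column): one row per individual and
#' year; values are averaged over years and the per-year table kept.
#'
#' @param path CSV path.
#' @return list with `values` (n x t matrix) and `replicates` (n x t x y
#'   array or `NULL`).
#' @export
read_phenotypes <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  names(df)[1L] <- "individual"
  if ("year" %in% names(df)) {
    years <- sort(unique(df$year))
    ids <- unique(df$individual)
    traits <- setdiff(names(df), c("individual", "year"))
    reps <- array(NA_real_, c(length(ids), length(traits), length(years)),
                  dimnames = list(ids, traits, years))
    for (yi in seq_along(years)) {
      sub <- df[df$year == years[yi], ]
      reps[match(sub$individual, ids), , yi] <- as.matrix(sub[, traits])
    }
    values <- apply(reps, c(1, 2), mean, na.rm = TRUE)
    list(values = values, replicates = reps)
  } else {
    vals <- as.matrix(df[, -1L, drop = FALSE])
    rownames(vals) <- df$individual
    list(values = vals, replicates = NULL)
  }
}
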