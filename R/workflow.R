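#' End-to-end analysis workflow
#'
#' Runs the standard pipeline on a dataset bundle: marker filtering with
#' the default 5% missing / 5% MAF thresholds, broad-sense heritability
#' per trait when replicate years are available, LOOCV model comparison
#' and best-method-per-trait selection, a mixed-model GWAS per target
#' trait, and the recurrent genomic-selection simulation. All outputs are
#' plain TSV/JSON in `out_dir`, stamped with the seed.
#'
#' @param geno path to a phased VCF or haplotype TSV.
#' @param map path to a marker map TSV.
#' @param pheno path to a phenotype CSV (wide, or long with `year`).
#' @param out_dir output directory (created if needed).
#' @param target_traits traits to select on in the simulation; default the
#'   first two.
#' @param methods WGP methods compared by LOOCV.
#' @param generations,replicates,N simulation settings (defaults 5, 5, 96).
#' @param n_pcs GWAS principal components, default 6.
#' @param fdr_level GWAS FDR level, default 0.05.
#' @param max_missing,min_maf marker filter thresholds, defaults 0.05.
#' @param bin_size_cm simulator bin width, default 0.1.
#' @param config a [shrinkage_config()] for the sampler-based methods.
#' @param seed master seed.
#' @return invisibly, a list with all in-memory results.
#' @export
run_workflow <- function(geno, map, pheno, out_dir,
                         target_traits = NULL,
                         methods = c("rr", "bl", "ebl", "bayesc", "rkhs"),
                         generations = 5, replicates = 5, N = 96,
                         n_pcs = 6, fdr_level = 0.05,
                         max_missing = 0.05, min_maf = 0.05,
                         bin_size_cm = 0.1,
                         config = shrinkage_config(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pop <- if (grepl("\\.vcf$", geno)) read_haplotype_vcf(geno)$pop
         else read_haplotype_tsv(geno)
  lmap <- read_marker_map(map)
  if (!all(pop$marker_ids %in% lmap$marker)) {
    miss <- setdiff(pop$marker_ids, lmap$marker)[1L]
    stop("marker ", miss, " in genotypes but not in map")
  }
  pop <- subset_markers(pop, as.character(lmap$marker))
  phe <- read_phenotypes(pheno)
  if (!setequal(rownames(phe$values), pop$individual_ids))
    stop("genotype and phenotype individuals differ")
  phe$values <- phe$values[pop$individual_ids, , drop = FALSE]
  if (is.null(target_traits))
    target_traits <- colnames(phe$values)[seq_len(min(2L, ncol(phe$values)))]

  d <- dosages(pop)
  filt <- filter_markers(d, max_missing, min_maf)
  data.table::fwrite(filt$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t")
  keep <- which(filt$keep)
  pop_f <- subset_markers(pop, keep)
  g <- impute_mean(filt$genotypes)

  h2_tab <- NULL
  if (!is.null(phe$replicates)) {
    h2_tab <- data.frame(
      trait = colnames(phe$values),
      h2 = vapply(seq_len(ncol(phe$values)), function(t) {
        estimate_heritability(phe$replicates[pop$individual_ids, t, ])$h2
      }, numeric(1)))
    data.table::fwrite(h2_tab, file.path(out_dir, "heritability.tsv"),
                       sep = "\t")
  }

  config$seed <- seed
  best <- select_best_models(g, phe$values, methods, config)
  cv_tab <- data.frame(trait = rownames(best$table), best$table,
                       best = best$best, check.names = FALSE)
  data.table::fwrite(cv_tab, file.path(out_dir, "loocv_accuracy.tsv"),
                     sep = "\t")

  kin <- compute_kinship(g)
  map_f <- linkage_map(as.data.frame(lmap)[keep, , drop = FALSE],
                       chrom_lengths(lmap))
  gwas_out <- list()
  for (tr in target_traits) {
    scan <- mlm_scan(g, phe$values[, tr], kin, n_pcs = n_pcs,
                     fdr_level = fdr_level)
    scan$chrom <- map_f$chrom[match(scan$marker, map_f$marker)]
    scan$pos_cm <- map_f$pos_cm[match(scan$marker, map_f$marker)]
    data.table::fwrite(scan, file.path(out_dir,
                                       sprintf("gwas_mlm_%s.tsv", tr)),
                       sep = "\t")
    sig <- which(scan$significant)
    reg <- if (length(sig))
      sig_marker_regression(phe$values[, tr], g[, sig, drop = FALSE])
    gwas_out[[tr]] <- list(scan = scan, regression = reg)
  }

  genome <- build_bins(map_f, bin_size_cm)
  sim <- run_recurrent_gs(pop_f, genome, best$models, target_traits,
                          generations = generations,
                          replicates = replicates, N = N, seed = seed)
  data.table::fwrite(sim$gebvs, file.path(out_dir, "gs_simulation.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(seed = seed, n_markers_retained = length(keep),
         target_traits = target_traits, best_methods = as.list(best$best),
         generations = generations, replicates = replicates, N = N),
    file.path(out_dir, "run_summary.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(list(filter = filt, h2 = h2_tab, cv = best, gwas = gwas_out,
                 simulation = sim))
}
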