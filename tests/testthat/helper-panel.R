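# Study-scale panel (96 founders, 12 chromosomes, ~10^4 markers, 20
# traits) plus fitted models and recurrent-selection runs, shared by the
# acceptance-level tests; built once on first use.

panel_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fnd <- simulate_founders(founder_config(seed = 2024))
      phe <- simulate_phenotypes(fnd, trait_architecture(seed = 2025))
      filt <- filter_markers(dosages(fnd$pop))
      g <- impute_mean(filt$genotypes)
      keep <- which(filt$keep)
      map_f <- linkage_map(as.data.frame(fnd$map)[keep, ],
                           chrom_lengths(fnd$map))
      genome <- build_bins(map_f)
      pop_f <- subset_markers(fnd$pop, keep)
      models <- lapply(colnames(phe$values), function(tr)
        fit_rr(g, phe$values[, tr]))
      names(models) <- colnames(phe$values)
      sim <- run_recurrent_gs(pop_f, genome, models, c("T01", "T02"),
                              generations = 5, replicates = 5, N = 96,
                              seed = 2026)
      cache <<- list(fnd = fnd, phe = phe, filt = filt, g = g,
                     genome = genome, pop_f = pop_f, models = models,
                     sim = sim)
    }
    cache
  }
})
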