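# Shared in-code fixtures; built once per test run.

tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- founder_config(n_individuals = 40, n_chromosomes = 3,
                            chrom_length_cm = 60, n_markers = 180,
                            ld_scale_cm = 20, n_ancestors = 4,
                            n_anchors = 20, seed = 101)
      arch <- trait_architecture(n_traits = 3, n_qtl = 30,
                                 h2 = c(0.3, 0.6, 0.9), seed = 102)
      fnd <- simulate_founders(cfg)
      phe <- simulate_phenotypes(fnd, arch)
      cache <<- list(fnd = fnd, phe = phe,
                     d = dosages(fnd$pop))
    }
    cache
  }
})

# single-chromosome genome for meiosis oracles: two fully informative
# inbred founders, markers every bin midpoint
toy_genome <- function(length_cm = 100, n_markers = 50) {
  pos <- seq(0.05, length_cm - 0.05, length.out = n_markers)
  map <- linkage_map(
    data.frame(marker = sprintf("m%03d", seq_len(n_markers)),
               chrom = "c1", pos_cm = pos),
    c(c1 = length_cm))
  genome <- build_bins(map)
  # founder 1 all 0s, founder 2 all 1s (fully homozygous)
  hap <- rbind(matrix(0L, 2, n_markers), matrix(1L, 2, n_markers))
  pop <- phased_population(hap, c("p1", "p2"),
                           sprintf("m%03d", seq_len(n_markers)))
  list(map = map, genome = genome, pop = pop,
       founders = founder_individuals(pop, genome))
}

# F1 of the two toy inbreds
toy_f1 <- function(tg) {
  sim_individual(tg$founders[[1]]$h1, tg$founders[[2]]$h1,
                 id = "f1", generation = 0L)
}
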