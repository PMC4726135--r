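# Meiosis on the binned genome. Simulated haplotypes are vectors over the
# bin lattice holding founder-haplotype identifiers; marker genotypes are
# materialized by looking up the founder allele carried by the nearest bin.

#' Draw crossover positions for one chromosome
#'
#' The crossover count is Poisson with rate equal to the chromosome's
#' genetic length in Morgans; positions are i.i.d. uniform on the
#' chromosome (no interference) and returned sorted.
#'
#' @param length_morgan chromosome genetic length in Morgans (>= 0).
#' @return sorted numeric vector of crossover positions in Morgans.
#' @export
draw_crossovers <- function(length_morgan) {
  if (length_morgan < 0) stop("chromosome length must be non-negative")
  k <- rpois(1L, length_morgan)
  sort(runif(k, 0, length_morgan))
}

#' Create a simulated individual from two bin haplotypes
#' @param h1,h2 integer vectors over the genome's bins (founder-haplotype
#'   identifiers).
#' @param id individual identifier.
#' @param parents character vector of two parent ids (`NA` for founders).
#' @param generation integer generation index.
#' @return object of class `sim_individual`.
#' @export
sim_individual <- function(h1, h2, id = NA_character_,
                           parents = c(NA_character_, NA_character_),
                           generation = 0L) {
  stopifnot(length(h1) == length(h2))
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2), id = id,
                 parents = parents, generation = as.integer(generation)),
            class = "sim_individual")
}

#' Founder individuals on the bin lattice
#'
#' Each founder's two haplotypes are constant over the genome and carry
#' that founder's haplotype identifiers (`2i - 1`, `2i`), which index rows
#' of the founder allele matrix at materialization time.
#'
#' @param pop founder [phased_population()].
#' @param genome a [build_bins()] result.
#' @return list of `sim_individual`s, one per founder.
#' @export
founder_individuals <- function(pop, genome) {
  B <- genome$total_bins
  lapply(seq_len(n_individuals(pop)), function(i)
    sim_individual(rep(2L * i - 1L, B), rep(2L * i, B),
                   id = pop$individual_ids[i], generation = 0L))
}

# crossover positions (Morgans) -> per-bin source index (0/1) for one
# chromosome; a crossover between bins switches source at that boundary.
chrom_source <- function(n_bins, length_morgan, bin_size_cm) {
  pos <- draw_crossovers(length_morgan)
  start <- sample.int(2L, 1L) - 1L
  if (length(pos) == 0L) return(rep(start, n_bins))
  boundary <- round(pos * 100 / bin_size_cm)
  (start + findInterval(seq_len(n_bins) - 0.5, boundary)) %% 2L
}

#' Generate a gamete from a parent
#'
#' Per chromosome, the crossover count is Poisson(length in Morgans),
#' positions uniform (rounded to the nearest bin boundary), and the gamete
#' is the mosaic of the parent's two haplotypes switching source at each
#' crossover; the starting haplotype is chosen fairly.
#'
#' @param parent a `sim_individual`.
#' @param genome a `binned_genome`.
#' @return integer vector over bins (the gamete haplotype).
#' @export
make_gamete <- function(parent, genome) {
  out <- integer(genome$total_bins)
  for (ci in seq_along(genome$chroms)) {
    nb <- genome$n_bins[ci]
    idx <- genome$offset[ci] + seq_len(nb)
    src <- chrom_source(nb, genome$length_morgan[ci], genome$bin_size_cm)
    out[idx] <- ifelse(src == 0L, parent$h1[idx], parent$h2[idx])
  }
  out
}

#' Cross two parents
#'
#' Each progeny receives one independently sampled gamete from each
#' parent; the pedigree (parent ids, generation) is recorded.
#'
#' @param p1,p2 `sim_individual` parents sharing a genome.
#' @param n_progeny number of progeny (> 0).
#' @param genome a `binned_genome`.
#' @param ids optional progeny identifiers.
#' @return list of `sim_individual` progeny.
#' @export
cross <- function(p1, p2, n_progeny, genome, ids = NULL) {
  if (n_progeny <= 0) stop("n_progeny must be positive")
  if (length(p1$h1) != length(p2$h1)) stop("parents on different genomes")
  gen <- max(p1$generation, p2$generation) + 1L
  lapply(seq_len(n_progeny), function(k)
    sim_individual(make_gamete(p1, genome), make_gamete(p2, genome),
                   id = if (is.null(ids)) sprintf("%sx%s_%d", p1$id, p2$id, k)
                        else ids[k],
                   parents = c(p1$id, p2$id), generation = gen))
}

#' Derive an inbred line by repeated selfing
#'
#' Single-seed descent: the individual is self-fertilized for the given
#' number of generations, carrying one offspring forward each generation
#' (default 6 generations, after which about `0.5^6` of initially
#' heterozygous loci remain heterozygous).
#'
#' @param ind a `sim_individual`.
#' @param genome a `binned_genome`.
#' @param generations selfing generations, default 6.
#' @return the final-generation `sim_individual` (pedigree records the
#'   selfing chain).
#' @export
derive_inbred <- function(ind, genome, generations = 6) {
  stopifnot(generations >= 1)
  cur <- ind
  for (gsf in seq_len(generations)) {
    cur <- sim_individual(make_gamete(cur, genome), make_gamete(cur, genome),
                          id = sprintf("%s_S%d", ind$id, gsf),
                          parents = c(cur$id, cur$id),
                          generation = ind$generation + gsf)
  }
  cur
}

#' Materialize marker genotypes from bin haplotypes
#'
#' Every marker takes its two alleles from the founder haplotypes recorded
#' in its nearest bin (the marker-to-bin assignment of the genome), giving
#' a phased population and the usual 0/1/2 dosage encoding.
#'
#' @param individuals list of `sim_individual`s.
#' @param genome a `binned_genome` whose `marker_bin` matches the founder
#'   allele matrix columns.
#' @param founder_alleles `2n_f x m` 0/1 matrix of founder haplotype
#'   alleles (rows indexed by the identifiers stored in bins).
#' @return a [phased_population()] of the individuals at the markers.
#' @export
materialize_genotypes <- function(individuals, genome, founder_alleles) {
  m <- length(genome$marker_bin)
  if (m != ncol(founder_alleles))
    stop("marker/bin assignment does not match founder allele matrix")
  if (anyNA(genome$marker_bin)) stop("marker mapped to no bin")
  n <- length(individuals)
  hap <- matrix(NA_integer_, 2L * n, m)
  js <- seq_len(m)
  for (i in seq_len(n)) {
    ind <- individuals[[i]]
    hap[2L * i - 1L, ] <- founder_alleles[cbind(ind$h1[genome$marker_bin], js)]
    hap[2L * i, ] <- founder_alleles[cbind(ind$h2[genome$marker_bin], js)]
  }
  ids <- vapply(individuals, function(x) x$id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- sprintf("ind%04d", seq_len(n))
  phased_population(hap, ids, genome$marker_ids)
}

#' Proportion of heterozygous bins of a simulated individual
#'
#' Heterozygosity at the descent level: the fraction of bins whose two
#' haplotypes descend from different founder haplotypes.
#'
#' @param ind a `sim_individual`.
#' @return fraction in `[0, 1]`.
#' @export
bin_heterozygosity <- function(ind) mean(ind$h1 != ind$h2)

#' Pedigree table of simulated individuals
#' @param individuals list of `sim_individual`s.
#' @return data frame with columns `id`, `parent1`, `parent2`, `generation`.
#' @export
pedigree_table <- function(individuals) {
  data.frame(
    id = vapply(individuals, function(x) x$id, character(1)),
    parent1 = vapply(individuals, function(x) x$parents[1L], character(1)),
    parent2 = vapply(individuals, function(x) x$parents[2L], character(1)),
    generation = vapply(individuals, function(x) x$generation, integer(1)))
}
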