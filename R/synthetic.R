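# Synthetic founder panels, linkage maps and trait architectures that
# carry the statistical structure the analyses assume: a diverse phased
# panel with long-range LD, a nonlinear bp/cM relation, and correlated
# polygenic traits observed over replicate years.

#' Configuration of the synthetic founder panel
#'
#' Defaults emulate the study panel this package targets: 96 phased
#' individuals, 12 chromosomes of 110 cM, about 10^4 mapped SNPs, and LD
#' extending over tens of cM induced by an ancestral haplotype-mosaic
#' model.
#'
#' @param n_individuals founders, default 96.
#' @param n_chromosomes default 12.
#' @param chrom_length_cm per-chromosome genetic length, recycled.
#' @param n_markers total marker count, default 9600.
#' @param ld_scale_cm mean ancestral mosaic segment length in cM
#'   (exponential), default 20 - LD then decays over tens of cM.
#' @param n_ancestors size of the ancestral haplotype pool, default 8.
#' @param bin_size_cm simulator bin width, default 0.1.
#' @param n_anchors anchor (bp, cM) pairs per chromosome for map
#'   projection, default 40.
#' @param seed RNG seed.
#' @return list of class `founder_config`.
#' @export
founder_config <- function(n_individuals = 96, n_chromosomes = 12,
                           chrom_length_cm = 110, n_markers = 9600,
                           ld_scale_cm = 20, n_ancestors = 8,
                           bin_size_cm = 0.1, n_anchors = 40, seed = 1) {
  stopifnot(n_individuals > 0, n_chromosomes > 0, n_markers > 0,
            ld_scale_cm > 0, n_ancestors > 0)
  structure(list(n_individuals = n_individuals,
                 n_chromosomes = n_chromosomes,
                 chrom_length_cm = rep_len(chrom_length_cm, n_chromosomes),
                 n_markers = n_markers, ld_scale_cm = ld_scale_cm,
                 n_ancestors = n_ancestors, bin_size_cm = bin_size_cm,
                 n_anchors = n_anchors, seed = seed),
            class = "founder_config")
}

#' Simulate a phased founder panel with linkage map and anchors
#'
#' Founder haplotypes are mosaics of a small ancestral haplotype pool with
#' exponentially distributed segment lengths at the LD scale, which
#' produces LD decaying over tens of cM. Physical positions follow a
#' smooth nonlinear monotone bp/cM relation (recombination suppressed
#' toward the chromosome middle), and a noisy anchor table is emitted to
#' exercise physical-to-genetic projection.
#'
#' @param cfg a [founder_config()].
#' @return list with `pop` ([phased_population()]), `map`
#'   ([linkage_map()]), `anchors` (data frame chrom/pos_bp/pos_cm),
#'   `config`.
#' @export
simulate_founders <- function(cfg = founder_config()) {
  set.seed(cfg$seed)
  nch <- cfg$n_chromosomes
  per <- diff(round(seq(0, cfg$n_markers, length.out = nch + 1)))
  chroms <- sprintf("chr%02d", seq_len(nch))
  map_list <- list()
  anchor_list <- list()
  for (c_i in seq_len(nch)) {
    L <- cfg$chrom_length_cm[c_i]
    pos_cm <- sort(runif(per[c_i], 0, L))
    # nonlinear monotone cM -> bp: physical distance per cM grows along
    # the chromosome (f(x) = (x + x^2)/2, strictly increasing)
    bp_of <- function(cm) {
      x <- cm / L
      round(1e6 * L * (0.5 * x + 0.5 * x^2)) + 1
    }
    map_list[[c_i]] <- data.frame(
      marker = sprintf("%s_m%04d", chroms[c_i], seq_len(per[c_i])),
      chrom = chroms[c_i], pos_cm = pos_cm, pos_bp = bp_of(pos_cm))
    a_cm <- seq(0, L, length.out = cfg$n_anchors)
    anchor_list[[c_i]] <- data.frame(
      chrom = chroms[c_i], pos_bp = bp_of(a_cm),
      pos_cm = pmax(a_cm + rnorm(cfg$n_anchors, 0, 0.15), 0))
  }
  map_df <- do.call(rbind, map_list)
  map <- linkage_map(map_df,
                     setNames(cfg$chrom_length_cm, chroms))
  m <- nrow(map)
  anc <- matrix(rbinom(cfg$n_ancestors * m, 1L, 0.5),
                cfg$n_ancestors, m)
  hap <- matrix(0L, 2L * cfg$n_individuals, m)
  chrom_idx <- split(seq_len(m), map$chrom)
  for (h in seq_len(nrow(hap))) {
    for (c_i in seq_len(nch)) {
      idx <- chrom_idx[[chroms[c_i]]]
      pcm <- map$pos_cm[idx]
      L <- cfg$chrom_length_cm[c_i]
      at <- 0
      while (at < L) {
        len <- rexp(1L, 1 / cfg$ld_scale_cm)
        a <- sample.int(cfg$n_ancestors, 1L)
        sel <- pcm >= at & pcm < at + len
        hap[h, idx[sel]] <- anc[a, idx[sel]]
        at <- at + len
      }
    }
  }
  pop <- phased_population(hap, sprintf("v%03d", seq_len(cfg$n_individuals)),
                           map$marker)
  list(pop = pop, map = map, anchors = do.call(rbind, anchor_list),
       config = cfg)
}

#' Trait architecture for phenotype simulation
#'
#' Defaults emulate a 20-trait panel with broad-sense heritabilities
#' spanning 0.1 to 1.0 observed over 4 replicate years, and an
#' antagonistic (negatively correlated) pair of primary traits modelled
#' as negative pleiotropic correlation at shared QTLs.
#'
#' @param n_traits default 20.
#' @param n_qtl QTLs per trait (shared across traits), default 100.
#' @param h2 target broad-sense heritabilities, recycled to `n_traits`;
#'   default evenly spans 0.1 to 1.0.
#' @param genetic_cor trait genetic correlation matrix (symmetric PSD,
#'   unit diagonal); default identity except -0.5 between the first two
#'   traits.
#' @param years replicate years, default 4.
#' @param trait_names optional trait names, default T01, T02, ...
#' @param seed RNG seed.
#' @return list of class `trait_architecture`.
#' @export
trait_architecture <- function(n_traits = 20, n_qtl = 100, h2 = NULL,
                               genetic_cor = NULL, years = 4,
                               trait_names = NULL, seed = 1) {
  if (is.null(h2)) h2 <- seq(0.1, 1.0, length.out = n_traits)
  h2 <- rep_len(h2, n_traits)
  stopifnot(all(h2 >= 0), all(h2 <= 1), years >= 1, n_qtl > 0)
  if (is.null(genetic_cor)) {
    genetic_cor <- diag(n_traits)
    if (n_traits >= 2) genetic_cor[1, 2] <- genetic_cor[2, 1] <- -0.5
  }
  if (!isSymmetric(genetic_cor) ||
      any(abs(diag(genetic_cor) - 1) > 1e-8))
    stop("genetic_cor must be symmetric with unit diagonal")
  ev <- eigen(genetic_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("genetic_cor is not positive semidefinite")
  if (is.null(trait_names)) trait_names <- sprintf("T%02d", seq_len(n_traits))
  structure(list(n_traits = n_traits, n_qtl = n_qtl, h2 = h2,
                 genetic_cor = genetic_cor, years = years,
                 trait_names = trait_names, seed = seed),
            class = "trait_architecture")
}

#' Simulate correlated polygenic phenotypes over replicate years
#'
#' QTL markers are sampled from the map and additive effects drawn so the
#' true breeding values have unit variance per trait and exactly the
#' target genetic correlation matrix (the drawn effect matrix is
#' recoloured against the realized covariance). Per-year phenotypes add
#' independent Gaussian noise scaled so the broad-sense heritability of
#' the year-replicated design matches the target.
#'
#' @param founders result of [simulate_founders()] (or a list with `pop`).
#' @param arch a [trait_architecture()].
#' @return list of class `sim_phenotypes`: `values` (n x t means over
#'   years), `replicates` (n x t x years array), `tbv` (true breeding
#'   values), `effects` (m x t marker-effect matrix, zero off-QTL), `qtl`
#'   (marker indices), `arch`.
#' @export
simulate_phenotypes <- function(founders, arch = trait_architecture()) {
  pop <- if (inherits(founders, "phased_pop")) founders else founders$pop
  set.seed(arch$seed)
  d <- dosages(pop)
  n <- nrow(d); m <- ncol(d)
  stopifnot(arch$n_qtl <= m)
  qtl <- sort(sample.int(m, arch$n_qtl))
  t <- arch$n_traits
  B <- matrix(rnorm(arch$n_qtl * t), arch$n_qtl, t) %*%
    chol(arch$genetic_cor + 1e-10 * diag(t))
  G <- d[, qtl, drop = FALSE] %*% B
  # recolour so sample cov of TBVs is exactly the target correlation
  Gc <- sweep(G, 2L, colMeans(G))
  S <- crossprod(Gc) / (n - 1)
  Tm <- solve(chol(S + 1e-10 * diag(t)),
              chol(arch$genetic_cor + 1e-10 * diag(t)))
  G <- Gc %*% Tm
  B <- B %*% Tm
  colnames(G) <- arch$trait_names
  sigma_e <- sqrt(ifelse(arch$h2 > 0, (1 - arch$h2) / arch$h2, Inf))
  reps <- array(NA_real_, c(n, t, arch$years),
                dimnames = list(pop$individual_ids, arch$trait_names, NULL))
  for (yy in seq_len(arch$years)) {
    noise <- matrix(rnorm(n * t), n, t) %*% diag(ifelse(is.finite(sigma_e),
                                                        sigma_e, 0), t)
    zero_h2 <- !is.finite(sigma_e)
    vals <- G + noise
    if (any(zero_h2)) {
      # h2 = 0: phenotype is pure noise, no genetic signal
      vals[, zero_h2] <- matrix(rnorm(n * sum(zero_h2)), n)
    }
    reps[, , yy] <- vals
  }
  values <- apply(reps, c(1, 2), mean)
  effects <- matrix(0, m, t, dimnames = list(pop$marker_ids,
                                             arch$trait_names))
  effects[qtl, ] <- B
  structure(list(values = values, replicates = reps, tbv = G,
                 effects = effects, qtl = qtl, arch = arch),
            class = "sim_phenotypes")
}

#' Write a self-contained synthetic dataset bundle to disk
#'
#' Generates a founder panel with map, anchors and phenotypes and writes
#' it as plain-text files: phased VCF, haplotype TSV, map TSV, anchor TSV,
#' averaged phenotype CSV, per-year long-format phenotype CSV, true
#' breeding values, and a JSON manifest recording the preset and seed.
#' The `tiny` preset is sized for examples and unit tests; `panel96`
#' emulates the study scale (96 individuals, 12 chromosomes, ~10^4
#' markers, 20 traits over 4 years).
#'
#' @param preset `"tiny"` or `"panel96"`.
#' @param dir output directory (created; must not exist unless `force`).
#' @param seed RNG seed; the bundle is byte-identical given the seed.
#' @param force overwrite an existing directory?
#' @return invisibly, a list with the generated objects and file paths.
#' @export
make_fixture <- function(preset = c("tiny", "panel96"), dir,
                         seed = 1, force = FALSE) {
  preset <- match.arg(preset)
  if (dir.exists(dir)) {
    if (!force) stop("output directory exists; use force = TRUE")
  } else dir.create(dir, recursive = TRUE)
  cfg <- switch(preset,
    tiny = founder_config(n_individuals = 30, n_chromosomes = 3,
                          chrom_length_cm = 50, n_markers = 150,
                          ld_scale_cm = 20, n_ancestors = 4,
                          n_anchors = 15, seed = seed),
    panel96 = founder_config(seed = seed))
  arch <- switch(preset,
    tiny = trait_architecture(n_traits = 3, n_qtl = 30,
                              h2 = c(0.3, 0.6, 0.9), seed = seed + 1),
    panel96 = trait_architecture(seed = seed + 1))
  fnd <- simulate_founders(cfg)
  phe <- simulate_phenotypes(fnd, arch)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    hap = file.path(dir, "haplotypes.tsv"),
    map = file.path(dir, "map.tsv"),
    anchors = file.path(dir, "anchors.tsv"),
    pheno = file.path(dir, "phenotypes.csv"),
    pheno_years = file.path(dir, "phenotype_years.csv"),
    tbv = file.path(dir, "true_breeding_values.csv"),
    manifest = file.path(dir, "manifest.json"))
  write_haplotype_vcf(fnd$pop, fnd$map, paths$vcf)
  write_haplotype_tsv(fnd$pop, paths$hap)
  write_marker_map(fnd$map, paths$map)
  data.table::fwrite(fnd$anchors, paths$anchors, sep = "\t")
  write_phenotypes(phe, paths$pheno, paths$pheno_years)
  tbv <- data.frame(individual = rownames(phe$values), phe$tbv,
                    check.names = FALSE)
  data.table::fwrite(tbv, paths$tbv)
  jsonlite::write_json(
    list(preset = preset, seed = seed, n_individuals = cfg$n_individuals,
         n_markers = nrow(fnd$map), n_traits = arch$n_traits,
         years = arch$years, files = lapply(paths, basename)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(pop = fnd$pop, map = fnd$map, anchors = fnd$anchors,
                 phenotypes = phe, config = cfg, arch = arch,
                 paths = paths))
}
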