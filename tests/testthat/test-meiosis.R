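test_that("crossover counts follow Poisson moments at the map length", {
  set.seed(81)
  lam <- 1.2
  counts <- replicate(10000, length(draw_crossovers(lam)))
  se_mean <- sqrt(lam / 10000)
  expect_lt(abs(mean(counts) - lam), 3 * se_mean)
  # equidispersion: Var = lambda (SE of the variance ~ sqrt(2/n)*lambda)
  expect_lt(abs(var(counts) - lam), 4 * lam * sqrt(2 / 10000))
  # positions sorted, inside the chromosome
  pos <- draw_crossovers(2)
  expect_true(all(diff(pos) >= 0))
  expect_true(all(pos >= 0 & pos <= 2))
  expect_identical(draw_crossovers(0), numeric(0))
  expect_error(draw_crossovers(-1), "non-negative")
})

test_that("gametes from a parent with identical haplotypes equal that haplotype", {
  tg <- toy_genome()
  set.seed(82)
  B <- tg$genome$total_bins
  p <- sim_individual(rep(1L, B), rep(1L, B), id = "hom")
  for (k in 1:5) expect_identical(make_gamete(p, tg$genome), p$h1)
  # founder individuals carry two distinct haplotype ids, but an
  # allelically homozygous founder still transmits constant genotypes
  f <- tg$founders[[1]]
  gam <- make_gamete(f, tg$genome)
  alleles <- tg$pop$hap[cbind(gam[tg$genome$marker_bin],
                              seq_along(tg$genome$marker_bin))]
  expect_true(all(alleles == 0L))
})

test_that("recombination fractions follow the Haldane map function", {
  tg <- toy_genome(length_cm = 100, n_markers = 50)
  f1 <- toy_f1(tg)
  set.seed(83)
  n_gam <- 20000
  bins <- tg$genome$marker_bin
  G <- matrix(0L, n_gam, length(bins))
  for (i in seq_len(n_gam))
    G[i, ] <- make_gamete(f1, tg$genome)[bins]
  # founder-hap ids 1/2 vs 3/4 encode parental origin at each marker
  origin <- G > 2L
  d_m <- 0.10  # 10 cM
  pairs <- which(abs(diff(tg$map$pos_cm)) > 0)
  # markers are ~2.04 cM apart; take pairs 5 steps apart (~10.2 cM)
  step <- 5
  rf <- mean(origin[, 1:(50 - step)] != origin[, (1 + step):50])
  d_actual <- (tg$map$pos_cm[1 + step] - tg$map$pos_cm[1]) / 100
  r_exp <- (1 - exp(-2 * d_actual)) / 2
  se <- sqrt(r_exp * (1 - r_exp) / n_gam)
  expect_lt(abs(rf - r_exp), 3 * se + 0.003)
  # near-Haldane across a range of distances: regression slope ~ 1 on the
  # transformed scale
  ds <- c(2, 5, 10, 20, 40)  # steps -> cM distances
  obs <- vapply(ds, function(s)
    mean(origin[, 1:(50 - s)] != origin[, (1 + s):50]), numeric(1))
  dd <- (tg$map$pos_cm[1 + ds] - tg$map$pos_cm[1]) / 100
  exp_r <- (1 - exp(-2 * dd)) / 2
  fit <- lm(obs ~ exp_r)
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
})

test_that("unlinked chromosomes assort independently", {
  map <- linkage_map(
    data.frame(marker = c("a", "b"), chrom = c("c1", "c2"),
               pos_cm = c(5, 5)),
    c(c1 = 10, c2 = 10))
  genome <- build_bins(map)
  hap <- rbind(matrix(0L, 2, 2), matrix(1L, 2, 2))
  pop <- phased_population(hap, c("p1", "p2"), c("a", "b"))
  f1 <- sim_individual(founder_individuals(pop, genome)[[1]]$h1,
                       founder_individuals(pop, genome)[[2]]$h1, id = "f1")
  set.seed(84)
  co <- replicate(8000, {
    g <- make_gamete(f1, genome)[genome$marker_bin]
    (g[1] > 2) == (g[2] > 2)
  })
  expect_lt(abs(mean(co) - 0.5), 3 * sqrt(0.25 / 8000))
})

test_that("crosses transmit Mendelian ratios and conserve alleles", {
  tg <- toy_genome(length_cm = 50, n_markers = 20)
  f1 <- toy_f1(tg)
  set.seed(85)
  prog <- cross(f1, f1, 4000, tg$genome)
  pp <- materialize_genotypes(prog, tg$genome, tg$pop$hap)
  d <- dosages(pp)
  # F2 of 0x1 inbreds: expected dosage frequencies 1/4, 1/2, 1/4
  fr <- table(factor(d[, 10], levels = 0:2)) / nrow(d)
  expect_lt(max(abs(fr - c(0.25, 0.5, 0.25))), 3 * sqrt(0.25 / 4000))
  # allele conservation: only parental alleles appear
  expect_true(all(d %in% 0:2))
  expect_error(cross(f1, f1, 0, tg$genome), "positive")
  # identical inbred parents -> progeny identical to parents
  p1 <- tg$founders[[1]]
  prog2 <- cross(p1, p1, 5, tg$genome)
  d2 <- dosages(materialize_genotypes(prog2, tg$genome, tg$pop$hap))
  expect_true(all(d2 == 0L))
})

test_that("selfing decays heterozygosity by one half per generation", {
  tg <- toy_genome(length_cm = 100, n_markers = 40)
  f1 <- toy_f1(tg)
  expect_equal(bin_heterozygosity(f1), 1)
  set.seed(86)
  n_rep <- 2000
  het <- vapply(seq_len(n_rep), function(k)
    bin_heterozygosity(derive_inbred(f1, tg$genome, generations = 6)),
    numeric(1))
  expected <- 0.5^6  # ~0.0156 of initially heterozygous loci
  se <- sd(het) / sqrt(n_rep)
  expect_lt(abs(mean(het) - expected), 3 * se + 0.002)
  # allelically homozygous input: materialized genotypes unchanged
  hom <- derive_inbred(tg$founders[[1]], tg$genome, generations = 3)
  hom$id <- "hom"
  d_hom <- dosages(materialize_genotypes(list(hom), tg$genome, tg$pop$hap))
  expect_true(all(d_hom == 0L))
  expect_equal(formals(derive_inbred)$generations, 6)
})

test_that("marker materialization follows the nearest-bin rule", {
  tg <- toy_genome()
  # founders materialized and re-derived reproduce their own haplotypes
  pp <- materialize_genotypes(tg$founders, tg$genome, tg$pop$hap)
  expect_identical(pp$hap, tg$pop$hap)
  # two markers in one bin are in perfect LD among F2 progeny
  map2 <- linkage_map(
    data.frame(marker = c("s1", "s2", "far"), chrom = "c1",
               pos_cm = c(10.02, 10.06, 40)),
    c(c1 = 50))
  g2 <- build_bins(map2)
  expect_equal(length(unique(g2$marker_bin[1:2])), 1L)
  hap <- rbind(matrix(0L, 2, 3), matrix(1L, 2, 3))
  pop2 <- phased_population(hap, c("p1", "p2"), c("s1", "s2", "far"))
  f1 <- sim_individual(rep(1L, g2$total_bins), rep(3L, g2$total_bins),
                       id = "f1")
  set.seed(87)
  prog <- cross(f1, f1, 300, g2)
  pp2 <- materialize_genotypes(prog, g2, hap)
  ld <- compute_ld_r2(pp2, cbind(1, 2))
  expect_equal(ld$r2, 1)
})

test_that("meiosis is bit-reproducible under a fixed seed", {
  tg <- toy_genome()
  f1 <- toy_f1(tg)
  set.seed(88); a <- make_gamete(f1, tg$genome)
  set.seed(88); b <- make_gamete(f1, tg$genome)
  expect_identical(a, b)
})
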