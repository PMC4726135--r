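test_that("parent selection takes per-trait maxima when lists are disjoint", {
  gb <- cbind(A = c(1, 5, 2, 4, 3), B = c(5, 1, 4, 2, 3))
  sel <- select_parents(gb, c("A", "B"), k = 2)
  expect_equal(sel$by_trait$A, c(2L, 4L))
  expect_equal(sel$by_trait$B, c(1L, 3L))
  expect_equal(sort(sel$parents), c(1L, 2L, 3L, 4L))
})

test_that("overlapping top lists are resolved by next-ranked replacement", {
  # individual 1 tops both traits; it ranks first for A and first for B,
  # tie -> kept for the earlier trait, B takes its next candidate
  gb <- cbind(A = c(9, 8, 1, 2, 3), B = c(9, 1, 8, 7, 2))
  sel <- select_parents(gb, c("A", "B"), k = 2)
  expect_equal(sel$by_trait$A, c(1L, 2L))
  expect_equal(sel$by_trait$B, c(3L, 4L))
  expect_equal(anyDuplicated(sel$parents), 0L)

  # brute-force oracle over random GEBVs: 2k distinct parents, each list
  # a prefix of its trait ranking once the other list's picks are removed
  set.seed(91)
  for (rep in 1:25) {
    gbr <- cbind(A = sample(20), B = sample(20))
    s <- select_parents(gbr, c("A", "B"), k = 4)
    expect_equal(length(unique(s$parents)), 8L)
    expect_equal(lengths(s$by_trait), c(A = 4L, B = 4L))
    for (tr in c("A", "B")) {
      other <- setdiff(s$parents, s$by_trait[[tr]])
      rank_tr <- order(-gbr[, tr])
      avail <- setdiff(rank_tr, other)
      expect_setequal(s$by_trait[[tr]], avail[1:4])
    }
  }
  expect_error(select_parents(cbind(A = 1:3, B = 3:1), c("A", "B"), k = 2),
               "fewer candidates")
})

test_that("round-robin plans reproduce the constant-size arithmetic", {
  sel4 <- list(A = 1:2, B = 3:4)
  plan4 <- round_robin_plan(sel4, 96)
  expect_equal(nrow(plan4$crosses), 4L)
  expect_equal(plan4$progeny_per_cross, 24L)   # 96 / 4 crosses
  sel8 <- list(A = 1:4, B = 5:8)
  plan8 <- round_robin_plan(sel8, 96)
  expect_equal(nrow(plan8$crosses), 8L)
  expect_equal(plan8$progeny_per_cross, 12L)   # 96 / 8 crosses
  # ring interleaves the trait groups: every cross pairs A with B
  ring_groups <- plan8$ring %in% sel8$A
  expect_true(all(ring_groups == rep(c(TRUE, FALSE), 4)))
  pairs_mixed <- xor(plan8$crosses[, 1] %in% sel8$A,
                     plan8$crosses[, 2] %in% sel8$A)
  expect_true(all(pairs_mixed))
})

test_that("round-robin handles rings of three, two, and indivisible sizes", {
  plan3 <- round_robin_plan(list(x = c(1L, 2L, 3L)), 9)
  expect_equal(plan3$crosses, cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)))
  plan2 <- round_robin_plan(list(x = c(4L, 9L)), 96)
  expect_equal(nrow(plan2$crosses), 1L)
  expect_equal(plan2$progeny_per_cross, 96L)
  expect_error(round_robin_plan(list(x = 1:5), 96), "divisible")
})

test_that("recurrent GS keeps population size constant and responds to selection", {
  b <- tiny_bundle()
  f <- filter_markers(b$d)
  g <- impute_mean(f$genotypes)
  genome <- build_bins(linkage_map(as.data.frame(b$fnd$map)[f$keep, ],
                                   chrom_lengths(b$fnd$map)))
  pf <- subset_markers(b$fnd$pop, which(f$keep))
  models <- list(T1 = fit_rr(g, b$phe$values[, 1]),
                 T2 = fit_rr(g, b$phe$values[, 2]))
  sim <- run_recurrent_gs(pf, genome, models, c("T1", "T2"),
                          generations = 3, replicates = 2, N = 24,
                          seed = 5)
  counts <- with(subset(sim$gebvs, generation > 0 & trait == "T1"),
                 table(replicate, generation))
  expect_true(all(counts == 24))
  # parents always come from the candidate population
  expect_true(all(grepl("^(v|r)", unlist(sim$parents))))
  # mean target GEBV rises from founders to the last generation
  m0 <- with(subset(sim$gebvs, generation == 0 & trait == "T1"), mean(gebv))
  m3 <- with(subset(sim$gebvs, generation == 3 & trait == "T1"), mean(gebv))
  expect_gt(m3, m0)
  # fixed seed reproduces the trajectory exactly
  sim2 <- run_recurrent_gs(pf, genome, models, c("T1", "T2"),
                           generations = 3, replicates = 2, N = 24,
                           seed = 5)
  expect_identical(sim$gebvs, sim2$gebvs)
})

test_that("genetically uniform founders give flat GEBV trajectories", {
  tg <- toy_genome(length_cm = 30, n_markers = 15)
  hap <- matrix(0L, 12, 15)
  hap[, 1] <- rep(c(0L, 1L), 3)  # one polymorphic marker so models fit
  pop <- phased_population(hap, sprintf("u%d", 1:6),
                           sprintf("m%03d", 1:15))
  genome <- build_bins(linkage_map(as.data.frame(tg$map), c(c1 = 100)))
  d <- dosages(pop)
  mdl <- fit_rr(d, rnorm(6))
  sim <- run_recurrent_gs(pop, genome, list(T = mdl, U = mdl), c("T", "U"),
                          generations = 2, replicates = 1, N = 8, seed = 2)
  spread <- tapply(sim$gebvs$gebv, sim$gebvs$generation, function(x)
    diff(range(x)))
  # heterozygous founders segregate, but the GEBV range cannot exceed the
  # single-marker span
  expect_true(all(spread <= abs(mdl$beta[1]) * 2 + 1e-8))
})

test_that("random selection is a trend-free negative control", {
  b <- tiny_bundle()
  f <- filter_markers(b$d)
  g <- impute_mean(f$genotypes)
  genome <- build_bins(linkage_map(as.data.frame(b$fnd$map)[f$keep, ],
                                   chrom_lengths(b$fnd$map)))
  pf <- subset_markers(b$fnd$pop, which(f$keep))
  models <- list(T1 = fit_rr(g, b$phe$values[, 1]),
                 T2 = fit_rr(g, b$phe$values[, 2]))
  run <- function(sel) run_recurrent_gs(pf, genome, models, c("T1", "T2"),
                                        generations = 4, replicates = 6,
                                        N = 24, selection = sel, seed = 17)
  rnd <- run("random")
  gsd <- run("gebv")
  slope_of <- function(sim, rep) {
    agg <- aggregate(gebv ~ generation,
                     subset(sim$gebvs, trait == "T1" & replicate == rep),
                     mean)
    coef(lm(gebv ~ generation, agg))[2]
  }
  sl_rnd <- vapply(1:6, function(r) slope_of(rnd, r), numeric(1))
  sl_gs <- vapply(1:6, function(r) slope_of(gsd, r), numeric(1))
  # drift: the mean random-selection slope is indistinguishable from 0
  ci <- t.test(sl_rnd)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
  # and far below the selection response
  expect_lt(mean(sl_rnd), 0.35 * mean(sl_gs))
})

test_that("derived inbred populations expose additive variance without shifting the mean", {
  tg <- toy_genome(length_cm = 60, n_markers = 30)
  f1 <- toy_f1(tg)
  set.seed(93)
  prog <- cross(f1, f1, 40, tg$genome)
  beta <- rnorm(30, 0, 0.3)
  d <- dosages(materialize_genotypes(prog, tg$genome, tg$pop$hap))
  mdl <- fit_rr(d, drop(d %*% beta) + rnorm(40, 0, 0.1))
  res <- derive_inbred_population(prog, tg$genome, tg$pop$hap,
                                  list(T = mdl), generations = 6)
  expect_length(res$inbreds, 40)
  par_gebv <- predict_gebv(mdl, d)
  inb_gebv <- res$gebvs[, "T"]
  # additive trait: inbreeding preserves the mean and inflates variance
  expect_lt(abs(mean(inb_gebv) - mean(par_gebv)),
            3 * sd(par_gebv) / sqrt(40) + 0.15 * sd(par_gebv))
  expect_gt(var(inb_gebv), 0.8 * var(par_gebv))
  # homozygous population: inbreds identical to inputs
  hom <- derive_inbred_population(tg$founders[1:2], tg$genome, tg$pop$hap,
                                  list(T = mdl))
  expect_equal(unname(hom$gebvs[, "T"]),
               unname(predict_gebv(mdl, dosages(materialize_genotypes(
                 tg$founders[1:2], tg$genome, tg$pop$hap)))))
})
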