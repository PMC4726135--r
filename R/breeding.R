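# Recurrent genomic selection: GEBV-based parent selection, round-robin
# crossing at constant population size, tracked across generations and
# replicates with founder-trained prediction models.

#' Select per-trait top parents with de-duplication
#'
#' For each target trait, the `k` candidates with highest GEBV are taken
#' (ties broken by candidate index). If an individual appears in more than
#' one trait's list it is kept for the trait where it ranks better (ties
#' go to the earlier trait) and the other list takes its next-ranked
#' unused candidate, so the stated parent counts are preserved and all
#' parents are distinct.
#'
#' @param gebvs `n x t` matrix of GEBVs, columns named by trait.
#' @param traits character vector of target trait names (columns of
#'   `gebvs`).
#' @param k parents per trait (scalar or per-trait vector).
#' @return list of class `parent_selection`: `by_trait` (list of index
#'   vectors, rank order) and `parents` (all selected indices).
#' @export
select_parents <- function(gebvs, traits, k) {
  gebvs <- as.matrix(gebvs)
  if (is.null(colnames(gebvs)))
    colnames(gebvs) <- paste0("trait", seq_len(ncol(gebvs)))
  if (!all(traits %in% colnames(gebvs))) stop("unknown target trait")
  if (length(k) == 1L) k <- rep(k, length(traits))
  n <- nrow(gebvs)
  if (sum(k) > n) stop("fewer candidates than required parents")
  ranks <- lapply(traits, function(tr) order(-gebvs[, tr], seq_len(n)))
  sel <- lapply(seq_along(traits), function(t) ranks[[t]][seq_len(k[t])])
  repeat {
    changed <- FALSE
    for (t1 in seq_along(sel)) {
      for (t2 in seq_along(sel)) {
        if (t2 <= t1) next
        dup <- intersect(sel[[t1]], sel[[t2]])
        if (!length(dup)) next
        id <- dup[1L]
        r1 <- match(id, ranks[[t1]])
        r2 <- match(id, ranks[[t2]])
        loser <- if (r1 <= r2) t2 else t1  # keep where it ranks better
        used <- unlist(sel)
        nxt <- setdiff(ranks[[loser]], used)
        if (!length(nxt)) stop("candidate pool exhausted during de-duplication")
        sel[[loser]] <- c(setdiff(sel[[loser]], id), nxt[1L])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # restore rank order within each trait list
  sel <- lapply(seq_along(sel), function(t)
    sel[[t]][order(match(sel[[t]], ranks[[t]]))])
  names(sel) <- traits
  structure(list(by_trait = sel, parents = unlist(sel, use.names = FALSE)),
            class = "parent_selection")
}

#' Round-robin crossing plan
#'
#' Parents are arranged in a ring interleaving the trait groups
#' (trait1-parent, trait2-parent, trait1-parent, ...), so every cross
#' pairs parents selected for different traits; each adjacent ring pair is
#' crossed once (`k` parents give `k` crosses) and the constant population
#' size is divided evenly over crosses. With 4 parents and N = 96 this is
#' 24 progeny per cross; with 8 parents, 12 per cross. Two parents
#' degenerate to a single cross with all N progeny.
#'
#' @param selection a [select_parents()] result (or a list of per-trait
#'   parent index vectors).
#' @param population_size total progeny N per generation, default 96;
#'   must be divisible by the number of crosses.
#' @return list of class `crossing_plan` with `ring`, `crosses` (two-column
#'   matrix), `progeny_per_cross`, `population_size`.
#' @export
round_robin_plan <- function(selection, population_size = 96) {
  by_trait <- if (inherits(selection, "parent_selection"))
    selection$by_trait else selection
  kper <- lengths(by_trait)
  if (length(unique(kper)) == 1L && length(by_trait) > 1L) {
    ring <- as.vector(t(do.call(cbind, lapply(by_trait, as.vector))))
  } else {
    ring <- unlist(by_trait, use.names = FALSE)
  }
  k <- length(ring)
  if (k < 2L) stop("at least two parents are required")
  if (k == 2L) {
    crosses <- matrix(ring, nrow = 1L)
    return(structure(list(ring = ring, crosses = crosses,
                          progeny_per_cross = population_size,
                          population_size = population_size),
                     class = "crossing_plan"))
  }
  if (population_size %% k != 0L)
    stop(sprintf("population size %d is not divisible by %d crosses",
                 population_size, k))
  crosses <- cbind(ring, ring[c(seq_len(k)[-1L], 1L)])
  dimnames(crosses) <- NULL
  structure(list(ring = ring, crosses = crosses,
                 progeny_per_cross = population_size %/% k,
                 population_size = population_size),
            class = "crossing_plan")
}

#' @export
print.crossing_plan <- function(x, ...) {
  cat(sprintf("crossing_plan: %d crosses x %d progeny (N = %d)\n",
              nrow(x$crosses), x$progeny_per_cross, x$population_size))
  invisible(x)
}

gebv_matrix <- function(individuals, genome, founder_alleles, models) {
  pop <- materialize_genotypes(individuals, genome, founder_alleles)
  d <- dosages(pop)
  vapply(models, function(mdl) predict_gebv(mdl, d), numeric(nrow(d)))
}

#' Run the recurrent genomic-selection scheme
#'
#' From a founder population, generation 1 is produced by a round-robin
#' cross of the top `k_first` (default 2) founders in GEBV for each target
#' trait; later generations use the top `k_later` (default 4) progeny per
#' trait. Population size is constant at `N` (default 96). Prediction
#' models are trained on the founders once and never retrained; GEBVs of
#' every trait (target and non-target) are recorded for every individual
#' of every generation and replicate.
#'
#' @param founders founder [phased_population()].
#' @param genome [build_bins()] result for the founders' map.
#' @param models named list of `marker_effect_model`s (one per tracked
#'   trait), trained on the founders.
#' @param target_traits two (or more) names of `models` to select on.
#' @param generations number of selection generations, default 5.
#' @param replicates independent simulation replicates, default 5.
#' @param N constant population size, default 96.
#' @param k_first,k_later parents per trait in generation 1 and later.
#' @param selection `"gebv"` (truncation selection) or `"random"`
#'   (negative control: parents drawn at random).
#' @param seed master seed; replicate r uses seed + r.
#' @return list of class `gs_sim`: `gebvs` (long data frame: replicate,
#'   generation, individual, trait, gebv; generation 0 = founders),
#'   `parents` (per replicate/generation selected parent ids), and the
#'   run settings.
#' @export
run_recurrent_gs <- function(founders, genome, models, target_traits,
                             generations = 5, replicates = 5, N = 96,
                             k_first = 2, k_later = 4,
                             selection = c("gebv", "random"), seed = 1) {
  selection <- match.arg(selection)
  stopifnot(inherits(founders, "phased_pop"), length(target_traits) >= 1)
  if (is.null(names(models))) stop("models must be a named list")
  if (!all(target_traits %in% names(models)))
    stop("target trait without a model")
  founder_alleles <- founders$hap
  founder_inds <- founder_individuals(founders, genome)
  d0 <- dosages(founders)
  g0 <- vapply(models, function(mdl) predict_gebv(mdl, d0), numeric(nrow(d0)))
  rows <- list()
  parent_log <- list()
  long <- function(rep, gen, ids, gb) {
    data.frame(replicate = rep, generation = gen,
               individual = rep(ids, times = ncol(gb)),
               trait = rep(colnames(gb), each = nrow(gb)),
               gebv = as.vector(gb))
  }
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    rows[[length(rows) + 1L]] <- long(r, 0L, founders$individual_ids, g0)
    current <- founder_inds
    gcur <- g0
    for (gen in seq_len(generations)) {
      k <- if (gen == 1L) k_first else k_later
      if (selection == "gebv") {
        picked <- select_parents(gcur, target_traits, k)
      } else {
        idx <- sample.int(nrow(gcur), k * length(target_traits))
        picked <- structure(
          list(by_trait = split(idx, rep(seq_along(target_traits), each = k)),
               parents = idx),
          class = "parent_selection")
      }
      plan <- round_robin_plan(picked, N)
      progeny <- list()
      for (cx in seq_len(nrow(plan$crosses))) {
        p1 <- current[[plan$crosses[cx, 1L]]]
        p2 <- current[[plan$crosses[cx, 2L]]]
        ids <- sprintf("r%d_g%d_c%d_%02d", r, gen, cx,
                       seq_len(plan$progeny_per_cross))
        progeny <- c(progeny, cross(p1, p2, plan$progeny_per_cross,
                                    genome, ids = ids))
      }
      gcur <- gebv_matrix(progeny, genome, founder_alleles, models)
      ids <- vapply(progeny, function(x) x$id, character(1))
      rows[[length(rows) + 1L]] <- long(r, gen, ids, gcur)
      parent_log[[sprintf("r%d_g%d", r, gen)]] <-
        vapply(current[picked$parents], function(x) x$id, character(1))
      current <- progeny
    }
  }
  structure(list(gebvs = do.call(rbind, rows), parents = parent_log,
                 target_traits = target_traits, N = N,
                 generations = generations, replicates = replicates,
                 selection = selection, seed = seed),
            class = "gs_sim")
}

#' @export
print.gs_sim <- function(x, ...) {
  cat(sprintf("gs_sim: %d replicates x %d generations, N = %d, targets: %s\n",
              x$replicates, x$generations, x$N,
              paste(x$target_traits, collapse = ", ")))
  invisible(x)
}

#' Derive an inbred population and its GEBVs
#'
#' One six-generation (by default) single-seed-descent inbred line is
#' produced from every individual of a population, and GEBVs of the
#' inbreds are computed with the same fixed models.
#'
#' @param individuals list of `sim_individual`s (one generation).
#' @param genome a `binned_genome`.
#' @param founder_alleles founder haplotype allele matrix.
#' @param models named list of `marker_effect_model`s.
#' @param generations selfing generations, default 6.
#' @return list with `inbreds` (list of `sim_individual`s) and `gebvs`
#'   (matrix, individuals x traits).
#' @export
derive_inbred_population <- function(individuals, genome, founder_alleles,
                                     models, generations = 6) {
  inbreds <- lapply(individuals, derive_inbred, genome = genome,
                    generations = generations)
  list(inbreds = inbreds,
       gebvs = gebv_matrix(inbreds, genome, founder_alleles, models))
}
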