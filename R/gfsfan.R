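# GFSFAN: two-stage genetic feature selection with fixed activation number.
# Stage 1 ranks features by Fisher Index and turns the ranks into selection
# probabilities for weighted initialization; stage 2 runs a generational GA
# whose crossover (COFAN) and mutation (MOFAN) operators preserve the
# activation count Ninit exactly, with tournament selection, crowding
# replacement, adaptive operator probabilities and single-elite protection.
# Fitness is the wrapper criterion f = exp(FM_all) + alpha * exp(FM_min)
# from 10-fold cross-validated LDA and naive-Bayes F-measures over the
# resampled groups.

#' GA configuration for GFSFAN
#'
#' @param ninit activation number: the fixed subset cardinality.
#' @param population population size (default 80).
#' @param max_iterations generations (default 100).
#' @param p_rank selection-probability endpoints `c(P1, P2)` for the
#'   FI-rank weighting (default `c(0.8, 0.4)`).
#' @param crossover_range adaptive crossover probability bounds
#'   `c(p1, p2)` (default `c(0.4, 0.8)`).
#' @param mutation_range adaptive mutation probability bounds (default
#'   `c(0.1, 0.4)`).
#' @param alpha weight of the minimum-class term in the fitness (default 0.1).
#' @param tournament_size tournament size (default 2).
#' @param crowding_size crowding cohort size (default 4).
#' @param folds wrapper cross-validation folds (default 10).
#' @param seed integer seed.
#' @return A `GAConfig` list.
#' @export
ga_config <- function(ninit, population = 80, max_iterations = 100,
                      p_rank = c(0.8, 0.4), crossover_range = c(0.4, 0.8),
                      mutation_range = c(0.1, 0.4), alpha = 0.1,
                      tournament_size = 2, crowding_size = 4, folds = 10,
                      seed = 1) {
  if (ninit < 1) stop_gfsfan("config error: ninit must be >= 1")
  if (p_rank[2] > p_rank[1]) stop_gfsfan("config error: P2 must be <= P1")
  stopifnot(all(c(p_rank, crossover_range, mutation_range) > 0),
            all(c(p_rank, crossover_range, mutation_range) <= 1))
  structure(list(ninit = ninit, population = population,
                 max_iterations = max_iterations, p_rank = p_rank,
                 crossover_range = crossover_range,
                 mutation_range = mutation_range, alpha = alpha,
                 tournament_size = tournament_size,
                 crowding_size = crowding_size, folds = folds, seed = seed),
            class = "GAConfig")
}

#' FI-rank selection probabilities
#'
#' The features with the largest and smallest Fisher Index get probabilities
#' `P1` and `P2`; intermediate ranks follow the arithmetic sequence between
#' them: `SP(r) = P1 - (P1 - P2) (r - 1) / (M - 1)`.
#'
#' @param ranking feature indices in descending-FI order (from
#'   [fisher_index()]).
#' @param p1,p2 endpoint probabilities (defaults 0.8, 0.4).
#' @return Numeric vector of selection probabilities indexed by feature
#'   (not by rank).
#' @export
selection_probabilities <- function(ranking, p1 = 0.8, p2 = 0.4) {
  M <- length(ranking)
  sp_by_rank <- if (M == 1) p1 else p1 - (p1 - p2) * (seq_len(M) - 1) / (M - 1)
  sp <- numeric(M)
  sp[ranking] <- sp_by_rank
  sp
}

#' Weighted initialization of one individual
#'
#' Weighted random sampling without replacement: each feature draws
#' `u ~ U(0, 1)` and key `w = u^(1 / SP)`; the `ninit` largest keys are
#' activated, so higher-probability features are selected more often while
#' every subset remains reachable.
#'
#' @param sp selection probabilities per feature.
#' @param ninit activation number.
#' @param seed optional integer seed (`NULL`: use the current RNG stream).
#' @return Logical mask with exactly `ninit` bits set.
#' @export
init_individual <- function(sp, ninit, seed = NULL) {
  M <- length(sp)
  if (ninit > M) stop_gfsfan("config error: ninit exceeds feature count")
  draw <- function() {
    u <- runif(M)
    w <- u^(1 / sp)
    mask <- logical(M)
    mask[order(-w)[seq_len(ninit)]] <- TRUE
    mask
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Fitness from aggregated F-measures
#'
#' `f = exp(FM_all) + alpha * exp(FM_min)`: the overall classification
#' performance dominates; the worst class acts as a tie-breaking supplement.
#'
#' @param fm_all mean per-class F-measure.
#' @param fm_min minimum per-class F-measure.
#' @param alpha supplement weight (default 0.1).
#' @return Scalar fitness.
#' @export
fitness_value <- function(fm_all, fm_min, alpha = 0.1) {
  exp(fm_all) + alpha * exp(fm_min)
}

#' GA fitness of a feature mask
#'
#' `f = exp(FM_all) + alpha * exp(FM_min)` where `FM_all` and `FM_min` are
#' the mean and minimum per-class F-measures of the wrapper classifiers
#' (LDA and Gaussian naive Bayes) under stratified 10-fold cross-validation,
#' averaged over the resampled groups.
#'
#' @param mask logical feature mask (>= 1 active).
#' @param data a `FeatureTable` or `ResampledEnsemble`.
#' @param alpha minimum-class weight (default 0.1).
#' @param folds CV folds.
#' @param seed integer seed for fold assignment.
#' @return Scalar fitness; attributes `fm_all`, `fm_min`.
#' @export
ga_fitness <- function(mask, data, alpha = 0.1, folds = 10, seed = 1) {
  cols <- which(mask)
  if (!length(cols)) stop_gfsfan("fitness of an empty mask")
  r <- wrapper_fm(as_groups(data), cols, seed = seed, folds = folds)
  structure(fitness_value(r$fm_all, r$fm_min, alpha),
            fm_all = r$fm_all, fm_min = r$fm_min)
}

#' Adaptive operator probability
#'
#' `p = p1 + (p2 - p1) (fmax - f) / (fmax - fmean)` for `f >= fmean`, else
#' `p2`: the fittest individuals are disturbed least (`p1` at `f = fmax`),
#' below-average ones most (`p2`). For crossover, `f` is the larger fitness
#' of the two parents. A degenerate population (`fmax = fmean`) returns
#' `p1` for `f >= fmean` (limit convention).
#'
#' @param f fitness of the individual (or larger parent).
#' @param f_mean,f_max population mean and maximum fitness.
#' @param range `c(p1, p2)` probability bounds.
#' @return Probability in `[p1, p2]`.
#' @export
adaptive_probability <- function(f, f_mean, f_max, range) {
  if (f_max < f_mean) stop_gfsfan("f_max must be >= f_mean")
  p1 <- range[1]; p2 <- range[2]
  if (f < f_mean) return(p2)
  if (f_max == f_mean) return(p1)
  p1 + (p2 - p1) * (f_max - f) / (f_max - f_mean)
}

#' Crossover with fixed activation number (COFAN)
#'
#' Active indices shared by both parents (the homogeneous genes) pass to
#' both children; the two disjoint remainders (equal length `d`) undergo
#' two-point crossover as index lists; each child's mask is rebuilt from
#' homogeneous plus crossed heterogeneous indices, so both children keep
#' exactly `ninit` active bits and no index outside the parents' union ever
#' appears.
#'
#' @param parent1,parent2 logical masks with equal popcount.
#' @return List of two children masks.
#' @export
cofan <- function(parent1, parent2) {
  a1 <- which(parent1); a2 <- which(parent2)
  if (length(a1) != length(a2))
    stop_gfsfan("parents must share the activation number")
  shared <- intersect(a1, a2)
  h1 <- setdiff(a1, shared); h2 <- setdiff(a2, shared)
  d <- length(h1)
  if (d == 0) return(list(parent1, parent2))
  cuts <- sort(sample.int(d + 1, 2, replace = TRUE) - 1L)  # 0..d boundaries
  seg <- if (cuts[1] < cuts[2]) (cuts[1] + 1):cuts[2] else integer(0)
  c1 <- h1; c2 <- h2
  c1[seg] <- h2[seg]; c2[seg] <- h1[seg]
  mk <- function(idx) {
    m <- logical(length(parent1)); m[c(shared, idx)] <- TRUE; m
  }
  list(mk(c1), mk(c2))
}

#' Mutation with fixed activation number (MOFAN)
#'
#' Each active bit deactivates independently with probability `p_mut`; the
#' realized number `m` of deactivations is matched by activating `m`
#' uniformly chosen inactive bits (capped at availability), preserving the
#' activation number.
#'
#' @param parent logical mask.
#' @param p_mut mutation probability per active bit.
#' @return Mutated mask.
#' @export
mofan <- function(parent, p_mut) {
  act <- which(parent)
  off <- act[runif(length(act)) < p_mut]
  m <- length(off)
  if (m == 0) return(parent)
  inact <- which(!parent)
  m <- min(m, length(inact))
  off <- off[seq_len(m)]
  on <- if (length(inact) == 1) inact else sample(inact, m)
  child <- parent
  child[off] <- FALSE
  child[on] <- TRUE
  child
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' Run the two-stage GFSFAN feature selection
#'
#' Stage 1: Fisher-Index ranking on the (first group of the) data yields
#' selection probabilities that bias the weighted initialization of the
#' population. Stage 2: generational GA with tournament selection, COFAN
#' crossover and MOFAN mutation at adaptive probabilities, crowding
#' replacement (an offspring replaces the most similar of a random cohort
#' only if fitter, so the best fitness never decreases) and single-elite
#' protection.
#'
#' @param data a `FeatureTable` or `ResampledEnsemble`.
#' @param config a [ga_config()].
#' @param verbose print per-generation progress.
#' @return List with `selected` (feature names), `mask`, `fitness`,
#'   `history` (data.frame `generation`, `best`, `mean`) and `config`.
#' @export
run_gfsfan <- function(data, config, verbose = FALSE) {
  stopifnot(inherits(config, "GAConfig"))
  groups <- as_groups(data)
  M <- ncol(groups[[1]]$x)
  if (config$ninit > M)
    stop_gfsfan("config error: ninit (", config$ninit,
                ") exceeds feature count (", M, ")")
  fi_table <- if (inherits(data, "ResampledEnsemble")) groups[[1]] else data
  rep_fi <- fisher_index(fi_table)
  sp <- selection_probabilities(rep_fi$ranking,
                                config$p_rank[1], config$p_rank[2])
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  fit_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- as.numeric(ga_fitness(mask, data, alpha = config$alpha,
                               folds = config$folds, seed = config$seed))
    evals <<- evals + 1L
    cache[[key]] <- f
    f
  }
  with_seed(derive_seed(config$seed, "ga"), {
    pop <- lapply(seq_len(config$population), function(i)
      init_individual(sp, config$ninit))
    fit <- vapply(pop, fit_of, 0)
    hist <- data.frame(generation = 0, best = max(fit), mean = mean(fit))
    for (gen in seq_len(config$max_iterations)) {
      if (config$ninit == M) break                # single-point search space
      f_mean <- mean(fit); f_max <- max(fit)
      n_pairs <- ceiling(config$population / 2)
      for (pair in seq_len(n_pairs)) {
        i1 <- tournament_pick(fit, config$tournament_size)
        i2 <- tournament_pick(fit, config$tournament_size)
        f_par <- max(fit[i1], fit[i2])
        p_c <- adaptive_probability(f_par, f_mean, f_max,
                                    config$crossover_range)
        kids <- if (runif(1) < p_c) cofan(pop[[i1]], pop[[i2]])
                else list(pop[[i1]], pop[[i2]])
        p_m <- adaptive_probability(f_par, f_mean, f_max,
                                    config$mutation_range)
        for (kid in kids) {
          child <- mofan(kid, p_m)
          fc <- fit_of(child)
          cohort <- sample.int(config$population,
                               min(config$crowding_size, config$population))
          sim <- vapply(cohort, function(j) sum(pop[[j]] & child), 0)
          tgt <- cohort[order(-sim, fit[cohort])[1]]
          if (fc > fit[tgt]) {                    # crowding: replace if fitter
            pop[[tgt]] <- child
            fit[tgt] <- fc
          }
        }
      }
      hist <- rbind(hist, data.frame(generation = gen, best = max(fit),
                                     mean = mean(fit)))
      if (verbose)
        message(sprintf("gen %3d  best %.5f  mean %.5f  evals %d",
                        gen, max(fit), mean(fit), evals))
    }
    best <- which.max(fit)
    list(selected = colnames(groups[[1]]$x)[which(pop[[best]])],
         mask = pop[[best]], fitness = fit[best], history = hist,
         config = config, evaluations = evals)
  })
}
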