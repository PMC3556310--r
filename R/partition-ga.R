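#' @title Maximizing the modularity score
#' @name optimizers
#' @description
#' A subnetwork is bipartitioned by finding the -1/+1 assignment vector `s`
#' maximizing `Q = s V s^T`. Small subnetworks (<= 8 nodes) are solved
#' exactly by exhaustive enumeration; larger ones use a genetic algorithm
#' (population 100, truncation selection of the top 60%, uniform-agreement
#' crossover, 20% per-element sign-flip mutation, termination when the mean
#' population fitness plateaus with absolute slope < 0.05 over a window of
#' generations). A leading-eigenvector method is provided as a comparator.
NULL

#' Genetic algorithm parameters
#'
#' @param population_size number of assignment vectors per generation.
#' @param selection_fraction fraction of the population kept as parents by
#'   truncation selection on Q.
#' @param mutation_rate per-element sign-flip probability applied to
#'   offspring.
#' @param plateau_slope termination threshold: absolute OLS slope of mean Q
#'   versus generation over the last `plateau_window` generations.
#' @param plateau_window number of generations in the slope fit.
#' @param max_generations hard stop.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a `ga_params` list.
#' @export
ga_params <- function(population_size = 100, selection_fraction = 0.6,
                      mutation_rate = 0.2, plateau_slope = 0.05,
                      plateau_window = 20, max_generations = 500,
                      seed = NULL) {
  stopifnot(population_size >= 2,
            selection_fraction > 0, selection_fraction < 1,
            mutation_rate >= 0, mutation_rate <= 1,
            plateau_slope >= 0, plateau_window >= 2, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 selection_fraction = selection_fraction,
                 mutation_rate = mutation_rate,
                 plateau_slope = plateau_slope,
                 plateau_window = as.integer(plateau_window),
                 max_generations = as.integer(max_generations),
                 seed = seed),
            class = "ga_params")
}

# Run expr under a local, seeded RNG stream without disturbing the caller's.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dense coupling matrix for fast Q evaluation (NA -> 0, zero diagonal).
q_matrix <- function(V) {
  M <- V$entries
  M[is.na(M)] <- 0
  diag(M) <- 0
  M
}

# Q for each row of a +-1 population matrix.
pop_fitness <- function(pop, M) {
  rowSums((pop %*% M) * pop)
}

#' Exhaustive optimal bipartition
#'
#' Enumerates all `2^(n-1)` sign-distinct assignments (the first node is
#' pinned to +1) and returns the global maximum of Q; on ties the first
#' assignment in enumeration order (-1 before +1 on the remaining
#' elements) is kept, which is deterministic.
#'
#' @param V a `modularity_matrix` over at most 8 nodes.
#' @return list with `s` (named -1/+1 vector) and `q`.
#' @export
exhaustive_bipartition <- function(V) {
  stopifnot(inherits(V, "modularity_matrix"))
  n <- length(V$nodes)
  if (n < 2L) stop("need at least 2 nodes to bipartition")
  if (n > 8L) stop("exhaustive search is limited to 8 nodes; use the GA")
  M <- q_matrix(V)
  best_q <- -Inf
  best_s <- NULL
  for (k in 0:(2^(n - 1L) - 1L)) {
    tail <- ifelse(bitwAnd(k, bitwShiftL(1L, (n - 2L):0)) > 0, 1, -1)
    s <- c(1, if (n > 1L) tail)
    q <- drop(s %*% M %*% s)
    if (q > best_q) {
      best_q <- q
      best_s <- s
    }
  }
  list(s = stats::setNames(best_s, V$nodes), q = best_q)
}

#' Genetic-algorithm bipartition
#'
#' Maximizes Q over -1/+1 assignments. Offspring inherit each element on
#' which both parents agree and draw the disputed elements uniformly at
#' random; each offspring element then flips sign with probability
#' `mutation_rate`. The best assignment ever seen (hall of fame) is
#' returned, so the reported Q never decreases across generations.
#'
#' @param V a `modularity_matrix` over at least 2 nodes.
#' @param params a [ga_params()].
#' @return list with `s`, `q`, `generations`, `mean_q_history`,
#'   `best_q_history`, and `degenerate` (TRUE when V has no defined,
#'   nonzero entry, in which case an arbitrary balanced split with Q = 0 is
#'   returned).
#' @export
ga_bipartition <- function(V, params = ga_params()) {
  stopifnot(inherits(V, "modularity_matrix"), inherits(params, "ga_params"))
  n <- length(V$nodes)
  if (n < 2L) stop("need at least 2 nodes to bipartition")
  M <- q_matrix(V)
  if (all(M == 0)) {
    s <- rep(c(1, -1), length.out = n)
    return(list(s = stats::setNames(s, V$nodes), q = 0, generations = 0L,
                mean_q_history = numeric(0), best_q_history = numeric(0),
                degenerate = TRUE))
  }
  with_local_seed(params$seed, {
    p_size <- params$population_size
    pop <- matrix(sample(c(-1, 1), p_size * n, replace = TRUE), p_size, n)
    fit <- pop_fitness(pop, M)
    best_idx <- which.max(fit)
    best_s <- pop[best_idx, ]
    best_q <- fit[best_idx]
    mean_hist <- numeric(0)
    best_hist <- numeric(0)
    n_sel <- max(2L, round(params$selection_fraction * p_size))
    gen <- 0L
    repeat {
      gen <- gen + 1L
      keep <- order(fit, decreasing = TRUE)[seq_len(n_sel)]
      parents <- pop[keep, , drop = FALSE]
      n_off <- p_size - n_sel
      if (n_off > 0L) {
        pa <- parents[sample.int(n_sel, n_off, replace = TRUE), , drop = FALSE]
        pb <- parents[sample.int(n_sel, n_off, replace = TRUE), , drop = FALSE]
        # s and -s encode the same partition: align the second parent with
        # the first so agreement is measured on partitions, not raw signs
        flip <- rowSums(pa == pb) < n / 2
        pb[flip, ] <- -pb[flip, , drop = FALSE]
        agree <- pa == pb
        rand <- matrix(sample(c(-1, 1), n_off * n, replace = TRUE), n_off, n)
        off <- ifelse(agree, pa, rand)
        flips <- matrix(stats::runif(n_off * n) < params$mutation_rate,
                        n_off, n)
        off[flips] <- -off[flips]
        pop <- rbind(parents, off)
      } else {
        pop <- parents
      }
      fit <- pop_fitness(pop, M)
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_q) {
        best_q <- fit[gen_best]
        best_s <- pop[gen_best, ]
      }
      mean_hist <- c(mean_hist, mean(fit))
      best_hist <- c(best_hist, best_q)
      if (gen >= params$plateau_window) {
        win <- mean_hist[seq(gen - params$plateau_window + 1L, gen)]
        slope <- stats::coef(stats::lm.fit(
          cbind(1, seq_along(win)), win))[2]
        if (abs(slope) < params$plateau_slope) break
      }
      if (gen >= params$max_generations) break
    }
    list(s = stats::setNames(best_s, V$nodes), q = best_q, generations = gen,
         mean_q_history = mean_hist, best_q_history = best_hist,
         degenerate = FALSE)
  })
}

#' Leading-eigenvector bipartition (comparator)
#'
#' Approximates the Q maximizer by the sign pattern of the leading
#' eigenvector of the (symmetrized) modularity matrix; zero entries are
#' assigned +1. Provided for comparison with the exact and GA optimizers,
#' which it generally does not beat.
#'
#' @param V a `modularity_matrix`.
#' @return list with `s` and `q`.
#' @export
spectral_bipartition <- function(V) {
  stopifnot(inherits(V, "modularity_matrix"))
  n <- length(V$nodes)
  if (n < 2L) stop("need at least 2 nodes to bipartition")
  M <- q_matrix(V)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  lead <- ev$vectors[, which.max(ev$values)]
  s <- ifelse(lead >= 0, 1, -1)
  list(s = stats::setNames(s, V$nodes), q = drop(s %*% M %*% s))
}
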