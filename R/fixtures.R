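#' @title Synthetic fixture networks
#' @name synth_fixtures
#' @description
#' Small reaction networks with steady-state-consistent fluxes, built
#' entirely in code: the two textbook edge-weighting examples (one producer
#' with two consumers; two producers feeding a shared pool), a five-reaction
#' cofactor-mediated cycle, and random networks of planted directed cycles
#' joined by weak bridge reactions. Steady state is guaranteed by
#' construction — every flux vector is a nonnegative combination of
#' cycle-indicator and closed bridge-pair flux modes — so `S v = 0` holds
#' exactly, not merely to fit tolerance.
NULL

#' Single-producer fixture (two consumers sharing one pool)
#'
#' A producer R1 makes 100 mol/min of the intermediary M2; consumer R2
#' draws 60 and consumer R3 draws 40. Boundary closure reactions make the
#' state exactly balanced. The flux edge distances are 100/60 = 1.67
#' (R1 to R2) and 100/40 = 2.50 (R1 to R3).
#'
#' @return list with `model` (a [metabolic_model()]) and `state`
#'   (a [flux_state()]).
#' @export
make_figure7a <- function() {
  rxns <- list(
    list(id = "Rin",   group = "exchange", stoich = c(M1 = 1), reversible = FALSE),
    list(id = "R1",    group = "pathway",  stoich = c(M1 = -1, M2 = 1), reversible = FALSE),
    list(id = "R2",    group = "pathway",  stoich = c(M2 = -1, M3 = 1), reversible = FALSE),
    list(id = "R3",    group = "pathway",  stoich = c(M2 = -1, M4 = 1), reversible = FALSE),
    list(id = "Rout2", group = "exchange", stoich = c(M3 = -1), reversible = FALSE),
    list(id = "Rout3", group = "exchange", stoich = c(M4 = -1), reversible = FALSE)
  )
  model <- metabolic_model(rxns)
  v <- c(Rin = 100, R1 = 100, R2 = 60, R3 = 40, Rout2 = 60, Rout3 = 40)
  list(model = model, state = flux_state(v, model, label = "figure7a"))
}

#' Two-producer fixture (homogeneous shared pool)
#'
#' Producers R1 and R2 both feed pool M0 (total 100 mol/min by default);
#' consumers R3 and R4 draw 70% and 30% of the pool. Because the pool is
#' homogeneous, the edge distance from either producer to a consumer
#' depends only on the consumer's share: all distances are unchanged by
#' how production is divided between R1 and R2.
#'
#' @param v1,v2 producer fluxes (default 50 each).
#' @param share3 fraction of the pool drawn by R3 (default 0.7).
#' @return list with `model` and `state`.
#' @export
make_figure7b <- function(v1 = 50, v2 = 50, share3 = 0.7) {
  stopifnot(v1 >= 0, v2 >= 0, v1 + v2 > 0, share3 > 0, share3 < 1)
  total <- v1 + v2
  rxns <- list(
    list(id = "Rin1",  group = "exchange", stoich = c(A = 1), reversible = FALSE),
    list(id = "Rin2",  group = "exchange", stoich = c(B = 1), reversible = FALSE),
    list(id = "R1",    group = "pathway",  stoich = c(A = -1, M0 = 1), reversible = FALSE),
    list(id = "R2",    group = "pathway",  stoich = c(B = -1, M0 = 1), reversible = FALSE),
    list(id = "R3",    group = "pathway",  stoich = c(M0 = -1, C = 1), reversible = FALSE),
    list(id = "R4",    group = "pathway",  stoich = c(M0 = -1, D = 1), reversible = FALSE),
    list(id = "Rout3", group = "exchange", stoich = c(C = -1), reversible = FALSE),
    list(id = "Rout4", group = "exchange", stoich = c(D = -1), reversible = FALSE)
  )
  model <- metabolic_model(rxns)
  v <- c(Rin1 = v1, Rin2 = v2, R1 = v1, R2 = v2,
         R3 = share3 * total, R4 = (1 - share3) * total,
         Rout3 = share3 * total, Rout4 = (1 - share3) * total)
  list(model = model, state = flux_state(v, model, label = "figure7b"))
}

#' Five-reaction cofactor cycle fixture
#'
#' A directed five-reaction cycle mirroring a fatty-acid-synthesis /
#' oxidative-phosphorylation / TCA loop closed through a CoA-like carrier:
#' R42 -> R50 -> R48 -> R34 -> R54 -> R42. All reactions carry the same
#' (configurable) flux, so the state is exactly balanced.
#'
#' @param flux cycle flux (default 100).
#' @return list with `model` and `state`.
#' @export
make_figure8_like <- function(flux = 100) {
  stopifnot(flux > 0)
  order <- c("R42", "R50", "R48", "R34", "R54")
  mets <- paste0("m_", order)  # m_X is the product of X, consumed by the next
  rxns <- lapply(seq_along(order), function(k) {
    prev <- mets[if (k == 1L) length(order) else k - 1L]
    list(id = order[k], group = "cycle",
         stoich = stats::setNames(c(-1, 1), c(prev, mets[k])),
         reversible = FALSE)
  })
  model <- metabolic_model(rxns)
  v <- stats::setNames(rep(flux, length(order)), order)
  list(model = model, state = flux_state(v, model, label = "figure8_like"))
}

#' Specification of a random planted-cycle fixture
#'
#' @param n_reactions total number of cycle reactions (split across the
#'   planted cycles; bridges are extra).
#' @param cycle_count number of planted directed cycles (>= 1).
#' @param flux_scale length-2 numeric range from which each cycle's flux is
#'   drawn uniformly.
#' @param bridge_ratio bridge flux as a fraction of the smaller adjoining
#'   cycle flux (default 0.01).
#' @param seed integer seed (byte-identical fixtures per seed).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_reactions = 12, cycle_count = 2,
                         flux_scale = c(50, 150), bridge_ratio = 0.01,
                         seed = 1) {
  stopifnot(cycle_count >= 1, n_reactions >= 3 * cycle_count,
            length(flux_scale) == 2, all(flux_scale > 0),
            flux_scale[1] <= flux_scale[2],
            bridge_ratio > 0, bridge_ratio < 1)
  structure(list(kind = "random", n_reactions = as.integer(n_reactions),
                 cycle_count = as.integer(cycle_count),
                 flux_scale = flux_scale, bridge_ratio = bridge_ratio,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Random planted-cycle network with exact steady state
#'
#' Builds `cycle_count` directed reaction cycles (dense internal coupling,
#' large fluxes), joined in a chain by pairs of opposed low-flux bridge
#' reactions (each pair forms a closed flux mode, so mass balance is exact).
#' Canonical group labels equal the planted cycle ids, and the returned
#' `labels` vector is the ground truth for module-recovery tests (bridge
#' reactions are labeled `"bridge"`).
#'
#' @param spec a [fixture_spec()].
#' @return list with `model`, `state`, and `labels` (named character
#'   vector: reaction id -> planted module).
#' @export
make_random <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    sizes <- rep(spec$n_reactions %/% spec$cycle_count, spec$cycle_count)
    extra <- spec$n_reactions %% spec$cycle_count
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    F <- stats::runif(spec$cycle_count, spec$flux_scale[1], spec$flux_scale[2])
    rxns <- list()
    v <- numeric(0)
    labels <- character(0)
    first_met <- character(spec$cycle_count)
    for (cyc in seq_len(spec$cycle_count)) {
      mets <- sprintf("c%d_m%d", cyc, seq_len(sizes[cyc]))
      first_met[cyc] <- mets[1]
      for (k in seq_len(sizes[cyc])) {
        rid <- sprintf("c%d_r%d", cyc, k)
        nxt <- mets[if (k == sizes[cyc]) 1L else k + 1L]
        rxns[[length(rxns) + 1L]] <- list(
          id = rid, group = sprintf("cycle%d", cyc),
          stoich = stats::setNames(c(-1, 1), c(mets[k], nxt)),
          reversible = FALSE)
        v[rid] <- F[cyc]
        labels[rid] <- sprintf("cycle%d", cyc)
      }
    }
    if (spec$cycle_count > 1L) {
      for (cyc in seq_len(spec$cycle_count - 1L)) {
        eps <- spec$bridge_ratio * min(F[cyc], F[cyc + 1L])
        fwd <- sprintf("b%d_fwd", cyc)
        rev <- sprintf("b%d_rev", cyc)
        rxns[[length(rxns) + 1L]] <- list(
          id = fwd, group = "bridge",
          stoich = stats::setNames(c(-1, 1), c(first_met[cyc], first_met[cyc + 1L])),
          reversible = FALSE)
        rxns[[length(rxns) + 1L]] <- list(
          id = rev, group = "bridge",
          stoich = stats::setNames(c(-1, 1), c(first_met[cyc + 1L], first_met[cyc])),
          reversible = FALSE)
        v[fwd] <- eps
        v[rev] <- eps
        labels[fwd] <- labels[rev] <- "bridge"
      }
    }
    model <- metabolic_model(rxns)
    list(model = model,
         state = flux_state(v, model, label = sprintf("random_seed%d", spec$seed)),
         labels = labels)
  })
}
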