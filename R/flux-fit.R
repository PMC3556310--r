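#' @title Flux estimation from measured exchange rates
#' @name flux_fit
#' @description
#' Steady-state flux distributions are estimated by minimizing the sum of
#' squared differences between measured and calculated metabolite exchange
#' rates, subject to the stoichiometric balance constraints `S v = 0` over
#' internal metabolites — no metabolic objective function is assumed. When
#' the optimum is non-unique the minimum-norm optimal flux vector is
#' returned and the dimension of the optimal set (remaining degrees of
#' freedom) is reported.
NULL

#' Construct an exchange-rate measurement set
#'
#' @param rates named numeric vector: exchange reaction id -> measured rate.
#' @param model a [metabolic_model()]; every id must be in its exchange set.
#' @param label state name.
#' @param sd optional named numeric vector of measurement standard
#'   deviations (used for inverse-variance weighting).
#' @return an object of class `exchange_measurements`.
#' @export
exchange_measurements <- function(rates, model, label = "state", sd = NULL) {
  stopifnot(inherits(model, "metabolic_model"), length(rates) >= 1L)
  bad <- setdiff(names(rates), model$exchanges)
  if (length(bad) > 0L) {
    stop("measured id(s) not in the model's exchange set: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(sd)) {
    stopifnot(all(names(sd) %in% names(rates)), all(sd > 0))
  }
  structure(list(rates = rates, sd = sd, label = label),
            class = "exchange_measurements")
}

# Orthonormal basis of {v : C v = 0}; 0-column matrix when C has full
# column rank.
null_basis <- function(C, n) {
  if (nrow(C) == 0L) return(diag(n))
  N <- MASS::Null(t(C))
  if (length(N) == 0L) matrix(0, n, 0) else N
}

#' Degrees-of-freedom report for a flux-estimation problem
#'
#' @param model a [metabolic_model()].
#' @param meas an [exchange_measurements()].
#' @return list with `n_reactions`, `n_balances_independent` (rank of the
#'   internal-metabolite stoichiometric matrix), `n_measured`, and `dof`
#'   (reactions minus the rank of the stacked balance-plus-measurement
#'   system; the dimension of the optimal flux set when measurements are
#'   consistent).
#' @export
dof_report <- function(model, meas) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(meas, "exchange_measurements"))
  S <- stoichiometric_matrix(model)
  S_int <- S[internal_metabolites(model), , drop = FALSE]
  ids <- model$reactions$id
  E <- matrix(0, length(meas$rates), length(ids),
              dimnames = list(names(meas$rates), ids))
  E[cbind(seq_along(meas$rates), match(names(meas$rates), ids))] <- 1
  list(n_reactions = length(ids),
       n_balances_independent = qr(S_int)$rank,
       n_measured = length(meas$rates),
       dof = length(ids) - qr(rbind(S_int, E))$rank)
}

#' Estimate fluxes by constrained least squares
#'
#' Solves `min sum_e (measured_e - v_e)^2` subject to `S v = 0` over
#' internal metabolites, via an orthonormal null-space reduction. With
#' `enforce_irreversibility = TRUE` (default), irreversible reactions
#' driven negative by the unconstrained optimum are pinned to zero
#' iteratively until all signs are admissible. Among non-unique optima the
#' minimum-norm flux vector is returned.
#'
#' @param model a [metabolic_model()].
#' @param meas an [exchange_measurements()].
#' @param weights `"none"` (default, unweighted sum of squares) or
#'   `"inverse_variance"` (requires `sd` in the measurement set).
#' @param enforce_irreversibility pin negative irreversible fluxes to zero.
#' @param tol numeric tolerance for constraint checks.
#' @return list with `state` (a [flux_state()]) and `report` (objective,
#'   per-measurement residuals, `dof` of the optimal set, pinned reaction
#'   ids, balance residual norm).
#' @export
estimate_fluxes <- function(model, meas, weights = c("none", "inverse_variance"),
                            enforce_irreversibility = TRUE, tol = 1e-8) {
  weights <- match.arg(weights)
  stopifnot(inherits(model, "metabolic_model"),
            inherits(meas, "exchange_measurements"))
  ids <- model$reactions$id
  n <- length(ids)
  S <- stoichiometric_matrix(model)
  S_int <- S[internal_metabolites(model), , drop = FALSE]
  E <- matrix(0, length(meas$rates), n,
              dimnames = list(names(meas$rates), ids))
  E[cbind(seq_along(meas$rates), match(names(meas$rates), ids))] <- 1
  b <- unname(meas$rates)
  w <- rep(1, length(b))
  if (weights == "inverse_variance") {
    if (is.null(meas$sd)) stop("inverse-variance weighting requires sd")
    w <- 1 / meas$sd[names(meas$rates)]
  }
  Ew <- E * w
  bw <- b * w

  pinned <- character(0)
  irrev <- ids[!model$reactions$reversible]
  for (iter in seq_len(n + 1L)) {
    C <- S_int
    if (length(pinned) > 0L) {
      P <- matrix(0, length(pinned), n, dimnames = list(pinned, ids))
      P[cbind(seq_along(pinned), match(pinned, ids))] <- 1
      C <- rbind(C, P)
    }
    N <- null_basis(C, n)
    if (ncol(N) == 0L) {
      v <- rep(0, n)
      dof <- 0L
    } else {
      A <- Ew %*% N
      z <- drop(MASS::ginv(A) %*% bw)
      v <- drop(N %*% z)
      dof <- ncol(N) - qr(A)$rank
    }
    if (!enforce_irreversibility) break
    viol <- irrev[v[match(irrev, ids)] < -max(tol, 1e2 * .Machine$double.eps)]
    viol <- setdiff(viol, pinned)
    if (length(viol) == 0L) break
    pinned <- c(pinned, viol)
  }
  names(v) <- ids
  v[abs(v) < tol] <- 0
  resid <- drop(E %*% v) - b
  names(resid) <- names(meas$rates)
  bal <- drop(S_int %*% v)
  if (max(abs(bal)) > 1e-6) {
    stop("infeasible constraints: steady-state balance violated for ",
         paste(rownames(S_int)[abs(bal) > 1e-6], collapse = ", "))
  }
  state <- flux_state(v, model, label = meas$label)
  list(state = state,
       report = list(objective = sum((resid * w)^2),
                     residuals = resid,
                     dof = dof,
                     pinned = pinned,
                     balance_residual_norm = sqrt(sum(bal^2))))
}
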