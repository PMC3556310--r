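#' @title Metabolic model and flux-state containers
#' @name metabolic_model
#' @description
#' A `metabolic_model` holds an ordered set of reactions, each with a signed
#' stoichiometry over metabolites (negative = consumed, positive = produced),
#' a reversibility flag and a canonical pathway group label. Exchange
#' reactions (one-sided equations crossing the system boundary) are tracked
#' so that steady-state balances are only enforced on internal metabolites.
NULL

#' Construct a metabolic model from a list of reactions
#'
#' @param reactions a list; each element is a list with fields `id`, `group`,
#'   `stoich` (named numeric vector, metabolite -> signed coefficient),
#'   `reversible` (logical) and optionally `name`.
#' @param exchanges character vector of exchange reaction ids. If `NULL`,
#'   exchanges are auto-detected as reactions whose stoichiometry is
#'   one-sided (all coefficients share a sign).
#' @return an object of class `metabolic_model` with components `reactions`
#'   (data frame of id, name, group, reversible), `stoich` (named list of
#'   named numeric vectors), `metabolites`, and `exchanges`.
#' @export
metabolic_model <- function(reactions, exchanges = NULL) {
  if (length(reactions) == 0L) stop("model must contain at least one reaction")
  ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate reaction id(s): ", paste(unique(dup), collapse = ", "))
  }
  stoich <- lapply(reactions, function(r) {
    s <- r$stoich
    if (length(s) == 0L) stop("reaction '", r$id, "' has empty stoichiometry")
    if (anyDuplicated(names(s))) {
      stop("reaction '", r$id, "' lists a metabolite twice")
    }
    s[s != 0]
  })
  names(stoich) <- ids
  tab <- data.frame(
    id = ids,
    name = vapply(reactions, function(r) {
      if (is.null(r$name)) as.character(r$id) else as.character(r$name)
    }, character(1)),
    group = vapply(reactions, function(r) {
      if (is.null(r$group) || is.na(r$group) || !nzchar(r$group)) "unassigned"
      else as.character(r$group)
    }, character(1)),
    reversible = vapply(reactions, function(r) isTRUE(r$reversible), logical(1)),
    stringsAsFactors = FALSE
  )
  mets <- unique(unlist(lapply(stoich, names), use.names = FALSE))
  if (is.null(exchanges)) {
    one_sided <- vapply(stoich, function(s) all(s > 0) || all(s < 0), logical(1))
    exchanges <- ids[one_sided]
  } else {
    missing <- setdiff(exchanges, ids)
    if (length(missing) > 0L) {
      stop("exchange id(s) not in model: ", paste(missing, collapse = ", "))
    }
  }
  structure(
    list(reactions = tab, stoich = stoich, metabolites = mets,
         exchanges = exchanges),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      length(x$metabolites), " metabolites, ",
      length(x$exchanges), " exchanges\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a [metabolic_model()].
#' @return numeric matrix S of dimension |metabolites| x |reactions|;
#'   S[m, r] is the signed coefficient of metabolite m in reaction r.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- matrix(0, nrow = length(model$metabolites),
              ncol = nrow(model$reactions),
              dimnames = list(model$metabolites, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoich[[rid]]
    S[names(s), rid] <- s
  }
  S
}

#' Internal (balanced) metabolites of a model
#'
#' Metabolites that occur only in exchange reactions sit on the system
#' boundary and are excluded from steady-state balances; all others are
#' internal.
#'
#' @param model a [metabolic_model()].
#' @return character vector of internal metabolite ids.
#' @export
internal_metabolites <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  internal_rxns <- setdiff(model$reactions$id, model$exchanges)
  inside <- unique(unlist(lapply(model$stoich[internal_rxns], names),
                          use.names = FALSE))
  model$metabolites[model$metabolites %in% inside]
}

#' Construct a flux state
#'
#' @param v named numeric vector, reaction id -> flux.
#' @param model a [metabolic_model()]; every reaction must have a flux.
#' @param label state name (e.g. `"Day 12"`).
#' @param zero_tol nonnegative threshold below which a flux magnitude is
#'   treated as zero (default `1e-9`).
#' @return an object of class `flux_state`.
#' @export
flux_state <- function(v, model, label = "state", zero_tol = 1e-9) {
  stopifnot(inherits(model, "metabolic_model"), zero_tol >= 0)
  ids <- model$reactions$id
  unknown <- setdiff(names(v), ids)
  if (length(unknown) > 0L) {
    stop("flux given for unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(ids, names(v))
  if (length(missing) > 0L) {
    stop("missing flux for reaction id(s): ", paste(missing, collapse = ", "))
  }
  v <- v[ids]
  irrev <- ids[!model$reactions$reversible]
  bad <- irrev[v[irrev] < -zero_tol]
  if (length(bad) > 0L) {
    stop("negative flux on irreversible reaction(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(label = label, v = v, zero_tol = zero_tol),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> '", x$label, "': ", length(x$v), " fluxes, range [",
      signif(min(x$v), 4), ", ", signif(max(x$v), 4), "]\n", sep = "")
  invisible(x)
}

#' Steady-state residual of a flux state
#'
#' Computes S.v restricted to internal metabolites. At steady state every
#' internal metabolite must be produced and consumed at equal rates, so all
#' residuals are zero.
#'
#' @param model a [metabolic_model()].
#' @param state a [flux_state()] over the model.
#' @param tolerance report threshold; residuals with absolute value above it
#'   are flagged in the `violations` attribute.
#' @return named numeric vector of residuals (one per internal metabolite)
#'   with attribute `violations` (character vector of flagged metabolites).
#' @export
steady_state_residual <- function(model, state, tolerance = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"), inherits(state, "flux_state"))
  S <- stoichiometric_matrix(model)
  internal <- internal_metabolites(model)
  r <- drop(S[internal, , drop = FALSE] %*% state$v[colnames(S)])
  names(r) <- internal
  attr(r, "violations") <- internal[abs(r) > tolerance]
  r
}
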