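#' @title Reaction-centric graphs and edge weighting
#' @name reaction_graph
#' @description
#' The network is modeled as a directed graph whose nodes are reactions and
#' whose edges are metabolite-mediated producer-to-consumer interactions: an
#' edge runs from reaction `R_i` to reaction `R_j` whenever a product of
#' `R_i` is a reactant of `R_j`. Three edge-distance schemes are supported:
#'
#' * `"unit"` — every edge has distance 1 (pure topology);
#' * `"flux"` — the distance is the inverse of the fraction of the
#'   intermediary metabolite's total production flux drawn by the consuming
#'   reaction (a consumer taking 60 of 100 units sits at distance
#'   100/60 = 1.67). The metabolite pool is treated as homogeneous, so the
#'   distance is identical for every producer of the metabolite;
#' * `"degree"` — the distance is the number of distinct reactions consuming
#'   the intermediary metabolite (a static connectivity-based weight).
#'
#' Cofactors (ATP, NAD(H), NADP(H), CoA, ...) are deliberately retained as
#' edge-mediating metabolites: they are essential carriers of metabolic
#' cycles, which is exactly what ShReD-based analysis measures.
NULL

#' Canonicalize reaction directions against a flux state
#'
#' Reversible reactions carrying negative flux have their stoichiometry
#' negated and the flux sign flipped, so that all fluxes are nonnegative and
#' edges can be read off the signed stoichiometry directly. Idempotent.
#'
#' @param model a [metabolic_model()].
#' @param state a [flux_state()] over the model.
#' @return list with components `model` and `state`.
#' @export
canonicalize_directions <- function(model, state) {
  stopifnot(inherits(model, "metabolic_model"), inherits(state, "flux_state"))
  v <- state$v
  flip <- names(v)[v < 0 & model$reactions$reversible]
  for (rid in flip) {
    model$stoich[[rid]] <- -model$stoich[[rid]]
    v[rid] <- -v[rid]
  }
  v[abs(v) <= state$zero_tol] <- 0
  v[v < 0] <- 0  # irreversible negatives within zero_tol
  list(model = model,
       state = flux_state(v, model, label = state$label,
                          zero_tol = state$zero_tol))
}

#' Flux-based edge distance mediated by a metabolite
#'
#' The distance from any producer of `metabolite` to the consuming reaction
#' `dst` is (total production flux of the metabolite) divided by (the
#' consumption flux of the metabolite by `dst`), where both sides are
#' stoichiometry-scaled rates: a reaction of flux v producing the metabolite
#' with coefficient c contributes v*c, and `dst` consuming with coefficient
#' c draws v_dst*|c|. The value does not depend on which producer the edge
#' starts from (the pool is homogeneous).
#'
#' @param metabolite metabolite id.
#' @param dst consuming reaction id.
#' @param model a canonicalized [metabolic_model()].
#' @param state a canonicalized [flux_state()].
#' @return the dimensionless edge distance (>= 1 at steady state), or `NA`
#'   if `dst` draws no flux of the metabolite.
#' @export
flux_edge_distance <- function(metabolite, dst, model, state) {
  stopifnot(inherits(model, "metabolic_model"), inherits(state, "flux_state"))
  v <- state$v
  prod_total <- 0
  for (rid in model$reactions$id) {
    c_m <- model$stoich[[rid]][metabolite]
    if (!is.na(c_m) && c_m > 0 && v[rid] > state$zero_tol) {
      prod_total <- prod_total + v[rid] * c_m
    }
  }
  c_dst <- model$stoich[[dst]][metabolite]
  if (is.na(c_dst) || c_dst >= 0) {
    stop("reaction '", dst, "' does not consume metabolite '", metabolite, "'")
  }
  cons <- v[dst] * abs(c_dst)
  if (cons <= state$zero_tol) return(NA_real_)
  if (prod_total <= state$zero_tol) {
    stop("flux inconsistency: metabolite '", metabolite,
         "' is consumed (by '", dst, "') but has zero total production")
  }
  unname(prod_total / cons)
}

#' Metabolite-degree edge distance
#'
#' The static weight for every edge mediated by a metabolite: the number of
#' distinct reactions in the model that consume it.
#'
#' @param metabolite metabolite id.
#' @param model a [metabolic_model()].
#' @return positive integer count of consumers.
#' @export
degree_edge_distance <- function(metabolite, model) {
  stopifnot(inherits(model, "metabolic_model"))
  sum(vapply(model$stoich, function(s) {
    c_m <- s[metabolite]
    !is.na(c_m) && c_m < 0
  }, logical(1)))
}

#' Build the directed reaction graph under a weighting scheme
#'
#' For each internal metabolite produced by `R_i` and consumed by `R_j`
#' (`i != j`) an edge `R_i -> R_j` is added with the scheme's distance.
#' Under flux weighting, reactions with flux at or below `zero_tol` neither
#' contribute nor draw edges (their nodes remain); the supplied state must
#' be canonicalized first (see [canonicalize_directions()]).
#'
#' @param model a [metabolic_model()].
#' @param weighting `"unit"`, `"flux"` or `"degree"`.
#' @param state a [flux_state()]; required for `"flux"`.
#' @return an object of class `reaction_graph` with components `nodes`,
#'   `edges` (data frame src, dst, metabolite, distance), `weighting`,
#'   `state_label`.
#' @export
build_graph <- function(model, weighting = c("unit", "flux", "degree"),
                        state = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "metabolic_model"))
  if (weighting == "flux") {
    if (is.null(state)) stop("flux weighting requires a flux state")
    stopifnot(inherits(state, "flux_state"))
    if (any(state$v < 0)) stop("flux state must be canonicalized (all v >= 0)")
  }
  internal <- internal_metabolites(model)
  v <- if (!is.null(state)) state$v
  ztol <- if (!is.null(state)) state$zero_tol else 0
  src <- dst <- met <- character(0)
  dist <- numeric(0)
  for (m in internal) {
    producers <- consumers <- character(0)
    pflux <- 0
    for (rid in model$reactions$id) {
      c_m <- model$stoich[[rid]][m]
      if (is.na(c_m)) next
      if (weighting == "flux" && v[rid] <= ztol) next
      if (c_m > 0) {
        producers <- c(producers, rid)
        if (weighting == "flux") pflux <- pflux + v[rid] * c_m
      } else {
        consumers <- c(consumers, rid)
      }
    }
    if (length(producers) == 0L || length(consumers) == 0L) next
    d_per_consumer <- switch(weighting,
      unit = stats::setNames(rep(1, length(consumers)), consumers),
      degree = stats::setNames(rep(degree_edge_distance(m, model),
                                   length(consumers)), consumers),
      flux = {
        dd <- vapply(consumers, function(j) {
          cons <- v[j] * abs(model$stoich[[j]][m])
          if (cons <= ztol) NA_real_ else pflux / cons
        }, numeric(1))
        dd
      })
    for (i in producers) {
      for (j in consumers) {
        if (i == j) next
        d <- d_per_consumer[[j]]
        if (is.na(d)) next
        src <- c(src, i); dst <- c(dst, j); met <- c(met, m)
        dist <- c(dist, d)
      }
    }
  }
  structure(
    list(nodes = model$reactions$id,
         edges = data.frame(src = src, dst = dst, metabolite = met,
                            distance = dist, stringsAsFactors = FALSE),
         weighting = weighting,
         state_label = if (!is.null(state)) state$label else NA_character_),
    class = "reaction_graph"
  )
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat("<reaction_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$weighting, " weighting",
      if (!is.na(x$state_label)) paste0(", state '", x$state_label, "'"),
      ")\n", sep = "")
  invisible(x)
}

#' Collapse parallel edges between the same reaction pair
#'
#' When several metabolites mediate the same `R_i -> R_j` interaction, the
#' retained distance is the minimum (the strongest interaction; under
#' shortest-path semantics the longer parallel edges are never used). Ties
#' are broken by lexicographic metabolite id, so the provenance column is
#' deterministic.
#'
#' @param graph a `reaction_graph`.
#' @return a `reaction_graph` with at most one edge per ordered pair.
#' @export
collapse_parallel_edges <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  e <- graph$edges
  if (nrow(e) > 1L) {
    o <- order(e$src, e$dst, e$distance, e$metabolite)
    e <- e[o, , drop = FALSE]
    keep <- !duplicated(e[, c("src", "dst")])
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
  }
  graph$edges <- e
  graph
}

#' Convert a reaction graph to an igraph object
#'
#' Parallel edges are collapsed first; edge distances become the `weight`
#' attribute.
#'
#' @param graph a `reaction_graph`.
#' @return an [igraph::graph] (directed, weighted).
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "reaction_graph"))
  graph <- collapse_parallel_edges(graph)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("src", "dst")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes)
  )
  igraph::E(g)$weight <- graph$edges$distance
  igraph::E(g)$metabolite <- graph$edges$metabolite
  g
}

#' Export a reaction graph as an edge-list TSV
#'
#' @param graph a `reaction_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "reaction_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a reaction graph in DOT format
#'
#' @param graph a `reaction_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dot <- function(graph, path) {
  stopifnot(inherits(graph, "reaction_graph"))
  lines <- c("digraph reactions {",
             paste0("  \"", graph$nodes, "\";"),
             vapply(seq_len(nrow(graph$edges)), function(k) {
               e <- graph$edges[k, ]
               sprintf("  \"%s\" -> \"%s\" [label=\"%s (%.3g)\"];",
                       e$src, e$dst, e$metabolite, e$distance)
             }, character(1)),
             "}")
  writeLines(lines, path)
  invisible(path)
}
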