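# Shared helpers: handmade graphs, brute-force oracles, tiny models.

# A reaction_graph built directly from an edge table (distances arbitrary).
make_graph <- function(nodes, src, dst, distance,
                       metabolite = paste0("m", seq_along(src)),
                       weighting = "unit") {
  structure(list(nodes = nodes,
                 edges = data.frame(src = src, dst = dst,
                                    metabolite = metabolite,
                                    distance = distance,
                                    stringsAsFactors = FALSE),
                 weighting = weighting, state_label = NA_character_),
            class = "reaction_graph")
}

# Random directed graph on <= 8 nodes with positive random distances.
random_graph <- function(n, p_edge = 0.35) {
  nodes <- paste0("n", seq_len(n))
  src <- dst <- character(0)
  d <- numeric(0)
  for (i in nodes) for (j in nodes) {
    if (i != j && stats::runif(1) < p_edge) {
      src <- c(src, i); dst <- c(dst, j)
      d <- c(d, stats::runif(1, 0.5, 3))
    }
  }
  make_graph(nodes, src, dst, d)
}

# Brute-force shortest path by exhaustive DFS over simple paths,
# independent of the package's (igraph) path machinery.
brute_shortest <- function(graph, from, to) {
  if (from == to) return(0)
  e <- graph$edges
  best <- Inf
  recurse <- function(at, visited, len) {
    if (len >= best) return(invisible(NULL))
    out <- which(e$src == at)
    for (k in out) {
      nxt <- e$dst[k]
      if (nxt == to) {
        best <<- min(best, len + e$distance[k])
      } else if (!(nxt %in% visited)) {
        recurse(nxt, c(visited, nxt), len + e$distance[k])
      }
    }
    invisible(NULL)
  }
  recurse(from, from, 0)
  best
}

# Brute-force ShReD: shortest closed route through both nodes, as the sum
# of the two exhaustively-enumerated one-way legs.
brute_shred <- function(graph, i, j) {
  brute_shortest(graph, i, j) + brute_shortest(graph, j, i)
}

# Random symmetric modularity matrix (some pairs possibly undefined).
random_V <- function(n, p_na = 0) {
  nodes <- paste0("n", seq_len(n))
  M <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    if (stats::runif(1) >= p_na) M[a, b] <- M[b, a] <- stats::rnorm(1)
  }
  structure(list(entries = M, floor_p = 0.01, nodes = nodes,
                 ties = numeric(0)),
            class = "modularity_matrix")
}

# Exhaustive Q maximum by direct enumeration (oracle for the optimizers).
brute_best_q <- function(V) {
  n <- length(V$nodes)
  M <- V$entries
  M[is.na(M)] <- 0
  diag(M) <- 0
  best <- -Inf
  for (k in 0:(2^n - 1)) {
    s <- ifelse(bitwAnd(k, bitwShiftL(1L, seq_len(n) - 1L)) > 0, 1, -1)
    best <- max(best, drop(s %*% M %*% s))
  }
  best
}

# Tiny three-reaction chain model used across IO tests.
chain_model <- function() {
  metabolic_model(list(
    list(id = "Rin", group = "exchange", stoich = c(A = 1), reversible = FALSE),
    list(id = "R2", group = "core", stoich = c(A = -1, B = 1), reversible = FALSE),
    list(id = "Rout", group = "exchange", stoich = c(B = -1), reversible = FALSE)
  ))
}

# Random small model (chains + optional reversibility) for IO round trips.
random_model <- function(n_rxn = 5) {
  mets <- paste0("X", seq_len(n_rxn + 1))
  rxns <- lapply(seq_len(n_rxn), function(k) {
    list(id = paste0("R", k), group = sample(c("g1", "g2"), 1),
         stoich = stats::setNames(c(-sample(1:3, 1), sample(1:3, 1)),
                                  c(mets[k], mets[k + 1])),
         reversible = stats::runif(1) < 0.3)
  })
  rxns[[n_rxn + 1]] <- list(id = "Rin", group = "exchange",
                            stoich = c(stats::setNames(1, mets[1])),
                            reversible = FALSE)
  rxns[[n_rxn + 2]] <- list(id = "Rout", group = "exchange",
                            stoich = stats::setNames(-1, mets[n_rxn + 1]),
                            reversible = FALSE)
  metabolic_model(rxns)
}
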