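#' @title Shortest Retroactive Distances
#' @name shred_engine
#' @description
#' The Shortest Retroactive Distance (ShReD) of a reaction pair `(i, j)` is
#' the length of the shortest directed path from `i` to `j` plus the length
#' of the shortest return path from `j` to `i` — the shortest cyclical
#' interaction passing through both reactions. Pairs with no cycle through
#' them are unreachable. Because an edge distance is inversely proportional
#' to a flux share, near-zero fluxes produce arbitrarily long distances;
#' flux-weighted ShReDs are therefore capped (default 100) so that pairs
#' whose fluxes are indistinguishable from zero are not spuriously spread
#' out. The two legs of a ShReD are independent shortest paths and may share
#' edges.
NULL

#' Exact shortest-path distance between two reactions
#'
#' Dijkstra on the collapsed graph (nonnegative distances, exact).
#'
#' @param graph a `reaction_graph`.
#' @param src,dst reaction ids.
#' @return numeric distance; `Inf` when `dst` is unreachable from `src`;
#'   0 when `src == dst`.
#' @export
shortest_path_distance <- function(graph, src, dst) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (!src %in% graph$nodes) stop("unknown node: ", src)
  if (!dst %in% graph$nodes) stop("unknown node: ", dst)
  g <- as_igraph(graph)
  drop(igraph::distances(g, v = src, to = dst, mode = "out",
                         algorithm = "dijkstra"))
}

#' ShReD of one reaction pair
#'
#' @param graph a `reaction_graph`.
#' @param i,j distinct reaction ids.
#' @param cap positive upper bound applied to the raw two-leg sum.
#' @return list with `value` (numeric or `NA` if unreachable) and `status`
#'   (`"finite"`, `"capped"`, or `"unreachable"`).
#' @export
shred <- function(graph, i, j, cap = 100) {
  if (identical(i, j)) stop("ShReD is defined for distinct reactions only")
  raw <- shortest_path_distance(graph, i, j) +
         shortest_path_distance(graph, j, i)
  if (is.infinite(raw)) return(list(value = NA_real_, status = "unreachable"))
  if (raw > cap) return(list(value = cap, status = "capped"))
  list(value = raw, status = "finite")
}

#' All-pairs ShReD matrix
#'
#' Computes the full symmetric matrix of ShReDs over every unordered pair of
#' nodes, with the cap applied.
#'
#' @param graph a `reaction_graph`.
#' @param cap positive upper bound (default 100).
#' @return an object of class `shred_matrix` with components `values`
#'   (symmetric numeric matrix, `NA` on the diagonal and for unreachable
#'   pairs, capped entries equal to `cap`), `status` (character matrix) and
#'   `cap`.
#' @export
all_pairs_shred <- function(graph, cap = 100) {
  stopifnot(inherits(graph, "reaction_graph"), cap > 0)
  g <- as_igraph(graph)
  D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  D <- D[graph$nodes, graph$nodes, drop = FALSE]
  raw <- D + t(D)
  status <- matrix("finite", nrow(raw), ncol(raw), dimnames = dimnames(raw))
  status[is.infinite(raw)] <- "unreachable"
  status[is.finite(raw) & raw > cap] <- "capped"
  values <- raw
  values[is.infinite(raw)] <- NA_real_
  values[status == "capped"] <- cap
  diag(values) <- NA_real_
  diag(status) <- "undefined"
  structure(list(values = values, status = status, cap = cap,
                 nodes = graph$nodes),
            class = "shred_matrix")
}

#' @export
print.shred_matrix <- function(x, ...) {
  up <- upper.tri(x$values)
  cat("<shred_matrix> ", length(x$nodes), " nodes, ",
      sum(x$status[up] == "finite"), " finite / ",
      sum(x$status[up] == "capped"), " capped / ",
      sum(x$status[up] == "unreachable"), " unreachable pairs (cap ",
      x$cap, ")\n", sep = "")
  invisible(x)
}

#' Summary statistics of a ShReD distribution
#'
#' Skewness is the third standardized moment over all non-infinite pair
#' values, with capped entries included at the cap value; a second variant
#' restricted to values strictly below the cap is also reported, since
#' histograms of ShReD distributions conventionally truncate at the cap.
#'
#' @param matrix a `shred_matrix`.
#' @param breaks passed to [graphics::hist()] bin computation (values below
#'   the cap only); default `"Sturges"`.
#' @return list with `skewness` (capped included), `skewness_below_cap`,
#'   `mean_finite` (capped included at cap), `mean_noncapped`,
#'   `fraction_capped`, `n_pairs_defined`, and `histogram` (counts and
#'   breaks over values below the cap).
#' @export
shred_summary <- function(matrix, breaks = "Sturges") {
  stopifnot(inherits(matrix, "shred_matrix"))
  up <- upper.tri(matrix$values)
  vals <- matrix$values[up]
  st <- matrix$status[up]
  defined <- vals[!is.na(vals)]
  if (length(defined) < 3L) stop("need at least 3 defined ShReD values")
  below <- vals[st == "finite" & !is.na(vals)]
  h <- graphics::hist(below, breaks = breaks, plot = FALSE)
  list(
    skewness = e1071::skewness(defined, type = 1),
    skewness_below_cap = if (length(below) >= 3L)
      e1071::skewness(below, type = 1) else NA_real_,
    mean_finite = mean(defined),
    mean_noncapped = mean(below),
    fraction_capped = mean(st[st != "undefined"] == "capped"),
    n_pairs_defined = length(defined),
    histogram = list(breaks = h$breaks, counts = h$counts)
  )
}

#' Write a ShReD matrix to CSV
#'
#' Unreachable entries are written as `inf`; a sidecar `<path>.status.csv`
#' carries the status matrix.
#'
#' @param matrix a `shred_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shred_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "shred_matrix"))
  out <- matrix$values
  chr <- matrix(format(out, trim = TRUE), nrow(out), dimnames = dimnames(out))
  chr[matrix$status == "unreachable"] <- "inf"
  chr[is.na(out) & matrix$status != "unreachable"] <- ""
  utils::write.csv(chr, path, quote = FALSE)
  utils::write.csv(matrix$status, paste0(path, ".status.csv"), quote = FALSE)
  invisible(path)
}

#' Read a ShReD matrix written by [write_shred_matrix()]
#'
#' @param path CSV path.
#' @param cap the cap used when the matrix was computed.
#' @return a `shred_matrix`.
#' @export
read_shred_matrix <- function(path, cap = 100) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                         colClasses = "character")
  m <- as.matrix(raw)
  values <- suppressWarnings(apply(m, c(1, 2), as.numeric))
  values[m == "inf"] <- NA_real_
  status <- matrix("finite", nrow(m), ncol(m), dimnames = dimnames(values))
  status[m == "inf"] <- "unreachable"
  status[is.finite(values) & values >= cap] <- "capped"
  diag(status) <- "undefined"
  diag(values) <- NA_real_
  structure(list(values = values, status = status, cap = cap,
                 nodes = rownames(values)),
            class = "shred_matrix")
}
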