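#' @title Cycle-preserving hierarchical partitioning
#' @name partitioner
#' @description
#' The network is partitioned recursively. Each step first splits the
#' current node set into weakly connected components (recorded as red,
#' "component" links in the module tree). Each connected subnetwork of two
#' or more reactions is then bipartitioned by maximizing the modularity
#' score Q of a matrix recomputed on the induced subgraph (ShReD paths may
#' not leave the subnetwork being partitioned). The bipartition is accepted
#' — a black, "partition" link — only if the best Q is strictly positive
#' and at least one daughter subnetwork still contains a directed cycle;
#' requiring only one daughter to keep a cycle lets single reactions peel
#' off a larger subnetwork without blocking its further partitioning.
#' Depth and height of a module count black links only.
NULL

induced_reaction_graph <- function(graph, nodes) {
  e <- graph$edges
  keep <- e$src %in% nodes & e$dst %in% nodes
  structure(list(nodes = intersect(graph$nodes, nodes),
                 edges = e[keep, , drop = FALSE],
                 weighting = graph$weighting,
                 state_label = graph$state_label),
            class = "reaction_graph")
}

#' Weakly connected components of a (sub)graph
#'
#' Edge direction is ignored for connectivity; singleton components are
#' allowed. Components are returned in order of their first member's
#' position in the node list, so the result is deterministic.
#'
#' @param graph a `reaction_graph`.
#' @param nodes optional node subset; default all nodes.
#' @return list of character vectors.
#' @export
connected_components <- function(graph, nodes = NULL) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (is.null(nodes)) nodes <- graph$nodes
  sub <- induced_reaction_graph(graph, nodes)
  g <- as_igraph(sub)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership[sub$nodes]
  split_list <- split(sub$nodes, membership)
  first_pos <- vapply(split_list, function(m) {
    min(match(m, sub$nodes))
  }, numeric(1))
  unname(split_list[order(first_pos)])
}

#' Does an induced subgraph contain a directed cycle?
#'
#' True iff the induced directed subgraph has a strongly connected
#' component of two or more nodes (self-loops are excluded at graph
#' construction).
#'
#' @param graph a `reaction_graph`.
#' @param nodes optional node subset; default all nodes.
#' @return logical.
#' @export
contains_cycle <- function(graph, nodes = NULL) {
  stopifnot(inherits(graph, "reaction_graph"))
  if (is.null(nodes)) nodes <- graph$nodes
  if (length(nodes) < 2L) return(FALSE)
  sub <- induced_reaction_graph(graph, nodes)
  if (nrow(sub$edges) == 0L) return(FALSE)
  g <- as_igraph(sub)
  any(igraph::components(g, mode = "strong")$csize >= 2L)
}

#' Recursive cycle-preserving hierarchical partition
#'
#' @param graph a `reaction_graph` built under one weighting scheme (and,
#'   for flux weighting, one canonicalized state).
#' @param params a [ga_params()]; its `seed` makes the whole tree
#'   reproducible (each GA call derives its own stream from the seed and
#'   the module id). Subnetworks of 8 or fewer nodes are solved
#'   exhaustively instead.
#' @param cap ShReD cap passed to [all_pairs_shred()].
#' @param floor_p clamp probability for the modularity matrix.
#' @param recompute_shred if `TRUE` (default) ShReDs are recomputed on each
#'   induced subnetwork; if `FALSE` the root-level ShReD matrix is reused
#'   by subsetting (for sensitivity comparison only).
#' @return an object of class `partition_tree` with components `root`
#'   (nested module nodes: `id`, `members`, `link_type`, `q`, `children`,
#'   `depth`, `height`), `modules` (flat list of the same nodes),
#'   `terminal_depth` (named integer, the black-link depth m_i of each
#'   reaction's terminal module), `state_label`, `weighting`.
#' @export
hierarchical_partition <- function(graph, params = ga_params(), cap = 100,
                                   floor_p = 0.01, recompute_shred = TRUE) {
  stopifnot(inherits(graph, "reaction_graph"), inherits(params, "ga_params"))
  counter <- 0L
  root_shred <- if (!recompute_shred) all_pairs_shred(graph, cap = cap)

  recurse <- function(members, link_type, depth) {
    counter <<- counter + 1L
    node <- list(id = counter, members = members, link_type = link_type,
                 q = NA_real_, depth = depth, children = list())
    if (length(members) < 2L) return(node)
    comps <- connected_components(graph, members)
    if (length(comps) > 1L) {
      node$children <- lapply(comps, recurse, link_type = "component",
                              depth = depth)
      return(node)
    }
    sm <- if (recompute_shred) {
      all_pairs_shred(induced_reaction_graph(graph, members), cap = cap)
    } else {
      structure(list(values = root_shred$values[members, members, drop = FALSE],
                     status = root_shred$status[members, members, drop = FALSE],
                     cap = cap, nodes = members),
                class = "shred_matrix")
    }
    V <- build_modularity_matrix(sm, floor_p = floor_p)
    opt <- if (length(members) <= 8L) {
      exhaustive_bipartition(V)
    } else {
      sub_seed <- if (is.null(params$seed)) NULL
                  else (params$seed + 9973L * counter) %% .Machine$integer.max
      sub_params <- params
      sub_params$seed <- sub_seed
      ga_bipartition(V, sub_params)
    }
    node$q <- opt$q
    if (!is.finite(opt$q) || opt$q <= 0) return(node)
    a <- names(opt$s)[opt$s > 0]
    b <- names(opt$s)[opt$s < 0]
    if (length(a) == 0L || length(b) == 0L) return(node)
    if (!(contains_cycle(graph, a) || contains_cycle(graph, b))) return(node)
    node$children <- list(recurse(a, "partition", depth + 1L),
                          recurse(b, "partition", depth + 1L))
    node
  }

  root <- recurse(graph$nodes, "root", 0L)

  set_height <- function(node) {
    if (length(node$children) == 0L) {
      node$height <- 0L
      return(node)
    }
    node$children <- lapply(node$children, set_height)
    node$height <- max(vapply(node$children, function(ch) {
      ch$height + as.integer(ch$link_type == "partition")
    }, integer(1)))
    node
  }
  root <- set_height(root)

  modules <- list()
  terminal_depth <- stats::setNames(integer(length(graph$nodes)), graph$nodes)
  walk <- function(node) {
    modules[[length(modules) + 1L]] <<- node[c("id", "members", "link_type",
                                               "q", "depth", "height")]
    if (length(node$children) == 0L) {
      terminal_depth[node$members] <<- node$depth
    } else {
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  walk(root)

  structure(list(root = root, modules = modules,
                 terminal_depth = terminal_depth,
                 state_label = graph$state_label,
                 weighting = graph$weighting),
            class = "partition_tree")
}

#' @export
print.partition_tree <- function(x, ...) {
  n_black <- sum(vapply(x$modules, function(m) m$link_type == "partition",
                        logical(1)))
  cat("<partition_tree> ", length(x$root$members), " reactions, ",
      length(x$modules), " modules (", n_black, " partition links), max depth ",
      max(x$terminal_depth), " [", x$weighting, " weighting",
      if (!is.na(x$state_label)) paste0(", state '", x$state_label, "'"),
      "]\n", sep = "")
  invisible(x)
}

#' Leaf (terminal) module membership
#'
#' @param tree a `partition_tree`.
#' @return named character vector: reaction id -> id of its terminal module.
#' @export
leaf_assignment <- function(tree) {
  stopifnot(inherits(tree, "partition_tree"))
  out <- character(0)
  walk <- function(node) {
    if (length(node$children) == 0L) {
      out[node$members] <<- as.character(node$id)
    } else {
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  walk(tree$root)
  out
}

tree_to_list <- function(node, groups = NULL) {
  out <- list(id = node$id,
              members = as.list(node$members),
              link_type = node$link_type,
              depth = node$depth,
              height = node$height,
              q = if (is.na(node$q)) NULL else node$q)
  if (!is.null(groups)) {
    out$homogeneity <- homogeneity_index(node, groups)
  }
  out$children <- lapply(node$children, tree_to_list, groups = groups)
  out
}

#' Write a partition tree as nested JSON
#'
#' @param tree a `partition_tree`.
#' @param path output path.
#' @param groups optional named character vector (reaction id -> canonical
#'   group); when given, each module is annotated with its homogeneity
#'   index.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path, groups = NULL) {
  stopifnot(inherits(tree, "partition_tree"))
  obj <- list(state_label = tree$state_label,
              weighting = tree$weighting,
              root = tree_to_list(tree$root, groups = groups))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Render the module hierarchy in DOT format
#'
#' Partition links are drawn black, component links red, matching the
#' conventional tree display.
#'
#' @param tree a `partition_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_dot <- function(tree, path) {
  stopifnot(inherits(tree, "partition_tree"))
  lines <- c("digraph modules {", "  node [shape=box];")
  walk <- function(node) {
    label <- if (length(node$members) <= 4L) {
      paste(node$members, collapse = ",")
    } else {
      paste0(length(node$members), " reactions")
    }
    lines <<- c(lines, sprintf("  m%d [label=\"#%d: %s\"];",
                               node$id, node$id, label))
    for (ch in node$children) {
      col <- if (ch$link_type == "partition") "black" else "red"
      lines <<- c(lines, sprintf("  m%d -> m%d [color=%s];",
                                 node$id, ch$id, col))
      walk(ch)
    }
  }
  walk(tree$root)
  writeLines(c(lines, "}"), path)
  invisible(path)
}
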