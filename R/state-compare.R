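#' @title Comparing partitions within and across metabolic states
#' @name state_compare
#' @description
#' Partition trees are scored against canonical pathway annotations (module
#' homogeneity) and against each other. The pair partition score
#' `H_ij = (Shared - 1) * (1/m_i + 1/m_j) / 2` measures how long two
#' reactions remain co-assigned through recursive partitions (`Shared` is
#' the number of hierarchy levels — the root and black partition modules —
#' containing both reactions; `m` is each reaction's terminal black-link
#' depth). Together with the pair's root-network modularity entry `V_ij`,
#' each pair gets an (H, V) coordinate per metabolic state; pairs with
#' `H > 0.7` and `V > 3.0` in every examined state are flagged as robust
#' (candidate co-regulation), and mean-normalized Euclidean distances in
#' H-V space quantify how strongly a state change reorganizes the
#' hierarchy.
NULL

#' Homogeneity index of a module
#'
#' The fraction of a module's reactions belonging to its most common
#' canonical pathway group (the largest slice of the module's pie chart).
#'
#' @param module a module node (list with a `members` field) or a character
#'   vector of reaction ids.
#' @param groups named character vector: reaction id -> group label.
#' @return fraction in (0, 1]; 1 iff the module is pure.
#' @export
homogeneity_index <- function(module, groups) {
  members <- if (is.list(module)) module$members else module
  if (length(members) == 0L) stop("module is empty")
  g <- groups[members]
  g[is.na(g)] <- "unassigned"
  max(table(g)) / length(members)
}

#' Mean module homogeneity as a function of partition height
#'
#' Height zero corresponds to terminal modules; the mean at each height is
#' unweighted over the modules at that height.
#'
#' @param tree a `partition_tree`.
#' @param groups named character vector: reaction id -> group label.
#' @return named numeric vector, height -> mean homogeneity.
#' @export
mean_homogeneity_by_height <- function(tree, groups) {
  stopifnot(inherits(tree, "partition_tree"))
  h <- vapply(tree$modules, function(m) m$height, integer(1))
  hom <- vapply(tree$modules, homogeneity_index, numeric(1), groups = groups)
  out <- tapply(hom, h, mean)
  stats::setNames(as.numeric(out), names(out))
}

#' Pair partition score H
#'
#' `H = (Shared - 1) * (1/m_i + 1/m_j) / 2`, where `Shared` counts the
#' hierarchy levels (root plus black partition-link modules) containing
#' both reactions and `m` is the terminal black-link depth of each
#' reaction. Zero means the pair separates at the first partition; one
#' means the pair stays together down to equal terminal depth. Reactions
#' that never undergo a black partition (`m = 0`) get `H = 0` by
#' convention.
#'
#' @param tree a `partition_tree`.
#' @param i,j reaction ids present in the tree.
#' @return H in `[0, 1]`.
#' @export
partition_score <- function(tree, i, j) {
  stopifnot(inherits(tree, "partition_tree"))
  ids <- names(tree$terminal_depth)
  if (!i %in% ids) stop("unknown reaction: ", i)
  if (!j %in% ids) stop("unknown reaction: ", j)
  m_i <- tree$terminal_depth[[i]]
  m_j <- tree$terminal_depth[[j]]
  if (m_i == 0L || m_j == 0L) return(0)
  shared <- sum(vapply(tree$modules, function(m) {
    m$link_type %in% c("root", "partition") &&
      i %in% m$members && j %in% m$members
  }, logical(1)))
  (shared - 1) * 0.5 * (1 / m_i + 1 / m_j)
}

#' H-V scores for every defined pair
#'
#' Couples each pair's partition score H (from the tree) with its
#' modularity entry V in the initial un-partitioned network. Pairs whose
#' root-level ShReD is unreachable have no V coordinate and are omitted
#' (listed in the `omitted` attribute).
#'
#' @param tree a `partition_tree`.
#' @param rootV a `modularity_matrix` built on the full root network.
#' @return data frame with columns `i`, `j`, `H`, `V`, `state_label`;
#'   attribute `omitted` holds the undefined pairs.
#' @export
pair_scores <- function(tree, rootV) {
  stopifnot(inherits(tree, "partition_tree"),
            inherits(rootV, "modularity_matrix"))
  nodes <- rootV$nodes
  stopifnot(all(nodes %in% names(tree$terminal_depth)))
  pairs <- which(upper.tri(rootV$entries), arr.ind = TRUE)
  i <- nodes[pairs[, 1]]
  j <- nodes[pairs[, 2]]
  V <- rootV$entries[pairs]
  keep <- !is.na(V)
  H <- mapply(partition_score, i = i[keep], j = j[keep],
              MoreArgs = list(tree = tree))
  out <- data.frame(i = i[keep], j = j[keep], H = as.numeric(H),
                    V = V[keep],
                    state_label = tree$state_label,
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- data.frame(i = i[!keep], j = j[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Correlation of partition score with root modularity
#'
#' Ordinary least-squares R^2 (with the standard F-test p-value) of H on V,
#' optionally restricted to pairs with positive modularity, as used to
#' judge whether the root-network modularity entry predicts co-assignment.
#'
#' @param scores a data frame from [pair_scores()].
#' @param positive_v_only restrict to pairs with `V > 0` (default TRUE).
#' @return list with `r_squared`, `p_value`, `n`.
#' @export
pair_score_correlation <- function(scores, positive_v_only = TRUE) {
  d <- if (positive_v_only) scores[scores$V > 0, ] else scores
  if (nrow(d) < 3L) stop("need at least 3 pairs for a correlation")
  fit <- stats::lm(H ~ V, data = d)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(r_squared = unname(sm$r.squared),
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       n = nrow(d))
}

pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

#' Robust reaction pairs across metabolic states
#'
#' Counts, for each pair, the states in which both `H > h_min` and
#' `V > v_min` (strict inequalities). With `require_all = TRUE` a pair is
#' robust when it meets the criterion in every state.
#'
#' @param scores_by_state named list of [pair_scores()] data frames, one
#'   per metabolic state.
#' @param h_min partition-score threshold (default 0.7).
#' @param v_min modularity-score threshold (default 3.0).
#' @param require_all robust = criterion met in all states (default TRUE);
#'   otherwise robust = met in at least one state.
#' @return data frame with columns `i`, `j`, one logical column per state,
#'   `count`, and `robust`, restricted to pairs meeting the criterion in at
#'   least one state (the candidate set).
#' @export
robust_pairs <- function(scores_by_state, h_min = 0.7, v_min = 3.0,
                         require_all = TRUE) {
  stopifnot(is.list(scores_by_state), length(scores_by_state) >= 1L)
  if (is.null(names(scores_by_state))) {
    names(scores_by_state) <- paste0("state", seq_along(scores_by_state))
  }
  hits <- lapply(scores_by_state, function(sc) {
    pair_key(sc$i, sc$j)[sc$H > h_min & sc$V > v_min]
  })
  candidates <- sort(unique(unlist(hits, use.names = FALSE)))
  if (length(candidates) == 0L) {
    out <- data.frame(i = character(0), j = character(0))
    for (nm in names(scores_by_state)) out[[nm]] <- logical(0)
    out$count <- integer(0)
    out$robust <- logical(0)
    return(out)
  }
  parts <- strsplit(candidates, "\r", fixed = TRUE)
  out <- data.frame(i = vapply(parts, `[`, character(1), 1),
                    j = vapply(parts, `[`, character(1), 2),
                    stringsAsFactors = FALSE)
  for (nm in names(scores_by_state)) {
    out[[nm]] <- candidates %in% hits[[nm]]
  }
  out$count <- rowSums(as.matrix(out[names(scores_by_state)]))
  out$robust <- if (require_all) out$count == length(scores_by_state)
                else out$count >= 1L
  out[order(out$i, out$j), , drop = FALSE]
}

normalize_coord <- function(x, what, state) {
  m <- mean(x)
  if (abs(m) < 1e-12) {
    m_abs <- mean(abs(x))
    if (m_abs < 1e-12) {
      stop("mean ", what, " of state '", state,
           "' is zero; cannot normalize H-V coordinates")
    }
    warning("mean ", what, " of state '", state,
            "' is near zero; normalizing by mean absolute value")
    m <- m_abs
  }
  x / m
}

#' Euclidean distance of reaction pairs in normalized H-V space
#'
#' Each state's H coordinates are divided by that state's mean H and its V
#' coordinates by its mean V (means over defined pairs), then the per-pair
#' Euclidean distance between the two states is computed. A large distance
#' means the state change substantially relocated the pair in the module
#' hierarchy.
#'
#' @param scoresA,scoresB [pair_scores()] data frames for the two states.
#' @return data frame with columns `i`, `j`, `distance` for pairs defined
#'   in both states; attribute `missing` lists pairs defined in only one.
#' @export
hv_distance <- function(scoresA, scoresB) {
  a <- scoresA
  b <- scoresB
  a$Hn <- normalize_coord(a$H, "partition score H", a$state_label[1])
  a$Vn <- normalize_coord(a$V, "modularity score V", a$state_label[1])
  b$Hn <- normalize_coord(b$H, "partition score H", b$state_label[1])
  b$Vn <- normalize_coord(b$V, "modularity score V", b$state_label[1])
  a$key <- pair_key(a$i, a$j)
  b$key <- pair_key(b$i, b$j)
  common <- intersect(a$key, b$key)
  ai <- a[match(common, a$key), ]
  bi <- b[match(common, b$key), ]
  out <- data.frame(i = ai$i, j = ai$j,
                    distance = sqrt((ai$Hn - bi$Hn)^2 + (ai$Vn - bi$Vn)^2),
                    stringsAsFactors = FALSE)
  only <- c(setdiff(a$key, b$key), setdiff(b$key, a$key))
  parts <- strsplit(only, "\r", fixed = TRUE)
  attr(out, "missing") <- data.frame(
    i = vapply(parts, `[`, character(1), 1),
    j = vapply(parts, `[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  out
}
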