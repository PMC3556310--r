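#' @title Rank-based modularity matrix and modularity score
#' @name modularity
#' @description
#' Flux weighting skews ShReD distributions strongly to the right, so the
#' arithmetic mean is not a usable reference for "expected" distance.
#' Instead, each pair's ShReD is ranked against all ShReDs involving either
#' member of the pair, and the modularity matrix entry is the log odds of
#' that rank: `V_ij = ln(p_ij / (1 - p_ij))`, where `p_ij` is the
#' (mid-rank) fraction of comparable ShReDs involving `R_i` or `R_j` that
#' are longer than `ShReD_ij`. A positive entry marks tighter-than-expected cyclical
#' coupling. `p` is clamped to `[floor_p, 1 - floor_p]` (default floor
#' 0.01, giving a smallest entry of -4.60) so extreme ranks stay on the
#' same order of magnitude as the rest of the matrix.
NULL

#' Rank fraction p for a reaction pair
#'
#' The comparable set consists of every defined (finite or capped) ShReD
#' involving `i` or `j` except the `(i, j)` entry itself; capped entries
#' participate at the cap value (tying with each other). `p` is the
#' mid-rank fraction of the comparable set longer than `ShReD_ij`: strictly
#' longer values count 1, ties count 1/2, so a pair tied with its whole
#' comparison set sits at the neutral p = 0.5 rather than at an extreme
#' rank.
#'
#' @param matrix a `shred_matrix` (restricted to the subnetwork of interest).
#' @param i,j distinct reaction ids with a defined ShReD.
#' @return `p` in `[0, 1]`, with attributes `n_longer` and `n_comparable`.
#' @export
p_fraction <- function(matrix, i, j) {
  stopifnot(inherits(matrix, "shred_matrix"))
  vals <- matrix$values
  sij <- vals[i, j]
  if (is.na(sij)) stop("ShReD(", i, ", ", j, ") is unreachable; no rank defined")
  others <- c(vals[i, setdiff(colnames(vals), c(i, j))],
              vals[j, setdiff(colnames(vals), c(i, j))])
  others <- others[!is.na(others)]
  if (length(others) == 0L) {
    p <- 0.5  # no comparison set: neutral, clamped downstream anyway
  } else {
    p <- (sum(others > sij) + 0.5 * sum(others == sij)) / length(others)
  }
  structure(p, n_longer = if (length(others)) sum(others > sij) else NA_integer_,
            n_ties = if (length(others)) sum(others == sij) else NA_integer_,
            n_comparable = length(others))
}

#' Log-odds modularity entry
#'
#' @param p rank fraction in `[0, 1]`.
#' @param floor_p clamp probability (default 0.01); `p` is clamped to
#'   `[floor_p, 1 - floor_p]` before the log odds.
#' @return `ln(p / (1 - p))` after clamping.
#' @export
modularity_entry <- function(p, floor_p = 0.01) {
  stopifnot(floor_p > 0, floor_p < 0.5)
  p <- pmin(pmax(p, floor_p), 1 - floor_p)
  log(p / (1 - p))
}

#' Build the modularity matrix for a subnetwork
#'
#' @param matrix a `shred_matrix` computed on the subnetwork being
#'   partitioned (ShReDs must be recomputed per subnetwork, since paths may
#'   not leave it).
#' @param nodes optional node subset; default all nodes of `matrix`.
#' @param floor_p clamp probability (default 0.01).
#' @return an object of class `modularity_matrix`: components `entries`
#'   (symmetric matrix, `NA` where the pair's ShReD is unreachable),
#'   `floor_p`, `nodes`, and `ties` (values shared by several comparable
#'   pairs, for diagnostic purposes).
#' @export
build_modularity_matrix <- function(matrix, nodes = NULL, floor_p = 0.01) {
  stopifnot(inherits(matrix, "shred_matrix"))
  if (is.null(nodes)) nodes <- matrix$nodes
  stopifnot(all(nodes %in% matrix$nodes))
  vals <- matrix$values[nodes, nodes, drop = FALSE]
  n <- length(nodes)
  V <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  if (n >= 2L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq(a + 1L, n)) {
        sij <- vals[a, b]
        if (is.na(sij)) next
        others <- c(vals[a, -c(a, b)], vals[b, -c(a, b)])
        others <- others[!is.na(others)]
        p <- if (length(others) == 0L) 0.5
             else (sum(others > sij) + 0.5 * sum(others == sij)) / length(others)
        V[a, b] <- V[b, a] <- modularity_entry(p, floor_p)
      }
    }
  }
  up <- vals[upper.tri(vals)]
  up <- up[!is.na(up)]
  tie_vals <- sort(unique(up[duplicated(up)]))
  structure(list(entries = V, floor_p = floor_p, nodes = nodes,
                 ties = tie_vals),
            class = "modularity_matrix")
}

#' @export
print.modularity_matrix <- function(x, ...) {
  up <- x$entries[upper.tri(x$entries)]
  cat("<modularity_matrix> ", length(x$nodes), " nodes, ",
      sum(!is.na(up)), " defined pairs, floor_p ", x$floor_p, "\n", sep = "")
  invisible(x)
}

#' Modularity score Q of an assignment
#'
#' `Q = sum_{i != j} V_ij s_i s_j = s V s^T` with the diagonal excluded and
#' undefined (unreachable-pair) entries contributing zero. Invariant under
#' the global sign flip `s -> -s`.
#'
#' @param V a `modularity_matrix`.
#' @param s named vector of -1/+1 assignments covering `V`'s nodes (an
#'   unnamed vector in `V$nodes` order is accepted).
#' @return the scalar Q.
#' @export
q_score <- function(V, s) {
  stopifnot(inherits(V, "modularity_matrix"))
  if (is.null(names(s))) {
    if (length(s) != length(V$nodes)) stop("assignment length mismatch")
    names(s) <- V$nodes
  }
  if (!setequal(names(s), V$nodes)) {
    stop("assignment nodes do not match modularity matrix nodes")
  }
  if (!all(s %in% c(-1, 1))) stop("assignments must be -1 or +1")
  s <- s[V$nodes]
  M <- V$entries
  M[is.na(M)] <- 0
  diag(M) <- 0
  drop(s %*% M %*% s)
}

#' Write a modularity matrix to CSV
#'
#' Undefined pairs are written as blank cells.
#'
#' @param V a `modularity_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_modularity_matrix <- function(V, path) {
  stopifnot(inherits(V, "modularity_matrix"))
  chr <- matrix(format(V$entries, trim = TRUE), nrow(V$entries),
                dimnames = dimnames(V$entries))
  chr[is.na(V$entries)] <- ""
  utils::write.csv(chr, path, quote = FALSE)
  invisible(path)
}
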