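mk_tree <- function(modules, terminal_depth, label = "stateX") {
  structure(list(root = NULL, modules = modules,
                 terminal_depth = terminal_depth,
                 state_label = label, weighting = "flux"),
            class = "partition_tree")
}
mod <- function(id, members, link, depth, height = 0L) {
  list(id = id, members = members, link_type = link, q = NA_real_,
       depth = as.integer(depth), height = as.integer(height))
}

test_that("homogeneity index is the modal-group fraction", {
  groups <- c(r1 = "TCA cycle", r2 = "TCA cycle", r3 = "TCA cycle",
              r4 = "TCA cycle", r5 = "lipid", r6 = "lipid",
              r7 = "transport", r8 = "lipid")
  expect_equal(homogeneity_index(c("r1", "r2", "r3", "r4"), groups), 1.0)
  expect_equal(homogeneity_index(c("r1", "r2", "r3", "r5", "r7"), groups), 0.6)
  expect_equal(homogeneity_index(c("r1", "r2", "r5", "r6"), groups), 0.5)
  expect_error(homogeneity_index(character(0), groups), "empty")
})

test_that("mean homogeneity by height averages modules at each height", {
  groups <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  modules <- list(
    mod(1, c("a", "b", "c", "d"), "root", 0, height = 1),
    mod(2, c("a", "b", "c"), "partition", 1, height = 0),
    mod(3, "d", "partition", 1, height = 0)
  )
  tree <- mk_tree(modules, c(a = 1L, b = 1L, c = 1L, d = 1L))
  hbh <- mean_homogeneity_by_height(tree, groups)
  expect_equal(hbh[["0"]], mean(c(2 / 3, 1)))
  expect_equal(hbh[["1"]], 0.5)
  # singleton leaves are always pure
  tree2 <- mk_tree(list(mod(1, "a", "root", 0)), c(a = 0L))
  expect_equal(mean_homogeneity_by_height(tree2, groups)[["0"]], 1.0)
})

test_that("partition score H reproduces the hand-derived hierarchy cases", {
  # immediate separation at the first partition -> 0
  t0 <- mk_tree(list(mod(1, c("a", "b"), "root", 0, 1),
                     mod(2, "a", "partition", 1),
                     mod(3, "b", "partition", 1)),
                c(a = 1L, b = 1L))
  expect_equal(partition_score(t0, "a", "b"), 0)

  # together in every module down to a shared terminal leaf -> 1
  t1 <- mk_tree(list(mod(1, c("a", "b", "c"), "root", 0, 1),
                     mod(2, c("a", "b"), "partition", 1),
                     mod(3, "c", "partition", 1)),
                c(a = 1L, b = 1L, c = 1L))
  expect_equal(partition_score(t1, "a", "b"), 1)

  # Shared = 2 with terminal depths 2 and 2 -> 0.5
  t2 <- mk_tree(list(mod(1, c("a", "b", "x", "y"), "root", 0, 2),
                     mod(2, c("a", "b"), "partition", 1, 1),
                     mod(3, c("x", "y"), "partition", 1, 0),
                     mod(4, "a", "partition", 2),
                     mod(5, "b", "partition", 2)),
                c(a = 2L, b = 2L, x = 1L, y = 1L))
  expect_equal(partition_score(t2, "a", "b"), 0.5)

  # a reaction isolated before any black partition has m = 0 -> H = 0
  t3 <- mk_tree(list(mod(1, c("a", "b"), "root", 0),
                     mod(2, "a", "component", 0),
                     mod(3, "b", "component", 0)),
                c(a = 0L, b = 0L))
  expect_equal(partition_score(t3, "a", "b"), 0)
  expect_error(partition_score(t3, "a", "zzz"), "unknown reaction")
})

test_that("H stays within [0, 1] across random fixture partitions", {
  for (seed in 1:6) {
    fx <- make_random(fixture_spec(n_reactions = sample(9:13, 1),
                                   cycle_count = sample(2:3, 1),
                                   seed = seed + 20))
    g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
    tree <- hierarchical_partition(g, ga_params(seed = seed))
    sm <- all_pairs_shred(g)
    rootV <- build_modularity_matrix(sm)
    sc <- pair_scores(tree, rootV)
    expect_true(all(sc$H >= 0 - 1e-12))
    expect_true(all(sc$H <= 1 + 1e-12))
  }
})

test_that("pair scores couple tree H with root V and omit unreachable pairs", {
  fx <- make_random(fixture_spec(n_reactions = 10, cycle_count = 2, seed = 31))
  g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
  tree <- hierarchical_partition(g, ga_params(seed = 1))
  rootV <- build_modularity_matrix(all_pairs_shred(g))
  sc <- pair_scores(tree, rootV)
  n <- length(g$nodes)
  expect_lte(nrow(sc), n * (n - 1) / 2)
  expect_equal(nrow(sc) + nrow(attr(sc, "omitted")), n * (n - 1) / 2)
  k <- sample(nrow(sc), 1)
  expect_equal(sc$V[k], rootV$entries[sc$i[k], sc$j[k]])
  expect_equal(sc$H[k], partition_score(tree, sc$i[k], sc$j[k]))
  corr <- pair_score_correlation(sc, positive_v_only = FALSE)
  expect_gte(corr$r_squared, 0)
  expect_lte(corr$r_squared, 1)
})

test_that("robust pairs require strict thresholds in the demanded number of states", {
  sA <- data.frame(i = c("r1", "r1", "r2"), j = c("r2", "r3", "r3"),
                   H = c(0.9, 0.7, 0.8), V = c(4, 5, 3.5),
                   state_label = "A")
  sB <- data.frame(i = c("r1", "r1", "r2"), j = c("r2", "r3", "r3"),
                   H = c(0.95, 0.9, 0.2), V = c(3.2, 2.0, 9),
                   state_label = "B")
  rp <- robust_pairs(list(A = sA, B = sB))
  # (r1, r2): above both thresholds in both states -> robust
  r12 <- rp[rp$i == "r1" & rp$j == "r2", ]
  expect_equal(r12$count, 2)
  expect_true(r12$robust)
  # (r1, r3): H exactly 0.7 in A is NOT counted (strict), V too low in B
  expect_false("r3" %in% rp$j[rp$i == "r1"])
  # (r2, r3): one state only
  r23 <- rp[rp$i == "r2" & rp$j == "r3", ]
  expect_equal(r23$count, 1)
  expect_false(r23$robust)

  # thresholds at -Inf admit every defined pair in every state
  all_rp <- robust_pairs(list(A = sA, B = sB), h_min = -Inf, v_min = -Inf)
  expect_equal(nrow(all_rp), 3)
  expect_true(all(all_rp$count == 2))
  # raised to +Inf: empty report
  expect_equal(nrow(robust_pairs(list(A = sA, B = sB),
                                 h_min = Inf, v_min = Inf)), 0)
})

test_that("H-V distances are mean-normalized, symmetric, and zero on identity", {
  sA <- data.frame(i = c("r1", "r1", "r2"), j = c("r2", "r3", "r3"),
                   H = c(0.4, 0.6, 0.8), V = c(1, 2, 3),
                   state_label = "A")
  expect_equal(hv_distance(sA, sA)$distance, rep(0, 3))

  sB <- sA
  sB$state_label <- "B"
  sB$H <- sA$H + 0.6 * mean(sA$H)  # shifts normalized H by exactly 0.6
  d <- hv_distance(sA, sB)
  dba <- hv_distance(sB, sA)
  expect_equal(d$distance, dba$distance)
  # single-axis displacement: |H~_A - H~_B| only
  hnA <- sA$H / mean(sA$H)
  hnB <- sB$H / mean(sB$H)
  expect_equal(d$distance, abs(hnA - hnB))

  # pairs absent from one state are reported separately
  sC <- sB[1:2, ]
  d2 <- hv_distance(sA, sC)
  expect_equal(nrow(d2), 2)
  expect_equal(attr(d2, "missing")$i, "r2")
  expect_error(hv_distance(sA, transform(sA, H = 0)),
               "zero")
})
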