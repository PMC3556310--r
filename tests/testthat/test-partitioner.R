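test_that("weak components and cycle detection behave on canonical cases", {
  two_cycles <- make_graph(paste0("n", 1:6),
                           src = c("n1", "n2", "n3", "n4", "n5", "n6"),
                           dst = c("n2", "n3", "n1", "n5", "n6", "n4"),
                           distance = rep(1, 6))
  comps <- connected_components(two_cycles)
  expect_length(comps, 2)
  expect_setequal(comps[[1]], c("n1", "n2", "n3"))
  expect_setequal(comps[[2]], c("n4", "n5", "n6"))
  expect_length(connected_components(two_cycles, c("n1", "n2", "n3")), 1)

  mixed <- make_graph(c("a", "b", "c"), src = "a", dst = "b", distance = 1)
  expect_equal(connected_components(mixed), list(c("a", "b"), "c"))

  expect_true(contains_cycle(make_graph(c("a", "b"), c("a", "b"),
                                        c("b", "a"), c(1, 1))))
  chain <- make_graph(c("a", "b", "c"), c("a", "b"), c("b", "c"), c(1, 1))
  expect_false(contains_cycle(chain))
  expect_false(contains_cycle(chain, "a"))  # a single node has no cycle
  expect_true(contains_cycle(two_cycles, c("n4", "n5", "n6")))
  expect_false(contains_cycle(two_cycles, c("n1", "n4")))
})

test_that("an acyclic chain is never partitioned (cycle-preservation stop rule)", {
  chain <- make_graph(paste0("n", 1:5), src = paste0("n", 1:4),
                      dst = paste0("n", 2:5), distance = rep(1, 4))
  tree <- hierarchical_partition(chain, ga_params(seed = 1))
  expect_length(tree$root$children, 0)
  expect_equal(unname(tree$terminal_depth), rep(0L, 5))
})

test_that("disconnected subnetworks split as red component links", {
  two_cycles <- make_graph(paste0("n", 1:4),
                           src = c("n1", "n2", "n3", "n4"),
                           dst = c("n2", "n1", "n4", "n3"),
                           distance = rep(1, 4))
  tree <- hierarchical_partition(two_cycles, ga_params(seed = 1))
  expect_length(tree$root$children, 2)
  expect_true(all(vapply(tree$root$children, function(ch) ch$link_type,
                         character(1)) == "component"))
  expect_equal(unname(tree$terminal_depth), rep(0L, 4))  # red links add no depth
})

test_that("trees partition the node set exactly and keep a cycle in one daughter", {
  for (seed in 1:6) {
    fx <- make_random(fixture_spec(n_reactions = sample(9:14, 1),
                                   cycle_count = sample(2:3, 1),
                                   seed = seed))
    g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
    tree <- hierarchical_partition(g, ga_params(seed = seed))
    leaves <- leaf_assignment(tree)
    expect_setequal(names(leaves), g$nodes)          # no loss
    # member sets of children partition the parent, at every node
    check_node <- function(node) {
      if (length(node$children) > 0) {
        kids <- unlist(lapply(node$children, `[[`, "members"))
        expect_setequal(kids, node$members)
        expect_equal(anyDuplicated(kids), 0L)
        if (node$children[[1]]$link_type == "partition") {
          expect_true(contains_cycle(g, node$children[[1]]$members) ||
                      contains_cycle(g, node$children[[2]]$members))
          expect_gt(node$q, 0)
        }
        lapply(node$children, check_node)
      }
      invisible(NULL)
    }
    check_node(tree$root)
    # depth + height of any module never exceeds the tree's deepest level
    maxd <- max(vapply(tree$modules, `[[`, integer(1), "depth"))
    for (m in tree$modules) expect_lte(m$depth + m$height, maxd)
  }
})

test_that("same seed gives identical trees; planted cycles are recovered", {
  fx <- make_random(fixture_spec(n_reactions = 12, cycle_count = 2, seed = 9))
  g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
  t1 <- hierarchical_partition(g, ga_params(seed = 5))
  t2 <- hierarchical_partition(g, ga_params(seed = 5))
  expect_identical(leaf_assignment(t1), leaf_assignment(t2))
  expect_identical(t1$terminal_depth, t2$terminal_depth)

  core <- names(fx$labels)[fx$labels != "bridge"]
  leaves <- leaf_assignment(t1)[core]
  # reactions of the same planted cycle end in the same terminal module
  for (cyc in unique(fx$labels[core])) {
    expect_length(unique(leaves[names(fx$labels)[fx$labels == cyc]]), 1)
  }
})

test_that("subnetwork ShReD reuse mode is available and differs only by construction", {
  fx <- make_random(fixture_spec(n_reactions = 10, cycle_count = 2, seed = 4))
  g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
  t_re <- hierarchical_partition(g, ga_params(seed = 2), recompute_shred = TRUE)
  t_ro <- hierarchical_partition(g, ga_params(seed = 2), recompute_shred = FALSE)
  expect_s3_class(t_ro, "partition_tree")
  expect_setequal(names(leaf_assignment(t_ro)), g$nodes)
  expect_setequal(names(leaf_assignment(t_re)), g$nodes)
})

test_that("tree export writes valid JSON and DOT with link-colored edges", {
  fx <- make_random(fixture_spec(n_reactions = 9, cycle_count = 2, seed = 11))
  g <- collapse_parallel_edges(build_graph(fx$model, "flux", fx$state))
  tree <- hierarchical_partition(g, ga_params(seed = 3))
  jp <- withr::local_tempfile(fileext = ".json")
  dp <- withr::local_tempfile(fileext = ".dot")
  groups <- stats::setNames(fx$model$reactions$group, fx$model$reactions$id)
  write_tree_json(tree, jp, groups = groups)
  obj <- jsonlite::read_json(jp)
  expect_equal(obj$root$link_type, "root")
  expect_equal(sort(unlist(obj$root$members)), sort(g$nodes))
  expect_true(!is.null(obj$root$homogeneity))
  write_tree_dot(tree, dp)
  txt <- readLines(dp)
  expect_true(any(grepl("color=black", txt)) || any(grepl("color=red", txt)))
})
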