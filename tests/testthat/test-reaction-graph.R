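test_that("direction canonicalization flips negative reversible fluxes and is idempotent", {
  m <- metabolic_model(list(
    list(id = "Rin", group = "exchange", stoich = c(A = 1), reversible = FALSE),
    list(id = "R", group = "core", stoich = c(A = -1, B = 1), reversible = TRUE),
    list(id = "Rout", group = "exchange", stoich = c(B = -1), reversible = TRUE)
  ))
  st <- flux_state(c(Rin = 0, R = -5, Rout = -5), m)
  canon <- canonicalize_directions(m, st)
  expect_equal(canon$model$stoich$R, c(A = 1, B = -1))
  expect_equal(canon$state$v[["R"]], 5)
  expect_true(all(canon$state$v >= 0))
  again <- canonicalize_directions(canon$model, canon$state)
  expect_equal(again$model$stoich, canon$model$stoich)
  expect_equal(again$state$v, canon$state$v)

  pos <- flux_state(c(Rin = 5, R = 5, Rout = 5), m)
  expect_equal(canonicalize_directions(m, pos)$model$stoich, m$stoich)
})

test_that("single-producer fixture yields the worked flux edge distances", {
  f <- make_figure7a()
  expect_equal(flux_edge_distance("M2", "R2", f$model, f$state), 100 / 60)
  expect_equal(flux_edge_distance("M2", "R3", f$model, f$state), 100 / 40)
  g <- build_graph(f$model, "flux", f$state)
  e <- g$edges[g$edges$metabolite == "M2", ]
  expect_setequal(paste(e$src, e$dst), c("R1 R2", "R1 R3"))
})

test_that("shared-pool fixture gives producer-independent distances", {
  f <- make_figure7b()
  g <- build_graph(f$model, "flux", f$state)
  e <- g$edges[g$edges$metabolite == "M0", ]
  expect_setequal(paste(e$src, e$dst),
                  c("R1 R3", "R1 R4", "R2 R3", "R2 R4"))
  expect_equal(e$distance[e$dst == "R3"], rep(100 / 70, 2))
  expect_equal(e$distance[e$dst == "R4"], rep(100 / 30, 2))

  skewed <- make_figure7b(v1 = 0.01, v2 = 99.99)
  g2 <- build_graph(skewed$model, "flux", skewed$state)
  e2 <- g2$edges[g2$edges$metabolite == "M0", ]
  expect_equal(e2[order(e2$src, e2$dst), "distance"],
               e[order(e$src, e$dst), "distance"])
})

test_that("reciprocal flux distances per metabolite sum to one (share conservation)", {
  check_shares <- function(model, state) {
    g <- build_graph(model, "flux", state)
    for (m in unique(g$edges$metabolite)) {
      e <- g$edges[g$edges$metabolite == m, ]
      e <- e[!duplicated(e$dst), ]  # one share per consumer
      expect_equal(sum(1 / e$distance), 1, tolerance = 1e-10)
    }
  }
  f <- make_figure7a(); check_shares(f$model, f$state)
  f <- make_figure7b(); check_shares(f$model, f$state)
  for (seed in 1:5) {
    fx <- make_random(fixture_spec(n_reactions = 9, cycle_count = 2,
                                   seed = seed))
    check_shares(fx$model, fx$state)
  }
})

test_that("degree weighting counts consumers and ignores the flux state", {
  f <- make_figure7a()
  expect_equal(degree_edge_distance("M2", f$model), 2)
  expect_equal(degree_edge_distance("M3", f$model), 1)
  g <- build_graph(f$model, "degree")
  e <- g$edges[g$edges$metabolite == "M2", ]
  expect_equal(e$distance, rep(2, 2))
  fx <- make_random(fixture_spec(seed = 3))
  g1 <- build_graph(fx$model, "degree")
  half <- fx$state; half$v <- half$v / 2
  g2 <- build_graph(fx$model, "degree", half)
  expect_equal(g1$edges[names(g1$edges) != "distance"],
               g2$edges[names(g2$edges) != "distance"])
  expect_equal(g1$edges$distance, g2$edges$distance)
})

test_that("flux weighting requires a state; zero-flux reactions draw no edges", {
  f <- make_figure7a()
  expect_error(build_graph(f$model, "flux"), "requires a flux state")
  v <- f$state$v
  v[c("R3", "Rout3")] <- 0
  st <- flux_state(v, f$model, label = "pruned")
  g <- build_graph(f$model, "flux", st)
  expect_false("R3" %in% g$edges$dst)
  expect_true("R3" %in% g$nodes)
  # unit topology equals flux topology restricted to positive-flux reactions
  gu <- build_graph(f$model, "unit")
  pos <- names(v)[v > 0]
  eu <- gu$edges[gu$edges$src %in% pos & gu$edges$dst %in% pos, ]
  expect_setequal(paste(g$edges$src, g$edges$dst, g$edges$metabolite),
                  paste(eu$src, eu$dst, eu$metabolite))
})

test_that("parallel edges collapse to the minimum with a deterministic tie rule", {
  g <- make_graph(c("a", "b"), src = c("a", "a"), dst = c("b", "b"),
                  distance = c(5, 2), metabolite = c("pyruvate", "NADH"))
  cg <- collapse_parallel_edges(g)
  expect_equal(nrow(cg$edges), 1L)
  expect_equal(cg$edges$distance, 2)
  expect_equal(cg$edges$metabolite, "NADH")

  tie <- make_graph(c("a", "b"), src = c("a", "a"), dst = c("b", "b"),
                    distance = c(2, 2), metabolite = c("zeta", "alpha"))
  expect_equal(collapse_parallel_edges(tie)$edges$metabolite, "alpha")

  single <- make_graph(c("a", "b"), "a", "b", 1.5, "m")
  expect_equal(collapse_parallel_edges(single)$edges, single$edges)
})
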