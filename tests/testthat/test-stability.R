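test_that("threshold collapses to the 2.555 coefficient on cliques", {
  # algebraic identity at the fully connected limit: s * (1 + 65/8)
  expect_equal(threshold_coefficient(0.28, 10, 5), 0.28 * 9.125)
  expect_equal(threshold_coefficient(0.28, 2 * 7, 7), 2.555,
               tolerance = 1e-12)
  # unweighted complete graph n = 4: lambda2 = 4, so eps = 2.555 * 4 / 4
  k4 <- complete_net(4, w = 1)
  eps <- edge_weight_threshold(k4, s = 0.28, lambda2_mode = "unweighted")
  expect_equal(as.numeric(eps), 2.555, tolerance = 1e-12)
  expect_true(attr(eps, "fully_connected"))
  expect_equal(attr(eps, "m"), 2)
  # the general (non-clique) branch agrees with its coefficient
  bow <- dumbbell_net(k = 4, w = 0.6, bridge_w = 0.3, bridges = 1L)
  epsb <- edge_weight_threshold(bow, s = 0.28)
  expect_false(attr(epsb, "fully_connected"))
  expect_equal(as.numeric(epsb),
               threshold_coefficient(0.28, attr(epsb, "n"), attr(epsb, "m")) *
                 attr(epsb, "lambda2") / attr(epsb, "n"))
  expect_error(edge_weight_threshold(
    gene_network(data.frame(a = character(0), b = character(0),
                            w = numeric(0)), nodes = "A")),
    "single-node")
})

test_that("greedy clique is a clique and never beats exhaustive search", {
  expect_length(max_clique_greedy(complete_net(3)), 3L)
  expect_length(max_clique_greedy(star_net(4)), 2L)
  for (seed in 1:20) {
    n <- sample(4:8, 1L)
    g <- random_net(n, p = 0.5, seed = 1000L + seed)
    cl <- max_clique_greedy(g)
    sub <- igraph::induced_subgraph(g, cl)
    expect_true(is_fully_connected_for_test(sub))
    expect_lte(length(cl), oracle_max_clique_size(g))
    expect_gte(length(cl), 2L)
    # deterministic
    expect_identical(max_clique_greedy(g), cl)
  }
})

test_that("hanging nodes are exactly the degree-1 nodes", {
  expect_setequal(find_hanging_nodes(path_net(c("A", "B", "C"))), c("A", "C"))
  expect_length(find_hanging_nodes(cycle_net(4)), 0L)
  st <- star_net(4, center = "HUB")
  expect_setequal(find_hanging_nodes(st), sprintf("L%02d", 1:4))
})

test_that("stabilize reaches a synchronously stable fixed point", {
  # already-stable network: unchanged, empty trace
  db <- dumbbell_net()
  expect_true(is_synchronously_stable(db, s = 0.28))
  db_s <- stabilize(db, s = 0.28)
  expect_true(graph_equal(db, db_s))
  expect_equal(nrow(attr(db_s, "stabilize_trace")), 0L)

  # uniform-weight clique at s = 0.28 (weighted mode): eps = 2.555 w > w,
  # the whole component dissolves into singletons
  k6 <- complete_net(6, w = 0.9)
  k6_s <- stabilize(k6, s = 0.28)
  expect_equal(igraph::ecount(k6_s), 0L)
  expect_equal(igraph::vcount(k6_s), 6L)  # singletons kept
  expect_equal(n_components(k6_s), 6L)
  expect_equal(igraph::vcount(stabilize(k6, s = 0.28,
                                        drop_singletons = TRUE)), 0L)

  # hanging nodes are removed with their edges
  gen <- generate_synthetic_network(synthetic_network_spec(seed = 21))
  gs <- stabilize(gen$network)
  expect_lt(igraph::vcount(gs), igraph::vcount(gen$network))
  tr <- attr(gs, "stabilize_trace")
  expect_true("delete-hanging-nodes" %in% tr$action)

  # post-condition and idempotence on varied inputs
  inputs <- list(gs = gen$network, r1 = random_net(15, 0.3, seed = 5),
                 r2 = random_net(20, 0.15, seed = 6),
                 st = star_net(5, w = 0.9))
  for (g in inputs) {
    out <- stabilize(g, s = 0.28)
    expect_true(is_synchronously_stable(out, s = 0.28))
    again <- stabilize(out, s = 0.28)
    expect_true(graph_equal(out, again))
    expect_equal(nrow(attr(again, "stabilize_trace")), 0L)
  }
})

test_that("every multi-node component of a stabilized network beats eps", {
  for (seed in 1:5) {
    g <- generate_synthetic_network(
      synthetic_network_spec(n_genes = 80, susceptible_fraction = 0.25,
                             module_size = 8, seed = seed))$network
    out <- stabilize(g, s = 0.28)
    for (comp in network_components(out)) {
      if (igraph::vcount(comp) < 2L) next
      eps <- edge_weight_threshold(comp, s = 0.28)
      expect_gt(min(igraph::E(comp)$weight), as.numeric(eps))
    }
  }
})

test_that("loss proportion hits its boundary cases and grows with s", {
  db <- dumbbell_net()
  expect_equal(loss_proportion(db, s = 0.28), 0)
  k5 <- complete_net(5, w = 0.5)
  expect_equal(loss_proportion(k5, s = 0.28), 1)
  expect_error(loss_proportion(gene_network(
    data.frame(a = character(0), b = character(0), w = numeric(0)),
    nodes = "A")), "edgeless")
  s_grid <- seq(0.04, 0.96, by = 0.08)
  for (seed in 1:3) {
    g <- generate_synthetic_network(
      synthetic_network_spec(n_genes = 60, susceptible_fraction = 0.35,
                             module_size = 7, seed = 100L + seed))$network
    losses <- vapply(s_grid, function(s) loss_proportion(g, s = s),
                     numeric(1))
    expect_true(all(diff(losses) >= -1e-12))
    expect_true(all(losses >= 0 & losses <= 1))
  }
})

test_that("coupling-factor selection finds the first flat grid point", {
  # network stable across the whole small grid: constant zero loss curve,
  # gradient identically zero, first interior point returned
  k4 <- complete_net(4, w = 0.9)
  sel <- select_coupling_factor(list(k4), s_grid = c(0.02, 0.05, 0.08),
                                lambda2_mode = "weighted")
  expect_equal(sel$s, 0.05)
  expect_false(sel$flagged)
  expect_equal(unname(sel$curve), rep(0, 3))
  expect_error(select_coupling_factor(list(k4), s_grid = c(0.1, 0.2)),
               "at least 3")
  expect_error(select_coupling_factor(list(k4), s_grid = c(0.3, 0.2, 0.4)),
               "strictly increasing")
  # the documented default coupling factor of the pipeline is 0.28
  expect_equal(eval(formals(stabilize)$s), 0.28)
})
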