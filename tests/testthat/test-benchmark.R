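test_that("synthetic networks are reproducible and hub-structured", {
  spec <- synthetic_network_spec(seed = 11)
  g1 <- generate_synthetic_network(spec)
  g2 <- generate_synthetic_network(spec)
  expect_true(graph_equal(g1$network, g2$network))
  expect_identical(g1$susceptible, g2$susceptible)
  expect_true(all(igraph::E(g1$network)$weight >= 0 &
                    igraph::E(g1$network)$weight <= 1))
  expect_error(synthetic_network_spec(susceptible_fraction = 0),
               "susceptible_fraction")
  expect_error(synthetic_network_spec(susceptible_fraction = 1),
               "susceptible_fraction")
  expect_error(synthetic_network_spec(n_genes = 30, module_size = 10,
                                      susceptible_fraction = 0.1),
               "infeasible")
})

test_that("planted genes out-weigh background genes across replicates", {
  hits <- 0L
  reps <- 100L
  for (seed in seq_len(reps)) {
    gen <- generate_synthetic_network(synthetic_network_spec(seed = seed))
    ws <- igraph::strength(gen$network)
    planted <- names(ws) %in% gen$susceptible
    if (mean(ws[planted]) > mean(ws[!planted])) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.95)
})

test_that("fusion datasets respect the sampling-without-replacement design", {
  sus <- sprintf("S%03d", 1:40)
  bg <- sprintf("B%03d", 1:320)
  ds <- sample_fusion_dataset(sus, bg, dataset_spec(150, 15, seed = 3))
  expect_equal(nrow(ds), 150L)
  expect_equal(sum(ds$label == 1L), 15L)
  expect_equal(sum(ds$label == 0L), 135L)
  # 2*N_f = 300 partner slots, all distinct under disjoint pools
  partners <- c(ds$partner_a, ds$partner_b)
  expect_equal(length(partners), 300L)
  expect_equal(anyDuplicated(partners), 0L)
  expect_equal(anyDuplicated(ds$fusion), 0L)
  expect_true(all(ds$partner_a < ds$partner_b))
  # determinism
  ds2 <- sample_fusion_dataset(sus, bg, dataset_spec(150, 15, seed = 3))
  expect_identical(ds, ds2)

  expect_error(sample_fusion_dataset(sus[1:10], bg,
                                     dataset_spec(150, 15, seed = 3)),
               "susceptible pool too small")
  expect_error(sample_fusion_dataset(sus, bg[1:100],
                                     dataset_spec(150, 15, seed = 3)),
               "background pool too small")
})

test_that("overlapping pools trigger the duplicate re-draw loop", {
  pool <- c("A", "B", "C", "D")
  # fully adversarial: the only possible ordinary fusion always duplicates
  # the susceptible one
  expect_error(sample_fusion_dataset(c("A", "B"), c("A", "B"),
                                     dataset_spec(2, 1, seed = 1),
                                     max_attempts = 25L),
               "could not draw")
  # overlap with escape routes: the final set is always duplicate-free
  for (seed in 1:25) {
    ds <- sample_fusion_dataset(pool, pool, dataset_spec(2, 1, seed = seed))
    expect_equal(anyDuplicated(ds$fusion), 0L)
    expect_equal(nrow(ds), 2L)
  }
})

test_that("interval distribution honors the half-open rank brackets", {
  mk <- function(n_f, pos_ranks) {
    data.frame(rank = seq_len(n_f),
               label = as.integer(seq_len(n_f) %in% pos_ranks),
               S = seq(1, 0, length.out = n_f))
  }
  expect_equal(unname(interval_distribution(mk(10, c(1, 5)))),
               c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(interval_distribution(mk(20, 19:20))),
               c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2))
  # non-multiple-of-10 N_f: real-valued edges, integer ranks
  counts <- interval_distribution(mk(15, c(1, 2, 3)))
  expect_equal(sum(counts), 3L)
  expect_equal(unname(counts[1:2]), c(1L, 2L))  # I1 = (0, 1.5], I2 = (1.5, 3]
  # conservation over random datasets
  for (seed in 1:5) {
    set.seed(seed)
    n_f <- sample(c(37L, 100L, 150L), 1L)
    pos <- sample(n_f, 12L)
    expect_equal(sum(interval_distribution(mk(n_f, pos))), 12L)
  }
  expect_error(interval_distribution(mk(10, 2)[-1L, ]), "permutation")
})

test_that("recognition rates accumulate to one", {
  counts <- c(13L, rep(0L, 9L))
  expect_equal(recognition_rate(counts, 15, 1), 13 / 15)
  expect_equal(recognition_rate(counts, 15, 10), 13 / 15)
  counts2 <- c(8L, 4L, 2L, 1L, rep(0L, 6L))
  p <- recognition_rate(counts2, 15)
  expect_equal(p[10], 1)
  expect_true(all(diff(p) >= 0))
  expect_error(recognition_rate(counts, 0), "N_i = 0")
})

test_that("ROC sweep matches the Mann-Whitney pair statistic", {
  df <- function(S, label) data.frame(S = S, label = label)
  expect_equal(roc_and_auc(df(c(4, 3, 2, 1), c(1, 1, 0, 0)))$auc, 1)
  expect_equal(roc_and_auc(df(rep(1, 6), c(1, 1, 1, 0, 0, 0)))$auc, 0.5)
  expect_equal(roc_and_auc(df(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)))$auc,
               0.75)
  expect_error(roc_and_auc(df(1:3, c(1, 1, 1))), "single class")
  for (seed in 1:10) {
    set.seed(400L + seed)
    n <- 40L
    S <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    label <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.8, 0.2))
    if (length(unique(label)) < 2L) next
    res <- roc_and_auc(df(S, label))
    expect_equal(res$auc, oracle_auc(S, label), tolerance = 1e-12)
    expect_equal(res$roc$fpr[1L], 0)
    expect_equal(res$roc$tpr[nrow(res$roc)], 1)
    expect_true(all(diff(res$roc$fpr) >= 0) && all(diff(res$roc$tpr) >= 0))
  }
})

test_that("a one-cell grid produces consistent aggregated results", {
  cfg <- benchmark_config(
    n_f_grid = 20L, n_i_grid = 5L, replicates = 3L,
    network_spec = synthetic_network_spec(n_genes = 60,
                                          susceptible_fraction = 0.35,
                                          module_size = 7),
    seed = 99L)
  bm <- run_experiment_grid(cfg, quiet = TRUE)
  expect_equal(bm$n_datasets, 3L)
  expect_equal(nrow(bm$errors), 0L)
  expect_setequal(unique(bm$results$algorithm), c("SYN", "DEG", "BET"))
  # conservation per dataset and algorithm
  for (r in 1:3) for (alg in c("SYN", "DEG", "BET")) {
    sub <- bm$results[bm$results$replicate == r &
                        bm$results$algorithm == alg, ]
    expect_equal(sum(sub$value[grepl("^I", sub$metric)]), 5)
    expect_equal(sub$value[sub$metric == "P10"], 1)
  }
  # summary is the mean over replicates
  syn_auc <- bm$results$value[bm$results$metric == "auc" &
                                bm$results$algorithm == "SYN"]
  expect_equal(bm$summary$value[bm$summary$metric == "auc" &
                                  bm$summary$algorithm == "SYN"],
               mean(syn_auc))
  # determinism of the whole grid
  bm2 <- run_experiment_grid(cfg, quiet = TRUE)
  expect_identical(bm$results, bm2$results)
})
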