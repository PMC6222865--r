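# Graph builders and independent brute-force oracles shared by the tests.

net <- function(a, b, w, nodes = NULL, validate = TRUE) {
  gene_network(data.frame(gene_a = a, gene_b = b, weight = w,
                          stringsAsFactors = FALSE),
               nodes = nodes, validate = validate)
}

complete_net <- function(n, w = 0.5, prefix = "K") {
  prs <- utils::combn(sprintf("%s%02d", prefix, seq_len(n)), 2L)
  net(prs[1L, ], prs[2L, ], rep(w, ncol(prs)))
}

path_net <- function(labels, w = 0.5) {
  k <- length(labels)
  net(labels[-k], labels[-1L], rep_len(w, k - 1L))
}

star_net <- function(leaves = 4L, w = 0.5, center = "HUB") {
  lv <- sprintf("L%02d", seq_len(leaves))
  net(rep(center, leaves), lv, rep_len(w, leaves))
}

cycle_net <- function(n, w = 0.5) {
  v <- sprintf("C%02d", seq_len(n))
  net(v, c(v[-1L], v[1L]), rep_len(w, n))
}

# Erdos-Renyi weighted graph for property tests
random_net <- function(n, p = 0.4, seed = 1L, wmin = 0.05, wmax = 0.95) {
  set.seed(seed)
  v <- sprintf("R%02d", seq_len(n))
  prs <- utils::combn(v, 2L)
  pick <- stats::runif(ncol(prs)) < p
  if (!any(pick)) pick[1L] <- TRUE
  net(prs[1L, pick], prs[2L, pick],
      stats::runif(sum(pick), wmin, wmax), nodes = v)
}

# two dense cliques joined by bridge edges: synchronously stable at s = 0.28
dumbbell_net <- function(k = 8L, w = 0.8, bridge_w = 0.8, bridges = 2L) {
  lhs <- sprintf("A%02d", seq_len(k))
  rhs <- sprintf("B%02d", seq_len(k))
  prs <- cbind(utils::combn(lhs, 2L), utils::combn(rhs, 2L))
  a <- c(prs[1L, ], lhs[seq_len(bridges)])
  b <- c(prs[2L, ], rhs[seq_len(bridges)])
  net(a, b, c(rep(w, ncol(prs)), rep(bridge_w, bridges)))
}

graph_equal <- function(g1, g2) {
  df <- function(g) {
    d <- igraph::as_data_frame(g, what = "edges")
    d <- data.frame(a = pmin(d$from, d$to), b = pmax(d$from, d$to),
                    w = d$weight)
    d[order(d$a, d$b), , drop = FALSE]
  }
  isTRUE(all.equal(df(g1), df(g2), check.attributes = FALSE)) &&
    setequal(igraph::V(g1)$name, igraph::V(g2)$name)
}

# ---- oracles ---------------------------------------------------------------

# exhaustive maximum clique size by enumerating all node subsets (n <= ~12)
oracle_max_clique_size <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  best <- 1L
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    k <- length(idx)
    if (k > best && all(A[idx, idx][upper.tri(diag(k))] == 1)) best <- k
  }
  best
}

# geodesic-count betweenness by walk counting with matrix powers:
# walks of minimal length are exactly the shortest simple paths, and paths
# avoiding v are counted in the graph with v removed.
oracle_betweenness <- function(g, v) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  vi <- match(v, nm)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  pow_list <- vector("list", max(1L, n - 1L))
  P <- A
  pow_list[[1L]] <- P
  if (n > 2L) for (k in 2:(n - 1L)) { P <- P %*% A; pow_list[[k]] <- P }
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- matrix(0, n, n); diag(S) <- 1
  for (k in seq_along(pow_list)) {
    newly <- is.infinite(D) & pow_list[[k]] > 0
    D[newly] <- k
    S[newly] <- pow_list[[k]][newly]
  }
  B <- A[-vi, -vi, drop = FALSE]
  bpow <- vector("list", length(pow_list))
  Q <- B
  bpow[[1L]] <- Q
  if (length(pow_list) > 1L) {
    for (k in 2:length(pow_list)) { Q <- Q %*% B; bpow[[k]] <- Q }
  }
  old <- seq_len(n)[-vi]
  g_tot <- 0; g_v <- 0
  for (s_i in seq_len(n - 1L)) {
    for (t_i in (s_i + 1L):n) {
      if (!is.finite(D[s_i, t_i])) next
      g_tot <- g_tot + S[s_i, t_i]
      if (s_i != vi && t_i != vi) {
        d <- D[s_i, t_i]
        avoid <- bpow[[d]][match(s_i, old), match(t_i, old)]
        g_v <- g_v + S[s_i, t_i] - avoid
      }
    }
  }
  if (g_tot > 0) g_v / g_tot else 0
}

# Mann-Whitney pair statistic with ties counted 1/2
oracle_auc <- function(s, label) {
  pos <- s[label == 1L]
  neg <- s[label == 0L]
  prs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(prs)
}

quiet_importance <- function(...) suppressWarnings(importance_table(...))

is_fully_connected_for_test <- function(g) {
  n <- igraph::vcount(g)
  igraph::ecount(g) == n * (n - 1) / 2
}
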