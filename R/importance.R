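#' Network metric M(G)
#'
#' The ratio of total edge weight to the number of connected subgraphs,
#' \deqn{M(G) = \frac{\sum_{i \in G}\sum_{j \ne i} w_{ij}}{m_G},}
#' with the ordered-pair double sum counting each undirected edge twice and
#' `m_G` the number of connected components (singletons included). Deleting
#' a node lowers the numerator (lost edge weight) and can raise the
#' denominator (lost connectivity), so M captures both facets of
#' destructiveness.
#'
#' @param network An igraph gene network with at least one node.
#' @return Scalar M; 0 for an edgeless network.
#' @export
network_metric <- function(network) {
  if (igraph::vcount(network) == 0L) {
    stop("network metric undefined for an empty (0-node) network")
  }
  2 * sum(igraph::E(network)$weight) / igraph::components(network)$no
}

#' Network difference D of deleting one gene
#'
#' `D = M(G_s) - M((G_s - v)_s)`: the stabilized baseline's metric minus the
#' metric after deleting `v` (and its edges) and re-identifying the
#' synchronously stable state. Stabilization acts independently on each
#' connected component, so only `v`'s component is re-stabilized; the other
#' components' weight and count carry over unchanged.
#'
#' D can be negative in degenerate cases — deleting an isolated singleton
#' leaves the total weight unchanged but lowers the component count, raising
#' M. Such nodes are assigned importance 0 upstream (see
#' [node_importance()]).
#'
#' @param stable_network A stabilized igraph network (output of
#'   [stabilize()]).
#' @param v A gene identifier present in `stable_network`.
#' @inheritParams stabilize
#' @return Scalar difference D.
#' @export
network_difference <- function(stable_network, v, s = 0.28,
                               lambda2_mode = c("weighted", "unweighted")) {
  lambda2_mode <- match.arg(lambda2_mode)
  nm <- igraph::V(stable_network)$name
  if (!(v %in% nm)) stop("gene not in network: ", v)
  comp <- igraph::components(stable_network)
  m_tot <- comp$no
  w_tot <- sum(igraph::E(stable_network)$weight)
  M <- 2 * w_tot / m_tot
  ci <- comp$membership[[match(v, nm)]]
  vids <- which(comp$membership == ci)
  if (length(vids) == 1L) {
    # v is a singleton: weight mass unchanged, one component fewer
    if (m_tot == 1L) stop("cannot delete the only node of the network")
    return(M - 2 * w_tot / (m_tot - 1L))
  }
  sub <- igraph::induced_subgraph(stable_network, vids)
  w_comp <- sum(igraph::E(sub)$weight)
  rest <- igraph::delete_vertices(sub, v)
  rest_s <- stabilize(rest, s = s, lambda2_mode = lambda2_mode)
  w_new <- w_tot - w_comp + sum(igraph::E(rest_s)$weight)
  m_new <- m_tot - 1L + igraph::components(rest_s)$no
  M - 2 * w_new / m_new
}

#' Importance H of one gene
#'
#' `H(G, v) = D(G, v) / M(G_s)`: the relative destructiveness of deleting
#' gene `v` from the synchronously stable network. Genes isolated in the
#' stabilized baseline (degree 0) destroy nothing and get `H = 0`.
#'
#' @inheritParams network_difference
#' @return Scalar H.
#' @export
node_importance <- function(stable_network, v, s = 0.28,
                            lambda2_mode = c("weighted", "unweighted")) {
  lambda2_mode <- match.arg(lambda2_mode)
  M <- network_metric(stable_network)
  if (M <= 0) {
    stop("baseline network metric is not positive; ",
         "an edgeless stabilized network cannot be scored")
  }
  if (igraph::degree(stable_network, v) == 0L) return(0)
  network_difference(stable_network, v, s = s,
                     lambda2_mode = lambda2_mode) / M
}

#' Importance table over a set of genes
#'
#' Stabilizes the network once, then evaluates every requested gene by
#' deleting it from the shared stabilized baseline, re-stabilizing, and
#' scoring the metric drop (see [network_difference()] and
#' [node_importance()]). Evaluating one gene never mutates the baseline, so
#' the result is deterministic and re-entrant.
#'
#' Genes missing from the stabilized network (either absent from the input
#' or pruned as hanging nodes) receive `H = 0` with one aggregate warning,
#' so downstream fusion scoring never fails on vocabulary gaps.
#'
#' @param network An igraph gene network (not yet stabilized).
#' @param genes Character vector of genes to score; default all nodes of
#'   `network`.
#' @inheritParams stabilize
#' @return A data frame of class `importance_table` with columns `gene`,
#'   `H` and `D`, and attributes `baseline_M`, `stabilized` (the baseline
#'   network) and `s`.
#' @export
importance_table <- function(network, genes = NULL, s = 0.28,
                             lambda2_mode = c("weighted", "unweighted"),
                             drop_singletons = FALSE) {
  lambda2_mode <- match.arg(lambda2_mode)
  if (is.null(genes)) genes <- igraph::V(network)$name
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in evaluation set")
  stray <- setdiff(genes, igraph::V(network)$name)
  if (length(stray) > 0L) {
    stop("genes absent from the input network: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  gs <- stabilize(network, s = s, lambda2_mode = lambda2_mode,
                  drop_singletons = drop_singletons)
  out <- data.frame(gene = genes, H = numeric(length(genes)),
                    D = rep(NA_real_, length(genes)),
                    stringsAsFactors = FALSE)
  if (length(genes) == 0L) {
    M <- if (igraph::vcount(gs) > 0L) network_metric(gs) else NA_real_
    attr(out, "baseline_M") <- M
    attr(out, "stabilized") <- gs
    attr(out, "s") <- s
    class(out) <- c("importance_table", "data.frame")
    return(out)
  }
  M <- network_metric(gs)
  if (M <= 0) {
    stop("stabilized network has no retained edge weight; ",
         "no gene can be scored (try a smaller coupling factor s)")
  }
  present <- igraph::V(gs)$name
  missing <- setdiff(genes, present)
  if (length(missing) > 0L) {
    warning(length(missing), " gene(s) absent from the stabilized network; ",
            "assigned H = 0")
  }
  deg <- igraph::degree(gs)
  for (i in seq_along(genes)) {
    gene <- genes[i]
    if (!(gene %in% present)) next
    if (deg[[gene]] == 0L) {
      out$D[i] <- NA_real_
      next
    }
    D <- network_difference(gs, gene, s = s, lambda2_mode = lambda2_mode)
    out$D[i] <- D
    out$H[i] <- D / M
  }
  attr(out, "baseline_M") <- M
  attr(out, "stabilized") <- gs
  attr(out, "s") <- s
  class(out) <- c("importance_table", "data.frame")
  out
}

#' @export
print.importance_table <- function(x, ...) {
  cat("Importance table over", nrow(x), "gene(s); baseline M =",
      format(attr(x, "baseline_M"), digits = 6),
      "at s =", attr(x, "s"), "\n")
  print.data.frame(utils::head(x[order(-x$H), , drop = FALSE], 10L),
                   row.names = FALSE, ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more gene(s)\n")
  invisible(x)
}
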