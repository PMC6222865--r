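#' Synchronous-stability edge-weight threshold for a component
#'
#' For a connected component with `n` nodes and coupling factor
#' `a = s * lambda_2`, an edge keeps the component synchronously stable only
#' if its weight exceeds
#' \deqn{\epsilon = \frac{s\,\lambda_2}{n}\Big(\frac{n}{2m}\Big)^3
#'       \Big(1 + \frac{65}{4}\,\frac{m}{n}\Big)}
#' where `2m` is the size of the component's maximum clique (found greedily).
#' For a fully connected component `2m = n`, and the expression collapses to
#' `s * 9.125 * lambda_2 / n`, i.e. `2.555 * lambda_2 / n` at the default
#' coupling factor `s = 0.28`.
#'
#' @param component An igraph graph with >= 2 vertices forming one connected
#'   component.
#' @param s Coupling factor multiplier in (0, 1); `a = s * lambda_2`.
#' @param lambda2_mode Laplacian used for lambda_2, `"weighted"` (default) or
#'   `"unweighted"`; see [algebraic_connectivity()].
#' @return The scalar threshold epsilon, with attributes `lambda2`, `n`, `m`
#'   and `fully_connected`.
#' @export
edge_weight_threshold <- function(component, s = 0.28,
                                  lambda2_mode = c("weighted", "unweighted")) {
  lambda2_mode <- match.arg(lambda2_mode)
  n <- igraph::vcount(component)
  if (n < 2L) stop("threshold undefined for a single-node component")
  lam2 <- algebraic_connectivity(component, mode = lambda2_mode)
  full <- is_fully_connected(component)
  m <- if (full) n / 2 else length(max_clique_greedy(component)) / 2
  eps <- threshold_coefficient(s, n, m) * lam2 / n
  structure(eps, lambda2 = lam2, n = n, m = m, fully_connected = full)
}

#' Dimensionless threshold coefficient
#'
#' The factor multiplying `lambda_2 / n` in the stability threshold:
#' `s * (n / 2m)^3 * (1 + (65/4) * (m/n))`. At the fully connected limit
#' `n = 2m` it equals `s * 9.125`.
#'
#' @param s Coupling factor multiplier.
#' @param n Component node count.
#' @param m Half the maximum-clique size (real-valued; odd cliques allowed).
#' @return The scalar coefficient `epsilon * n / lambda_2`.
#' @export
threshold_coefficient <- function(s, n, m) {
  s * (n / (2 * m))^3 * (1 + (65 / 4) * (m / n))
}

#' Is a component fully connected (a clique)?
#' @param component An igraph graph.
#' @return Logical.
#' @keywords internal
is_fully_connected <- function(component) {
  n <- igraph::vcount(component)
  igraph::ecount(component) == n * (n - 1) / 2
}

#' Greedy maximum clique
#'
#' Deterministic greedy heuristic for the (NP-hard) maximum clique problem:
#' vertices are visited in order of decreasing weighted degree, ties broken
#' lexicographically by gene identifier, and each vertex is added if adjacent
#' to every clique member so far.
#'
#' @param component A non-empty igraph graph.
#' @return Character vector of clique member names (size >= 2 whenever the
#'   graph has an edge; a single vertex for edgeless graphs).
#' @export
max_clique_greedy <- function(component) {
  n <- igraph::vcount(component)
  if (n == 0L) stop("empty component")
  nm <- igraph::V(component)$name
  strength <- igraph::strength(component)
  ord <- order(-strength, nm)
  adj <- igraph::as_adj_list(component)
  adj <- lapply(adj, as.integer)
  clique <- integer(0)
  for (v in ord) {
    if (all(clique %in% adj[[v]])) clique <- c(clique, v)
  }
  nm[clique]
}

#' Hanging (degree-1) nodes of a component
#' @param component An igraph graph.
#' @return Character vector of names of all vertices with degree exactly 1.
#' @export
find_hanging_nodes <- function(component) {
  deg <- igraph::degree(component)
  names(deg)[deg == 1L]
}

#' Identify the synchronously stable network
#'
#' Iteratively filters a weighted gene network until every connected
#' component with >= 2 nodes satisfies `w > epsilon` for all its edges
#' (see [edge_weight_threshold()]). Per component per iteration: a component
#' already satisfying the condition is left alone; a fully connected
#' component has all edges with `w <= epsilon` deleted in one batch; a
#' non-fully-connected component has its hanging nodes deleted if any exist
#' (node and incident edge), otherwise its sub-threshold edges are deleted in
#' one batch. Components and thresholds are recomputed every iteration, and
#' the loop runs to a fixed point. Nodes isolated by edge deletion are kept
#' as singleton components unless `drop_singletons = TRUE`; nodes deleted as
#' hanging nodes are removed from the network.
#'
#' @inheritParams edge_weight_threshold
#' @param network An igraph gene network.
#' @param drop_singletons Drop degree-0 vertices from the result
#'   (default `FALSE`: genes still exist even when all interactions are
#'   filtered).
#' @return The stabilized igraph network. Attribute `"stabilize_trace"`
#'   holds a data frame (one row per component action) with columns
#'   `iteration`, `component`, `action` (`"delete-edges"` or
#'   `"delete-hanging-nodes"`), `n_removed` and `epsilon`; the trace has zero
#'   rows iff the input was already stable. Attribute `"s"` records the
#'   coupling factor.
#' @export
stabilize <- function(network, s = 0.28,
                      lambda2_mode = c("weighted", "unweighted"),
                      drop_singletons = FALSE) {
  lambda2_mode <- match.arg(lambda2_mode)
  stopifnot(s > 0, s < 1)
  g <- network
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    comp <- igraph::components(g)
    edge_kill <- list()   # two-column name matrices
    node_kill <- character(0)
    for (ci in seq_len(comp$no)) {
      vids <- which(comp$membership == ci)
      if (length(vids) < 2L) next
      sub <- igraph::induced_subgraph(g, vids)
      eps <- edge_weight_threshold(sub, s = s, lambda2_mode = lambda2_mode)
      w <- igraph::E(sub)$weight
      if (min(w) > eps) next  # component already synchronously stable
      if (attr(eps, "fully_connected")) {
        bad <- which(w <= eps)
        ends <- igraph::ends(sub, bad, names = TRUE)
        edge_kill[[length(edge_kill) + 1L]] <- ends
        act <- "delete-edges"; nrem <- length(bad)
      } else {
        hang <- find_hanging_nodes(sub)
        if (length(hang) > 0L) {
          node_kill <- c(node_kill, hang)
          act <- "delete-hanging-nodes"; nrem <- length(hang)
        } else {
          bad <- which(w <= eps)
          ends <- igraph::ends(sub, bad, names = TRUE)
          edge_kill[[length(edge_kill) + 1L]] <- ends
          act <- "delete-edges"; nrem <- length(bad)
        }
      }
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = iter, component = ci, action = act,
        n_removed = nrem, epsilon = as.numeric(eps)
      )
    }
    if (length(edge_kill) == 0L && length(node_kill) == 0L) break
    if (length(edge_kill) > 0L) {
      ends <- do.call(rbind, edge_kill)
      eids <- igraph::get_edge_ids(g, t(ends))
      g <- igraph::delete_edges(g, eids)
    }
    if (length(node_kill) > 0L) {
      g <- igraph::delete_vertices(g, node_kill)
    }
  }
  if (drop_singletons) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  }
  trace <- if (length(trace) > 0L) {
    do.call(rbind, trace)
  } else {
    data.frame(iteration = integer(0), component = integer(0),
               action = character(0), n_removed = integer(0),
               epsilon = numeric(0))
  }
  attr(g, "stabilize_trace") <- trace
  attr(g, "s") <- s
  g
}

#' Check the synchronous-stability condition on every component
#'
#' @inheritParams stabilize
#' @return `TRUE` iff every connected component with >= 2 nodes satisfies
#'   `w > epsilon` for all of its edges.
#' @export
is_synchronously_stable <- function(network, s = 0.28,
                                    lambda2_mode = c("weighted", "unweighted")) {
  lambda2_mode <- match.arg(lambda2_mode)
  comp <- igraph::components(network)
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) < 2L) next
    sub <- igraph::induced_subgraph(network, vids)
    eps <- edge_weight_threshold(sub, s = s, lambda2_mode = lambda2_mode)
    if (min(igraph::E(sub)$weight) <= eps) return(FALSE)
  }
  TRUE
}

#' Proportion of information lost by stabilization
#'
#' Fraction of the network's total edge-weight mass (or edge count, with
#' `measure = "count"`) removed when the network is filtered to its
#' synchronously stable state at coupling factor `s`.
#'
#' @inheritParams stabilize
#' @param measure `"weight"` (default; information in a probability-weighted
#'   network is weight mass) or `"count"`.
#' @return Scalar in `[0, 1]`.
#' @export
loss_proportion <- function(network, s = 0.28,
                            lambda2_mode = c("weighted", "unweighted"),
                            measure = c("weight", "count")) {
  measure <- match.arg(measure)
  lambda2_mode <- match.arg(lambda2_mode)
  if (igraph::ecount(network) == 0L) {
    stop("loss proportion undefined for an edgeless network")
  }
  before <- if (measure == "weight") {
    sum(igraph::E(network)$weight)
  } else {
    igraph::ecount(network)
  }
  stab <- stabilize(network, s = s, lambda2_mode = lambda2_mode)
  after <- if (measure == "weight") {
    sum(igraph::E(stab)$weight)
  } else {
    igraph::ecount(stab)
  }
  (before - after) / before
}

#' Select the coupling factor from the loss-proportion curve
#'
#' Computes the mean loss-proportion curve over a set of networks on a grid
#' of coupling factors, takes its central finite-difference gradient, and
#' returns the smallest grid point whose absolute gradient is within
#' `gradient_tol` — the "depression point" where further increases of `s`
#' stop removing information. If no grid point qualifies, the point of
#' minimum absolute gradient is returned and flagged.
#'
#' @param networks A list of igraph gene networks (>= 2 recommended).
#' @param s_grid Strictly increasing grid within (0, 1); default
#'   `seq(0.01, 0.99, by = 0.01)`. Must have length >= 3.
#' @param gradient_tol Absolute gradient tolerance per unit `s` on the mean
#'   curve (default 0.05).
#' @inheritParams loss_proportion
#' @return A list with `s` (the selected factor), `flagged` (`TRUE` when no
#'   grid point met the tolerance), `curve` (mean loss per grid point) and
#'   `gradient` (central differences; `NA` at the grid ends).
#' @export
select_coupling_factor <- function(networks,
                                   s_grid = seq(0.01, 0.99, by = 0.01),
                                   gradient_tol = 0.05,
                                   lambda2_mode = c("weighted", "unweighted"),
                                   measure = c("weight", "count")) {
  lambda2_mode <- match.arg(lambda2_mode)
  measure <- match.arg(measure)
  if (length(s_grid) < 3L) {
    stop("s_grid must have at least 3 points for a central-difference gradient")
  }
  if (is.unsorted(s_grid, strictly = TRUE) ||
      s_grid[1L] <= 0 || s_grid[length(s_grid)] >= 1) {
    stop("s_grid must be strictly increasing within (0, 1)")
  }
  if (igraph::is_igraph(networks)) networks <- list(networks)
  losses <- vapply(networks, function(g) {
    vapply(s_grid, function(s) {
      loss_proportion(g, s = s, lambda2_mode = lambda2_mode, measure = measure)
    }, numeric(1))
  }, numeric(length(s_grid)))
  curve <- rowMeans(as.matrix(losses))
  k <- length(s_grid)
  grad <- rep(NA_real_, k)
  grad[2:(k - 1)] <- (curve[3:k] - curve[1:(k - 2)]) /
    (s_grid[3:k] - s_grid[1:(k - 2)])
  ok <- which(!is.na(grad) & abs(grad) <= gradient_tol)
  if (length(ok) > 0L) {
    list(s = s_grid[ok[1L]], flagged = FALSE, curve = curve, gradient = grad)
  } else {
    best <- which.min(abs(grad))
    list(s = s_grid[best], flagged = TRUE, curve = curve, gradient = grad)
  }
}
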