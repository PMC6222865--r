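#' Merge two partner genes into a burden node
#'
#' Implements the "network fusion centrality" representation of a fusion:
#' the two partner nodes are replaced by a single burden node adjacent to
#' every former neighbor of either partner. When a neighbor was connected to
#' both partners, the overlapped edges are resolved by `max` weight
#' (default) or by their `sum`; the partner-partner edge, if any, would
#' become a self-loop and is dropped. A partner absent from the network
#' contributes nothing; at least one partner must be present.
#'
#' @param network An igraph gene network.
#' @param i,j Distinct partner gene identifiers.
#' @param merge_policy `"max"` (default) or `"sum"` for overlapped edges.
#' @param merged_name Name of the burden node (default `"i+j"`).
#' @return An igraph network with the burden node in place of the partners.
#' @export
merge_partners <- function(network, i, j, merge_policy = c("max", "sum"),
                           merged_name = paste0(i, "+", j)) {
  merge_policy <- match.arg(merge_policy)
  if (identical(i, j)) stop("partner genes must be distinct")
  nm <- igraph::V(network)$name
  present <- c(i, j)[c(i, j) %in% nm]
  if (length(present) == 0L) {
    stop("neither partner is present in the network")
  }
  df <- igraph::as_data_frame(network, what = "edges")
  df$from[df$from %in% c(i, j)] <- merged_name
  df$to[df$to %in% c(i, j)] <- merged_name
  df <- df[df$from != df$to, , drop = FALSE]  # former i-j edge
  if (nrow(df) > 0L) {
    key <- edge_key(df$from, df$to)
    if (anyDuplicated(key)) {
      agg <- if (merge_policy == "max") max else sum
      w <- tapply(df$weight, key, agg)
      first <- !duplicated(key)
      df <- df[first, , drop = FALSE]
      df$weight <- unname(w[key[first]])
    }
  }
  verts <- c(setdiff(nm, c(i, j)), merged_name)
  g <- igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  if (merge_policy == "sum") {
    # summed overlaps may exceed 1; cap at the probability ceiling
    igraph::E(g)$weight <- pmin(igraph::E(g)$weight, 1)
  }
  g
}

#' Normalized weighted degree centrality
#'
#' `K(i) = sum_j a_ij / (N - 1)` with `a_ij` the edge weight (0 when
#' absent) and `N` the network's node count.
#'
#' @param network An igraph gene network with >= 2 nodes.
#' @param v A gene identifier.
#' @return Scalar in `[0, 1]` for weights in `[0, 1]`.
#' @export
degree_centrality <- function(network, v) {
  n <- igraph::vcount(network)
  if (n < 2L) stop("degree centrality undefined for N < 2")
  unname(igraph::strength(network, v)) / (n - 1)
}

#' Shortest-path-count betweenness centrality
#'
#' `B(k) = g(k) / g`, where `g` is the total number of shortest paths over
#' all unordered node pairs (all geodesics counted when several are tied)
#' and `g(k)` is the number of those passing through `k` as an interior
#' node. Pairs whose geodesic is a direct edge contribute paths that cannot
#' pass through `k`; pairs with `k` as an endpoint contribute to `g` only.
#' `B = 0` for isolated nodes, leaves and every node of a clique.
#'
#' `path_mode = "hop"` (default, Freeman's unweighted definition) counts
#' geodesics by hop length via a C++ breadth-first kernel;
#' `"inverse-weight"` measures path length as the sum of `1 / w` over edges
#' (strong interactions are short) and is evaluated in R.
#'
#' @param network An igraph gene network.
#' @param v A gene identifier.
#' @param path_mode `"hop"` or `"inverse-weight"`.
#' @return Scalar B in `[0, 1]`.
#' @export
betweenness_centrality <- function(network, v,
                                   path_mode = c("hop", "inverse-weight")) {
  path_mode <- match.arg(path_mode)
  nm <- igraph::V(network)$name
  focal <- match(v, nm)
  if (is.na(focal)) stop("gene not in network: ", v)
  n <- igraph::vcount(network)
  if (n < 3L || igraph::degree(network, v) == 0L) return(0)
  if (path_mode == "hop") {
    ends <- igraph::ends(network, igraph::E(network), names = FALSE)
    counts <- geodesic_counts_through(n, ends - 1L, focal - 1L)
    g_tot <- counts[1L]
    g_v <- counts[2L]
    return(if (g_tot > 0) g_v / g_tot else 0)
  }
  # inverse-weight mode: weighted geodesic counts per source via igraph
  wts <- 1 / igraph::E(network)$weight
  d <- igraph::distances(network, weights = wts)
  sig <- matrix(0, n, n)
  for (s_idx in seq_len(n)) {
    asp <- igraph::all_shortest_paths(network, from = s_idx, weights = wts)
    sig[s_idx, ] <- asp$nrgeo
  }
  tol <- 1e-9
  g_tot <- 0
  g_v <- 0
  for (s_idx in seq_len(n - 1L)) {
    for (t_idx in (s_idx + 1L):n) {
      if (!is.finite(d[s_idx, t_idx])) next
      g_tot <- g_tot + sig[s_idx, t_idx]
      if (s_idx != focal && t_idx != focal &&
          is.finite(d[s_idx, focal]) && is.finite(d[focal, t_idx]) &&
          abs(d[s_idx, focal] + d[focal, t_idx] - d[s_idx, t_idx]) < tol) {
        g_v <- g_v + sig[s_idx, focal] * sig[focal, t_idx]
      }
    }
  }
  if (g_tot > 0) g_v / g_tot else 0
}

#' Fusion-centrality baseline score
#'
#' Merges the partner pair into a burden node (see [merge_partners()]) on
#' the original network — the baselines are defined independently of the
#' stability machinery — and returns the burden node's weighted degree
#' (`"DEG"`) or shortest-path betweenness (`"BET"`). If both partners are
#' absent from the network the score is 0 with a warning.
#'
#' @inheritParams merge_partners
#' @inheritParams betweenness_centrality
#' @param method `"DEG"` or `"BET"`.
#' @return Scalar centrality score of the burden node.
#' @export
baseline_fusion_score <- function(network, i, j, method = c("DEG", "BET"),
                                  merge_policy = c("max", "sum"),
                                  path_mode = c("hop", "inverse-weight")) {
  method <- match.arg(method)
  nm <- igraph::V(network)$name
  if (!(i %in% nm) && !(j %in% nm)) {
    warning("both partners absent from the network; score 0 for ",
            i, "--", j)
    return(0)
  }
  burden <- paste0(i, "+", j)
  merged <- merge_partners(network, i, j, merge_policy = merge_policy,
                           merged_name = burden)
  if (method == "DEG") {
    degree_centrality(merged, burden)
  } else {
    betweenness_centrality(merged, burden, path_mode = path_mode)
  }
}
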