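#' Significance of one fusion from its partners' importances
#'
#' `S(f) = (1 + w_ij) * (H_i + H_j)`: partner importances are added, then
#' amplified by the interaction tendency between the partners. A missing
#' edge contributes `w_ij = 0` (multiplier 1), the natural zero of the
#' formula.
#'
#' @param h_i,h_j Importance scores of the two partner genes.
#' @param w_ij Edge weight between the partners in `[0, 1]`; 0 when no edge
#'   joins them.
#' @return Scalar significance S.
#' @export
#' @examples
#' fusion_significance(0.2, 0.3, 0.5)  # 1.5 * 0.5 = 0.75
fusion_significance <- function(h_i, h_j, w_ij) {
  stopifnot(all(w_ij >= 0), all(w_ij <= 1))
  (1 + w_ij) * (h_i + h_j)
}

#' Canonicalize fusion partner pairs
#'
#' Sorts each pair so `partner_a <= partner_b` and rejects self-fusions.
#'
#' @param fusions Data frame with columns `partner_a`, `partner_b` and
#'   optionally `label`.
#' @return The canonicalized data frame with an added `fusion` name column
#'   (`"A--B"`).
#' @keywords internal
canonical_fusions <- function(fusions) {
  fusions <- as.data.frame(fusions)
  if (nrow(fusions) == 0L) stop("no fusions supplied")
  if (!all(c("partner_a", "partner_b") %in% names(fusions))) {
    names(fusions)[1:2] <- c("partner_a", "partner_b")
  }
  a <- as.character(fusions$partner_a)
  b <- as.character(fusions$partner_b)
  if (any(a == b)) {
    stop("self-fusion (identical partners) at row ", which(a == b)[1L])
  }
  out <- fusions
  out$partner_a <- pmin(a, b)
  out$partner_b <- pmax(a, b)
  out$fusion <- paste(out$partner_a, out$partner_b, sep = "--")
  out
}

#' Score and rank fusions from an importance table
#'
#' Applies [fusion_significance()] to every fusion, resolving each partner's
#' H from `importances` (genes missing from the table contribute `H = 0`)
#' and the partner-pair edge weight from `network`. By default the weight is
#' read from the original, pre-stabilization network: the biological
#' interaction tendency of the partners is not something the stability
#' filter should erase. Results are sorted by descending S, ties broken by
#' canonical fusion name, and ranked 1..N.
#'
#' @param fusions Data frame with columns `partner_a`, `partner_b`, and
#'   optionally `label` (1 = susceptible, 0 = ordinary). Duplicate fusions
#'   (as unordered pairs) are an error.
#' @param importances An [importance_table()] result, or any data frame with
#'   columns `gene` and `H`.
#' @param network The igraph network from which the partner edge weight
#'   `w_ij` is looked up; use the original input network (default behaviour
#'   of the pipeline) or a stabilized one.
#' @return Data frame of class `fusion_scores` with columns `partner_a`,
#'   `partner_b`, `fusion`, `S`, `rank`, `algorithm` (`"SYN"`) and `label`
#'   when supplied.
#' @export
rank_fusions <- function(fusions, importances, network) {
  fus <- canonical_fusions(fusions)
  if (anyDuplicated(fus$fusion)) {
    stop("duplicate fusion in input: ", fus$fusion[duplicated(fus$fusion)][1L])
  }
  h <- stats::setNames(importances$H, importances$gene)
  h_a <- unname(h[fus$partner_a])
  h_b <- unname(h[fus$partner_b])
  h_a[is.na(h_a)] <- 0
  h_b[is.na(h_b)] <- 0
  w <- partner_edge_weights(network, fus$partner_a, fus$partner_b)
  fus$S <- fusion_significance(h_a, h_b, w)
  finalize_fusion_ranks(fus, "SYN")
}

#' Edge weights between partner pairs (0 when absent)
#' @keywords internal
partner_edge_weights <- function(network, a, b) {
  nm <- igraph::V(network)$name
  w <- numeric(length(a))
  ok <- a %in% nm & b %in% nm
  if (any(ok)) {
    vp <- rbind(a[ok], b[ok])
    eids <- igraph::get_edge_ids(network, as.vector(vp))
    has <- eids > 0
    w_ok <- numeric(sum(ok))
    w_ok[has] <- igraph::E(network)$weight[eids[has]]
    w[ok] <- w_ok
  }
  w
}

#' Order by descending score, tie-break by fusion name, assign ranks
#' @keywords internal
finalize_fusion_ranks <- function(fus, algorithm) {
  ord <- order(-fus$S, fus$fusion)
  fus <- fus[ord, , drop = FALSE]
  fus$rank <- seq_len(nrow(fus))
  fus$algorithm <- algorithm
  rownames(fus) <- NULL
  keep <- c("partner_a", "partner_b", "fusion", "S", "rank", "algorithm",
            intersect("label", names(fus)))
  fus <- fus[, keep, drop = FALSE]
  class(fus) <- c("fusion_scores", "data.frame")
  fus
}

#' Score fusions with any of the three algorithms
#'
#' Unified front end: `"SYN"` ranks fusions by partner importances from the
#' synchronous-stability destructiveness score; `"DEG"` and `"BET"` rank
#' them by the weighted degree / betweenness centrality of the merged burden
#' node (see [baseline_fusion_score()]).
#'
#' @inheritParams rank_fusions
#' @param network The original igraph gene network.
#' @param algorithm One of `"SYN"`, `"DEG"`, `"BET"`.
#' @param importances Optional precomputed [importance_table()] (SYN only);
#'   computed from `network` when `NULL`.
#' @param s Coupling factor for stabilization (SYN only).
#' @param lambda2_mode Laplacian mode for stabilization (SYN only).
#' @param merge_policy Overlapped-edge policy for burden-node merging
#'   (DEG/BET only); see [merge_partners()].
#' @param path_mode Shortest-path metric for BET; see
#'   [betweenness_centrality()].
#' @return A `fusion_scores` data frame (see [rank_fusions()]).
#' @export
score_fusions <- function(fusions, network,
                          algorithm = c("SYN", "DEG", "BET"),
                          importances = NULL, s = 0.28,
                          lambda2_mode = c("weighted", "unweighted"),
                          merge_policy = c("max", "sum"),
                          path_mode = c("hop", "inverse-weight")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "SYN") {
    if (is.null(importances)) {
      importances <- importance_table(network, s = s,
                                      lambda2_mode = lambda2_mode)
    }
    return(rank_fusions(fusions, importances, network))
  }
  merge_policy <- match.arg(merge_policy)
  path_mode <- match.arg(path_mode)
  fus <- canonical_fusions(fusions)
  if (anyDuplicated(fus$fusion)) {
    stop("duplicate fusion in input: ", fus$fusion[duplicated(fus$fusion)][1L])
  }
  fus$S <- vapply(seq_len(nrow(fus)), function(i) {
    baseline_fusion_score(network, fus$partner_a[i], fus$partner_b[i],
                          method = algorithm, merge_policy = merge_policy,
                          path_mode = path_mode)
  }, numeric(1))
  finalize_fusion_ranks(fus, algorithm)
}

#' Write fusion scores as TSV
#' @param scores A `fusion_scores` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fusion_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
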