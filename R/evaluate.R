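#' Interval distribution of susceptible fusions over the ranking
#'
#' The descending ranking of `N_f` fusions is divided into 10 intervals
#' `I_i = ((i-1)/10 * N_f, i/10 * N_f]`. For each interval the number of
#' susceptible (label 1) fusions whose rank falls inside is counted; with
#' the half-open bracket, a rank sitting exactly on a boundary belongs to
#' the lower-indexed interval. When `N_f` is not a multiple of 10 the
#' interval edges are real-valued and integer ranks are compared against
#' them directly.
#'
#' @param scores A `fusion_scores` data frame with columns `rank` and
#'   `label`; ranks must be the permutation `1..N_f`.
#' @return Named integer vector of length 10 (`I1`..`I10`); its sum is the
#'   number of susceptible fusions.
#' @export
interval_distribution <- function(scores) {
  if (!all(c("rank", "label") %in% names(scores))) {
    stop("scores need `rank` and `label` columns")
  }
  n_f <- nrow(scores)
  if (!setequal(scores$rank, seq_len(n_f))) {
    stop("ranks must be a permutation of 1..N_f")
  }
  ranks <- scores$rank[scores$label == 1L]
  counts <- vapply(1:10, function(i) {
    sum(ranks > (i - 1) / 10 * n_f & ranks <= i / 10 * n_f)
  }, integer(1))
  stats::setNames(counts, paste0("I", 1:10))
}

#' Cumulative recognition rate P(i)
#'
#' `P(i) = f(R(i)) / N_i`, the fraction of all susceptible fusions found
#' within the top `i/10` of the ranking, i.e. the cumulative sum of the
#' interval counts divided by the number of susceptible fusions. `P` is
#' non-decreasing and `P(10) = 1`.
#'
#' @param counts Interval counts from [interval_distribution()].
#' @param n_i Number of susceptible fusions (> 0).
#' @param i Interval index or vector of indices in `1..10` (default all).
#' @return Numeric vector of recognition rates.
#' @export
recognition_rate <- function(counts, n_i, i = 1:10) {
  if (n_i <= 0L) stop("recognition rate undefined for N_i = 0")
  stopifnot(all(i >= 1L), all(i <= 10L))
  unname(cumsum(counts)[i]) / n_i
}

#' ROC curve and AUC of a fusion ranking
#'
#' Turns the scored ranking into a binary classifier by sweeping a
#' classification boundary over the distinct significance values in
#' descending order; fusions above the boundary are called susceptible.
#' Tied scores are processed as a single threshold step. The area under the
#' curve is computed by the trapezoidal rule, which makes it equal to the
#' Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores A `fusion_scores` data frame with columns `S` and `label`;
#'   both labels must be present.
#' @return A list with `roc` (data frame of `fpr`, `tpr` points, including
#'   the (0,0) and (1,1) anchors) and `auc`.
#' @export
roc_and_auc <- function(scores) {
  if (!all(c("S", "label") %in% names(scores))) {
    stop("scores need `S` and `label` columns")
  }
  lab <- as.integer(scores$label)
  if (length(unique(lab)) < 2L) {
    stop("ROC undefined with a single class")
  }
  ord <- order(-scores$S)
  s_sorted <- scores$S[ord]
  lab_sorted <- lab[ord]
  pos <- sum(lab_sorted)
  neg <- length(lab_sorted) - pos
  tp <- cumsum(lab_sorted)
  fp <- cumsum(1L - lab_sorted)
  # keep the last index of each run of tied scores: one step per threshold
  boundary <- c(s_sorted[-1L] != s_sorted[-length(s_sorted)], TRUE)
  tpr <- c(0, tp[boundary] / pos)
  fpr <- c(0, fp[boundary] / neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate one scored dataset
#'
#' Bundles the three evaluation criteria for a scored, labeled fusion
#' ranking: interval counts, recognition rates and ROC/AUC.
#'
#' @param scores A labeled `fusion_scores` data frame.
#' @return A list of class `evaluation_result` with `counts`, `P`, `roc`,
#'   `auc`, `n_f`, `n_i` and `algorithm`.
#' @export
evaluate_scores <- function(scores) {
  counts <- interval_distribution(scores)
  n_i <- sum(scores$label == 1L)
  roc <- roc_and_auc(scores)
  structure(list(counts = counts,
                 P = recognition_rate(counts, n_i),
                 roc = roc$roc,
                 auc = roc$auc,
                 n_f = nrow(scores),
                 n_i = n_i,
                 algorithm = scores$algorithm[1L]),
            class = "evaluation_result")
}
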