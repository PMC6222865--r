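#' Configuration for a benchmark experiment grid
#'
#' The default grid reproduces the benchmark design: total fusion counts
#' `N_f` in {150, 200, 250} crossed with susceptible counts `N_i` in
#' {15, 25}, 20 randomly sampled datasets per configuration — 120 datasets
#' in all — each scored by the SYN, DEG and BET algorithms. All datasets of
#' one run are sampled from a single gene network: either a supplied one or
#' a synthetic network generated from `network_spec` (the default spec is
#' sized so the largest configuration's `2 * N_o` ordinary partner draw is
#' feasible). The susceptible partner pool is the planted gene list; the
#' ordinary partner pool is the whole gene set, so pool overlap — and the
#' duplicate-fusion re-draw — can genuinely occur.
#'
#' @param n_f_grid,n_i_grid Integer vectors of dataset sizes.
#' @param replicates Datasets per (N_f, N_i) cell.
#' @param algorithms Subset of `c("SYN", "DEG", "BET")`.
#' @param network,susceptible Optional igraph network and its susceptible
#'   gene list; both or neither.
#' @param network_spec A [synthetic_network_spec()] used when `network` is
#'   `NULL`; its seed is rederived from `seed`.
#' @param s,lambda2_mode Stabilization settings for SYN.
#' @param merge_policy,path_mode Baseline settings for DEG/BET.
#' @param seed Master seed; every dataset's draws use child seeds derived
#'   from it.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_f_grid = c(150L, 200L, 250L),
                             n_i_grid = c(15L, 25L),
                             replicates = 20L,
                             algorithms = c("SYN", "DEG", "BET"),
                             network = NULL, susceptible = NULL,
                             network_spec = synthetic_network_spec(
                               n_genes = 700, susceptible_fraction = 0.15),
                             s = 0.28,
                             lambda2_mode = "weighted",
                             merge_policy = "max",
                             path_mode = "hop",
                             seed = 1L) {
  algorithms <- match.arg(algorithms, c("SYN", "DEG", "BET"),
                          several.ok = TRUE)
  if (is.null(network) != is.null(susceptible)) {
    stop("supply `network` and `susceptible` together, or neither")
  }
  structure(list(n_f_grid = as.integer(n_f_grid),
                 n_i_grid = as.integer(n_i_grid),
                 replicates = as.integer(replicates),
                 algorithms = algorithms,
                 network = network, susceptible = susceptible,
                 network_spec = network_spec,
                 s = s, lambda2_mode = lambda2_mode,
                 merge_policy = merge_policy, path_mode = path_mode,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run the benchmark experiment grid
#'
#' For every `(N_f, N_i)` cell and replicate, samples a labeled fusion
#' dataset from the run's gene network, scores it with each configured
#' algorithm and computes the evaluation metrics (interval counts,
#' recognition rates, AUC). The SYN importance table is computed once per
#' run and shared by all datasets. A failure in one dataset is recorded and
#' does not abort the grid.
#'
#' @param config A [benchmark_config()].
#' @param quiet Suppress per-cell progress messages.
#' @return A list of class `fusion_benchmark` with
#'   \describe{
#'     \item{results}{long data frame: `n_f`, `n_i`, `replicate`,
#'       `algorithm`, `metric`, `value` (metrics `I1..I10`, `P1..P10`,
#'       `auc`).}
#'     \item{summary}{per-configuration means over replicates.}
#'     \item{n_datasets}{number of datasets sampled.}
#'     \item{errors}{data frame of per-dataset failures (zero rows when
#'       clean).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
run_experiment_grid <- function(config = benchmark_config(), quiet = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  if (is.null(config$network)) {
    spec <- config$network_spec
    spec$seed <- derive_seed(config$seed, 0L)
    gen <- generate_synthetic_network(spec)
    network <- gen$network
    susceptible <- gen$susceptible
  } else {
    network <- config$network
    susceptible <- config$susceptible
  }
  all_genes <- igraph::V(network)$name
  imp <- NULL
  if ("SYN" %in% config$algorithms) {
    if (!quiet) message("computing SYN importance table (",
                        length(all_genes), " genes) ...")
    imp <- suppressWarnings(
      importance_table(network, s = config$s,
                       lambda2_mode = config$lambda2_mode)
    )
  }
  grid <- expand.grid(n_i = config$n_i_grid, n_f = config$n_f_grid,
                      KEEP.OUT.ATTRS = FALSE)
  results <- list()
  errors <- list()
  n_datasets <- 0L
  for (cell in seq_len(nrow(grid))) {
    n_f <- grid$n_f[cell]
    n_i <- grid$n_i[cell]
    if (!quiet) message("cell N_f=", n_f, " N_i=", n_i)
    for (rep_i in seq_len(config$replicates)) {
      ds_seed <- derive_seed(config$seed, cell, rep_i)
      res <- tryCatch({
        ds <- sample_fusion_dataset(susceptible, all_genes,
                                    dataset_spec(n_f, n_i, seed = ds_seed))
        n_datasets <- n_datasets + 1L
        lapply(config$algorithms, function(alg) {
          sc <- score_fusions(ds, network, algorithm = alg,
                              importances = imp, s = config$s,
                              merge_policy = config$merge_policy,
                              path_mode = config$path_mode)
          ev <- evaluate_scores(sc)
          data.frame(n_f = n_f, n_i = n_i, replicate = rep_i,
                     algorithm = alg,
                     metric = c(paste0("I", 1:10), paste0("P", 1:10), "auc"),
                     value = c(as.numeric(ev$counts), ev$P, ev$auc),
                     stringsAsFactors = FALSE)
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          n_f = n_f, n_i = n_i, replicate = rep_i,
          message = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        results <- c(results, res)
      }
    }
  }
  results <- if (length(results) > 0L) do.call(rbind, results) else
    data.frame(n_f = integer(0), n_i = integer(0), replicate = integer(0),
               algorithm = character(0), metric = character(0),
               value = numeric(0))
  errors <- if (length(errors) > 0L) do.call(rbind, errors) else
    data.frame(n_f = integer(0), n_i = integer(0), replicate = integer(0),
               message = character(0))
  summary <- stats::aggregate(value ~ n_f + n_i + algorithm + metric,
                              data = results, FUN = mean)
  summary <- summary[order(summary$n_f, summary$n_i, summary$algorithm,
                           summary$metric), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 n_datasets = n_datasets, errors = errors, config = config),
            class = "fusion_benchmark")
}

#' @export
print.fusion_benchmark <- function(x, ...) {
  cat("Fusion benchmark:", x$n_datasets, "dataset(s),",
      length(unique(x$results$algorithm)), "algorithm(s)\n")
  auc <- x$summary[x$summary$metric == "auc", , drop = FALSE]
  if (nrow(auc) > 0L) {
    cat("Mean AUC per configuration:\n")
    print.data.frame(auc[, c("n_f", "n_i", "algorithm", "value")],
                     row.names = FALSE, digits = 3)
  }
  if (nrow(x$errors) > 0L) {
    cat(nrow(x$errors), "dataset(s) failed\n")
  }
  invisible(x)
}
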