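#' Specification for a synthetic gene network
#'
#' The generator emulates the structural premise of fusion-driver
#' benchmarking: susceptible ("planted") genes are the network-important
#' ones. Planted genes are organized into dense, high-weight modules whose
#' members are heavily interconnected; consecutive modules are linked into a
#' chain by single moderate-weight bridge edges, keeping the backbone's
#' algebraic connectivity low. Background genes attach to the network by one
#' weak edge each. Under the synchronous-stability filter this yields a
#' backbone of planted modules that survives stabilization while the
#' background periphery — degree-1 leaves hanging off module genes — is
#' stripped; planted genes have stochastically larger weighted degree than
#' background genes by construction.
#'
#' @param n_genes Total number of genes.
#' @param susceptible_fraction Fraction of genes planted as susceptible,
#'   in (0, 1).
#' @param module_size Target module size for planted genes (remainder genes
#'   are spread over the modules).
#' @param intra_module_prob Probability that two genes of the same module
#'   are connected (the module edge density), in (0, 1).
#' @param intra_weight,bridge_weight,background_weight Length-2 Beta shape
#'   parameters for intra-module, bridge and background edge weights.
#'   Defaults give means of about 0.75, 0.30 and 0.07 respectively.
#' @param background_degree Number of weak attachment edges per background
#'   gene (default 1).
#' @param seed Integer seed making the network reproducible.
#' @return A list of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(n_genes = 200,
                                   susceptible_fraction = 0.15,
                                   module_size = 10,
                                   intra_module_prob = 0.9,
                                   intra_weight = c(12, 4),
                                   bridge_weight = c(12, 28),
                                   background_weight = c(2, 28),
                                   background_degree = 1,
                                   seed = 1L) {
  if (!(susceptible_fraction > 0 && susceptible_fraction < 1)) {
    stop("susceptible_fraction must be strictly inside (0, 1)")
  }
  if (!(intra_module_prob > 0 && intra_module_prob < 1)) {
    stop("intra_module_prob must be strictly inside (0, 1)")
  }
  n_planted <- round(n_genes * susceptible_fraction)
  if (n_planted < module_size) {
    stop("infeasible spec: fewer planted genes (", n_planted,
         ") than one module (", module_size, ")")
  }
  if (n_planted >= n_genes) stop("no background genes left")
  structure(list(n_genes = as.integer(n_genes),
                 susceptible_fraction = susceptible_fraction,
                 n_planted = as.integer(n_planted),
                 module_size = as.integer(module_size),
                 intra_module_prob = intra_module_prob,
                 intra_weight = intra_weight,
                 bridge_weight = bridge_weight,
                 background_weight = background_weight,
                 background_degree = as.integer(background_degree),
                 seed = as.integer(seed)),
            class = "synthetic_network_spec")
}

#' Generate a synthetic gene network with planted susceptible genes
#'
#' @param spec A [synthetic_network_spec()].
#' @return A list with `network` (igraph gene network), `susceptible`
#'   (character vector of planted genes) and `spec`. Identical specs yield
#'   identical networks.
#' @export
generate_synthetic_network <- function(spec = synthetic_network_spec()) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  set.seed(spec$seed)
  genes <- sprintf("G%05d", seq_len(spec$n_genes))
  planted <- sort(sample(genes, spec$n_planted))
  background <- setdiff(genes, planted)

  # partition planted genes into chained modules
  k <- spec$n_planted %/% spec$module_size
  sizes <- rep(spec$n_planted %/% k, k)
  extra <- spec$n_planted - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  modules <- split(sample(planted), rep(seq_len(k), times = sizes))

  rw <- function(n, shape) stats::rbeta(n, shape[1L], shape[2L])
  ea <- character(0); eb <- character(0); ew <- numeric(0)

  for (mod in modules) {
    prs <- utils::combn(sort(mod), 2L)
    pick <- stats::runif(ncol(prs)) < spec$intra_module_prob
    if (any(pick)) {
      ea <- c(ea, prs[1L, pick])
      eb <- c(eb, prs[2L, pick])
      ew <- c(ew, rw(sum(pick), spec$intra_weight))
    }
  }
  if (k > 1L) {
    for (ci in seq_len(k - 1L)) {
      a <- sample(modules[[ci]], 1L)
      b <- sample(modules[[ci + 1L]], 1L)
      ea <- c(ea, a); eb <- c(eb, b)
      ew <- c(ew, rw(1L, spec$bridge_weight))
    }
  }
  # weak periphery: each background gene hangs off randomly chosen planted
  # (module) genes, one leaf edge per attachment
  for (bg in background) {
    targets <- sample(planted, spec$background_degree)
    ea <- c(ea, rep(bg, length(targets))); eb <- c(eb, targets)
    ew <- c(ew, rw(length(targets), spec$background_weight))
  }
  net <- gene_network(data.frame(gene_a = ea, gene_b = eb, weight = ew,
                                 stringsAsFactors = FALSE),
                      nodes = genes)
  list(network = net, susceptible = planted, spec = spec)
}

#' Specification of one fusion dataset
#'
#' `n_f = n_i + n_o` total fusions: `n_i` susceptible fusions assembled from
#' `2 * n_i` susceptible partner genes and `n_o` ordinary fusions from
#' `2 * n_o` common partner genes, each drawn without replacement.
#'
#' @param n_f Total number of fusions.
#' @param n_i Number of susceptible (positive-label) fusions; `n_i <= n_f`.
#' @param seed Master seed for the dataset's random draws.
#' @return A list of class `dataset_spec` with fields `n_f`, `n_i`, `n_o`
#'   and `seed`.
#' @export
dataset_spec <- function(n_f, n_i, seed = 1L) {
  n_f <- as.integer(n_f); n_i <- as.integer(n_i)
  if (n_i < 1L || n_i > n_f) stop("need 1 <= n_i <= n_f")
  structure(list(n_f = n_f, n_i = n_i, n_o = n_f - n_i,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Derive an independent child seed from a master seed
#'
#' A cheap deterministic hash keeping results below 2^31, so that each
#' random process (the susceptible draw, the ordinary draw, every ordinary
#' re-draw, every replicate) gets its own seed reset.
#'
#' @param master Integer master seed.
#' @param ... Integers naming the stream (stage index, replicate, attempt).
#' @return A positive integer seed.
#' @keywords internal
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), as.numeric(c(...)))
  h <- 104729
  for (p in parts) h <- (h * 69091 + (p %% 2038074743) + 1) %% 2038074743
  as.integer(h + 1)
}

#' Sample one labeled fusion dataset
#'
#' Draws `2 * n_i` partner genes from the susceptible pool without
#' replacement and pairs them into `n_i` susceptible fusions, then draws
#' `2 * n_o` partner genes from the background pool without replacement and
#' pairs them into `n_o` ordinary fusions. The random seed is reset (to a
#' derived child seed) before each random process. If any ordinary fusion
#' duplicates a susceptible fusion — possible when the pools overlap, as
#' they do when ordinary partners are drawn from the whole network — the
#' entire ordinary draw is redone until no duplication remains.
#'
#' @param susceptible_pool Character vector of susceptible genes
#'   (`length >= 2 * n_i`).
#' @param background_pool Character vector of common genes
#'   (`length >= 2 * n_o`); may overlap the susceptible pool.
#' @param spec A [dataset_spec()].
#' @param max_attempts Cap on ordinary re-draws (default 1000).
#' @return Data frame with columns `partner_a`, `partner_b` (canonical
#'   order), `fusion` and `label` (1 susceptible / 0 ordinary). No fusion
#'   appears twice.
#' @export
sample_fusion_dataset <- function(susceptible_pool, background_pool, spec,
                                  max_attempts = 1000L) {
  stopifnot(inherits(spec, "dataset_spec"))
  susceptible_pool <- unique(as.character(susceptible_pool))
  background_pool <- unique(as.character(background_pool))
  if (length(susceptible_pool) < 2L * spec$n_i) {
    stop("susceptible pool too small: need ", 2L * spec$n_i, " genes, have ",
         length(susceptible_pool))
  }
  if (length(background_pool) < 2L * spec$n_o) {
    stop("background pool too small: need ", 2L * spec$n_o, " genes, have ",
         length(background_pool))
  }
  pair_up <- function(partners) {
    n2 <- length(partners)
    a <- partners[seq(1L, n2, by = 2L)]
    b <- partners[seq(2L, n2, by = 2L)]
    data.frame(partner_a = pmin(a, b), partner_b = pmax(a, b),
               stringsAsFactors = FALSE)
  }
  set.seed(derive_seed(spec$seed, 1L))
  sus <- pair_up(sample(susceptible_pool, 2L * spec$n_i))
  sus$fusion <- paste(sus$partner_a, sus$partner_b, sep = "--")
  ord <- NULL
  if (spec$n_o > 0L) {
    for (attempt in seq_len(max_attempts)) {
      set.seed(derive_seed(spec$seed, 2L, attempt))
      cand <- pair_up(sample(background_pool, 2L * spec$n_o))
      cand$fusion <- paste(cand$partner_a, cand$partner_b, sep = "--")
      if (!any(cand$fusion %in% sus$fusion)) {
        ord <- cand
        break
      }
    }
    if (is.null(ord)) {
      stop("could not draw an ordinary fusion set free of susceptible ",
           "duplicates in ", max_attempts, " attempts")
    }
  } else {
    ord <- sus[0, , drop = FALSE]
  }
  sus$label <- 1L
  ord$label <- 0L
  out <- rbind(sus, ord)
  rownames(out) <- NULL
  out
}
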