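#' Build a validated gene network
#'
#' A gene network is an undirected, simple [igraph][igraph::igraph] graph
#' whose vertices are gene identifiers (opaque, case-sensitive strings) and
#' whose edges carry a `weight` attribute in `[0, 1]`, interpreted as the
#' probability that the two genes work together (interaction tendency).
#' Self-loops and duplicate unordered pairs are rejected; isolated genes are
#' allowed.
#'
#' @param edges A data frame (or coercible) whose first three columns are
#'   `gene_a`, `gene_b` and `weight`. May have zero rows.
#' @param nodes Optional character vector of gene identifiers. Must contain
#'   every edge endpoint; extra identifiers become isolated vertices.
#' @param validate If `FALSE`, skip the weight-range check (useful for toy
#'   graphs with illustrative weights outside `[0, 1]`). Structural checks
#'   (self-loops, duplicates) always run.
#'
#' @return An igraph object with vertex attribute `name` and edge attribute
#'   `weight`.
#' @export
#' @examples
#' g <- gene_network(data.frame(gene_a = c("A", "B"),
#'                              gene_b = c("B", "C"),
#'                              weight = c(0.5, 0.2)))
#' igraph::vcount(g)
gene_network <- function(edges, nodes = NULL, validate = TRUE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3L && nrow(edges) > 0L) {
    stop("`edges` must have columns gene_a, gene_b, weight")
  }
  if (nrow(edges) > 0L) {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    w <- as.numeric(edges[[3L]])
    if (anyNA(a) || anyNA(b) || any(a == "") || any(b == "")) {
      stop("missing gene identifier in edge list")
    }
    if (anyNA(w)) stop("non-numeric edge weight in edge list")
    if (any(a == b)) {
      stop("self-loop forbidden: ", a[which(a == b)[1L]])
    }
    if (validate && (any(w < 0) || any(w > 1))) {
      bad <- which(w < 0 | w > 1)[1L]
      stop("edge weight outside [0, 1]: ", a[bad], "-", b[bad], " = ", w[bad])
    }
    key <- edge_key(a, b)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1L]
      stop("duplicate unordered gene pair in edge list: ", dup)
    }
  } else {
    a <- character(0); b <- character(0); w <- numeric(0)
  }
  verts <- unique(c(a, b))
  if (!is.null(nodes)) {
    nodes <- as.character(nodes)
    if (!all(verts %in% nodes)) {
      stop("`nodes` is missing edge endpoints: ",
           paste(utils::head(setdiff(verts, nodes), 5L), collapse = ", "))
    }
    verts <- nodes
  }
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
}

#' Canonical key for an unordered gene pair
#' @param a,b Character vectors of gene identifiers.
#' @return Character vector, one key per pair, invariant to order.
#' @keywords internal
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read a weighted edge-list TSV as a gene network
#'
#' The file is tab-separated with columns `gene_a`, `gene_b`, `weight`.
#' A header line is auto-detected (non-numeric third field); lines starting
#' with `#` and blank lines are ignored. Malformed rows raise an error that
#' names the offending line.
#'
#' @param path Path to the edge-list file.
#' @inheritParams gene_network
#' @return An igraph gene network (see [gene_network()]).
#' @export
read_gene_network <- function(path, nodes = NULL, validate = TRUE) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(gene_network(data.frame(gene_a = character(0),
                                   gene_b = character(0),
                                   weight = numeric(0)),
                        nodes = nodes))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("malformed row (need 3 tab-separated fields) at line ", bad)
  }
  first <- fields[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3L])))
  if (has_header) {
    fields <- fields[-1L]
    idx <- idx[-1L]
    if (length(fields) == 0L) {
      return(gene_network(data.frame(gene_a = character(0),
                                     gene_b = character(0),
                                     weight = numeric(0)),
                          nodes = nodes))
    }
  }
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(w)) {
    stop("non-numeric weight at line ", idx[which(is.na(w))[1L]])
  }
  gene_network(data.frame(gene_a = a, gene_b = b, weight = w,
                          stringsAsFactors = FALSE),
               nodes = nodes, validate = validate)
}

#' Write a gene network as an edge-list TSV
#'
#' Emits `gene_a  gene_b  weight` with a header, one row per unordered pair,
#' sorted lexicographically for deterministic output.
#'
#' @param network An igraph gene network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_network <- function(network, path) {
  df <- igraph::as_data_frame(network, what = "edges")
  if (nrow(df) > 0L) {
    a <- pmin(df$from, df$to)
    b <- pmax(df$from, df$to)
    df <- data.frame(gene_a = a, gene_b = b, weight = df$weight,
                     stringsAsFactors = FALSE)
    df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  } else {
    df <- data.frame(gene_a = character(0), gene_b = character(0),
                     weight = numeric(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene list (one identifier per line)
#' @param path Path to the file; `#` comments and blank lines are skipped.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines[!grepl("^(#|$)", lines)]
}

#' Read fusion partner pairs from a TSV
#'
#' Columns `partner_a`, `partner_b` and an optional third `label` column
#' (1 = susceptible, 0 = ordinary). Header auto-detected on the label column;
#' files without labels must carry a header naming the two columns or be
#' plain two-column rows.
#'
#' @param path Path to the fusion-pair file.
#' @return Data frame with columns `partner_a`, `partner_b` and, when
#'   present, `label`.
#' @export
read_fusion_pairs <- function(path) {
  if (!file.exists(path)) stop("fusion file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  # header row if the first row's last column is not interpretable as 0/1
  # and the first two fields look like column names
  if (ncol(df) >= 3L) {
    if (is.na(suppressWarnings(as.numeric(df[1L, 3L])))) {
      df <- df[-1L, , drop = FALSE]
    }
    out <- data.frame(partner_a = as.character(df[[1L]]),
                      partner_b = as.character(df[[2L]]),
                      label = as.integer(df[[3L]]),
                      stringsAsFactors = FALSE)
  } else {
    if (identical(tolower(df[1L, 1L]), "partner_a")) {
      df <- df[-1L, , drop = FALSE]
    }
    out <- data.frame(partner_a = as.character(df[[1L]]),
                      partner_b = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Connected components of a gene network
#'
#' @param network An igraph gene network.
#' @return A list of igraph subgraphs, one per connected component (single
#'   nodes included). The list is named by an arbitrary but deterministic
#'   component index; the union of vertex sets partitions the input's.
#' @export
network_components <- function(network) {
  comp <- igraph::components(network)
  lapply(seq_len(comp$no), function(ci) {
    igraph::induced_subgraph(network,
                             which(comp$membership == ci))
  })
}

#' Number of connected components
#' @param network An igraph gene network.
#' @return Integer count of connected subgraphs (singletons included).
#' @export
n_components <- function(network) {
  igraph::components(network)$no
}

#' Algebraic connectivity of a connected component
#'
#' The second-smallest eigenvalue of the graph Laplacian
#' (0 = lambda_1 <= lambda_2 <= ... <= lambda_n). In `weighted` mode the
#' Laplacian entries are the edge weights; in `unweighted` mode the 0/1
#' adjacency is used. Strictly positive iff the graph is connected.
#'
#' @param component An igraph graph with at least 2 vertices; expected to be
#'   a single connected component.
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @return The scalar algebraic connectivity lambda_2.
#' @export
#' @examples
#' p3 <- gene_network(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                               w = c(1, 1)), validate = FALSE)
#' algebraic_connectivity(p3)  # path graph: eigenvalues {0, 1, 3}
algebraic_connectivity <- function(component,
                                   mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(component)
  if (n < 2L) {
    stop("algebraic connectivity is undefined for a single-node component ",
         "(singletons are trivially stable)")
  }
  if (mode == "unweighted" && "weight" %in%
        igraph::edge_attr_names(component)) {
    component <- igraph::delete_edge_attr(component, "weight")
  }
  L <- igraph::laplacian_matrix(component)
  vals <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  # eigen() returns values in decreasing order
  vals[n - 1L]
}
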