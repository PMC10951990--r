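#' Gene interaction network
#'
#' A simple undirected graph over gene identifiers. The node order is stable
#' and defines the canonical row order of every matrix used downstream
#' (features, adjacency, scores).
#'
#' @param nodes Character vector of unique gene identifiers. Its order is
#'   preserved and used as the canonical matrix row order.
#' @param edges Two-column character matrix (or data frame) of gene pairs.
#'   Self-loops are dropped and reciprocal/duplicate pairs collapsed; a
#'   message reports how many of each were removed.
#' @return An object of class \code{gene_network} with elements
#'   \code{nodes} (character) and \code{edges} (two-column character matrix,
#'   endpoints sorted within each row, rows unique).
#' @export
gene_network <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  edges <- if (is.null(edges)) matrix(character(), ncol = 2L)
           else as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    if (ncol(edges) < 2L) stop("edges must have two columns")
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  }
  bad <- setdiff(c(edges), nodes)
  if (length(bad))
    stop("edge endpoints not among nodes: ", paste(utils::head(bad, 5), collapse = ", "))
  n_self <- sum(edges[, 1L] == edges[, 2L])
  if (n_self > 0L) {
    message("dropping ", n_self, " self-loop(s)")
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  }
  # canonical orientation, then dedupe (covers reciprocal duplicates)
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  dup <- duplicated(paste(edges[, 1L], edges[, 2L], sep = "\r"))
  if (any(dup)) {
    message("collapsing ", sum(dup), " duplicate edge(s)")
    edges <- edges[!dup, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Read an undirected gene network from an edge-list file
#'
#' Accepts two-column (or three-column; the third, e.g. a weight or SIF
#' interaction type, is ignored) delimited text, tab or comma separated.
#'
#' @param path Path to the edge-list file.
#' @return A \code{\link{gene_network}}.
#' @export
load_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path)
  sep <- detect_delimiter(lines[[1L]])
  parts <- strsplit(lines, sep, fixed = FALSE)
  ncols <- lengths(parts)
  if (any(ncols < 2L))
    stop("edge list needs at least 2 columns (line ", which(ncols < 2L)[1L], ")")
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  nodes <- unique(c(rbind(a, b)))
  gene_network(nodes, cbind(a, b))
}

detect_delimiter <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else "[[:space:]]+"
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Largest connected component of an induced subnetwork
#'
#' Restricts the network to the genes in \code{keep} and returns the largest
#' connected component of the induced subgraph. Size ties are broken in
#' favour of the component containing the lexicographically smallest gene
#' identifier. Node order of the result follows the input network's order.
#'
#' @param net A \code{\link{gene_network}}.
#' @param keep Character vector of gene identifiers to retain.
#' @return A \code{\link{gene_network}} for the selected component.
#' @export
max_connected_subnetwork <- function(net, keep) {
  stopifnot(inherits(net, "gene_network"))
  keep <- intersect(net$nodes, as.character(keep))
  if (length(keep) == 0L) stop("'keep' shares no genes with the network")
  g <- igraph::induced_subgraph(as_igraph(net), keep)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component holding the smallest gene ID
    anchor <- vapply(best, function(k)
      min(igraph::V(g)$name[comp$membership == k]), "")
    best <- best[order(anchor)][1L]
  }
  members <- igraph::V(g)$name[comp$membership == best]
  members <- net$nodes[net$nodes %in% members]
  e <- net$edges
  e <- e[e[, 1L] %in% members & e[, 2L] %in% members, , drop = FALSE]
  gene_network(members, e)
}

#' Sparse adjacency matrix of a gene network
#'
#' @param net A \code{\link{gene_network}}.
#' @return A symmetric sparse 0/1 matrix in the network's node order.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  idx <- match(net$edges, net$nodes)
  i <- idx[seq_len(nrow(net$edges))]
  j <- idx[nrow(net$edges) + seq_len(nrow(net$edges))]
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} where
#' \eqn{\tilde D} is the diagonal degree matrix of \eqn{A + I}. This is the
#' propagation operator applied in every graph-convolution layer.
#'
#' @param net A \code{\link{gene_network}}.
#' @return Symmetric sparse matrix with entries in \[0, 1\]; entry (i, j) is
#'   positive iff i = j or \{i, j\} is an edge.
#' @export
normalize_adjacency <- function(net) {
  A <- adjacency_matrix(net)
  if (nrow(A) == 0L) stop("empty network")
  At <- A + Matrix::Diagonal(nrow(A))
  d_inv_sqrt <- 1 / sqrt(Matrix::rowSums(At))
  Ahat <- Matrix::Diagonal(x = d_inv_sqrt) %*% At %*% Matrix::Diagonal(x = d_inv_sqrt)
  dimnames(Ahat) <- dimnames(A)
  methods::as(Ahat, "CsparseMatrix")
}
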