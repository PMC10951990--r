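# Shared fixtures, all built in code.

# 3-node path a-b-c
path3 <- function() gene_network(c("a", "b", "c"),
                                 rbind(c("a", "b"), c("b", "c")))

# dense brute-force normalized adjacency, independent of the package's
# sparse implementation
dense_norm_adj <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges[r, 1L]; j <- net$edges[r, 2L]
    A[i, j] <- A[i, j] + 1
    A[j, i] <- A[j, i] + 1
  }
  At <- A + diag(n)
  d <- rowSums(At)
  diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
}

# small random connected-ish network with given seed
random_network <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (stats::runif(1) < p) edges <- rbind(edges, c(ids[i], ids[j]))
  if (is.null(edges)) edges <- cbind(ids[1], ids[2])
  gene_network(ids, edges)
}

# minimal coregulation_network without going through the splicing pipeline
make_coreg <- function(nodes, edges = NULL, threshold = 0.3) {
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 weight_threshold = threshold),
            class = "coregulation_network")
}

# psi_matrix from a plain matrix whose rownames are "GENE;CLASS;coords" IDs
make_psi <- function(m, condition = "tumor") {
  psi_matrix(glims:::parse_event_ids(rownames(m)), m, condition)
}

# random labeled score fixture for metric tests
random_scored_labels <- function(n_pos, n_neg, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_pos + n_neg))
  scores <- stats::setNames(stats::runif(n_pos + n_neg), genes)
  labels <- label_set(genes[seq_len(n_pos)], genes[-seq_len(n_pos)], genes)
  list(scores = scores, labels = labels)
}

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
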