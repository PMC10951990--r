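#' Filter configuration for alternative-splicing events
#'
#' Defaults implement the differential-splicing filter used to call an
#' event cancer-informative: expressed (non-missing PSI) in more than half
#' of the tumor samples and present in normal tissue, mean tumor PSI above
#' 0.1, and absolute log2 fold-change of mean PSI between tumor and normal
#' above 1.5. A minimum-variance filter is available (off by default) for
#' the looser variance-based variant.
#'
#' @param min_mean_psi Minimum mean tumor PSI (strict, default 0.1).
#' @param min_abs_log2fc Minimum |log2(mean tumor / mean normal)| (strict,
#'   default 1.5); a pseudo-count of 1e-3 is added to both means.
#' @param min_tumor_fraction_expressed Minimum fraction of tumor samples
#'   with non-missing PSI (strict, default 0.5).
#' @param require_in_normal Require the event to occur (non-missing PSI) in
#'   at least one normal sample (default TRUE).
#' @param min_psi_variance Minimum tumor PSI variance (default 0 = off).
#' @return List of class \code{as_filter_config}.
#' @export
as_filter_config <- function(min_mean_psi = 0.1, min_abs_log2fc = 1.5,
                             min_tumor_fraction_expressed = 0.5,
                             require_in_normal = TRUE,
                             min_psi_variance = 0) {
  stopifnot(min_mean_psi >= 0, min_abs_log2fc >= 0,
            min_tumor_fraction_expressed >= 0, min_psi_variance >= 0)
  structure(list(min_mean_psi = min_mean_psi,
                 min_abs_log2fc = min_abs_log2fc,
                 min_tumor_fraction_expressed = min_tumor_fraction_expressed,
                 require_in_normal = isTRUE(require_in_normal),
                 min_psi_variance = min_psi_variance),
            class = "as_filter_config")
}

#' Select cancer-informative alternative-splicing events
#'
#' Applies \code{\link{as_filter_config}} rules to paired tumor/normal PSI
#' matrices (events joined by ID; an event absent from the normal matrix
#' fails the presence rule when required, otherwise its normal mean is
#' taken as 0 before the pseudo-count).
#'
#' @param tumor,normal \code{\link{psi_matrix}} objects.
#' @param cfg An \code{\link{as_filter_config}}.
#' @return Object of class \code{as_event_table}: \code{events} data frame
#'   (event_id, gene, class, mean_tumor, mean_normal, log2fc) and
#'   \code{psi}, the tumor PSI sub-matrix of surviving events.
#' @export
filter_as_events <- function(tumor, normal, cfg = as_filter_config()) {
  stopifnot(inherits(tumor, "psi_matrix"), inherits(normal, "psi_matrix"))
  if (nrow(tumor$psi) == 0L) stop("empty tumor PSI matrix")
  pc <- 1e-3
  keep <- logical(nrow(tumor$psi))
  mt <- mn <- fc <- numeric(nrow(tumor$psi))
  for (r in seq_len(nrow(tumor$psi))) {
    ev <- tumor$events$event_id[r]
    x <- tumor$psi[r, ]
    frac_expr <- mean(!is.na(x))
    mt[r] <- mean(x, na.rm = TRUE)
    in_normal <- ev %in% normal$events$event_id
    y <- if (in_normal) normal$psi[ev, ] else NA_real_
    occurred <- in_normal && any(!is.na(y))
    mn[r] <- if (occurred) mean(y, na.rm = TRUE) else 0
    fc[r] <- log2((mt[r] + pc) / (mn[r] + pc))
    keep[r] <- frac_expr > cfg$min_tumor_fraction_expressed &&
      (!cfg$require_in_normal || occurred) &&
      !is.nan(mt[r]) && mt[r] > cfg$min_mean_psi &&
      abs(fc[r]) > cfg$min_abs_log2fc &&
      (cfg$min_psi_variance <= 0 ||
         (stats::var(x, na.rm = TRUE) > cfg$min_psi_variance))
  }
  events <- cbind(tumor$events,
                  data.frame(mean_tumor = mt, mean_normal = mn, log2fc = fc))
  events <- events[keep, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events,
                 psi = tumor$psi[keep, , drop = FALSE]),
            class = "as_event_table")
}

#' @export
print.as_event_table <- function(x, ...) {
  cat("as_event_table:", nrow(x$events), "events x", ncol(x$psi), "samples\n")
  invisible(x)
}

#' First-order partial correlation
#'
#' Correlation between a gene and a splicing event after removing the
#' linear effect of the event's host gene:
#' \deqn{r_{ge|h} = \frac{r_{ge} - r_{he} r_{gh}}
#'   {\sqrt{(1 - r_{he}^2)(1 - r_{gh}^2)}}}
#'
#' @param r_ge Correlation between the gene and the event.
#' @param r_he Correlation between the host gene and the event.
#' @param r_gh Correlation between the gene and the host gene.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(r_ge, r_he, r_gh) {
  stopifnot(abs(r_ge) <= 1, abs(r_he) <= 1, abs(r_gh) <= 1)
  if (abs(r_he) >= 1 || abs(r_gh) >= 1)
    stop("degenerate conditioning: |r_he| or |r_gh| equals 1")
  (r_ge - r_he * r_gh) / sqrt((1 - r_he^2) * (1 - r_gh^2))
}

#' Gene-event raw and partial correlation table
#'
#' For each candidate gene and each filtered splicing event hosted by a
#' different gene, computes the Pearson correlation between the candidate's
#' expression and the event's PSI over the shared samples
#' (pairwise-complete), then the partial correlation conditioning on the
#' host gene's expression. Pairs with undefined correlations (constant
#' vectors, fewer than 3 complete observations, or host missing from the
#' expression matrix) are skipped; the skip count is reported as a message
#' and stored in the \code{"n_skipped"} attribute.
#'
#' @param candidates Character vector of candidate gene IDs.
#' @param expr Gene-by-sample expression matrix.
#' @param events An \code{\link{as_event_table}}.
#' @return Data frame (gene, event, host, r, partial_r).
#' @export
gene_event_correlations <- function(candidates, expr, events) {
  stopifnot(inherits(events, "as_event_table"))
  candidates <- intersect(candidates, rownames(expr))
  shared <- intersect(colnames(expr), colnames(events$psi))
  if (length(shared) < 3L)
    stop("expression and PSI share ", length(shared), " samples; need >= 3")
  E <- expr[, shared, drop = FALSE]
  P <- events$psi[, shared, drop = FALSE]
  hosts <- events$events$gene
  ok_host <- hosts %in% rownames(E)

  out <- vector("list", nrow(events$events))
  n_skipped <- sum(!ok_host) * length(candidates)
  # pairwise-complete correlation matrices, computed in bulk
  R_ge <- suppressWarnings(stats::cor(t(E[candidates, , drop = FALSE]), t(P),
                                      use = "pairwise.complete.obs"))
  host_set <- unique(hosts[ok_host])
  R_gh <- suppressWarnings(stats::cor(t(E[candidates, , drop = FALSE]),
                                      t(E[host_set, , drop = FALSE]),
                                      use = "pairwise.complete.obs"))
  for (j in seq_len(nrow(events$events))) {
    if (!ok_host[j]) next
    ev <- events$events$event_id[j]
    h <- hosts[j]
    r_he <- suppressWarnings(stats::cor(E[h, ], P[ev, ],
                                        use = "pairwise.complete.obs"))
    gi <- setdiff(candidates, h)
    if (length(gi) == 0L) next
    r_ge <- R_ge[gi, ev]
    r_gh <- R_gh[gi, h]
    valid <- !is.na(r_ge) & !is.na(r_gh) & !is.na(r_he) &
      abs(r_he) < 1 - 1e-12 & abs(r_gh) < 1 - 1e-12
    # enough complete pairwise observations?
    n_c <- sum(!is.na(E[h, ]) & !is.na(P[ev, ]))
    if (n_c < 3L) valid[] <- FALSE
    n_skipped <- n_skipped + sum(!valid) + (h %in% candidates)
    gi <- gi[valid]
    if (length(gi) == 0L) next
    pr <- (r_ge[valid] - r_he * r_gh[valid]) /
      sqrt((1 - r_he^2) * (1 - r_gh[valid]^2))
    out[[j]] <- data.frame(gene = gi, event = ev, host = h,
                           r = unname(r_ge[valid]), partial_r = unname(pr),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), event = character(),
                      host = character(), r = numeric(),
                      partial_r = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  if (n_skipped > 0) message(n_skipped, " gene-event pair(s) skipped")
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Permutation-FDR cutoff for absolute partial correlations
#'
#' Builds a null distribution by independently shuffling the sample labels
#' of the expression matrix and of the PSI matrix (default 5 permutations)
#' and recomputing all gene-event partial correlations. For a candidate
#' cutoff c, \code{FDR(c) = mean_perm(#null >= c) / max(1, #observed >= c)};
#' the returned cutoff is the smallest observed |partial r| achieving
#' \code{FDR < fdr_level}, or \code{Inf} if none does (empty network).
#'
#' @param observed Numeric vector of observed |partial r| values.
#' @param candidates,expr,events As in
#'   \code{\link{gene_event_correlations}}.
#' @param n_perm Number of permutations (default 5).
#' @param fdr_level FDR level (default 0.05).
#' @param seed Integer seed for the shuffles.
#' @return The cutoff; attribute \code{"fdr"} holds FDR(cutoff).
#' @export
permutation_fdr_cutoff <- function(observed, candidates, expr, events,
                                   n_perm = 5L, fdr_level = 0.05, seed = 1L) {
  if (length(observed) == 0L) stop("no observed values")
  stopifnot(n_perm >= 1L, fdr_level > 0, fdr_level < 1)
  observed <- abs(observed)
  set.seed(seed)
  null_counts <- function(cuts) {
    tot <- numeric(length(cuts))
    for (b in seq_len(n_perm)) {
      e2 <- expr[, sample(ncol(expr)), drop = FALSE]
      colnames(e2) <- colnames(expr)
      ev2 <- events
      ev2$psi <- events$psi[, sample(ncol(events$psi)), drop = FALSE]
      colnames(ev2$psi) <- colnames(events$psi)
      null_r <- abs(suppressMessages(
        gene_event_correlations(candidates, e2, ev2))$partial_r)
      tot <- tot + vapply(cuts, function(cc) sum(null_r >= cc), 0)
    }
    tot / n_perm
  }
  cuts <- sort(unique(observed))
  n_null <- null_counts(cuts)
  n_obs <- vapply(cuts, function(cc) sum(observed >= cc), 0)
  fdr <- n_null / pmax(1, n_obs)
  ok <- which(fdr < fdr_level)
  if (length(ok) == 0L) {
    out <- Inf
    attr(out, "fdr") <- NA_real_
    return(out)
  }
  out <- cuts[ok[1L]]
  attr(out, "fdr") <- fdr[ok[1L]]
  out
}

#' Build the gene-event co-splicing network
#'
#' Computes all candidate-gene x filtered-event partial correlations,
#' derives the permutation-FDR cutoff, and retains edges with
#' \code{|partial r| >= cutoff}.
#'
#' @param candidates Character vector of Stage-I candidate genes.
#' @param expr Gene-by-sample expression matrix.
#' @param events An \code{\link{as_event_table}}.
#' @param n_perm,fdr_level,seed Passed to
#'   \code{\link{permutation_fdr_cutoff}}.
#' @return Object of class \code{cosplicing_network}: \code{edges} data
#'   frame (gene, event, host, r, partial_r), \code{cutoff},
#'   \code{candidates}, \code{seed}.
#' @export
build_cosplicing_network <- function(candidates, expr, events,
                                     n_perm = 5L, fdr_level = 0.05,
                                     seed = 1L) {
  tab <- gene_event_correlations(candidates, expr, events)
  if (nrow(tab) == 0L) stop("no computable gene-event correlations")
  cutoff <- permutation_fdr_cutoff(abs(tab$partial_r), candidates, expr,
                                   events, n_perm = n_perm,
                                   fdr_level = fdr_level, seed = seed)
  edges <- tab[abs(tab$partial_r) >= cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, cutoff = as.numeric(cutoff),
                 candidates = candidates, seed = seed),
            class = "cosplicing_network")
}

#' @export
print.cosplicing_network <- function(x, ...) {
  cat("cosplicing_network:", nrow(x$edges), "gene-event edges (|r| >=",
      format(x$cutoff, digits = 4), ")\n")
  invisible(x)
}

#' Dice co-regulation weight of two splicing-target sets
#'
#' \deqn{W = \frac{2 |T_i \cap T_j|}{|T_i| + |T_j|}}
#'
#' @param t_i,t_j Character vectors of event IDs targeted by each gene (at
#'   least one nonempty).
#' @return Weight in \[0, 1\].
#' @export
coregulation_weight <- function(t_i, t_j) {
  t_i <- unique(t_i); t_j <- unique(t_j)
  if (length(t_i) == 0L && length(t_j) == 0L)
    stop("both target sets are empty")
  2 * length(intersect(t_i, t_j)) / (length(t_i) + length(t_j))
}

#' Build the gene-gene co-regulation network
#'
#' Genes sharing splicing targets in the co-splicing network are connected
#' with the Dice weight of their target sets; edges with weight at or above
#' the threshold survive (inclusive). All Stage-I candidates remain as
#' nodes even when isolated.
#'
#' @param cosplice A \code{\link{build_cosplicing_network}} result.
#' @param weight_threshold Minimum edge weight in \[0, 1\] (default 0.3,
#'   inclusive).
#' @return Object of class \code{coregulation_network}: \code{nodes}
#'   (character), \code{edges} data frame (gene_a, gene_b, weight).
#' @export
build_coregulation_network <- function(cosplice, weight_threshold = 0.3) {
  stopifnot(inherits(cosplice, "cosplicing_network"),
            weight_threshold >= 0, weight_threshold <= 1)
  targets <- split(cosplice$edges$event, cosplice$edges$gene)
  genes <- sort(names(targets))
  rows <- list()
  if (length(genes) >= 2L) {
    for (a in seq_len(length(genes) - 1L)) {
      for (b in seq(a + 1L, length(genes))) {
        w <- coregulation_weight(targets[[genes[a]]], targets[[genes[b]]])
        if (w >= weight_threshold && w > 0)
          rows[[length(rows) + 1L]] <-
            data.frame(gene_a = genes[a], gene_b = genes[b], weight = w,
                       stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = cosplice$candidates, edges = edges,
                 weight_threshold = weight_threshold),
            class = "coregulation_network")
}

#' @export
print.coregulation_network <- function(x, ...) {
  cat("coregulation_network:", length(x$nodes), "genes,",
      nrow(x$edges), "edges (Dice >=", x$weight_threshold, ")\n")
  invisible(x)
}

#' PageRank with restart on a weighted undirected network
#'
#' Iterates \eqn{p_{k+1} = \alpha p_0 + (1 - \alpha) W p_k} with
#' \eqn{W = A D^{-1}} (each undirected edge expanded to two directed arcs,
#' D the out-degree matrix) until the L1 change falls below \code{tol}.
#' Dangling nodes (out-degree 0) redistribute their mass to the prior.
#'
#' @param network A \code{\link{coregulation_network}} (edge weights are
#'   used in the column normalization).
#' @param prior Named nonnegative vector over the network's nodes, summing
#'   to 1.
#' @param alpha Restart probability in (0, 1\]: weight of the prior versus
#'   network smoothing (default 0.5).
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 1000).
#' @return Named score vector over nodes, summing to 1.
#' @export
pagerank <- function(network, prior, alpha = 0.5, tol = 1e-12,
                     max_iter = 1000L) {
  stopifnot(inherits(network, "coregulation_network"))
  nodes <- network$nodes
  if (length(nodes) == 0L) stop("empty network")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!all(names(prior) %in% nodes) || any(prior < 0))
    stop("prior must be nonnegative with support in the network's nodes")
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[names(prior)] <- prior
  if (abs(sum(p0) - 1) > 1e-9) stop("prior must sum to 1")

  n <- length(nodes)
  e <- network$edges
  if (nrow(e) > 0L) {
    i <- match(c(e$gene_a, e$gene_b), nodes)
    j <- match(c(e$gene_b, e$gene_a), nodes)
    A <- Matrix::sparseMatrix(i = i, j = j, x = rep(e$weight, 2L),
                              dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  }
  out_deg <- Matrix::colSums(A)
  dangling <- out_deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / out_deg)
  W <- A %*% Matrix::Diagonal(x = inv_deg)

  p <- p0
  for (k in seq_len(max_iter)) {
    spread <- as.vector(W %*% p) + sum(p[dangling]) * p0
    p_new <- alpha * p0 + (1 - alpha) * spread
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  stats::setNames(as.vector(p), nodes)
}

#' Re-prioritize candidate genes with the co-regulation network
#'
#' Stage-I probabilities of the co-regulation network's genes are
#' normalized to a prior, propagated by \code{\link{pagerank}}, and the
#' converged vector is rescaled to \[0, 1\] by max-normalization. Genes in
#' \code{scores} absent from the network keep their Stage-I score and are
#' flagged in the \code{"in_network"} attribute.
#'
#' @param scores Named Stage-I probability vector (must cover the network's
#'   nodes).
#' @param coreg A \code{\link{coregulation_network}}.
#' @param alpha Restart parameter, see \code{\link{pagerank}}.
#' @return Named post-optimization score vector over the same genes as
#'   \code{scores}, with logical attribute \code{"in_network"}.
#' @export
reprioritize <- function(scores, coreg, alpha = 0.5) {
  stopifnot(inherits(coreg, "coregulation_network"))
  if (!all(coreg$nodes %in% names(scores)))
    stop("scores must cover every co-regulation network gene")
  prior <- scores[coreg$nodes]
  if (sum(prior) <= 0) stop("prior mass is zero over network nodes")
  prior <- prior / sum(prior)
  pr <- pagerank(coreg, prior, alpha = alpha)
  out <- scores
  out[coreg$nodes] <- pr / max(pr)
  attr(out, "in_network") <- stats::setNames(names(scores) %in% coreg$nodes,
                                             names(scores))
  out
}
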