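#' Configuration for the hierarchical graph-convolution model
#'
#' @param per_omics_out_dim Output dimension of each per-omics GCN layer
#'   (default 50; the four outputs concatenate to \code{4 * 50 = 200}).
#' @param hidden_dim Hidden dimension of the integrative two-layer GCN
#'   (default 100; its output dimension is 1, a logit per gene).
#' @param learning_rate Adam base learning rate (default 0.001).
#' @param epochs Number of full-batch training epochs. The pan-cancer
#'   default is 6000; cancer-type presets use 2000 (BRCA), 3000 (GBM) and
#'   1500 (LUAD).
#' @param lambda1,lambda2 L1 and squared-L2 regularization weights applied
#'   to all six weight matrices (default 5e-4 each).
#' @param folds Cross-validation folds (default 3, stratified by class).
#' @param seed Integer seed governing weight initialization and fold
#'   assignment.
#' @param preset Optional epoch preset: \code{"pan_cancer"} (6000),
#'   \code{"brca"} (2000), \code{"gbm"} (3000), \code{"luad"} (1500).
#'   Explicit \code{epochs} overrides the preset.
#' @return A list of class \code{himgcn_control}.
#' @export
himgcn_control <- function(per_omics_out_dim = 50L, hidden_dim = 100L,
                           learning_rate = 0.001, epochs = NULL,
                           lambda1 = 5e-4, lambda2 = 5e-4,
                           folds = 3L, seed = 42L,
                           preset = c("pan_cancer", "brca", "gbm", "luad")) {
  preset <- match.arg(preset)
  if (is.null(epochs))
    epochs <- c(pan_cancer = 6000L, brca = 2000L, gbm = 3000L,
                luad = 1500L)[[preset]]
  stopifnot(per_omics_out_dim > 0, hidden_dim > 0, epochs >= 0,
            learning_rate > 0, folds >= 2, lambda1 >= 0, lambda2 >= 0)
  structure(list(per_omics_out_dim = as.integer(per_omics_out_dim),
                 hidden_dim = as.integer(hidden_dim),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 lambda1 = lambda1, lambda2 = lambda2,
                 folds = as.integer(folds), seed = as.integer(seed),
                 preset = preset),
            class = "himgcn_control")
}

OMICS_ORDER <- c("expression", "mutation", "methylation", "cnv")

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Single graph-convolution layer
#'
#' Computes \code{activation(Ahat \%*\% H \%*\% W)}: features are mixed
#' along edges of the normalized adjacency, then linearly transformed.
#'
#' @param Ahat Normalized adjacency from \code{\link{normalize_adjacency}}.
#' @param H Node-feature matrix (nodes x d_in).
#' @param W Weight matrix (d_in x d_out).
#' @param activation \code{"relu"}, \code{"identity"} or \code{"sigmoid"}.
#' @return Node-feature matrix (nodes x d_out).
#' @export
gcn_layer <- function(Ahat, H, W, activation = c("relu", "identity", "sigmoid")) {
  activation <- match.arg(activation)
  H <- as.matrix(H)
  W <- as.matrix(W)
  if (ncol(H) != nrow(W))
    stop("shape mismatch: H is ", nrow(H), "x", ncol(H),
         " but W is ", nrow(W), "x", ncol(W))
  out <- as.matrix(Ahat %*% (H %*% W))
  switch(activation, relu = relu(out), identity = out, sigmoid = sigmoid(out))
}

glorot_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_weights <- function(dims, cfg, seed) {
  set.seed(seed)
  d <- cfg$per_omics_out_dim
  W <- lapply(OMICS_ORDER, function(nm) glorot_init(dims[[nm]], d))
  names(W) <- OMICS_ORDER
  W$int0 <- glorot_init(4L * d, cfg$hidden_dim)
  W$int1 <- glorot_init(cfg$hidden_dim, 1L)
  W
}

# Forward pass. AX: list of precomputed Ahat %*% X_t (constant across
# epochs since the inputs never change). Returns probabilities plus the
# intermediates needed for backprop.
himgcn_forward <- function(Ahat, AX, W) {
  S <- lapply(OMICS_ORDER, function(nm) AX[[nm]] %*% W[[nm]])
  Z <- lapply(S, relu)
  Xint <- do.call(cbind, Z)
  S0 <- as.matrix(Ahat %*% (Xint %*% W$int0))
  H1 <- relu(S0)
  logits <- as.vector(as.matrix(Ahat %*% (H1 %*% W$int1)))
  list(prob = sigmoid(logits), logits = logits,
       S = S, Xint = Xint, S0 = S0, H1 = H1)
}

# Gradient of the imbalance-weighted cross-entropy (plus regularizers)
# with respect to all six weight matrices. lab_idx: indices of labeled
# nodes; y: their 0/1 labels; a1/a2: class weights.
himgcn_backward <- function(Ahat, AX, W, fw, lab_idx, y, a1, a2,
                            lambda1, lambda2) {
  n_lab <- length(lab_idx)
  p <- fw$prob[lab_idx]
  gz <- numeric(length(fw$prob))
  gz[lab_idx] <- (a1 * y * (p - 1) + a2 * (1 - y) * p) / n_lab
  Agz <- as.vector(as.matrix(Ahat %*% gz))

  grads <- vector("list", length(W))
  names(grads) <- names(W)
  grads$int1 <- crossprod(fw$H1, Agz)
  gH1 <- Agz %*% t(W$int1)
  gS0 <- gH1 * (fw$S0 > 0)
  AgS0 <- as.matrix(Ahat %*% gS0)
  grads$int0 <- crossprod(fw$Xint, AgS0)
  gXint <- AgS0 %*% t(W$int0)

  d <- ncol(W[[OMICS_ORDER[1L]]])
  for (k in seq_along(OMICS_ORDER)) {
    nm <- OMICS_ORDER[k]
    gZ <- gXint[, (k - 1L) * d + seq_len(d), drop = FALSE]
    gS <- gZ * (fw$S[[k]] > 0)
    grads[[nm]] <- crossprod(AX[[nm]], gS)
  }
  for (nm in names(W))
    grads[[nm]] <- grads[[nm]] + lambda1 * sign(W[[nm]]) + 2 * lambda2 * W[[nm]]
  grads
}

#' Imbalance-weighted cross-entropy loss
#'
#' \deqn{L = -\frac{1}{N}\sum_{i \in labeled} [\alpha_1 y_i \log p_i +
#'   \alpha_2 (1 - y_i) \log(1 - p_i)] + \lambda_1 \|W\|_1 +
#'   \lambda_2 \|W\|_2^2}
#' with \eqn{\alpha_1 = N / N_{positive}}, \eqn{\alpha_2 = N / N_{negative}}
#' and \eqn{N} the number of labeled genes; unlabeled genes contribute
#' nothing. The regularizers sum over all trainable weight matrices.
#'
#' @param scores Named numeric vector of per-gene probabilities.
#' @param labels A \code{\link{label_set}}; only genes present in
#'   \code{scores} count.
#' @param weights Optional list of weight matrices for the regularization
#'   terms (e.g. \code{coef()} of a fitted model); \code{NULL} means no
#'   regularization.
#' @param lambda1,lambda2 Regularization strengths.
#' @param alpha1,alpha2 Optional class-weight overrides; by default the
#'   imbalance weights \eqn{N/N_{positive}} and \eqn{N/N_{negative}} are
#'   used. With \code{alpha1 = alpha2 = 1} and zero lambdas the loss is the
#'   plain mean binary cross-entropy.
#' @return The scalar loss.
#' @export
weighted_loss <- function(scores, labels, weights = NULL,
                          lambda1 = 0, lambda2 = 0,
                          alpha1 = NULL, alpha2 = NULL) {
  pos <- intersect(labels$positives, names(scores))
  neg <- intersect(labels$negatives, names(scores))
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be present among scored genes")
  n <- length(pos) + length(neg)
  a1 <- alpha1 %||% (n / length(pos))
  a2 <- alpha2 %||% (n / length(neg))
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  ce <- -(a1 * sum(log(p[pos])) + a2 * sum(log(1 - p[neg]))) / n
  reg <- 0
  if (!is.null(weights))
    reg <- lambda1 * sum(vapply(weights, function(w) sum(abs(w)), 0)) +
      lambda2 * sum(vapply(weights, function(w) sum(w^2), 0))
  ce + reg
}

loss_value <- function(prob, lab_idx, y, a1, a2, W, lambda1, lambda2) {
  p <- pmin(pmax(prob[lab_idx], 1e-12), 1 - 1e-12)
  ce <- -sum(a1 * y * log(p) + a2 * (1 - y) * log(1 - p)) / length(lab_idx)
  ce + lambda1 * sum(vapply(W, function(w) sum(abs(w)), 0)) +
    lambda2 * sum(vapply(W, function(w) sum(w^2), 0))
}

# Full-batch Adam on the fixed architecture. Returns final weights and the
# per-epoch loss trace.
fit_himgcn <- function(Ahat, AX, dims, lab_idx, y, cfg, init_seed) {
  W <- init_weights(dims, cfg, init_seed)
  n <- length(lab_idx)
  n_pos <- sum(y == 1)
  n_neg <- n - n_pos
  if (n_pos == 0L || n_neg == 0L)
    stop("training labels must include both classes")
  a1 <- n / n_pos
  a2 <- n / n_neg
  m <- lapply(W, function(w) w * 0)
  v <- lapply(W, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  trace <- numeric(cfg$epochs)
  for (t in seq_len(cfg$epochs)) {
    fw <- himgcn_forward(Ahat, AX, W)
    trace[t] <- loss_value(fw$prob, lab_idx, y, a1, a2, W,
                           cfg$lambda1, cfg$lambda2)
    g <- himgcn_backward(Ahat, AX, W, fw, lab_idx, y, a1, a2,
                         cfg$lambda1, cfg$lambda2)
    for (nm in names(W)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - b1^t)
      vh <- v[[nm]] / (1 - b2^t)
      W[[nm]] <- W[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(weights = W, loss_trace = trace)
}

stratified_folds <- function(positives, negatives, k, seed) {
  set.seed(seed)
  assign_one <- function(ids) {
    ids <- sample(ids)
    split(ids, rep_len(seq_len(k), length(ids)))
  }
  fp <- assign_one(positives)
  fn <- assign_one(negatives)
  lapply(seq_len(k), function(i) list(positives = fp[[i]],
                                      negatives = fn[[i]]))
}

#' Fit the hierarchical graph-convolution cancer-gene model
#'
#' Stage I of the two-stage prioritization. Four omics feature sets are each
#' passed through a one-layer graph convolution with ReLU, the resulting
#' representations are concatenated, and a two-layer integrative graph
#' convolution produces a scalar logit per gene, mapped through the logistic
#' function to a probability of being a cancer gene. Training minimizes an
#' imbalance-weighted cross-entropy over the labeled genes (semi-supervised:
#' unlabeled genes participate in propagation but not in the loss) with
#' full-batch Adam. Performance is estimated by stratified k-fold
#' cross-validation; the reported scores come from a final model trained on
#' all labels (set \code{score_mode = "fold_average"} to average the fold
#' models instead).
#'
#' @param network A \code{\link{gene_network}}.
#' @param features Named list of four gene-by-component matrices
#'   (\code{expression}, \code{mutation}, \code{methylation}, \code{cnv}),
#'   rows in network node order — see \code{\link{prepare_features}}.
#' @param labels A \code{\link{label_set}} over the network's genes.
#' @param control A \code{\link{himgcn_control}}.
#' @param cv Run cross-validation (default TRUE). With FALSE only the
#'   full-data model is fitted.
#' @param score_mode \code{"full"} or \code{"fold_average"}.
#' @return Object of class \code{himgcn}: \code{scores} (named probability
#'   vector over all genes), \code{cv_metrics} (one row per fold: accuracy,
#'   auroc, auprc, f1), \code{weights}, \code{loss_trace}, \code{folds},
#'   \code{control}, plus the network and labels used.
#' @seealso \code{\link{select_candidates}}, \code{\link{reprioritize}}
#' @export
himgcn <- function(network, features, labels, control = himgcn_control(),
                   cv = TRUE, score_mode = c("full", "fold_average")) {
  score_mode <- match.arg(score_mode)
  stopifnot(inherits(network, "gene_network"),
            inherits(labels, "label_set"),
            inherits(control, "himgcn_control"))
  if (!setequal(names(features), OMICS_ORDER))
    stop("features must be named: ", paste(OMICS_ORDER, collapse = ", "))
  features <- features[OMICS_ORDER]
  for (nm in OMICS_ORDER)
    if (!identical(rownames(features[[nm]]), network$nodes))
      stop("feature set '", nm, "' is not aligned to the network node order")
  if (length(labels$positives) < control$folds ||
      length(labels$negatives) < control$folds)
    stop("need at least ", control$folds, " genes per class for ",
         control$folds, "-fold cross-validation")

  Ahat <- normalize_adjacency(network)
  AX <- lapply(features, function(X) as.matrix(Ahat %*% X))
  names(AX) <- OMICS_ORDER
  dims <- lapply(features, ncol)

  node_index <- stats::setNames(seq_along(network$nodes), network$nodes)
  make_y <- function(pos, neg) {
    idx <- node_index[c(pos, neg)]
    list(idx = unname(idx), y = c(rep(1, length(pos)), rep(0, length(neg))))
  }

  cv_metrics <- NULL
  fold_models <- list()
  folds <- NULL
  if (cv) {
    folds <- stratified_folds(labels$positives, labels$negatives,
                              control$folds, control$seed)
    rows <- vector("list", control$folds)
    for (i in seq_len(control$folds)) {
      test <- folds[[i]]
      train_pos <- setdiff(labels$positives, test$positives)
      train_neg <- setdiff(labels$negatives, test$negatives)
      tr <- make_y(train_pos, train_neg)
      fit <- fit_himgcn(Ahat, AX, dims, tr$idx, tr$y, control,
                        init_seed = control$seed + i)
      fw <- himgcn_forward(Ahat, AX, fit$weights)
      scores <- stats::setNames(fw$prob, network$nodes)
      rep_i <- binary_metrics(scores,
                              label_set(test$positives, test$negatives,
                                        network$nodes))
      rows[[i]] <- data.frame(fold = i, accuracy = rep_i$accuracy,
                              auroc = rep_i$auroc, auprc = rep_i$auprc,
                              f1 = rep_i$f1)
      fold_models[[i]] <- fit$weights
    }
    cv_metrics <- do.call(rbind, rows)
  }

  all_lab <- make_y(labels$positives, labels$negatives)
  full <- fit_himgcn(Ahat, AX, dims, all_lab$idx, all_lab$y, control,
                     init_seed = control$seed)
  if (score_mode == "full" || !cv) {
    prob <- himgcn_forward(Ahat, AX, full$weights)$prob
  } else {
    prob <- rowMeans(vapply(fold_models, function(w)
      himgcn_forward(Ahat, AX, w)$prob, numeric(length(network$nodes))))
  }

  structure(list(scores = stats::setNames(prob, network$nodes),
                 cv_metrics = cv_metrics,
                 weights = full$weights,
                 fold_weights = fold_models,
                 loss_trace = full$loss_trace,
                 folds = folds,
                 control = control,
                 network = network,
                 labels = labels,
                 feature_dims = dims),
            class = "himgcn")
}

#' @export
print.himgcn <- function(x, ...) {
  cat("Hierarchical GCN cancer-gene model\n")
  cat("  genes:", length(x$scores), "  labeled:",
      length(x$labels$positives), "positive /",
      length(x$labels$negatives), "negative\n")
  cat("  epochs:", x$control$epochs, " lr:", x$control$learning_rate, "\n")
  if (!is.null(x$cv_metrics))
    cat("  mean CV AUROC:", round(mean(x$cv_metrics$auroc), 4), "\n")
  invisible(x)
}

#' @export
summary.himgcn <- function(object, cutoff = 0.7, ...) {
  cand <- select_candidates(object$scores, cutoff)
  out <- list(n_genes = length(object$scores),
              n_positive = length(object$labels$positives),
              n_negative = length(object$labels$negatives),
              cv_metrics = object$cv_metrics,
              cv_mean = if (!is.null(object$cv_metrics))
                colMeans(object$cv_metrics[-1L]),
              final_loss = utils::tail(object$loss_trace, 1L),
              cutoff = cutoff,
              n_candidates = length(cand))
  class(out) <- "summary.himgcn"
  out
}

#' @export
print.summary.himgcn <- function(x, ...) {
  cat("Hierarchical GCN model over", x$n_genes, "genes\n")
  cat("Labels:", x$n_positive, "positive,", x$n_negative, "negative\n")
  if (!is.null(x$cv_metrics)) {
    cat("\nCross-validation (held-out, per fold):\n")
    print(x$cv_metrics, row.names = FALSE)
    cat("\nMean:", paste(names(x$cv_mean),
                         sprintf("%.4f", x$cv_mean), collapse = "  "), "\n")
  }
  cat("\nFinal training loss:", format(x$final_loss), "\n")
  cat("Candidates with probability >", x$cutoff, ":", x$n_candidates, "\n")
  invisible(x)
}

#' @export
coef.himgcn <- function(object, ...) object$weights

#' Predict cancer-gene probabilities from a fitted model
#'
#' With \code{newdata = NULL} returns the fitted scores. Otherwise
#' \code{newdata} must be a named list of four feature matrices aligned to
#' the model's network (same graph; the convolution operator is part of the
#' model), and the forward pass is recomputed.
#'
#' @param object A fitted \code{\link{himgcn}} model.
#' @param newdata Optional named list of feature matrices.
#' @param ... Unused.
#' @return Named numeric vector of probabilities.
#' @export
predict.himgcn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  if (!setequal(names(newdata), OMICS_ORDER))
    stop("newdata must be named: ", paste(OMICS_ORDER, collapse = ", "))
  newdata <- newdata[OMICS_ORDER]
  for (nm in OMICS_ORDER) {
    if (!identical(rownames(newdata[[nm]]), object$network$nodes))
      stop("feature set '", nm, "' is not aligned to the model's network")
    if (ncol(newdata[[nm]]) != object$feature_dims[[nm]])
      stop("feature set '", nm, "' has ", ncol(newdata[[nm]]),
           " columns, model expects ", object$feature_dims[[nm]])
  }
  Ahat <- normalize_adjacency(object$network)
  AX <- lapply(newdata, function(X) as.matrix(Ahat %*% X))
  names(AX) <- OMICS_ORDER
  stats::setNames(himgcn_forward(Ahat, AX, object$weights)$prob,
                  object$network$nodes)
}

#' @export
fitted.himgcn <- function(object, ...) object$scores

#' Residuals of a fitted model on labeled genes
#'
#' \code{y - p} for labeled genes (y = 1 for positives, 0 for negatives);
#' unlabeled genes are excluded.
#'
#' @param object A fitted \code{\link{himgcn}} model.
#' @param ... Unused.
#' @return Named numeric vector over labeled genes.
#' @export
residuals.himgcn <- function(object, ...) {
  lab <- c(object$labels$positives, object$labels$negatives)
  y <- c(rep(1, length(object$labels$positives)),
         rep(0, length(object$labels$negatives)))
  stats::setNames(y - object$scores[lab], lab)
}

#' Plot the training loss trace of a fitted model
#'
#' @param x A fitted \code{\link{himgcn}} model.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.himgcn <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "weighted cross-entropy loss",
       main = "HIM-GCN training loss", ...)
  invisible(x)
}

#' Select candidate cancer genes by probability cutoff
#'
#' @param scores Named probability vector (e.g. \code{fitted(model)}).
#' @param cutoff Probability threshold in \[0, 1\]; genes with probability
#'   strictly greater than the cutoff are candidates (default 0.7).
#' @return Character vector of candidate gene IDs, in score order
#'   (descending, ties by gene ID).
#' @export
select_candidates <- function(scores, cutoff = 0.7) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  keep <- scores > cutoff
  ids <- names(scores)[keep]
  ids[order(-scores[keep], ids)]
}
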