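#' Read a gene-by-sample omics matrix from delimited text
#'
#' First column holds gene identifiers, the header row sample identifiers;
#' tab and comma delimiters are auto-detected. Cells equal to a declared
#' missing-value sentinel are parsed to \code{NA}; any other non-numeric
#' cell is a hard error naming its row and column.
#'
#' @param path Path to the table.
#' @param kind Omics tag, one of \code{"expression"}, \code{"mutation"},
#'   \code{"methylation"}, \code{"cnv"} (or any label; stored as an
#'   attribute).
#' @param na_strings Values parsed as missing. Default \code{c("NA", "")}.
#' @return Numeric matrix, rows named by gene, columns by sample, with a
#'   \code{"kind"} attribute.
#' @export
load_omics_matrix <- function(path, kind = "expression", na_strings = c("NA", "")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data rows in ", path)
  sep <- detect_delimiter(lines[[1L]])
  split1 <- strsplit(lines, sep)
  header <- split1[[1L]]
  body <- split1[-1L]
  samples <- header[-1L]
  if (length(samples) == 0L) stop("no sample columns in ", path)
  genes <- vapply(body, `[[`, "", 1L)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (r in seq_along(body)) {
    cells <- body[[r]][-1L]
    if (length(cells) != length(samples))
      stop("row ", r, " ('", genes[r], "') has ", length(cells),
           " values, expected ", length(samples))
    cells[cells %in% na_strings] <- NA
    x <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(x) & !is.na(cells))
    if (length(bad))
      stop("non-numeric cell at gene '", genes[r], "', sample '",
           samples[bad[1L]], "': '", cells[bad[1L]], "'")
    vals[r, ] <- x
  }
  attr(vals, "kind") <- kind
  vals
}

#' Write a gene-by-sample matrix as TSV
#'
#' Inverse of \code{\link{load_omics_matrix}}; numbers are written with
#' \code{format(..., digits = 15)} so that identical matrices produce
#' byte-identical files.
#'
#' @param m Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @export
write_omics_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(row)
    paste(ifelse(is.na(row), "NA", format(row, digits = 15, trim = TRUE,
                                          scientific = FALSE)),
          collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
}

#' Impute missing values to per-sample (column) means
#'
#' @param m Numeric gene-by-sample matrix.
#' @return Matrix with every \code{NA} replaced by its column mean (0 if the
#'   whole column is missing).
#' @export
impute_column_means <- function(m) {
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2L]]
  m
}

#' Align an omics matrix to a network's node order
#'
#' Rows are reordered to the network node order. Genes present in the
#' network but absent from the matrix receive all-zero rows and are
#' recorded in the \code{"missing_genes"} attribute (with a message); genes
#' absent from the network are dropped.
#'
#' @param m Numeric gene-by-sample (or gene-by-feature) matrix.
#' @param nodes Character vector: the canonical gene order.
#' @return Matrix with \code{length(nodes)} rows in node order.
#' @export
align_to_network <- function(m, nodes) {
  missing <- setdiff(nodes, rownames(m))
  out <- matrix(0, nrow = length(nodes), ncol = ncol(m),
                dimnames = list(nodes, colnames(m)))
  common <- intersect(nodes, rownames(m))
  out[common, ] <- m[common, , drop = FALSE]
  if (length(missing)) {
    message(length(missing), " network gene(s) missing from the ",
            attr(m, "kind") %||% "omics", " matrix; zero-filled")
  }
  attr(out, "kind") <- attr(m, "kind")
  attr(out, "missing_genes") <- missing
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA reduction of an omics matrix to leading components
#'
#' Columns (samples) are mean-centered, a full PCA is computed, and the
#' smallest number of leading components whose cumulative explained-variance
#' ratio strictly exceeds \code{variance_ratio} is retained. Gene scores on
#' those components form the feature matrix handed to the graph-convolution
#' model. Missing values must be imputed beforehand (see
#' \code{\link{impute_column_means}}).
#'
#' @param m Numeric gene-by-sample matrix without \code{NA}s.
#' @param variance_ratio Fraction in (0, 1]; defaults follow the model's
#'   conventions: 0.98 for expression and methylation, 0.7 for mutation and
#'   copy number.
#' @return Gene-by-component score matrix; attribute
#'   \code{"explained_ratio"} holds the cumulative ratio retained.
#' @export
pca_reduce <- function(m, variance_ratio = 0.98) {
  if (!is.numeric(variance_ratio) || length(variance_ratio) != 1L ||
      variance_ratio <= 0 || variance_ratio > 1)
    stop("variance_ratio must be in (0, 1]")
  if (ncol(m) < 2L) stop("need at least 2 samples for PCA")
  if (anyNA(m)) stop("matrix contains missing values; impute first")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  tot <- sum(v)
  if (tot <= .Machine$double.eps) {
    # degenerate: no variance at all; a single zero component
    out <- matrix(0, nrow = nrow(m), ncol = 1L,
                  dimnames = list(rownames(m), "PC1"))
    attr(out, "explained_ratio") <- 1
    return(out)
  }
  cum <- cumsum(v) / tot
  k <- which(cum > variance_ratio | cum >= 1 - 1e-12)[1L]
  if (is.na(k)) k <- length(cum)
  out <- pc$x[, seq_len(k), drop = FALSE]
  rownames(out) <- rownames(m)
  attr(out, "explained_ratio") <- cum[k]
  out
}

#' Build the four aligned feature sets for the hierarchical GCN
#'
#' Convenience wrapper: imputes missing values to column means, PCA-reduces
#' each omics matrix at its conventional variance threshold, and aligns the
#' result to the network node order (zero-filling genes without data).
#'
#' @param net A \code{\link{gene_network}}.
#' @param expression,mutation,methylation,cnv Gene-by-sample matrices.
#' @param variance_ratios Named list of PCA thresholds per omics.
#' @return Named list of four gene-by-component matrices in node order.
#' @export
prepare_features <- function(net, expression, mutation, methylation, cnv,
                             variance_ratios = list(expression = 0.98,
                                                    mutation = 0.7,
                                                    methylation = 0.98,
                                                    cnv = 0.7)) {
  raw <- list(expression = expression, mutation = mutation,
              methylation = methylation, cnv = cnv)
  out <- lapply(names(raw), function(nm) {
    m <- impute_column_means(raw[[nm]])
    red <- pca_reduce(m, variance_ratios[[nm]])
    attr(red, "kind") <- nm
    align_to_network(red, net$nodes)
  })
  names(out) <- names(raw)
  out
}
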