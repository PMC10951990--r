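#' Positive/negative/unlabeled gene label set
#'
#' @param positives Character vector of known cancer genes.
#' @param negatives Character vector of genes confidently not cancer-related.
#' @param nodes Character vector of all network genes; positives and
#'   negatives must be subsets and must not overlap. Remaining genes are
#'   unlabeled.
#' @return Object of class \code{label_set} with elements \code{positives},
#'   \code{negatives}, \code{unlabeled}.
#' @export
label_set <- function(positives, negatives, nodes) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  overlap <- intersect(positives, negatives)
  if (length(overlap))
    stop("genes labeled both positive and negative: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  positives <- intersect(positives, nodes)
  negatives <- intersect(negatives, nodes)
  structure(list(positives = positives, negatives = negatives,
                 unlabeled = setdiff(nodes, c(positives, negatives))),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("label_set:", length(x$positives), "positive,",
      length(x$negatives), "negative,",
      length(x$unlabeled), "unlabeled\n")
  invisible(x)
}

#' Read a gene list (one identifier per line)
#'
#' @param path Path to the file.
#' @return Character vector of gene identifiers.
#' @export
load_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Draw negative training genes from a candidate pool
#'
#' In pan-cancer mode the whole pool is used. In cancer-type-specific mode
#' negatives are sampled uniformly at random at ten times the number of
#' positives (the whole pool, with a warning, if it is smaller).
#'
#' @param negative_pool Character vector of eligible negative genes,
#'   disjoint from \code{positives}.
#' @param positives Character vector of positive genes.
#' @param mode \code{"pan_cancer"} or \code{"specific"}.
#' @param seed Integer seed for the draw.
#' @return Character vector of selected negatives.
#' @export
sample_negatives <- function(negative_pool, positives,
                             mode = c("pan_cancer", "specific"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(negative_pool) == 0L) stop("empty negative pool")
  if (length(intersect(negative_pool, positives)))
    stop("negative pool overlaps positives")
  if (mode == "pan_cancer") return(negative_pool)
  want <- 10L * length(positives)
  if (length(negative_pool) <= want) {
    warning("negative pool (", length(negative_pool),
            ") smaller than 10x positives (", want, "); using all")
    return(negative_pool)
  }
  set.seed(seed)
  sort(sample(negative_pool, want))
}
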