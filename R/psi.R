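#' Percent-spliced-in (PSI) matrix for alternative-splicing events
#'
#' Events carry SUPPA2-style identifiers \code{"GENE;CLASS;coords"}; only
#' the host gene and event class (SE, MX, A5, A3, RI, AF, AL) are parsed,
#' the coordinate field is opaque. PSI values lie in \[0, 1\] or are
#' missing (\code{NA}, emitted when an event is undefined in a sample).
#'
#' @param events Data frame with columns \code{event_id}, \code{gene},
#'   \code{class}.
#' @param psi Numeric event-by-sample matrix, rows named by event.
#' @param condition \code{"tumor"} or \code{"normal"}.
#' @return Object of class \code{psi_matrix}.
#' @export
psi_matrix <- function(events, psi, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  stopifnot(is.data.frame(events), is.matrix(psi))
  if (anyDuplicated(events$event_id))
    stop("duplicate event IDs")
  if (!identical(rownames(psi), events$event_id))
    stop("psi row names must equal events$event_id, in order")
  rng <- range(psi, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1L] < 0 || rng[2L] > 1))
    stop("PSI values outside [0, 1]")
  structure(list(events = events, psi = psi, condition = condition),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat("psi_matrix (", x$condition, "): ", nrow(x$psi), " events x ",
      ncol(x$psi), " samples\n", sep = "")
  invisible(x)
}

parse_event_ids <- function(ids) {
  parts <- strsplit(ids, ";", fixed = TRUE)
  short <- lengths(parts) < 2L
  if (any(short))
    stop("event ID not in 'GENE;CLASS;coords' form: ", ids[which(short)[1L]])
  data.frame(event_id = ids,
             gene = vapply(parts, `[[`, "", 1L),
             class = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a PSI matrix from SUPPA2-style TSV
#'
#' First column: event IDs \code{"GENE;CLASS;coords"}; header: sample IDs.
#'
#' @param path Path to the table.
#' @param condition \code{"tumor"} or \code{"normal"}.
#' @return A \code{\link{psi_matrix}}.
#' @export
load_psi_matrix <- function(path, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  m <- load_omics_matrix(path, kind = "psi")
  psi_matrix(parse_event_ids(rownames(m)), unclass_matrix(m), condition)
}

unclass_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' Write a PSI matrix as TSV
#' @param x A \code{\link{psi_matrix}}.
#' @param path Output path.
#' @export
write_psi_matrix <- function(x, path) {
  stopifnot(inherits(x, "psi_matrix"))
  write_omics_matrix(x$psi, path)
}
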