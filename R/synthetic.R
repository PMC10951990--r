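#' Configuration for the synthetic dataset generator
#'
#' The generator plants exactly the structure the two prioritization stages
#' exploit: an assortative community-structured gene network whose positive
#' labels concentrate in designated communities, omics matrices in which
#' positive genes carry mean-shifted signal, and tumor/normal PSI matrices
#' in which a planted subset of positive genes drives shared splicing
#' events. Two presets ship: \code{"easy"} (strong effects, the validation
#' workhorse) and \code{"hard"} (weak effects, for power exploration).
#'
#' @param preset \code{"easy"} or \code{"hard"}.
#' @param n_genes Number of genes (easy default 1000).
#' @param n_samples_tumor,n_samples_normal Sample counts (easy 100/50).
#' @param n_communities Stochastic-block-model communities (default 5).
#' @param p_in,p_out Within/between-community edge probabilities (easy
#'   0.08/0.002; assortative, \code{p_in > p_out}).
#' @param frac_positive Fraction of genes labeled positive (default 0.08);
#'   positives are drawn from the first communities so network structure is
#'   label-informative.
#' @param frac_negative Fraction labeled negative (default 0.25), drawn
#'   from the remaining communities; the rest stay unlabeled.
#' @param omics_effect_size Mean shift of positive-gene feature rows, in
#'   noise standard deviations (easy 1.5, hard 0.4).
#' @param n_events Number of splicing events (default 200).
#' @param frac_regulated_events Fraction of events driven by a planted
#'   positive regulator (default 0.5).
#' @param regulation_strength Logit-scale coefficient from standardized
#'   regulator expression to event PSI (easy 2, hard 0.5).
#' @param noise_sd Logit-scale Gaussian noise on regulated PSI (easy 0.1).
#' @param seed Master seed; all stage seeds fan out from it.
#' @param ... Named overrides of any field.
#' @return List of class \code{synthetic_config}.
#' @export
synthetic_config <- function(preset = c("easy", "hard"), ...) {
  preset <- match.arg(preset)
  cfg <- list(n_genes = 1000L, n_samples_tumor = 100L,
              n_samples_normal = 50L, n_communities = 5L,
              p_in = 0.08, p_out = 0.002,
              frac_positive = 0.08, frac_negative = 0.25,
              omics_effect_size = 1.5,
              n_events = 200L, frac_regulated_events = 0.5,
              regulation_strength = 2, noise_sd = 0.1,
              seed = 17L, preset = preset)
  if (preset == "hard") {
    cfg$omics_effect_size <- 0.4
    cfg$regulation_strength <- 0.5
    cfg$noise_sd <- 0.5
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$p_in >= 0, cfg$p_in <= 1, cfg$p_out >= 0, cfg$p_out <= 1,
            cfg$n_genes > 0, cfg$n_samples_tumor > 0,
            cfg$n_samples_normal > 0, cfg$n_communities > 0,
            cfg$frac_positive > 0, cfg$frac_positive < 1,
            cfg$n_events > 0)
  structure(cfg, class = "synthetic_config")
}

# deterministic per-stage seeds fanned out from the master seed
stage_seed <- function(cfg, k) (cfg$seed * 101L + k * 7919L) %% 2147483647L

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a community-structured gene network
#'
#' Stochastic-block-model graph with \code{n_communities} near-equal
#' blocks, within-block edge probability \code{p_in} and between-block
#' probability \code{p_out}.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return A \code{\link{gene_network}}; the \code{"community"} attribute
#'   maps each gene to its block.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(stage_seed(cfg, 1L))
  k <- cfg$n_communities
  sizes <- rep(cfg$n_genes %/% k, k)
  sizes[seq_len(cfg$n_genes %% k)] <- sizes[seq_len(cfg$n_genes %% k)] + 1L
  pref <- matrix(cfg$p_out, k, k)
  diag(pref) <- cfg$p_in
  g <- igraph::sample_sbm(cfg$n_genes, pref.matrix = pref,
                          block.sizes = sizes)
  ids <- gene_ids(cfg$n_genes)
  el <- igraph::as_edgelist(g, names = FALSE)
  net <- gene_network(ids, cbind(ids[el[, 1L]], ids[el[, 2L]]))
  attr(net, "community") <- stats::setNames(rep(seq_len(k), sizes), ids)
  net
}

#' Generate planted gene labels
#'
#' Positives are sampled from the first community (spilling into the next
#' ones if it is too small), negatives from the remaining communities, so
#' that both network topology and omics signal are informative.
#'
#' @param net A network from \code{\link{generate_network}}.
#' @param cfg A \code{\link{synthetic_config}}.
#' @return A \code{\link{label_set}}.
#' @export
generate_labels <- function(net, cfg) {
  comm <- attr(net, "community")
  set.seed(stage_seed(cfg, 2L))
  n_pos <- max(1L, round(cfg$frac_positive * length(net$nodes)))
  n_neg <- max(1L, round(cfg$frac_negative * length(net$nodes)))
  ord <- net$nodes[order(comm[net$nodes])]   # community 1 first
  pos_pool <- ord[seq_len(min(2L * n_pos, length(ord)))]
  positives <- sort(sample(pos_pool, n_pos))
  neg_pool <- setdiff(ord, ord[seq_len(min(2L * n_pos, length(ord)))])
  negatives <- sort(sample(neg_pool, min(n_neg, length(neg_pool))))
  label_set(positives, negatives, net$nodes)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate the four omics matrices with planted class signal
#'
#' Positive genes receive mean-shifted rows: expression and copy number
#' get an additive shift of \code{omics_effect_size} noise SDs;
#' methylation and mutation frequency get proportionally scaled shifts and
#' are clipped to \[0, 1\].
#'
#' @param net A \code{\link{gene_network}}.
#' @param labels A \code{\link{label_set}}.
#' @param cfg A \code{\link{synthetic_config}}.
#' @return Named list of four gene-by-sample matrices (\code{expression},
#'   \code{mutation}, \code{methylation}, \code{cnv}).
#' @export
generate_omics <- function(net, labels, cfg) {
  set.seed(stage_seed(cfg, 3L))
  n <- length(net$nodes)
  ns <- cfg$n_samples_tumor
  samples <- sprintf("s%03d", seq_len(ns))
  is_pos <- net$nodes %in% labels$positives
  eff <- cfg$omics_effect_size
  mk <- function(base, sd, shift, clip = FALSE) {
    m <- matrix(stats::rnorm(n * ns, base, sd), n, ns,
                dimnames = list(net$nodes, samples))
    m[is_pos, ] <- m[is_pos, ] + shift
    if (clip) m <- clip01(m)
    m
  }
  list(
    expression = mk(5, 1, eff),                      # log2(FPKM+1)-like
    mutation = mk(0.05, 0.03, 0.04 * eff, clip = TRUE),
    methylation = mk(0.5, 0.1, 0.08 * eff, clip = TRUE),
    cnv = mk(0, 0.5, 0.5 * eff)
  )
}

#' Generate tumor/normal PSI matrices with planted co-regulation
#'
#' A fraction of events are regulated. Regulators are positive genes
#' organized in modules of three; each regulated event picks one module and
#' two of its members, so module members share many splicing targets (the
#' co-regulation structure Stage II exploits). The event's tumor PSI is
#' \code{logistic(strength/sqrt(2) * (z(reg1) + z(reg2)) + z(host expr) +
#' noise)} with a distinct host gene. Unregulated events are
#' Beta-distributed noise. Normal PSI is drawn with low means for regulated
#' events (and for half of the unregulated ones, which therefore survive
#' the fold-change filter as decoys).
#'
#' @param net A \code{\link{gene_network}}.
#' @param labels A \code{\link{label_set}}.
#' @param expr The expression matrix from \code{\link{generate_omics}}.
#' @param cfg A \code{\link{synthetic_config}}.
#' @return List: \code{tumor} and \code{normal} (\code{\link{psi_matrix}}),
#'   \code{truth} (data frame regulator/event of planted edges).
#' @export
generate_splicing <- function(net, labels, expr, cfg) {
  set.seed(stage_seed(cfg, 4L))
  n_ev <- cfg$n_events
  n_reg <- round(cfg$frac_regulated_events * n_ev)
  classes <- c("SE", "MX", "A5", "A3", "RI", "AF", "AL")
  # planted regulators: positives grouped in modules of 3; an event is
  # driven by 2 members of one module, so module members share targets
  n_regulators <- max(3L, min(length(labels$positives) -
                                length(labels$positives) %% 3L, 9L))
  regulators <- sort(sample(labels$positives, n_regulators))
  modules <- split(regulators, (seq_along(regulators) - 1L) %/% 3L)
  reg_of_event <- matrix(NA_character_, nrow = n_reg, ncol = 2L)
  for (j in seq_len(n_reg)) {
    mod <- modules[[sample(length(modules), 1L)]]
    reg_of_event[j, ] <- sample(mod, 2L)
  }
  hosts <- character(n_ev)
  for (j in seq_len(n_ev)) {
    excl <- if (j <= n_reg) reg_of_event[j, ] else character()
    hosts[j] <- sample(setdiff(net$nodes, excl), 1L)
  }
  event_ids <- sprintf("%s;%s;chr1:%d-%d:+", hosts,
                       classes[(seq_len(n_ev) - 1L) %% 7L + 1L],
                       1000L * seq_len(n_ev), 1000L * seq_len(n_ev) + 500L)

  tum_samples <- colnames(expr)
  nt <- length(tum_samples)
  z <- function(x) (x - mean(x)) / max(stats::sd(x), 1e-9)
  tumor <- matrix(NA_real_, n_ev, nt, dimnames = list(event_ids, tum_samples))
  for (j in seq_len(n_ev)) {
    if (j <= n_reg) {
      lin <- cfg$regulation_strength / sqrt(2) *
        (z(expr[reg_of_event[j, 1L], ]) + z(expr[reg_of_event[j, 2L], ])) +
        z(expr[hosts[j], ]) + stats::rnorm(nt, 0, cfg$noise_sd)
      tumor[j, ] <- 1 / (1 + exp(-lin))
    } else {
      tumor[j, ] <- stats::rbeta(nt, 2, 2)
    }
  }
  nn <- cfg$n_samples_normal
  normal_samples <- sprintf("n%03d", seq_len(nn))
  normal <- matrix(NA_real_, n_ev, nn,
                   dimnames = list(event_ids, normal_samples))
  low_mean <- c(rep(TRUE, n_reg),                       # regulated: shifted
                rep(c(TRUE, FALSE), length.out = n_ev - n_reg))
  for (j in seq_len(n_ev)) {
    normal[j, ] <- if (low_mean[j]) stats::rbeta(nn, 0.5, 9.5)
                   else stats::rbeta(nn, 2, 2)
  }

  ev_df <- parse_event_ids(event_ids)
  list(tumor = psi_matrix(ev_df, tumor, "tumor"),
       normal = psi_matrix(ev_df, normal, "normal"),
       truth = data.frame(regulator = as.vector(t(reg_of_event)),
                          event = rep(event_ids[seq_len(n_reg)], each = 2L),
                          stringsAsFactors = FALSE))
}

#' Generate a full synthetic dataset in memory
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return List: \code{network}, \code{labels}, \code{omics} (list of 4),
#'   \code{splicing} (tumor/normal/truth), \code{config}.
#' @export
generate_bundle <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  labels <- generate_labels(net, cfg)
  omics <- generate_omics(net, labels, cfg)
  splicing <- generate_splicing(net, labels, omics$expression, cfg)
  list(network = net, labels = labels, omics = omics,
       splicing = splicing, config = cfg)
}

#' Write a synthetic dataset to disk in the package's file formats
#'
#' Produces \code{edges.tsv}, the four omics TSVs, \code{pos.txt} /
#' \code{neg.txt}, tumor/normal PSI TSVs, the planted-edge truth table and
#' a \code{manifest.json} recording the configuration. Identical
#' configuration and seed give byte-identical files.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory bundle with a \code{files} element.
#' @export
generate_dataset <- function(cfg = synthetic_config(), dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  bundle <- generate_bundle(cfg)
  f <- function(x) file.path(dir, x)
  writeLines(paste(bundle$network$edges[, 1L], bundle$network$edges[, 2L],
                   sep = "\t"), f("edges.tsv"))
  write_omics_matrix(bundle$omics$expression, f("exp.tsv"))
  write_omics_matrix(bundle$omics$mutation, f("mut.tsv"))
  write_omics_matrix(bundle$omics$methylation, f("meth.tsv"))
  write_omics_matrix(bundle$omics$cnv, f("cnv.tsv"))
  writeLines(bundle$labels$positives, f("pos.txt"))
  writeLines(bundle$labels$negatives, f("neg.txt"))
  write_psi_matrix(bundle$splicing$tumor, f("psi_tumor.tsv"))
  write_psi_matrix(bundle$splicing$normal, f("psi_normal.tsv"))
  utils::write.table(bundle$splicing$truth, f("truth_splicing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- unclass(bundle$config)
  jsonlite::write_json(manifest, f("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$files <- list(
    edges = f("edges.tsv"), expression = f("exp.tsv"),
    mutation = f("mut.tsv"), methylation = f("meth.tsv"),
    cnv = f("cnv.tsv"), positives = f("pos.txt"), negatives = f("neg.txt"),
    psi_tumor = f("psi_tumor.tsv"), psi_normal = f("psi_normal.tsv"),
    truth = f("truth_splicing.tsv"), manifest = f("manifest.json"))
  invisible(bundle)
}
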