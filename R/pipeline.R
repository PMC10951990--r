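#' Default pipeline configuration
#'
#' Single configuration list with sections \code{data}, \code{himgcn},
#' \code{splice_opt}, \code{evaluation} and \code{simulate}; every value
#' can be overridden from a YAML file or programmatically. One top-level
#' seed fans out deterministically to every stage.
#'
#' @param seed Top-level seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 17L) {
  list(
    seed = as.integer(seed),
    data = list(network = NULL, expression = NULL, mutation = NULL,
                methylation = NULL, cnv = NULL, positives = NULL,
                negatives = NULL, psi_tumor = NULL, psi_normal = NULL,
                variance_ratios = list(expression = 0.98, mutation = 0.7,
                                       methylation = 0.98, cnv = 0.7)),
    himgcn = list(per_omics_out_dim = 50L, hidden_dim = 100L,
                  learning_rate = 0.001, epochs = NULL,
                  preset = "pan_cancer", lambda1 = 5e-4, lambda2 = 5e-4,
                  folds = 3L, candidate_cutoff = 0.7,
                  score_mode = "full"),
    splice_opt = list(n_perm = 5L, fdr_level = 0.05,
                      coregulation_threshold = 0.3, pagerank_alpha = 0.5,
                      filter = list(min_mean_psi = 0.1,
                                    min_abs_log2fc = 1.5,
                                    min_tumor_fraction_expressed = 0.5,
                                    require_in_normal = TRUE,
                                    min_psi_variance = 0)),
    evaluation = list(threshold = 0.5, aucn = c(10L, 50L, 100L)),
    simulate = list(preset = "easy", overrides = list())
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override \code{\link{default_config}};
#' everything else keeps its default.
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

merge_config <- function(overrides = list()) {
  modifyList(default_config(), overrides)
}

#' Run the full two-stage prioritization pipeline
#'
#' Loads the input files named in \code{config$data} (or, if none are
#' given, simulates a dataset with the \code{config$simulate} preset),
#' fits the Stage-I hierarchical GCN, selects candidates, and — when PSI
#' matrices are available — runs the Stage-II co-splicing optimization.
#' All intermediate tables, the final ranked gene table (gene,
#' stage1_prob, stage2_prob, rank) and a JSON run manifest are written to
#' \code{out_dir}. Stage II is skipped, with a notice and a manifest mark,
#' when PSI inputs are absent; a stage failure aborts with the stage name,
#' retaining partial outputs under \code{out_dir/partial}.
#'
#' @param config Configuration list (see \code{\link{default_config}}), a
#'   YAML path, or \code{NULL} for all defaults (simulation mode).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted model, the final table and
#'   the manifest.
#' @export
glims_run <- function(config = NULL, out_dir) {
  if (is.character(config)) config <- load_config(config)
  cfg <- merge_config(config %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(package_version = as.character(utils::packageVersion("glims")),
                   seed = cfg$seed, config = cfg, stages = list())
  fail <- function(stage, e) {
    partial <- file.path(out_dir, "partial")
    dir.create(partial, showWarnings = FALSE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # --- inputs -------------------------------------------------------------
  simulated <- is.null(cfg$data$network)
  inputs <- tryCatch({
    if (simulated) {
      scfg <- do.call(synthetic_config,
                      c(list(preset = cfg$simulate$preset, seed = cfg$seed),
                        cfg$simulate$overrides))
      bundle <- generate_bundle(scfg)
      list(network = bundle$network, labels = bundle$labels,
           omics = bundle$omics,
           psi_tumor = bundle$splicing$tumor,
           psi_normal = bundle$splicing$normal)
    } else {
      net <- load_edge_list(cfg$data$network)
      omics <- list(
        expression = load_omics_matrix(cfg$data$expression, "expression"),
        mutation = load_omics_matrix(cfg$data$mutation, "mutation"),
        methylation = load_omics_matrix(cfg$data$methylation, "methylation"),
        cnv = load_omics_matrix(cfg$data$cnv, "cnv"))
      common <- Reduce(intersect, lapply(omics, rownames))
      net <- max_connected_subnetwork(net, common)
      labels <- label_set(load_gene_list(cfg$data$positives),
                          load_gene_list(cfg$data$negatives), net$nodes)
      pt <- pn <- NULL
      if (!is.null(cfg$data$psi_tumor) && !is.null(cfg$data$psi_normal)) {
        pt <- load_psi_matrix(cfg$data$psi_tumor, "tumor")
        pn <- load_psi_matrix(cfg$data$psi_normal, "normal")
      }
      list(network = net, labels = labels, omics = omics,
           psi_tumor = pt, psi_normal = pn)
    }
  }, error = function(e) fail("load", e))
  manifest$stages$load <- list(status = "complete",
                               n_genes = length(inputs$network$nodes),
                               n_edges = nrow(inputs$network$edges),
                               simulated = simulated)

  # --- stage I ------------------------------------------------------------
  hc <- cfg$himgcn
  control <- himgcn_control(per_omics_out_dim = hc$per_omics_out_dim,
                            hidden_dim = hc$hidden_dim,
                            learning_rate = hc$learning_rate,
                            epochs = hc$epochs, preset = hc$preset,
                            lambda1 = hc$lambda1, lambda2 = hc$lambda2,
                            folds = hc$folds, seed = cfg$seed)
  fit <- tryCatch({
    features <- prepare_features(inputs$network,
                                 inputs$omics$expression,
                                 inputs$omics$mutation,
                                 inputs$omics$methylation,
                                 inputs$omics$cnv,
                                 cfg$data$variance_ratios)
    himgcn(inputs$network, features, inputs$labels, control,
           score_mode = hc$score_mode)
  }, error = function(e) fail("himgcn", e))
  write_scores(fit$scores, file.path(out_dir, "stage1_scores.tsv"))
  utils::write.table(fit$cv_metrics, file.path(out_dir, "cv_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  candidates <- select_candidates(fit$scores, hc$candidate_cutoff)
  manifest$stages$himgcn <- list(
    status = "complete",
    cv_mean_auroc = if (!is.null(fit$cv_metrics)) mean(fit$cv_metrics$auroc),
    n_candidates = length(candidates))

  # --- stage II -----------------------------------------------------------
  stage2 <- NULL
  if (is.null(inputs$psi_tumor) || length(candidates) < 2L) {
    message("stage II skipped: ",
            if (is.null(inputs$psi_tumor)) "no PSI inputs"
            else "fewer than 2 candidates")
    manifest$stages$splice_opt <- list(status = "skipped")
    final_scores <- fit$scores
    stage2_prob <- rep(NA_real_, length(fit$scores))
  } else {
    stage2 <- tryCatch({
      fcfg <- do.call(as_filter_config, cfg$splice_opt$filter)
      events <- filter_as_events(inputs$psi_tumor, inputs$psi_normal, fcfg)
      cos <- build_cosplicing_network(candidates, inputs$omics$expression,
                                      events,
                                      n_perm = cfg$splice_opt$n_perm,
                                      fdr_level = cfg$splice_opt$fdr_level,
                                      seed = cfg$seed)
      coreg <- build_coregulation_network(
        cos, cfg$splice_opt$coregulation_threshold)
      post <- reprioritize(fit$scores[candidates], coreg,
                           alpha = cfg$splice_opt$pagerank_alpha)
      list(events = events, cosplice = cos, coreg = coreg, post = post)
    }, error = function(e) fail("splice_opt", e))
    utils::write.table(stage2$cosplice$edges,
                       file.path(out_dir, "cosplicing_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stage2$coreg$edges,
                       file.path(out_dir, "coregulation_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    final_scores <- fit$scores
    final_scores[names(stage2$post)] <- stage2$post
    stage2_prob <- rep(NA_real_, length(fit$scores))
    names(stage2_prob) <- names(fit$scores)
    stage2_prob[names(stage2$post)] <- stage2$post
    stage2_prob <- unname(stage2_prob)
    manifest$stages$splice_opt <- list(
      status = "complete",
      n_filtered_events = nrow(stage2$events$events),
      cutoff = stage2$cosplice$cutoff,
      n_cosplicing_edges = nrow(stage2$cosplice$edges),
      n_coregulation_edges = nrow(stage2$coreg$edges))
  }

  ord <- order(-final_scores, names(fit$scores))
  final <- data.frame(gene = names(fit$scores)[ord],
                      stage1_prob = unname(fit$scores)[ord],
                      stage2_prob = stage2_prob[ord],
                      rank = seq_along(ord),
                      stringsAsFactors = FALSE)
  utils::write.table(format_final(final), file.path(out_dir, "final_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  # atomic write: temp file then rename
  tmp <- tempfile(tmpdir = out_dir)
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(list(fit = fit, stage2 = stage2, final = final,
                 manifest = manifest))
}

format_final <- function(df) {
  df$stage1_prob <- sprintf("%.10g", df$stage1_prob)
  df$stage2_prob <- ifelse(is.na(df$stage2_prob), "NA",
                           sprintf("%.10g", df$stage2_prob))
  df
}

#' Write a gene score table as two-column TSV
#' @param scores Named numeric vector.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene\tprobability", con)
  writeLines(paste(names(scores), sprintf("%.10g", scores), sep = "\t"), con)
}

#' Read a gene score table written by \code{\link{write_scores}}
#' @param path Path to the TSV.
#' @return Named numeric vector.
#' @export
load_scores <- function(path) {
  m <- load_omics_matrix(path, kind = "scores")
  stats::setNames(m[, 1L], rownames(m))
}
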