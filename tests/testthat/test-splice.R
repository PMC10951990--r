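toy_psi_pair <- function() {
  # five events with tumor/normal mean pairs:
  #   e1: 0.05 / 0.5  -> fails mean > 0.1
  #   e2: 0.4  / 0.1  -> |log2FC| ~ 1.99 -> kept
  #   e3: 0.4  / 0.4  -> log2FC 0 -> dropped
  #   e4: 0.6  / 0.1  -> |log2FC| ~ 2.57 -> kept
  #   e5: 0.3  / absent -> fails the normal-presence rule
  ids <- sprintf("G%d;SE;chr1:%d-%d:+", 1:5, 1:5, 11:15)
  tum <- matrix(rep(c(0.05, 0.4, 0.4, 0.6, 0.3), 4), 5, 4,
                dimnames = list(ids, sprintf("t%d", 1:4)))
  nor <- matrix(rep(c(0.5, 0.1, 0.4, 0.1), 3), 4, 3,
                dimnames = list(ids[1:4], sprintf("m%d", 1:3)))
  list(tumor = make_psi(tum, "tumor"), normal = make_psi(nor, "normal"))
}

test_that("AS-event filtering applies mean, fold-change and presence rules", {
  fx <- toy_psi_pair()
  kept <- filter_as_events(fx$tumor, fx$normal)
  expect_setequal(kept$events$gene, c("G2", "G4"))
  # hand-checked fold changes with the 1e-3 pseudo-count
  expect_equal(kept$events$log2fc,
               log2(c(0.401, 0.601) / 0.101), tolerance = 1e-12)

  # without the presence requirement e5 is compared against mean 0 and kept
  kept2 <- filter_as_events(fx$tumor, fx$normal,
                            as_filter_config(require_in_normal = FALSE))
  expect_true("G5" %in% kept2$events$gene)

  # expression-fraction rule: event mostly missing in tumor is dropped
  tum3 <- fx$tumor
  tum3$psi[2, 1:3] <- NA
  kept3 <- filter_as_events(tum3, fx$normal)
  expect_false("G2" %in% kept3$events$gene)

  empty <- fx$tumor
  empty$psi <- empty$psi[0, , drop = FALSE]
  empty$events <- empty$events[0, , drop = FALSE]
  expect_error(filter_as_events(empty, fx$normal), "empty tumor")
})

test_that("partial correlation follows the first-order formula", {
  # zero conditioning returns the raw correlation
  expect_equal(partial_correlation(0.6, 0, 0), 0.6)
  # hand-derived: (0.8 - 0.25) / 0.75
  expect_equal(partial_correlation(0.8, 0.5, 0.5), 0.55 / 0.75,
               tolerance = 1e-12)
  expect_error(partial_correlation(0.5, 1, 0), "degenerate")

  # residual-regression oracle on a simulated triple
  set.seed(63)
  n <- 200
  h <- rnorm(n)                # host-gene expression
  g <- 0.7 * h + rnorm(n)      # focus gene, confounded through the host
  e <- 0.5 * h + 0.4 * g + rnorm(n)  # event PSI driver
  pr <- partial_correlation(cor(g, e), cor(h, e), cor(g, h))
  res_g <- resid(lm(g ~ h))
  res_e <- resid(lm(e ~ h))
  expect_equal(pr, cor(res_g, res_e), tolerance = 0.02)
})

test_that("gene-event correlation tables match a per-pair oracle", {
  set.seed(71)
  genes <- c("gA", "gB", "gC", "gD")
  samples <- sprintf("s%d", 1:30)
  expr <- matrix(rnorm(4 * 30), 4, 30, dimnames = list(genes, samples))
  ids <- c("gC;SE;1-2:+", "gD;RI;3-4:+", "gD;A5;5-6:+")
  psi <- matrix(runif(3 * 30), 3, 30, dimnames = list(ids, samples))
  psi[1, ] <- plogis(2 * scale(expr["gA", ])[, 1] + rnorm(30, 0, 0.2))
  events <- structure(list(events = glims:::parse_event_ids(ids), psi = psi),
                      class = "as_event_table")

  tab <- suppressMessages(gene_event_correlations(genes, expr, events))
  # hosts excluded from their own events
  expect_false(any(tab$gene == tab$host))
  # every row agrees with a direct recomputation
  for (r in seq_len(nrow(tab))) {
    g <- tab$gene[r]; ev <- tab$event[r]; h <- tab$host[r]
    r_ge <- cor(expr[g, ], psi[ev, ])
    r_he <- cor(expr[h, ], psi[ev, ])
    r_gh <- cor(expr[g, ], expr[h, ])
    expect_equal(tab$r[r], r_ge, tolerance = 1e-10)
    expect_equal(tab$partial_r[r],
                 (r_ge - r_he * r_gh) / sqrt((1 - r_he^2) * (1 - r_gh^2)),
                 tolerance = 1e-10)
  }
  # the planted gA -> event 1 signal is the strongest entry
  top <- tab[which.max(abs(tab$partial_r)), ]
  expect_equal(top$gene, "gA")
  expect_equal(top$event, ids[1])

  # constant PSI rows are skipped with a count, not propagated as NA
  psi2 <- psi
  psi2[2, ] <- 0.5
  events2 <- structure(list(events = glims:::parse_event_ids(ids),
                            psi = psi2), class = "as_event_table")
  expect_message(tab2 <- gene_event_correlations(genes, expr, events2),
                 "skipped")
  expect_false(ids[2] %in% tab2$event)
  expect_false(anyNA(tab2$partial_r))

  expect_error(gene_event_correlations(genes, expr[, 1:2],
                                       events), "need >= 3")
})

test_that("permutation FDR cutoff separates signal from exchangeable noise", {
  set.seed(81)
  genes <- sprintf("g%d", 1:6)
  samples <- sprintf("s%d", 1:40)
  expr <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(genes, samples))
  ids <- sprintf("g%d;SE;%d-%d:+", rep(5:6, 4), 1:8, 11:18)
  hosts <- matrix(rnorm(8 * 40), 8, 40)
  psi <- plogis(hosts * 0.3 + rnorm(8 * 40, 0, 0.5))
  dimnames(psi) <- list(ids, samples)
  # plant strong signal from g1 into events 1-3
  for (j in 1:3) psi[j, ] <- plogis(3 * scale(expr["g1", ])[, 1] +
                                      rnorm(40, 0, 0.2))
  events <- structure(list(events = glims:::parse_event_ids(ids), psi = psi),
                      class = "as_event_table")
  tab <- suppressMessages(gene_event_correlations(genes, expr, events))
  cut <- permutation_fdr_cutoff(abs(tab$partial_r), genes, expr, events,
                                n_perm = 5, fdr_level = 0.05, seed = 3)
  expect_true(is.finite(cut))

  # independent brute-force FDR scan with the same permutation stream
  set.seed(3)
  null_r <- c()
  for (b in 1:5) {
    e2 <- expr[, sample(ncol(expr))]
    colnames(e2) <- samples
    ev2 <- events
    ev2$psi <- psi[, sample(ncol(psi))]
    colnames(ev2$psi) <- samples
    null_r <- c(null_r, abs(suppressMessages(
      gene_event_correlations(genes, e2, ev2))$partial_r))
  }
  obs <- sort(unique(abs(tab$partial_r)))
  fdr <- sapply(obs, function(cc)
    (sum(null_r >= cc) / 5) / max(1, sum(abs(tab$partial_r) >= cc)))
  expect_equal(cut, obs[which(fdr < 0.05)[1]], ignore_attr = TRUE)

  # the planted edges clear the cutoff
  strong <- tab[abs(tab$partial_r) >= cut, ]
  expect_true(all(paste("g1", ids[1:3]) %in%
                    paste(strong$gene, strong$event)))

  # null distributions perfectly separated below the observed values
  small <- abs(tab$partial_r[tab$gene == "g1" & tab$event %in% ids[1:3]])
  cut2 <- permutation_fdr_cutoff(small, genes[1], expr, events,
                                 n_perm = 2, fdr_level = 0.5, seed = 5)
  expect_equal(as.numeric(cut2), min(small))

  expect_error(permutation_fdr_cutoff(numeric(), genes, expr, events),
               "no observed")
})

test_that("observed-equals-null data yields the empty-network sentinel", {
  set.seed(99)
  genes <- sprintf("g%d", 1:4)
  samples <- sprintf("s%d", 1:25)
  expr <- matrix(rnorm(4 * 25), 4, 25, dimnames = list(genes, samples))
  ids <- sprintf("g%d;SE;%d-%d:+", rep(3:4, 3), 1:6, 11:16)
  psi <- matrix(runif(6 * 25), 6, 25, dimnames = list(ids, samples))
  events <- structure(list(events = glims:::parse_event_ids(ids), psi = psi),
                      class = "as_event_table")
  tab <- suppressMessages(gene_event_correlations(genes, expr, events))
  cut <- permutation_fdr_cutoff(abs(tab$partial_r), genes, expr, events,
                                n_perm = 5, fdr_level = 0.05, seed = 7)
  expect_identical(as.numeric(cut), Inf)
})

test_that("Dice co-regulation weights and network thresholding", {
  expect_equal(coregulation_weight(c("a", "b"), c("a", "b")), 1)
  expect_equal(coregulation_weight(c("a"), c("b")), 0)
  expect_equal(coregulation_weight(c("a", "b", "c"), c("a", "d")), 0.4)
  # symmetry over random set fixtures
  set.seed(5)
  for (i in 1:10) {
    t1 <- sample(letters, sample(1:8, 1))
    t2 <- sample(letters, sample(1:8, 1))
    expect_equal(coregulation_weight(t1, t2), coregulation_weight(t2, t1))
  }
  expect_error(coregulation_weight(character(), character()), "empty")
})

test_that("co-regulation network matches an all-pairs oracle, inclusive at 0.3", {
  targets <- list(gA = c("e1", "e2", "e3"), gB = c("e1", "e2", "e4"),
                  gC = c("e5", "e6"), gD = c("e5", "e6"),
                  gE = c("e1", "e7", "e8", "e9", "e10", "e11", "e12"))
  edges <- do.call(rbind, lapply(names(targets), function(g)
    data.frame(gene = g, event = targets[[g]], host = "h", r = 0.9,
               partial_r = 0.9, stringsAsFactors = FALSE)))
  cos <- structure(list(edges = edges, cutoff = 0.5,
                        candidates = c(names(targets), "gIso"), seed = 1),
                   class = "cosplicing_network")
  coreg <- build_coregulation_network(cos, 0.3)
  # exhaustive pairwise Dice: gA-gB = 4/6, gC-gD = 1, gA-gE = 2/10 (below)
  got <- paste(coreg$edges$gene_a, coreg$edges$gene_b)
  expect_setequal(got, c("gA gB", "gC gD"))
  expect_equal(coreg$edges$weight[got == "gA gB"], 2 * 2 / 6)
  # isolated candidates retained as nodes
  expect_true("gIso" %in% coreg$nodes)

  # weight exactly at threshold is retained (inclusive)
  t2 <- list(g1 = c("e1", "e2", "e3"), g2 = c("e1", "e4", "e5", "e6",
                                              "e7", "e8", "e9"))
  # Dice = 2*1/10 = 0.2 -> dropped at 0.3; use sets giving exactly 0.3:
  t3 <- list(g1 = sprintf("a%d", 1:7), g2 = c("a1", "a2", sprintf("b%d", 1:11)))
  # |T1| = 7, |T2| = 13, shared 2 -> 2*2/20 = 0.2; build exact 0.3 instead
  t4 <- list(g1 = sprintf("a%d", 1:10), g2 = c("a1", "a2", "a3",
                                               sprintf("b%d", 1:7)))
  # 2*3/20 = 0.3 exactly
  e4 <- do.call(rbind, lapply(names(t4), function(g)
    data.frame(gene = g, event = t4[[g]], host = "h", r = 1, partial_r = 1,
               stringsAsFactors = FALSE)))
  cos4 <- structure(list(edges = e4, cutoff = 0.5, candidates = names(t4),
                         seed = 1), class = "cosplicing_network")
  coreg4 <- build_coregulation_network(cos4, 0.3)
  expect_equal(nrow(coreg4$edges), 1L)
  expect_equal(coreg4$edges$weight, 0.3)
})

test_that("PageRank with restart matches closed forms and conserves mass", {
  # 2-node single edge, prior (1, 0), alpha 0.5 -> (2/3, 1/3)
  cn <- make_coreg(c("a", "b"),
                   data.frame(gene_a = "a", gene_b = "b", weight = 1))
  p <- pagerank(cn, c(a = 1, b = 0), alpha = 0.5)
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # regular graph + uniform prior -> uniform stationary vector
  ring <- make_coreg(sprintf("v%d", 1:6),
                     data.frame(gene_a = sprintf("v%d", 1:6),
                                gene_b = sprintf("v%d", c(2:6, 1)),
                                weight = 1))
  pu <- pagerank(ring, stats::setNames(rep(1 / 6, 6), sprintf("v%d", 1:6)),
                 alpha = 0.3)
  expect_equal(unname(pu), rep(1 / 6, 6), tolerance = 1e-9)

  # stochasticity: output sums to 1 for arbitrary priors/dangling nodes
  set.seed(15)
  for (i in 1:5) {
    nodes <- sprintf("n%d", 1:8)
    edges <- data.frame(gene_a = sample(nodes[1:5], 6, TRUE),
                        gene_b = sample(nodes[1:5], 6, TRUE),
                        weight = runif(6))
    edges <- edges[edges$gene_a != edges$gene_b, ]
    cn2 <- make_coreg(nodes, edges)          # n6-n8 dangle
    prior <- runif(8)
    prior <- stats::setNames(prior / sum(prior), nodes)
    p2 <- pagerank(cn2, prior, alpha = 0.5)
    expect_equal(sum(p2), 1, tolerance = 1e-9)
  }
  expect_error(pagerank(make_coreg(character()), c(a = 1)), "empty")
})

test_that("PageRank agrees with an established implementation", {
  set.seed(25)
  nodes <- sprintf("n%d", 1:7)
  edges <- data.frame(gene_a = c("n1", "n1", "n2", "n3", "n4", "n5"),
                      gene_b = c("n2", "n3", "n3", "n4", "n5", "n6"),
                      weight = runif(6, 0.2, 1))
  cn <- make_coreg(nodes, edges)
  prior <- runif(7)
  prior <- stats::setNames(prior / sum(prior), nodes)
  alpha <- 0.4
  mine <- pagerank(cn, prior, alpha = alpha)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = nodes))
  # igraph's damping is the propagation weight 1 - alpha; igraph also
  # redistributes dangling mass to the personalization vector
  ref <- igraph::page_rank(g, personalized = prior[nodes],
                           weights = edges$weight,
                           damping = 1 - alpha)$vector
  expect_equal(unname(mine[nodes]), unname(ref[nodes]), tolerance = 1e-6)
})

test_that("PageRank is invariant under node relabeling", {
  cn <- make_coreg(c("a", "b", "c"),
                   data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                              weight = c(1, 0.5)))
  prior <- c(a = 0.5, b = 0.3, c = 0.2)
  p1 <- pagerank(cn, prior)
  ren <- c(a = "x", b = "y", c = "z")
  cn2 <- make_coreg(unname(ren[cn$nodes]),
                    data.frame(gene_a = unname(ren[c("a", "b")]),
                               gene_b = unname(ren[c("b", "c")]),
                               weight = c(1, 0.5)))
  p2 <- pagerank(cn2, stats::setNames(unname(prior), unname(ren[names(prior)])))
  expect_equal(unname(p2), unname(p1), tolerance = 1e-12)
})

test_that("reprioritization rescales, preserves ties, and promotes hubs", {
  # single-node network: max-normalized score is 1
  single <- make_coreg("g1")
  out <- reprioritize(c(g1 = 0.8), single)
  expect_equal(unname(out["g1"]), 1)

  # equal priors on a regular graph keep the tie
  ring <- make_coreg(sprintf("v%d", 1:4),
                     data.frame(gene_a = sprintf("v%d", 1:4),
                                gene_b = sprintf("v%d", c(2:4, 1)),
                                weight = 1))
  tied <- stats::setNames(rep(0.9, 4), sprintf("v%d", 1:4))
  out2 <- reprioritize(tied, ring)
  expect_equal(unname(out2), rep(1, 4), ignore_attr = TRUE)

  # planted hub: sharing targets with everyone improves (or keeps) its rank
  nodes <- sprintf("g%d", 1:5)
  hub_edges <- data.frame(gene_a = "g5", gene_b = nodes[1:4], weight = 0.8)
  hub <- make_coreg(nodes, hub_edges)
  pre <- stats::setNames(c(0.95, 0.9, 0.85, 0.8, 0.75), nodes)  # hub last
  post <- reprioritize(pre, hub)
  rank_pre <- match("g5", names(sort(-pre)))
  rank_post <- match("g5", names(sort(-post)))
  expect_lte(rank_post, rank_pre)

  # genes outside the network keep their stage-I score, flagged
  out3 <- reprioritize(c(g1 = 0.8, far = 0.4), single)
  expect_equal(unname(out3["far"]), 0.4)
  expect_false(attr(out3, "in_network")[["far"]])
})
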