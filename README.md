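# glims

Two-stage prioritization of candidate cancer genes from multi-omics data
and alternative-splicing co-regulation.

## The problem

Known cancer genes are few, candidate genes are many, and no single omics
layer separates them. `glims` is for computational biologists who have (i)
gene-level matrices of expression, mutation frequency, methylation and
copy number across tumor samples, (ii) a gene interaction (PPI) network,
(iii) short lists of known cancer genes (positives) and confidently
unrelated genes (negatives), and optionally (iv) tumor and normal
percent-spliced-in (PSI) matrices for alternative-splicing events. It
produces a per-gene probability of being a cancer gene, then refines the
top candidates using post-transcriptional co-regulation structure.

## The model

**Stage I — hierarchical graph convolution (HIM-GCN).** With adjacency
*A*, self-connections *Ã = A + I*, degrees *D̃*, the propagation operator
is *Â = D̃^(−1/2) Ã D̃^(−1/2)*. Each omics feature matrix *X_t* (PCA-reduced)
passes through a one-layer graph convolution

&nbsp;&nbsp;&nbsp;&nbsp;*Z_t = ReLU(Â X_t W_t)*,&nbsp;&nbsp; t ∈ {exp, mut, meth, cnv},

the four representations are concatenated, *X_int = Z_exp ⊕ Z_mut ⊕
Z_meth ⊕ Z_cnv*, and a two-layer integrative convolution produces a logit
per gene, mapped by the logistic function to a probability. Training is
semi-supervised (unlabeled genes propagate but carry no loss) and
imbalance-weighted:

&nbsp;&nbsp;&nbsp;&nbsp;*L = −(1/N) Σ [α₁ y log p + α₂ (1−y) log(1−p)] +
λ₁‖W‖₁ + λ₂‖W‖₂²*,&nbsp;&nbsp; α₁ = N/N₊, α₂ = N/N₋,

minimized with full-batch Adam under 3-fold stratified cross-validation.

**Stage II — co-splicing refinement.** Candidates (probability > 0.7) are
linked to differential splicing events via the first-order partial
correlation *r(g, e | host)* = (r_ge − r_he·r_gh)/√((1−r_he²)(1−r_gh²)),
thresholded by a permutation FDR cutoff (5 sample-label shuffles,
FDR < 0.05). Genes sharing event targets are joined with the Dice weight
*W(g_i, g_j) = 2|T_i ∩ T_j| / (|T_i| + |T_j|)* (kept at weight ≥ 0.3), and
candidate scores are re-prioritized by PageRank with restart,
*p_{k+1} = α p₀ + (1−α) A D^(−1) p_k*, with the Stage-I probabilities as
prior. Rankings are compared with the partial-ROC statistic
*AUCn = (1/nT) Σᵢ Tᵢ*.

## Worked example

The package ships a seeded generator that plants exactly the structure the
method exploits — an assortative community network, class-shifted omics,
and positive genes that co-regulate shared splicing events:

```r
library(glims)

cfg    <- synthetic_config("easy", seed = 101L)   # 1000 genes, 100 samples
bundle <- generate_bundle(cfg)
feats  <- prepare_features(bundle$network, bundle$omics$expression,
                           bundle$omics$mutation, bundle$omics$methylation,
                           bundle$omics$cnv)
fit    <- himgcn(bundle$network, feats, bundle$labels,
                 himgcn_control(epochs = 400L, seed = 101L))
summary(fit)
#> Hierarchical GCN model over 1000 genes
#> Labels: 80 positive, 250 negative
#>
#> Cross-validation (held-out, per fold):
#>  fold  accuracy     auroc     auprc        f1
#>     1 0.9639640 0.9788360 0.9094392 0.9310345
#>     2 0.9727273 0.9794734 0.8984697 0.9473684
#>     3 0.9816514 0.9884152 0.9340365 0.9629630
#>
#> Mean: accuracy 0.9728  auroc 0.9822  auprc 0.9140  f1 0.9471
#> ...
#> Candidates with probability > 0.7 : 200
```

Held-out AUROC ≈ 0.98 means the model almost perfectly separates planted
cancer genes from negatives; ~200 genes clear the 0.7 candidate cutoff
(the 80 planted positives plus their network neighborhood). Stage II then
tightens the top of the ranking:

```r
cand  <- select_candidates(fit$scores)
ev    <- filter_as_events(bundle$splicing$tumor, bundle$splicing$normal)
cos   <- build_cosplicing_network(cand, bundle$omics$expression, ev, seed = 101L)
coreg <- build_coregulation_network(cos)
post  <- reprioritize(fit$scores[cand], coreg)

labs  <- label_set(intersect(cand, bundle$labels$positives),
                   setdiff(cand, bundle$labels$positives), cand)
auc_n(rank_genes(fit$scores[cand], labs), 10)  # 0.0525
auc_n(rank_genes(post, labs), 10)              # 0.1375
```

AUC₁₀ — the fraction of true positives ranked above each of the ten
best-ranked non-positives — more than doubles after co-splicing
re-prioritization: genes that share splicing targets with other strong
candidates move up, isolated false positives move down.

The whole pipeline, including file I/O and a run manifest, is one call
(`glims_run(config, out_dir)`) or one shell command
(`Rscript inst/cli/glims.R run --seed 17 --out run/`).

## Documentation

The methods vignette (`vignettes/glims-methods.Rmd`) describes the model,
its assumptions, every tunable threshold, the synthetic-data design and
known limitations.
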