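# regnet

Inference of RBP-, TF- and miRNA-mediated regulation of gene expression in
cancer, by per-sample lasso regression of expression on genetic, epigenetic
and binding-site features.

Most regression studies of tumor expression use copy number, methylation, TF
and miRNA features and ignore RNA-binding proteins, even though RBPs control
mRNA stability and translation and are widely dysregulated in tumors. This
package implements, as a tested and reusable pipeline, an analysis that puts
RBP binding-site features on equal footing with the classical feature
classes and asks three questions: how well do regulatory features predict a
tumor's expression profile, which regulators carry the predictive signal,
and which genes does each regulator target?

## The model

For each tumor sample, the expression of gene *g* is modelled as

```
y_g = w0 + wC·C_g + wM·M_g + Σ_TF w_TF·N_g^TF + Σ_miR w_miR·N_g^miR + Σ_RBP w_RBP·N_g^RBP + ε_g
```

where `C_g` is the gene's copy-number level, `M_g` its methylation
beta-value, and `N_g` are binding-site counts: TF motif hits in the ±2 kb
promoter (exact motif-score p-value < 1e-4, restricted to open chromatin),
and miRNA-seed / RBP-motif matches in the 3'UTR. One model is fit per
sample with an L1 (lasso) penalty on the standardized features,

```
min over (w0, w) of  (1/2n)·||y − w0 − Xw||² + λ·||w||₁,
```

λ chosen by 10-fold cross-validation. Downstream of the fits:

* **Performance** — nested cross-validation over genes; the score is the
  Spearman rank correlation between predicted and observed expression of
  held-out genes, averaged over folds and samples. Feature-class ablation
  quantifies each class's added predictive value.
* **Candidate regulators** — fixed-λ polyhedral (selective) inference gives
  valid p-values for the lasso-selected features of each sample; regulators
  are ranked by the number of samples in which they are selected with
  p < 0.05.
* **Target genes** — removing a regulator's fitted contribution increases
  each gene's squared prediction error; the increases are summed across
  samples and compared with a permutation null (feature columns shuffled
  independently, models refit at the same λ). Empirical p-values
  `(1 + #{null ≥ obs})/(B + 1)` are FDR-adjusted per regulator
  (Benjamini–Hochberg).

A synthetic-data generator with planted regulators, weights and target sets
stands in for the tumor cohort, so every step can be validated against known
ground truth — including a sequence-level round trip in which emitted
FASTA/PFM/BED fixtures rebuild the planted count matrix exactly.

## Worked example

```r
library(regnet)

cfg <- sim_config(n_genes = 500, n_samples = 12, n_tf = 6, n_mirna = 5, n_rbp = 5,
                  n_active_per_class = c(tf = 0, mirna = 0, rbp = 3),
                  site_density = 0.15, seed = 42)
sim  <- simulate_dataset(cfg)
sim$truth
#> <sim_truth> 3 active regulator(s): RBP04, RBP05, RBP03

fits <- fit_sample_models(sim$features, sim$expression, folds = 10, seed = 42)
X <- feature_design(sim$features)
Y <- as.matrix(sim$expression[-1]); rownames(Y) <- sim$expression$gene

sel <- lapply(seq_len(nrow(fits)), function(i)
  selective_pvalues(X, Y[, fits$sample[i]], fits$lambda[i],
                    sigma = fits$sigma[i], fit = fits$fit[[i]]))
count_selections(sel, n_samples = nrow(fits), alpha = 0.05,
                 feature_info = sim$features$info)
#> # A tibble: 18 × 4
#>   regulator class n_selected selection_pct
#> 1 RBP03     RBP           12        100
#> 2 RBP04     RBP           12        100
#> 3 CNV       CNV           11         91.7
#> 4 RBP05     RBP           11         91.7
#> 5 METH      METH           4         33.3
#> 6 MIR01     MIRNA          1          8.33
#> ...
```

The three planted RBPs top the selection table (selected with a significant
selective p-value in 92–100% of samples), together with the copy-number
covariate whose effect is also planted; null regulators stay below 10%.
Target discovery then recovers a planted regulator's target set:

```r
td <- discover_targets(X, Y, fits$fit, "RBP04", B = 500, seed = 42,
                       q_threshold = 0.05)
overlap_report(td$calls$gene, sim$truth$target_sets[["RBP04"]])
#> # A tibble: 1 × 4
#>   n_predicted n_reference n_overlap fraction_predicted_in_reference
#> 1          64          69        64                               1
```

All 64 called targets are true planted targets (precision 1.0, recall
64/69 ≈ 0.93). `evaluate_cv()` reports the held-out prediction skill of a
sample's model (here mean Spearman rho = 0.52 under noise SD 1), and
`autoplot()` methods display CV reports, selection tables and group-wise LFC
ECDF comparisons. `run_pipeline()` drives the whole chain from a YAML or
list configuration and writes per-stage TSV outputs plus a JSON manifest.

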