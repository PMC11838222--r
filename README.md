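# pathwaycnn

Pathway-based multi-omics integration for survival classification, with an
explainable convolutional network and per-gene survival screening — in R.

## What it does, and for whom

Given several omics matrices over one cohort (e.g. copy number, expression,
methylation), a GMT file of pathway gene sets, and a clinical table with
overall-survival times, `pathwaycnn`:

1. **harmonizes** the layers to common samples and genes, and labels each
   sample *LTS* (survival > 2 years), *non-LTS* (death ≤ 2 years) or
   *excluded* (censored ≤ 2 years);
2. **embeds** each sample as a *pathway-PC image*: for every
   (class, omics, pathway) triple a separate PCA is fitted on that class's
   samples over that pathway's genes (2 classes × 3 omics × 146 pathways =
   876 models), and the per-pathway principal-component scores form a
   `pathways × (omics × PCs)` grid — e.g. 146 × 6 with two components;
3. **classifies** LTS vs non-LTS with a compact CNN (conv → batch norm →
   ReLU → max-pool blocks, softmax head), evaluated by stratified 5-fold
   cross-validation with accuracy, precision, recall, F1, AUC and the
   pooled confusion matrix;
4. **explains** the trained model with a from-scratch gradient SHAP
   estimator,
   `phi_i = E[ df(x' + a(x - x'))/dx_i * (x_i - x'_i) ]`,
   averages attributions per class, and rolls the top-10 cells up to
   significant pathways (common vs class-unique);
5. **screens** the genes of significant pathways with Cox proportional
   hazards models (Breslow partial likelihood, Newton–Raphson), reporting
   Wald statistics `W = beta/SE`, hazard ratios `exp(beta)` with 95% CIs,
   and the `p < 0.01` gene table ready for a forest plot.

It is intended for computational biologists analysing TCGA-style cohorts
who want class-aware pathway embeddings *and* an honest, leak-free
evaluation mode: class-specific PCA consults the survival label, so the
package ships both the own-class formulation and a cross-fitted `fold-safe`
mode (see the methods vignette for why that matters).

A synthetic-data module generates full multi-omics cohorts with planted
discriminative pathways and known log-hazard coefficients, so every stage
is testable without external data.

## Worked example

```r
library(pathwaycnn)

## a synthetic cohort at study scale: 150 labelled samples, 3 omics,
## 146 pathways, two planted discriminative pathways (delta = 2 SD on EXP)
co  <- generate_multiomics(synthetic_config(seed = 101))
lab <- assign_survival_labels(co$clinical)      # > 2 y = LTS, etc.
ds  <- harmonize(co$omics, lab, co$clinical)
ds
#> <harmonized_dataset: 150 samples x 3899 genes, layers: CNV, EXP, MET>
#>
#>     LTS non-LTS
#>      60      90

## honest cross-validated classification (fold-safe embedding); the
## training protocol is scaled to the cohort size (see the vignette)
cnn <- cnn_config(epochs = 40, batch_size = 16, lr = 3e-3,
                  augment_sd = 0.10, weight_decay = 1e-3, seed = 1)
cv <- cross_validate(ds, co$pathways, n_pcs = 2, k = 5,
                     mode = "fold-safe", cnn = cnn, seed = 11)
cv$pooled
#> accuracy 0.8800  precision 0.9091  recall 0.8889  f1 0.8989  auc 0.9585  (n = 150, positive = non-LTS)
#> confusion: TP 80  TN 52  FP 8  FN 10

## interpretation: explain the fold-safe model (all samples cross-fitted)
stk <- build_image_stack(ds, co$pathways, 2, mode = "fold-safe",
                         train_ids = ds$samples, seed = 7)
y   <- ds$labels$class[match(ds$samples, ds$labels$sample_id)]
fit <- train_cnn(NULL, stk, y, cnn)
maps   <- cohort_attributions(fit, stk, y,
                              gradient_shap_config(n_baselines = 25,
                                                   n_path_samples = 4,
                                                   seed = 6))
scores <- aggregate_class_attributions(maps, as.character(y))
report <- pathway_set_analysis(scores, k = 10)
report
#> <pathway_report: top-10 cells per class>
#> common pathways: PW010, PW080, PW009, PW007
#> unique to LTS: (none)
#> unique to non-LTS: PW008, PW001

## gene-level survival screen inside the significant pathways
surv <- run_pathway_survival(ds, report, co$pathways, omics = "EXP")
head(surv$significant, 4)
#>    pathway_id   gene    beta     se   wald        p    hr ci_low ci_high significant
#> 1       PW010 G00287  0.798  0.178  4.488  7.2e-06  2.22   1.57    3.15        TRUE
#> 58      PW080 G02140  0.566  0.161  3.514  4.4e-04  1.76   1.28    2.42        TRUE
#> 40      PW080 G02122 -0.514  0.174 -2.955  3.1e-03  0.60   0.42    0.84        TRUE
#> 3       PW010 G00289  0.462  0.160  2.898  3.8e-03  1.59   1.16    2.17        TRUE
```

The pooled metrics answer "how well can held-out samples be classified
without their labels leaking into the embedding".  The pathway report
lists which (pathway, omics, PC) cells drove the model's decisions per
class: both planted pathways (PW010, PW080) head the list.  The survival
table gives per-SD hazard ratios for genes of those pathways: the
generator's planted log-hazard coefficient on G00287 (truth 0.8) is
estimated at 0.80, and G00289 (truth 0.6) at 0.46 with matching signs;
the PW080 hits are genuine indirect associations, since its planted
expression shift separates the survival classes.

A thin command-line wrapper with `simulate`, `run-all`, `cv` and
`sweep-pcs` subcommands lives at `inst/cli/pathwaycnn.R`; the number of
principal components can be swept with `sweep_n_pcs()` (AUC typically
peaks at a small count).

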