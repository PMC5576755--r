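# phyloperturb

Tree-aware multivariate analysis of longitudinal microbiome perturbation
studies.

## The problem

A strong, one-day disturbance of the gut community (for example an
iso-osmotic bowel cleanout) is bracketed by dense longitudinal sampling:
weekly samples for months on either side, daily samples in the weeks
immediately around the perturbation day (day 0). The data come as linked
tables — a sample-by-taxon count matrix, a rooted phylogeny over the taxa,
per-sample metadata (subject, study day), and a sample-by-gene-term
abundance table from shotgun metagenomics. Two features of such data defeat
off-the-shelf analyses: subjects differ from each other far more than any
sample differs from its subject's baseline, and the perturbation response is
carried by *clades* of related taxa rather than by independent features.

phyloperturb packages the statistical toolkit for this design:

* **Adaptive generalized PCA.** PCA under the metric
  `S = Q (Q + k I)^(-1)`, where `Q` is the Brownian-motion covariance of the
  tree (`Q[i,j]` = shared root-to-MRCA path length). Rows are modeled as
  `N(0, sigma2_tree * Q + sigma2_iid * I)`; the variance ratio
  `k = sigma2_iid / sigma2_tree` is estimated by marginal likelihood, so the
  ordination interpolates between ordinary PCA (`k -> 0`) and the DPCoA tree
  geometry (`k -> Inf`) at a data-chosen point
  `r = sigma2_tree / (sigma2_tree + sigma2_iid)`.
* **Tree-based sparse discriminant analysis.** Sparse optimal scoring on a
  feature set holding one column per leaf *and* one per internal node (the
  sum of its descendant leaves' transformed abundances, branch lengths
  ignored), so a whole clade can be selected as a single predictor. The
  active-feature budget is tuned by leave-one-subject-out cross-validation;
  the l1 penalty is what makes the leaf+node design identifiable.
* **Sparse CCA** by penalized matrix decomposition: maximize `u' X'Y v`
  under `||u||_2, ||v||_2 <= 1` and l1 bounds, coupling taxon abundances
  with gene-function abundances through alternating soft-threshold updates.
* **A resilience statistic**: the relative change in mean Shannon diversity
  between the three days before and the three days after the perturbation,
  predicted from baseline family-level composition by an elastic net tuned
  by bootstrap resampling of subjects.
* **A design power study**: crossover ("internal", every subject perturbed)
  versus parallel ("external", half the subjects as controls) designs under
  `y = mu_subject + beta * treated + noise`, `mu ~ N(0, tau2)`, analyzed by
  a profiled-REML random-intercept model versus ordinary least squares.
* **A synthetic-study generator** reproducing the statistical structure the
  analyses assume (subject signatures, a transient clade-level bloom and
  depression, linked gene content), so the entire pipeline runs and is
  tested without any external data.

## Worked example

```r
library(phyloperturb)

sim <- simulate_experiment(synth_config(seed = 42,
                                        phylo_subject_effects = TRUE))
sim$study
#> <study_table> 276 samples x 60 taxa; 8 subjects; days -70..70
#> imm_post     post      pre
#>       23       97      156

al  <- align_study(sim$study, sim$tree)
ord <- adaptive_gpca(al$study, al$tree)
ord
#> <ordination:agpca> 276 samples, 2 axes; variance fractions 0.377, 0.168
#>   tree-prior weight r = 0.804
```

`r = 0.80` says the data put most of their weight on the tree prior: axes
are smooth over clades, not single taxa. `autoplot(ord)` draws the sample
map; `center_scores_by_subject(ord, sim$study)` exposes the transient
post-perturbation excursion that subject differences otherwise hide.

```r
cv <- treeda_cv(sim$study, sim$tree, c(2, 5, 10, 15, 20, 25))
cv
#> <treeda_cv> best budget 15 (mean error 0.028)
model <- treeda(sim$study, sim$tree, cv$best_budget)
model
#> <treeda_model> 12 active features (budget 15); classes pre vs imm_post
#>   leaves with non-zero effective coefficient: 58
head(tidy(model), 4)
#> # A tibble: 4 x 4
#>   feature kind  coefficient clade_size
#> 1 t53     leaf     -0.0395           1
#> 2 n63     node     -0.00763         39
#> 3 n67     node     -0.00348          3
#> 4 n69     node     -0.0533           8
```

Twelve active features — several of them internal nodes — separate the
immediate-post samples from baseline with 2.8% leave-one-subject-out error;
the `clade_size` column shows whole clades acting as single predictors, and
`model$leaf_effects` maps them back to the 58 taxa they cover.

```r
fit <- scca(sim$study, sim$genes)
fit
#> <scca> 2 component(s); score correlations 0.600, 0.679
#>   non-zero taxon weights: 1, 1; gene-term weights: 8, 5

resilience_score(sim$study)[1:3, ]
#>   subject_id pre_mean_H post_mean_H   score n_pre n_post missing
#> 1 S1               3.32        2.77 -0.165      3      3 FALSE
#> 2 S2               3.40        3.14 -0.0760     3      3 FALSE
#> 3 S3               3.50        3.23 -0.0789     3      2 FALSE

ps <- power_study(tau2_grid = c(0, 5), beta_grid = c(0, 1),
                  replicates = 200, seed = 42)
dplyr::filter(ps$power, tau2 == 5, beta == 1)
#>    tau2  beta design   model power
#> 1     5     1 external mixed 0.965
#> 2     5     1 external ols   0.48
#> 3     5     1 internal mixed 1
#> 4     5     1 internal ols   0.77
```

The sparse CCA couples the blooming genus with the gene terms its clade
carries (score correlation 0.60); every subject's diversity drops right
after the perturbation (negative resilience scores); and under strong
intersubject variance the crossover design analyzed with the mixed model is
the most powerful combination, while ordinary regression in the parallel
design loses half its power.

A command-line wrapper over the same functions ships in
`inst/scripts/phyloperturb`:

```sh
Rscript inst/scripts/phyloperturb all --outdir out --seed 7
Rscript inst/scripts/phyloperturb powersim --replicates 10 --outdir out_power
```

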