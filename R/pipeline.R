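#' Run a pipeline stage
#'
#' Reproducible driver tying the stages together. Every stage reads the
#' standard text formats (or generates synthetic inputs when `indir` is
#' `NULL`), writes TSV outputs plus a JSON run manifest (stage, parameters,
#' seed, package version) into `outdir`, and is deterministic given `seed`.
#'
#' Stages: `synth` (write a synthetic study), `ordinate` (Bray-Curtis MDS or
#' adaptive gPCA), `treeda` (budget CV + final discriminant fit), `scca`
#' (sparse CCA of taxa against gene terms), `resilience` (scores +
#' elastic-net prediction), `powersim` (design power study), `all` (synth
#' followed by every analysis on the synthetic study).
#'
#' @param stage one of the stage names above.
#' @param outdir output directory (created).
#' @param indir optional directory holding `counts.tsv`, `metadata.tsv`,
#'   `taxonomy.tsv`, `tree.nwk` and optionally `genes.tsv` (the format
#'   `stage = "synth"` writes).
#' @param seed integer seed for every random step.
#' @param params named list of stage parameters overriding defaults:
#'   `ordination_method` (`"agpca"`/`"bray"`), `transform`, `k`,
#'   `budget_grid`, `min_count`, `min_samples`, `cu_frac`, `cv_frac`,
#'   `n_components`, `genus_filter`, `window_days`, `onset_days`, `alpha_mix`,
#'   `n_boot`, `tau2_grid`, `beta_grid`, `replicates`, `alpha`, plus any
#'   [synth_config()] field.
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(stage = c("synth", "ordinate", "treeda", "scca",
                                   "resilience", "powersim", "all"),
                         outdir, indir = NULL, seed = 1L, params = list()) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  defaults <- list(ordination_method = "agpca", transform = "log1p", k = 2L,
                   budget_grid = c(2L, 5L, 10L, 15L, 20L, 25L),
                   min_count = 5L, min_samples = 10L,
                   cu_frac = 0.3, cv_frac = 0.3, n_components = 2L,
                   genus_filter = "Bacteroides",
                   window_days = 3L, onset_days = 7L, alpha_mix = 0.5,
                   n_boot = 200L,
                   tau2_grid = seq(0, 5, length.out = 12),
                   beta_grid = seq(0, 2, length.out = 30),
                   replicates = 10L, alpha = 0.05)
  p <- modifyList(defaults, params)
  paths <- character()

  load_or_simulate <- function() {
    if (!is.null(indir)) {
      study <- read_study(file.path(indir, "counts.tsv"),
                          file.path(indir, "metadata.tsv"),
                          file.path(indir, "taxonomy.tsv"))
      tree <- read_newick(file.path(indir, "tree.nwk"))
      genes <- NULL
      if (file.exists(file.path(indir, "genes.tsv"))) {
        genes <- read_gene_table(file.path(indir, "genes.tsv"))
      }
      list(study = study, tree = tree, genes = genes, truth = NULL)
    } else {
      cfg_fields <- intersect(names(p), names(formals(synth_config)))
      cfg <- do.call(synth_config, c(list(seed = seed), p[cfg_fields]))
      simulate_experiment(cfg)
    }
  }

  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_plain(as.data.frame(df), path)
    paths[[name]] <<- path
  }

  stage_synth <- function(sim) {
    wp <- write_study(sim$study, outdir)
    for (nm in names(wp)) paths[[basename(wp[[nm]])]] <<- wp[[nm]]
    tree_path <- file.path(outdir, "tree.nwk")
    ape::write.tree(sim$tree, tree_path, digits = 15)
    paths[["tree.nwk"]] <<- tree_path
    if (!is.null(sim$genes)) {
      emit(data.frame(sample_id = rownames(sim$genes$abundances),
                      sim$genes$abundances, check.names = FALSE),
           "genes.tsv")
    }
    if (!is.null(sim$truth)) {
      truth_path <- file.path(outdir, "truth.json")
      jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                           digits = NA)
      paths[["truth.json"]] <<- truth_path
    }
  }

  stage_ordinate <- function(sim) {
    ord <- if (p$ordination_method == "bray") {
      bray_mds(sim$study, p$k)
    } else {
      al <- align_study(sim$study, sim$tree)
      adaptive_gpca(al$study, al$tree, p$k, p$transform)
    }
    emit(tidy(ord, "scores"), "scores.tsv")
    if (!is.null(ord$loadings)) emit(tidy(ord, "loadings"), "loadings.tsv")
    emit(tidy(ord, "eigenvalues"), "eigenvalues.tsv")
  }

  stage_treeda <- function(sim) {
    cv <- treeda_cv(sim$study, sim$tree, p$budget_grid, p$transform,
                    min_count = p$min_count, min_samples = p$min_samples)
    emit(tidy(cv), "cv.tsv")
    model <- treeda(sim$study, sim$tree, cv$best_budget, p$transform,
                    min_count = p$min_count, min_samples = p$min_samples)
    emit(tidy(model), "model.tsv")
    emit(tibble(taxon_id = names(model$leaf_effects),
                leaf_effect = unname(model$leaf_effects)),
         "leaf_effects.tsv")
  }

  stage_scca <- function(sim) {
    if (is.null(sim$genes)) abort("scca requires a gene table (genes.tsv).")
    fit <- scca(sim$study, sim$genes, p$cu_frac, p$cv_frac, p$n_components,
                p$genus_filter)
    emit(tidy(fit, "u"), "scca_u.tsv")
    emit(tidy(fit, "v"), "scca_v.tsv")
    emit(tidy(fit, "scores"), "scca_scores.tsv")
    emit(glance(fit), "scca_summary.tsv")
  }

  stage_resilience <- function(sim) {
    model <- resilience_enet(sim$study, p$window_days, p$onset_days,
                             p$alpha_mix, p$n_boot, seed = seed)
    emit(model$scores, "resilience_scores.tsv")
    emit(tibble(family = names(model$coefficients),
                coefficient = unname(model$coefficients)),
         "resilience_coefficients.tsv")
  }

  stage_powersim <- function() {
    ps <- power_study(p$tau2_grid, p$beta_grid, replicates = p$replicates,
                      alpha = p$alpha, seed = seed)
    emit(ps$t_stats, "tstats.tsv")
    emit(ps$power, "power.tsv")
  }

  if (stage == "powersim") {
    stage_powersim()
  } else if (stage == "all") {
    sim <- load_or_simulate()
    stage_synth(sim)
    stage_ordinate(sim)
    stage_treeda(sim)
    if (!is.null(sim$genes)) stage_scca(sim)
    stage_resilience(sim)
    # a reduced grid keeps the end-to-end run quick; the full factorial is
    # available through stage = "powersim" with explicit grids
    p$tau2_grid <- params$tau2_grid %||% c(0, 5)
    p$beta_grid <- params$beta_grid %||% c(0, 1, 2)
    p$replicates <- params$replicates %||% 5L
    stage_powersim()
  } else {
    sim <- load_or_simulate()
    switch(stage,
           synth = stage_synth(sim),
           ordinate = stage_ordinate(sim),
           treeda = stage_treeda(sim),
           scca = stage_scca(sim),
           resilience = stage_resilience(sim))
  }

  manifest <- list(stage = stage, seed = seed, indir = indir,
                   params = p[order(names(p))],
                   package = "phyloperturb",
                   version = as.character(packageVersion("phyloperturb")))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths[["manifest.json"]] <- manifest_path
  invisible(paths)
}
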