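make_feature_matrix <- function(X) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

test_that("the prevalence filter is boundary-inclusive", {
  # taxon a: count 5 in exactly 10 samples (kept); taxon b: 4 everywhere
  # (dropped); taxon c: rich everywhere (kept)
  counts <- cbind(a = c(rep(5L, 10), rep(0L, 2)),
                  b = rep(4L, 12),
                  c = rep(50L, 12))
  rownames(counts) <- paste0("s", 1:12)
  st <- study_table(counts, data.frame(sample_id = paste0("s", 1:12),
                                       subject_id = "P", day = 1:12))
  kept <- filter_taxa(st, 5, 10)
  expect_setequal(colnames(kept$counts), c("a", "c"))

  # brute-force count per taxon on a random table
  sim <- simulate_study(synth_config(seed = 20, p_leaves = 30,
                                     schedule = c(-5:-1, 1:5),
                                     missing_day_prob = 0))
  f5 <- filter_taxa(sim$study, 5, 10)
  manual <- colnames(sim$study$counts)[
    vapply(seq_len(ncol(sim$study$counts)),
           function(j) sum(sim$study$counts[, j] >= 5) >= 10, logical(1))]
  expect_setequal(colnames(f5$counts), manual)

  expect_error(filter_taxa(st, 100, 12), "no taxon survives")
})

test_that("a single separating feature is found with budget 1", {
  set.seed(3)
  n <- 60
  y <- factor(rep(c("pre", "imm_post"), each = n / 2),
              levels = c("pre", "imm_post"))
  X <- matrix(rnorm(n * 10), n, 10)
  X[y == "imm_post", 4] <- X[y == "imm_post", 4] + 10
  colnames(X) <- paste0("f", 1:10)
  m <- fit_sparse_lda(X, y, n_predictors = 1)
  expect_equal(names(m$active), "f4")
  pred <- project_lda(m, X)$predicted
  expect_equal(mean(pred == as.character(y)), 1)
})

test_that("the dense, unpenalized limit matches Fisher's discriminant", {
  set.seed(10)
  n <- 100; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X[y == "b", 1] <- X[y == "b", 1] + 2
  X[y == "b", 2] <- X[y == "b", 2] + 1
  colnames(X) <- paste0("f", 1:p)
  m <- fit_sparse_lda(X, y, n_predictors = p, ridge = 1e-9)
  Sw <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xc <- scale(X[y == cl, ], scale = FALSE)
    Sw <- Sw + crossprod(Xc)
  }
  fisher <- solve(Sw, colMeans(X[y == "b", ]) - colMeans(X[y == "a", ]))
  cosine <- abs(sum(m$coefficients * fisher) /
                  sqrt(sum(m$coefficients^2) * sum(fisher^2)))
  expect_gt(cosine, 0.999)
})

test_that("degenerate inputs are rejected or clipped", {
  X <- make_feature_matrix(matrix(rnorm(40), 20, 2))
  one_class <- factor(rep("a", 20))
  expect_error(fit_sparse_lda(X, one_class, 1), "two classes")
  y <- factor(rep(c("a", "b"), 10))
  expect_warning(fit_sparse_lda(X, y, 99), "clipped")
})

test_that("swapping class labels negates the discriminant scores", {
  set.seed(5)
  X <- make_feature_matrix(matrix(rnorm(200), 40, 5))
  y <- factor(rep(c("a", "b"), 20), levels = c("a", "b"))
  y_swapped <- factor(as.character(y), levels = c("b", "a"))
  m1 <- fit_sparse_lda(X, y, 3)
  m2 <- fit_sparse_lda(X, y_swapped, 3)
  expect_equal(m1$scores, -m2$scores, tolerance = 1e-8)
})

test_that("active leaf effects are identifiable under feature permutation", {
  sim <- simulate_study(synth_config(seed = 22, p_leaves = 20,
                                     schedule = c(-5:-1, 1:5),
                                     missing_day_prob = 0))
  al <- suppressMessages(align_study(sim$study, sim$tree))
  f <- expand_features(al$study, al$tree)
  lab <- treeda_labels(al$study)
  m1 <- fit_sparse_lda(f, lab, 6, tree = al$tree)
  perm <- sample(ncol(f$values))
  f2 <- f; f2$values <- f$values[, perm]; f2$kind <- f$kind[perm]
  m2 <- fit_sparse_lda(f2, lab, 6, tree = al$tree)
  # identical active support; values agree up to solver tolerance
  expect_identical(names(which(m1$leaf_effects != 0)),
                   names(which(m2$leaf_effects != 0)))
  expect_equal(m1$leaf_effects, m2$leaf_effects, tolerance = 1e-4)
})

test_that("node-only models give clade-piecewise-constant leaf effects", {
  tr <- simulate_tree(16, seed = 2)
  nid <- node_ids(tr)[3]
  eff <- leaf_coefficients(setNames(1.25, nid), tr)
  inside <- clade_leaves(tr, nid)
  expect_true(all(eff[inside] == 1.25))
  expect_true(all(eff[setdiff(tr$tip.label, inside)] == 0))
})

test_that("projection reproduces training scores and handles zero models", {
  sim <- simulate_study(synth_config(seed = 23, p_leaves = 15,
                                     schedule = c(-5:-1, 1:5),
                                     missing_day_prob = 0))
  al <- suppressMessages(align_study(sim$study, sim$tree))
  f <- expand_features(al$study, al$tree)
  lab <- treeda_labels(al$study)
  m <- fit_sparse_lda(f, lab, 5, tree = al$tree)
  keep <- !is.na(lab)
  pr <- project_lda(m, f$values[keep, , drop = FALSE])
  expect_lt(max(abs(pr$score - unname(m$scores))), 1e-10)

  zero <- m
  zero$coefficients[] <- 0
  zero$active <- zero$coefficients[0]
  zero$n_active <- 0L
  zero$centroids[] <- 0
  przero <- project_lda(zero, f$values[keep, , drop = FALSE])
  expect_true(all(przero$score == przero$score[1]))
  majority <- names(which.max(m$class_sizes))
  expect_true(all(przero$predicted == majority))

  expect_error(project_lda(m, f$values[, 1:3]), "missing feature")
})

test_that("LOSO CV finds a perfectly predictive feature at budget 1", {
  set.seed(8)
  n_subj <- 5
  lab <- factor(rep(rep(c("pre", "imm_post"), each = 6), n_subj),
                levels = c("pre", "imm_post"))
  subj <- rep(paste0("P", 1:n_subj), each = 12)
  X <- matrix(rnorm(length(lab) * 8), ncol = 8)
  X[lab == "imm_post", 2] <- X[lab == "imm_post", 2] + 8
  counts <- matrix(rpois(length(lab) * 8, 5), ncol = 8)
  # feed the signal through a study so the whole treeda path is exercised:
  # taxon t2 alone carries the class difference, by a wide margin
  counts[lab == "imm_post", 2] <- counts[lab == "imm_post", 2] + 5000L
  colnames(counts) <- paste0("t", 1:8)
  rownames(counts) <- paste0("s", seq_along(lab))
  md <- data.frame(sample_id = rownames(counts), subject_id = subj,
                   day = ifelse(lab == "pre", -1L, 2L))
  st <- study_table(counts, md)
  tr <- simulate_tree(8, seed = 1)
  cv <- suppressMessages(
    treeda_cv(st, tr, budget_grid = c(1, 3, 5), min_samples = 0))
  expect_equal(cv$best_budget, 1L)
  expect_equal(unname(cv$mean_errors[1]), 0)
})

test_that("with random labels, CV error sits at the no-signal baseline", {
  errs <- numeric(20); base <- numeric(20)
  for (seed in 1:20) {
    sim <- simulate_study(synth_config(
      seed = 400 + seed, p_leaves = 15, delta_up = 0, delta_down = 0,
      schedule = c(-4:-1, 1:4), missing_day_prob = 0, n_subjects = 6))
    md <- sim$study$metadata
    lab <- withr::with_seed(seed,
      factor(sample(c("pre", "imm_post"), nrow(md), replace = TRUE),
             levels = c("pre", "imm_post")))
    cv <- suppressWarnings(suppressMessages(
      treeda_cv(sim$study, sim$tree, budget_grid = c(2, 4), labels = lab,
                min_samples = 0)))
    errs[seed] <- min(cv$mean_errors)
    base[seed] <- min(mean(lab == "pre"), mean(lab == "imm_post"))
  }
  mc_se <- sd(errs - base) / sqrt(20)
  expect_lt(abs(mean(errs) - mean(base)), 3 * mc_se)
})

test_that("the chosen budget is never worse than the grid endpoints", {
  sim <- simulate_study(synth_config(seed = 27, p_leaves = 25,
                                     schedule = c(-5:-1, 1:5),
                                     missing_day_prob = 0))
  cv <- suppressMessages(
    treeda_cv(sim$study, sim$tree, budget_grid = c(1, 5, 10, 20),
              min_samples = 0))
  best_err <- cv$mean_errors[as.character(cv$best_budget)]
  expect_lte(best_err, cv$mean_errors["1"])
  expect_lte(best_err, cv$mean_errors["20"])
  expect_s3_class(tidy(cv), "tbl_df")
  expect_s3_class(autoplot(cv), "ggplot")
})

test_that("held-out subjects still score imm_post above pre", {
  hits <- logical(10)
  for (seed in 1:10) {
    sim <- simulate_study(synth_config(seed = 600 + seed))
    st <- suppressMessages(filter_taxa(sim$study))
    al <- suppressMessages(align_study(st, sim$tree))
    f <- expand_features(al$study, al$tree)
    lab <- treeda_labels(al$study)
    subj <- al$study$metadata$subject_id
    tr_idx <- subj != "S1" & !is.na(lab)
    te_idx <- subj == "S1" & !is.na(lab)
    ftr <- f; ftr$values <- f$values[tr_idx, , drop = FALSE]
    m <- fit_sparse_lda(ftr, lab[tr_idx], 15)
    pr <- project_lda(m, f$values[te_idx, , drop = FALSE])
    hits[seed] <- mean(pr$score[lab[te_idx] == "imm_post"]) >
      mean(pr$score[lab[te_idx] == "pre"])
  }
  expect_gte(mean(hits), 0.8)
})
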