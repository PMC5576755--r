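test_that("Bray-Curtis has the expected boundary and hand values", {
  counts <- rbind(s1 = c(4L, 4L, 0L), s2 = c(2L, 2L, 0L),
                  s3 = c(0L, 0L, 9L), s4 = c(3L, 3L, 3L))
  colnames(counts) <- c("a", "b", "c")
  md <- data.frame(sample_id = rownames(counts), subject_id = "P",
                   day = c(-2L, -1L, 1L, 2L))
  st <- study_table(counts, md)
  D <- bray_curtis(st)
  expect_equal(D["s1", "s2"], 0)              # identical compositions
  expect_equal(D["s1", "s3"], 1)              # disjoint supports
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))

  # x = (1,1,0), y = (0,1,1) as proportions -> 1/2
  counts2 <- rbind(s1 = c(1L, 1L, 0L), s2 = c(0L, 1L, 1L))
  colnames(counts2) <- c("a", "b", "c")
  st2 <- study_table(counts2, data.frame(sample_id = c("s1", "s2"),
                                         subject_id = "P", day = 0:1))
  expect_equal(bray_curtis(st2)["s1", "s2"], 0.5)

  zero <- rbind(s1 = c(1L, 0L), s2 = c(0L, 0L))
  colnames(zero) <- c("a", "b")
  stz <- study_table(zero, data.frame(sample_id = c("s1", "s2"),
                                      subject_id = "P", day = 0:1))
  expect_error(bray_curtis(stz), "s2")
})

test_that("classical scaling recovers Euclidean configurations", {
  # collinear points at 0, 1, 2
  D <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  rownames(D) <- colnames(D) <- paste0("s", 1:3)
  o <- suppressWarnings(pcoa(D, 2))
  expect_equal(as.numeric(dist(o$scores[, 1])), c(1, 2, 1))
  expect_lt(abs(o$all_eigenvalues[2]), 1e-10)

  # all-zero dissimilarities: no positive eigenvalues
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  o0 <- suppressWarnings(pcoa(D0, 2))
  expect_true(all(abs(o0$all_eigenvalues) < 1e-12))

  # 10 random points in 3-D: the 3-axis embedding reproduces distances
  set.seed(31)
  P <- matrix(rnorm(30), 10, 3)
  Dp <- as.matrix(dist(P))
  rownames(Dp) <- colnames(Dp) <- paste0("s", 1:10)
  op <- pcoa(Dp, 3)
  expect_lt(max(abs(as.matrix(dist(op$scores)) - Dp)), 1e-8)

  # independent oracle: cmdscale gives the same axes up to sign
  cm <- cmdscale(Dp, k = 3)
  for (j in 1:3) {
    expect_lt(min(max(abs(op$scores[, j] - cm[, j])),
                  max(abs(op$scores[, j] + cm[, j]))), 1e-8)
  }

  # k beyond the positive spectrum is truncated with a warning
  expect_warning(pcoa(Dp, 9), "reduced")
})

test_that("gpca endpoints: identity metric is PCA, scaling behaves", {
  set.seed(7)
  X <- scale(matrix(rnorm(15 * 8), 15, 8), scale = FALSE)
  colnames(X) <- paste0("t", 1:8)
  g1 <- gpca(X, diag(8), k = 3)
  pc <- prcomp(X, center = FALSE)
  for (j in 1:3) {
    expect_lt(min(max(abs(g1$scores[, j] - pc$x[, j])),
                  max(abs(g1$scores[, j] + pc$x[, j]))), 1e-8)
  }
  # S = c I scales scores by sqrt(c)
  g4 <- gpca(X, 4 * diag(8), k = 3)
  expect_equal(abs(g4$scores), abs(g1$scores) * 2, tolerance = 1e-8)

  expect_error(gpca(X, diag(c(rep(1, 7), -1))), "positive semidefinite")
})

test_that("gpca with a tree metric realizes the generalized distances", {
  tr <- simulate_tree(8, seed = 3)
  Q <- tree_similarity(tr)
  set.seed(11)
  X <- scale(matrix(rnorm(15 * 8), 15, 8), scale = FALSE)
  colnames(X) <- tr$tip.label
  g <- gpca(X, Q, k = 8)
  expect_lt(max(abs(as.matrix(dist(g$scores)) - quadratic_distances(X, Q))),
            1e-8)
  # X %*% loadings reproduces the scores
  expect_lt(max(abs(X %*% g$loadings - g$scores)), 1e-8)
  # eigenvalues nonincreasing and summing to the total metric variance
  expect_true(all(diff(g$all_eigenvalues) <= 1e-12))
  expect_equal(sum(g$all_eigenvalues),
               sum(diag(X %*% Q %*% t(X))) / (nrow(X) - 1),
               tolerance = 1e-8)
})

test_that("shrinkage estimation flags unidentifiable and null-tree cases", {
  # Q proportional to the identity cannot separate the two variances
  set.seed(2)
  X <- scale(matrix(rnorm(200 * 10), 200, 10), scale = FALSE)
  est <- estimate_shrinkage(X, 3 * diag(10))
  expect_true(est$unidentifiable)
  expect_equal(est$r, 0)

  # data generated without any tree component: r-hat near 0
  tr <- simulate_tree(20, seed = 8)
  Q <- tree_similarity(tr)
  X2 <- scale(matrix(rnorm(800 * 20), 800, 20), scale = FALSE)
  est2 <- estimate_shrinkage(X2, Q)
  expect_lt(est2$r, 0.1)
})

test_that("the fitted shrinkage beats both interpolation endpoints", {
  tr <- simulate_tree(15, seed = 21)
  Q <- tree_similarity(tr)
  ed <- eigen(Q, symmetric = TRUE)
  for (seed in 1:5) {
    set.seed(seed)
    L <- t(chol(0.5 * Q + 1.5 * diag(15)))
    X <- scale(t(L %*% matrix(rnorm(300 * 15), 15)), scale = FALSE)
    est <- estimate_shrinkage(X, Q)
    s <- colMeans((X %*% ed$vectors)^2)
    lam <- pmax(ed$values, 0)
    ll_at <- function(k) {
      sig_t <- mean(s / (lam + k))
      -nrow(X) / 2 * sum(log(2 * pi * sig_t * (lam + k)) +
                           s / (sig_t * (lam + k)))
    }
    expect_gte(est$log_likelihood + 1e-6, ll_at(1e-6))  # ~DPCoA endpoint
    expect_gte(est$log_likelihood + 1e-6, ll_at(1e6))   # ~PCA endpoint
  }
})

test_that("adaptive gPCA hits its PCA and DPCoA endpoints", {
  sim <- simulate_study(synth_config(seed = 13, p_leaves = 12,
                                     schedule = c(-3:-1, 1:3),
                                     missing_day_prob = 0))
  st <- sim$study; tr <- sim$tree
  X <- scale(log1p(st$counts[, tr$tip.label]), scale = FALSE)

  # forced k_ratio = 0: ordinary PCA up to sign
  a0 <- adaptive_gpca(st, tr, k = 2, k_ratio = 0)
  pc <- prcomp(X, center = FALSE)
  for (j in 1:2) {
    expect_lt(min(max(abs(a0$scores[, j] - pc$x[, j])),
                  max(abs(a0$scores[, j] + pc$x[, j]))), 1e-8)
  }

  # forced enormous k_ratio: DPCoA generalized distances, up to the known
  # 1/sqrt(k) scaling of the metric Q/(k)
  k_big <- 1e9
  ab <- adaptive_gpca(st, tr, k = 12, k_ratio = k_big)
  D_sc <- as.matrix(dist(ab$scores)) * sqrt(k_big)
  D_gen <- quadratic_distances(X, tree_similarity(tr))
  expect_lt(max(abs(D_sc - D_gen) / (D_gen + 1e-12)), 1e-6)
})

test_that("adaptive gPCA is invariant to taxon column order", {
  sim <- simulate_study(synth_config(seed = 14, p_leaves = 10,
                                     schedule = c(-3:-1, 1:3),
                                     missing_day_prob = 0))
  st <- sim$study
  perm <- sample(ncol(st$counts))
  st_perm <- study_table(st$counts[, perm], st$metadata,
                         st$taxonomy[perm, ])
  o1 <- adaptive_gpca(st, sim$tree, k = 2)
  o2 <- adaptive_gpca(st_perm, sim$tree, k = 2)
  for (j in 1:2) {
    expect_lt(min(max(abs(o1$scores[, j] - o2$scores[, j])),
                  max(abs(o1$scores[, j] + o2$scores[, j]))), 1e-8)
  }
})

test_that("subject centering removes per-subject means", {
  sim <- simulate_study(synth_config(seed = 15, p_leaves = 10,
                                     schedule = c(-3:-1, 1:3),
                                     missing_day_prob = 0))
  ord <- adaptive_gpca(sim$study, sim$tree, k = 2)
  cs <- center_scores_by_subject(ord, sim$study)
  subj <- sim$study$metadata$subject_id
  for (s in unique(subj)) {
    expect_lt(max(abs(colMeans(cs[subj == s, , drop = FALSE]))), 1e-10)
  }
  # constant per-subject scores center to exactly zero
  fake <- ord
  fake$scores <- matrix(as.numeric(factor(subj)), ncol = 2,
                        nrow = length(subj),
                        dimnames = dimnames(ord$scores))
  expect_true(all(center_scores_by_subject(fake, sim$study) == 0))
})

test_that("ordination tidiers and plots behave", {
  sim <- simulate_study(synth_config(seed = 16, p_leaves = 10,
                                     schedule = c(-3:-1, 1:3),
                                     missing_day_prob = 0))
  ord <- adaptive_gpca(sim$study, sim$tree, k = 2)
  sc <- tidy(ord, "scores")
  expect_s3_class(sc, "tbl_df")
  expect_true(all(c("Axis1", "Axis2", "subject_id", "phase") %in% names(sc)))
  expect_equal(nrow(tidy(ord, "loadings")), 10)
  expect_s3_class(autoplot(ord), "ggplot")
  expect_equal(glance(ord)$method, "agpca")
})
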