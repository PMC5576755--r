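test_that("Shannon diversity matches closed forms and its extremes", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(2, 1, 1)), 1.5 * log(2))
  expect_error(shannon(c(0, 0)), "all-zero")

  # permutation invariance and the uniform maximum
  set.seed(6)
  for (i in 1:20) {
    x <- rgamma(8, 2)
    expect_equal(shannon(x), shannon(sample(x)))
    expect_lte(shannon(x), shannon(rep(1, 8)) + 1e-12)
  }
})

window_study <- function(pre_rows, post_rows, extra_days = integer(0)) {
  rows <- rbind(pre_rows, post_rows)
  n_pre <- nrow(pre_rows); n_post <- nrow(post_rows)
  days <- c(seq(-n_pre, -1), seq_len(n_post))
  ids <- paste0("s", seq_len(nrow(rows)))
  rownames(rows) <- ids
  colnames(rows) <- paste0("t", seq_len(ncol(rows)))
  study_table(rows, data.frame(sample_id = ids, subject_id = "P1",
                               day = as.integer(days)))
}

test_that("the resilience score is the relative change in windowed H", {
  # identical composition before and after: score 0
  same <- matrix(rep(c(5L, 5L, 10L), 4), 4, 3, byrow = TRUE)
  st0 <- window_study(same[1:2, ], same[3:4, ])
  rs0 <- resilience_score(st0)
  expect_equal(rs0$score, 0)

  # uniform over 4 taxa before (H = ln 4), single taxon after (H = 0):
  # relative change is -1
  pre <- matrix(rep(3L, 8), 2, 4)
  post <- matrix(c(9L, 0L, 0L, 0L, 9L, 0L, 0L, 0L), 2, 4, byrow = TRUE)
  st1 <- window_study(pre, post)
  rs1 <- resilience_score(st1)
  expect_equal(rs1$pre_mean_H, log(4))
  expect_equal(rs1$post_mean_H, 0)
  expect_equal(rs1$score, -1)

  # a subject with no sample in [1, 3] is flagged, not dropped
  counts <- matrix(rep(c(3L, 3L), 2), 2, 2)
  rownames(counts) <- c("a1", "a2")
  colnames(counts) <- c("t1", "t2")
  st2 <- study_table(counts, data.frame(sample_id = c("a1", "a2"),
                                        subject_id = "P1",
                                        day = c(-2L, 10L)))
  rs2 <- resilience_score(st2)
  expect_true(rs2$missing)
  expect_true(is.na(rs2$score))
  expect_equal(nrow(rs2), 1)
})

test_that("resilience depends only on proportions, not depth", {
  sim <- simulate_study(synth_config(seed = 41, missing_day_prob = 0))
  rs <- resilience_score(sim$study)
  scaled <- sim$study
  # rescale each sample's depth by an integer factor
  scaled_counts <- sim$study$counts * 3L
  st2 <- study_table(scaled_counts, sim$study$metadata, sim$study$taxonomy)
  rs2 <- resilience_score(st2)
  expect_equal(rs$score, rs2$score, tolerance = 1e-12)
})

test_that("baseline family features average onset-window compositions", {
  # two samples with family splits (0.2, 0.8) and (0.4, 0.6): mean (0.3, 0.7)
  counts <- rbind(s1 = c(2L, 8L), s2 = c(4L, 6L))
  colnames(counts) <- c("tA", "tB")
  md <- data.frame(sample_id = c("s1", "s2"), subject_id = "P1",
                   day = c(-10L, -9L))
  tax <- data.frame(taxon_id = c("tA", "tB"),
                    family = c("FamA", "FamB"))
  st <- study_table(counts, md, tax)
  ff <- baseline_family_features(st, onset_days = 7)
  expect_equal(ff["P1", c("FamA", "FamB")], c(FamA = 0.3, FamB = 0.7))

  # single-family community: feature exactly 1
  tax1 <- data.frame(taxon_id = c("tA", "tB"), family = "FamA")
  st1 <- study_table(counts, md, tax1)
  expect_equal(unname(baseline_family_features(st1)[1, 1]), 1)

  # rows always sum to one
  sim <- simulate_study(synth_config(seed = 42))
  ffs <- baseline_family_features(sim$study)
  expect_true(all(abs(rowSums(ffs) - 1) < 1e-12))

  st_nofam <- study_table(counts, md)
  expect_error(baseline_family_features(st_nofam), "family")
})

test_that("the elastic net hits its analytic limits", {
  set.seed(11)
  n <- 40; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  X <- qr.Q(qr(X)) * sqrt(n)          # centered, X'X = n I
  colnames(X) <- paste0("f", 1:p)
  beta_true <- c(1, -0.5, 0.25, 0, 0)
  y <- as.numeric(X %*% beta_true + rnorm(n, 0, 0.3))

  # lambda = 0 with p < n: ordinary least squares
  f0 <- fit_enet(X, y, alpha = 0.5, lambda_grid = c(1, 0.1, 0), n_boot = 20,
                 seed = 2)
  ols <- coef(lm(y ~ X))
  bhat <- as.numeric(glmnet::coef.glmnet(f0$fit, s = 0))
  expect_equal(bhat, unname(ols), tolerance = 1e-6)

  # enormous lambda: all coefficients zero, intercept = mean(y)
  flarge <- fit_enet(X, y, alpha = 0.5, lambda_grid = c(1e6, 1e5), n_boot = 20,
                     seed = 2)
  expect_true(all(flarge$coefficients == 0))
  expect_equal(unname(flarge$intercept), mean(y), tolerance = 1e-8)

  # orthonormal design, alpha = 1: soft-thresholded least squares
  lam <- 0.15
  f1 <- fit_enet(X, y, alpha = 1, lambda_grid = c(lam), n_boot = 20, seed = 2)
  b_ls <- as.numeric(crossprod(X, y - mean(y))) / n
  b_soft <- sign(b_ls) * pmax(abs(b_ls) - lam, 0)
  expect_equal(unname(f1$coefficients), b_soft, tolerance = 1e-6)
})

test_that("sparsity is monotone in lambda and small cohorts are rejected", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- paste0("f", 1:10)
  y <- rnorm(20)
  lams <- c(0.5, 0.2, 0.1, 0.05, 0.01, 0)
  nnz <- vapply(lams, function(lam) {
    m <- fit_enet(X, y, alpha = 0.7, lambda_grid = c(lam), n_boot = 5,
                  seed = 1)
    sum(m$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # lambda decreasing -> support grows

  expect_error(fit_enet(X[1:2, ], y[1:2], n_boot = 5), "at least 3")
})

test_that("the end-to-end resilience model runs on a synthetic cohort", {
  sim <- simulate_study(synth_config(seed = 44, missing_day_prob = 0))
  model <- resilience_enet(sim$study, n_boot = 40, seed = 3)
  expect_s3_class(model, "resilience_enet")
  expect_equal(model$n_subjects, 8)
  expect_true(all(!model$scores$missing))
  # the perturbation depresses diversity immediately after day 0 here
  expect_s3_class(tidy(model), "tbl_df")
  expect_s3_class(autoplot(model), "ggplot")
  expect_equal(glance(model)$n_subjects, 8)
})
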