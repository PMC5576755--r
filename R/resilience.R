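#' Shannon diversity of a count or proportion vector
#'
#' `H = -sum p_j log p_j` in nats, with `0 log 0 = 0`; depends only on the
#' proportions, so sequencing depth cancels.
#'
#' @param counts_row nonnegative vector with positive sum.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts_row) {
  if (any(counts_row < 0)) abort("negative abundances.")
  if (sum(counts_row) <= 0) abort("all-zero abundance row.")
  as.numeric(vegan::diversity(counts_row, index = "shannon"))
}

#' Per-subject resilience of Shannon diversity
#'
#' The resilience statistic: mean Shannon diversity over the window of
#' `window_days` calendar days immediately before the perturbation
#' (`[-window_days, -1]`) and immediately after it (`[1, window_days]`), and
#' their relative change `(post - pre) / pre`. Negative scores mean diversity
#' dropped. Days without a sample are tolerated (the mean runs over available
#' samples); a subject with an empty window is flagged missing rather than
#' silently dropped.
#'
#' @param study a [study_table].
#' @param window_days window length in days (default 3).
#' @return tibble of class `resilience_scores` with columns `subject_id`,
#'   `pre_mean_H`, `post_mean_H`, `score`, `n_pre`, `n_post`, `missing`.
#' @export
resilience_score <- function(study, window_days = 3L) {
  md <- study$metadata
  H <- apply(study$counts, 1, shannon)
  per_subject <- lapply(unique(md$subject_id), function(s) {
    pre_idx <- md$subject_id == s & md$day >= -window_days & md$day <= -1
    post_idx <- md$subject_id == s & md$day >= 1 & md$day <= window_days
    pre_H <- mean(H[pre_idx]); post_H <- mean(H[post_idx])
    missing <- sum(pre_idx) == 0 || sum(post_idx) == 0 ||
      (sum(pre_idx) > 0 && pre_H <= 0)
    tibble(subject_id = s,
           pre_mean_H = if (sum(pre_idx)) pre_H else NA_real_,
           post_mean_H = if (sum(post_idx)) post_H else NA_real_,
           score = if (!missing) (post_H - pre_H) / pre_H else NA_real_,
           n_pre = sum(pre_idx), n_post = sum(post_idx),
           missing = missing)
  })
  out <- dplyr::bind_rows(per_subject)
  class(out) <- c("resilience_scores", class(out))
  out
}

#' Baseline family-level composition per subject
#'
#' Predictor matrix for resilience: for each subject, the mean relative
#' abundance of each taxonomic family over the samples taken within the first
#' `onset_days` days of that subject's own sampling. Rows sum to 1. Taxa
#' without a family assignment are pooled as `"Unclassified"`.
#'
#' @param study a [study_table] whose taxonomy has a `family` rank.
#' @param onset_days length of the onset window, counted from each subject's
#'   first sampled day.
#' @return numeric matrix, subjects x families.
#' @export
baseline_family_features <- function(study, onset_days = 7L) {
  if (is.null(study$taxonomy) || is.null(study$taxonomy$family) ||
      all(is.na(study$taxonomy$family))) {
    abort("taxonomy with a `family` rank is required.")
  }
  fam <- as.character(study$taxonomy$family)
  fam[is.na(fam)] <- "Unclassified"
  rel <- relative_abundance(study)
  # per-sample family proportions
  fam_rel <- t(rowsum(t(rel), fam))
  md <- study$metadata
  subjects <- unique(md$subject_id)
  feats <- t(vapply(subjects, function(s) {
    days <- md$day[md$subject_id == s]
    idx <- md$subject_id == s & md$day <= min(days) + onset_days - 1
    colMeans(fam_rel[idx, , drop = FALSE])
  }, numeric(ncol(fam_rel))))
  rownames(feats) <- subjects
  feats
}

#' Elastic net tuned by bootstrap resampling of subjects
#'
#' Minimizes `(1/2n) ||y - X b - b0||^2 + lambda (alpha ||b||_1 +
#' (1 - alpha)/2 ||b||^2)`, choosing `lambda` to minimize the mean
#' out-of-bag squared prediction error over `n_boot` bootstrap resamples of
#' the subjects (resamples with no out-of-bag subject are redrawn), then
#' refits on all complete subjects.
#'
#' @param Xf subject-by-feature matrix (e.g. [baseline_family_features()]).
#' @param y response per subject (e.g. the resilience score); `NA` entries
#'   drop the subject.
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param lambda_grid decreasing penalty grid; default from the full-data
#'   path, extended to 0.
#' @param n_boot bootstrap resamples.
#' @param seed optional seed for the resampling.
#' @return object of class `resilience_enet` with `coefficients`,
#'   `intercept`, `lambda`, `alpha` and the bootstrap tuning trace.
#' @export
fit_enet <- function(Xf, y, alpha = 0.5, lambda_grid = NULL, n_boot = 200L,
                     seed = NULL) {
  keep <- !is.na(y)
  Xf <- as.matrix(Xf)[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 3) abort("need at least 3 complete subjects.")
  if (is.null(lambda_grid)) {
    base <- glmnet::glmnet(Xf, y, alpha = alpha, standardize = FALSE)
    lambda_grid <- sort(unique(c(base$lambda, min(base$lambda) *
                                   c(0.3, 0.1, 0.03, 0.01), 0)),
                        decreasing = TRUE)
  }
  run_boot <- function() {
    errs <- matrix(NA_real_, n_boot, length(lambda_grid))
    for (bidx in seq_len(n_boot)) {
      repeat {
        bag <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(bag))
        if (length(oob) > 0) break
      }
      fit <- glmnet::glmnet(Xf[bag, , drop = FALSE], y[bag], alpha = alpha,
                            lambda = lambda_grid, standardize = FALSE,
                            thresh = 1e-10)
      pred <- predict(fit, Xf[oob, , drop = FALSE], s = lambda_grid)
      errs[bidx, ] <- colMeans((y[oob] - pred)^2)
    }
    errs
  }
  errs <- if (is.null(seed)) run_boot() else withr::with_seed(seed, run_boot())
  mean_err <- colMeans(errs)
  best <- which.min(mean_err)
  final <- glmnet::glmnet(Xf, y, alpha = alpha, lambda = lambda_grid,
                          standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(final$beta[, best])
  names(beta) <- colnames(Xf)
  structure(list(coefficients = beta,
                 intercept = final$a0[best],
                 lambda = lambda_grid[best],
                 alpha = alpha,
                 lambda_grid = lambda_grid,
                 boot_mse = mean_err,
                 n_boot = n_boot,
                 n_subjects = n,
                 fit = final),
            class = "resilience_enet")
}

#' Resilience prediction from baseline composition
#'
#' Convenience wrapper: [resilience_score()] responses regressed on
#' [baseline_family_features()] via [fit_enet()]. With small cohorts this is
#' exploratory by construction; treat selected families as hypotheses.
#'
#' @param study a [study_table] with family-level taxonomy.
#' @param window_days resilience window (days).
#' @param onset_days predictor window (days from each subject's first
#'   sample).
#' @param alpha,n_boot,seed passed to [fit_enet()].
#' @return a `resilience_enet`; its `scores` element holds the per-subject
#'   resilience table.
#' @export
resilience_enet <- function(study, window_days = 3L, onset_days = 7L,
                            alpha = 0.5, n_boot = 200L, seed = NULL) {
  scores <- resilience_score(study, window_days)
  feats <- baseline_family_features(study, onset_days)
  y <- scores$score[match(rownames(feats), scores$subject_id)]
  model <- fit_enet(feats, y, alpha = alpha, n_boot = n_boot, seed = seed)
  model$scores <- scores
  model
}

#' @export
print.resilience_enet <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<resilience_enet> lambda =", signif(x$lambda, 4), "alpha =", x$alpha,
      ";", nz, "of", length(x$coefficients),
      "family coefficients non-zero\n")
  invisible(x)
}

#' @export
tidy.resilience_enet <- function(x, ...) {
  tibble(family = names(x$coefficients),
         coefficient = unname(x$coefficients)) |>
    dplyr::filter(.data$coefficient != 0)
}

#' @export
glance.resilience_enet <- function(x, ...) {
  tibble(lambda = x$lambda, alpha = x$alpha,
         n_nonzero = sum(x$coefficients != 0),
         n_subjects = x$n_subjects,
         boot_mse = min(x$boot_mse))
}

#' @export
autoplot.resilience_enet <- function(object, ...) {
  df <- tibble(lambda = object$lambda_grid, mse = object$boot_mse)
  ggplot(df, aes(x = .data$lambda, y = .data$mse)) +
    geom_line() + geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    labs(x = "penalty lambda (log scale)", y = "out-of-bag MSE") +
    theme_bw()
}
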