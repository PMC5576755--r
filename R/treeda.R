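#' Filter taxa by prevalence at a minimum abundance
#'
#' Keeps taxa observed at a count of at least `min_count` in at least
#' `min_samples` samples (boundary inclusive). The defaults (5 in 10) are the
#' standard pre-filter applied before the supervised analysis.
#'
#' @param study a [study_table].
#' @param min_count minimum count for a sample to count as "present".
#' @param min_samples minimum number of such samples.
#' @return the filtered [study_table].
#' @export
filter_taxa <- function(study, min_count = 5L, min_samples = 10L) {
  keep <- colSums(study$counts >= min_count) >= min_samples
  if (!any(keep)) abort("no taxon survives the abundance filter.")
  taxonomy <- study$taxonomy
  if (!is.null(taxonomy)) taxonomy <- taxonomy[keep, ]
  study_table(study$counts[, keep, drop = FALSE], study$metadata, taxonomy)
}

#' Default class labels for the discriminant analysis
#'
#' `pre` versus `imm_post` (days 1-3 after the perturbation); `post` samples
#' get `NA` and are excluded from fitting.
#'
#' @param study a [study_table].
#' @return factor with levels `pre`, `imm_post` (positive scores point toward
#'   `imm_post`), `NA` for late samples.
#' @export
treeda_labels <- function(study) {
  ph <- study$metadata$phase
  factor(ifelse(ph == "post", NA, ph), levels = c("pre", "imm_post"))
}

# elastic net with an explicit ridge term and an active-feature budget:
# lasso on ridge-augmented data, path truncated at the requested count
enet_budget <- function(X, z, budget, ridge) {
  p <- ncol(X)
  Xa <- rbind(X, diag(sqrt(ridge), p))
  za <- c(z, rep(0, p))
  lam_max <- max(abs(crossprod(Xa, za))) / length(za)
  lam <- exp(seq(log(lam_max), log(lam_max * 1e-7), length.out = 100))
  # dfmax stops the path once the budget is exceeded; the kept solution is
  # the smallest-penalty point with at most `budget` active features
  fit <- withCallingHandlers(
    glmnet::glmnet(Xa, za, alpha = 1, lambda = lam,
                   standardize = FALSE, intercept = FALSE,
                   dfmax = budget, thresh = 1e-10, maxit = 1e6),
    warning = function(w) {
      # the early path stop at the budget is intended, not a problem
      if (grepl("pmax|10041|lambdas", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  ok <- which(fit$df <= budget)
  beta <- as.numeric(fit$beta[, max(ok)])
  names(beta) <- colnames(X)
  beta
}

#' Sparse discriminant analysis by optimal scoring
#'
#' Fits one sparse discriminant direction for a binary response by
#' alternating (a) an elastic-net regression of the scored class indicator on
#' the centered features, constrained to at most `n_predictors` active
#' features (a penalty path is solved and truncated at the requested count),
#' and (b) the optimal-scoring update of the class scores. Sparsity is what
#' makes the problem well-posed when node features are included: each node
#' column is exactly the sum of its descendant leaf columns, so the
#' unpenalized problem is unidentifiable.
#'
#' @param features a `feature_matrix` from [expand_features()], or a plain
#'   numeric matrix with column names.
#' @param labels binary factor/character per sample (`NA` rows are dropped);
#'   the second factor level receives positive scores.
#' @param n_predictors maximum number of active features.
#' @param ridge ridge penalty for numerical stability; default `1e-6 * p`.
#' @param max_iter,tol alternation control.
#' @param tree optional [ape::phylo] tree for leaf-level back-mapping of the
#'   coefficients.
#' @return object of class `treeda_model` with sparse `coefficients`,
#'   `n_active`, per-class score `centroids`, `feature_means`, per-sample
#'   training `scores`, and (given a tree) `leaf_effects`.
#' @export
fit_sparse_lda <- function(features, labels, n_predictors, ridge = NULL,
                           max_iter = 50L, tol = 1e-6, tree = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  kind <- if (inherits(features, "feature_matrix")) features$kind else
    rep("leaf", ncol(X))
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  labels <- droplevels(factor(labels[keep]))
  if (nlevels(labels) != 2) abort("need exactly two classes.")
  n <- nrow(X); p <- ncol(X)
  if (n_predictors < 1) abort("`n_predictors` must be at least 1.")
  if (n_predictors > p) {
    warn("`n_predictors` exceeds the feature count; clipped.")
    n_predictors <- p
  }
  if (is.null(ridge)) ridge <- 1e-6 * p
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)

  Y <- stats::model.matrix(~ labels - 1)
  pri <- colMeans(Y)
  # initial scores: the unique (up to sign) contrast orthogonal to the
  # weighted ones vector, oriented so the second level scores positive
  theta <- c(-sqrt(pri[2] / pri[1]), sqrt(pri[1] / pri[2]))
  beta <- numeric(p)
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    z <- as.numeric(Y %*% theta)
    beta <- enet_budget(Xc, z, n_predictors, ridge)
    yhat <- as.numeric(Xc %*% beta)
    obj <- mean((z - yhat)^2) + ridge * sum(beta^2) / n
    if (all(beta == 0)) break
    # optimal-scoring update of theta, orthogonal to 1 under the class
    # proportions, unit length, orientation kept
    th <- as.numeric(crossprod(Y, yhat)) / (n * pri)
    th <- th - sum(th * pri)
    nrm <- sqrt(sum(pri * th^2))
    if (nrm < 1e-12) break
    th <- th / nrm
    if (sum(th * theta * pri) < 0) th <- -th
    theta <- th
    if (abs(obj_old - obj) < tol * max(obj, 1e-12)) break
    obj_old <- obj
  }
  scores <- as.numeric(Xc %*% beta)
  names(scores) <- rownames(X)
  centroids <- tapply(scores, labels, mean)
  active <- beta[beta != 0]
  leaf_eff <- NULL
  if (!is.null(tree)) leaf_eff <- leaf_coefficients(active, tree)
  structure(list(coefficients = beta,
                 active = active,
                 n_active = length(active),
                 kind = setNames(kind, colnames(X)),
                 centroids = centroids,
                 classes = levels(labels),
                 class_sizes = table(labels),
                 feature_means = means,
                 scores = scores,
                 labels = labels,
                 leaf_effects = leaf_eff,
                 n_predictors = n_predictors,
                 ridge = ridge,
                 iterations = it,
                 tree = tree),
            class = "treeda_model")
}

#' @export
print.treeda_model <- function(x, ...) {
  cat("<treeda_model> ", x$n_active, " active features (budget ",
      x$n_predictors, "); classes ", paste(x$classes, collapse = " vs "),
      "\n", sep = "")
  if (!is.null(x$leaf_effects)) {
    cat("  leaves with non-zero effective coefficient: ",
        sum(x$leaf_effects != 0), "\n", sep = "")
  }
  invisible(x)
}

#' Project samples onto a fitted discriminant axis
#'
#' @param model a `treeda_model`.
#' @param features a `feature_matrix` (or matrix) with the same feature ids.
#' @return tibble with `sample_id`, `score` (centered features times
#'   coefficients) and `predicted` (nearest class centroid; when the model is
#'   all-zero the larger training class is predicted).
#' @export
project_lda <- function(model, features) {
  X <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  miss <- setdiff(names(model$coefficients), colnames(X))
  if (length(miss)) {
    abort(paste0("missing feature(s): ", paste(head(miss, 5), collapse = ", ")))
  }
  X <- X[, names(model$coefficients), drop = FALSE]
  s <- as.numeric(sweep(X, 2, model$feature_means) %*% model$coefficients)
  if (model$n_active == 0 ||
      abs(diff(model$centroids)) < 1e-12) {
    pred <- rep(names(which.max(model$class_sizes)), length(s))
  } else {
    d1 <- abs(s - model$centroids[1]); d2 <- abs(s - model$centroids[2])
    pred <- ifelse(d1 <= d2, names(model$centroids)[1],
                   names(model$centroids)[2])
  }
  tibble(sample_id = rownames(X) %||% as.character(seq_along(s)),
         score = s, predicted = pred)
}

#' Tree-based sparse discriminant analysis of a study
#'
#' End-to-end wrapper: prevalence filter, alignment with the tree, leaf+node
#' feature expansion, and the sparse optimal-scoring fit, discriminating
#' `pre` from `imm_post` samples by default.
#'
#' @param study a [study_table] with taxonomy (optional) and metadata.
#' @param tree a rooted [ape::phylo] tree covering the taxa.
#' @param n_predictors active-feature budget (use [treeda_cv()] to choose).
#' @param transform variance-stabilizing transform.
#' @param labels optional label factor (default [treeda_labels()]).
#' @param min_count,min_samples prevalence filter (see [filter_taxa()]);
#'   set `min_samples = 0` to skip.
#' @param ridge see [fit_sparse_lda()].
#' @return a `treeda_model` carrying `leaf_effects` and the pruned tree.
#' @export
treeda <- function(study, tree, n_predictors, transform = c("log1p", "asinh"),
                   labels = NULL, min_count = 5L, min_samples = 10L,
                   ridge = NULL) {
  transform <- match.arg(transform)
  if (min_samples > 0) study <- filter_taxa(study, min_count, min_samples)
  al <- align_study(study, tree)
  feats <- expand_features(al$study, al$tree, transform)
  if (is.null(labels)) labels <- treeda_labels(al$study)
  model <- fit_sparse_lda(feats, labels, n_predictors, ridge = ridge,
                          tree = al$tree)
  model$transform <- transform
  model
}

#' Leave-one-subject-out cross-validation for the discriminant budget
#'
#' For each held-out subject, fits the discriminant model on the remaining
#' subjects at every candidate budget and classifies the held-out samples by
#' nearest class centroid on the discriminant axis. The chosen budget
#' minimizes the mean misclassification rate over folds, with ties broken
#' toward the sparser model. Folds whose training data contain a single class
#' are skipped with a warning.
#'
#' @inheritParams treeda
#' @param budget_grid integer vector of candidate active-feature counts.
#' @return object of class `treeda_cv`: fold-by-budget error matrix, mean
#'   errors, and `best_budget`.
#' @export
treeda_cv <- function(study, tree, budget_grid, transform = c("log1p", "asinh"),
                      labels = NULL, min_count = 5L, min_samples = 10L,
                      ridge = NULL) {
  transform <- match.arg(transform)
  if (min_samples > 0) study <- filter_taxa(study, min_count, min_samples)
  al <- align_study(study, tree)
  feats <- expand_features(al$study, al$tree, transform)
  if (is.null(labels)) labels <- treeda_labels(al$study)
  subj <- al$study$metadata$subject_id
  use <- !is.na(labels)
  subjects <- unique(subj[use])
  if (length(subjects) < 2) abort("need at least 2 subjects for CV.")
  budget_grid <- sort(unique(as.integer(budget_grid)))
  errs <- matrix(NA_real_, length(subjects), length(budget_grid),
                 dimnames = list(subjects, budget_grid))
  for (s in subjects) {
    tr <- use & subj != s
    te <- use & subj == s
    if (length(unique(labels[tr])) < 2) {
      warn(paste0("fold ", s, " skipped: single-class training data."))
      next
    }
    Xtr <- feats; Xtr$values <- feats$values[tr, , drop = FALSE]
    Xte <- feats$values[te, , drop = FALSE]
    for (j in seq_along(budget_grid)) {
      m <- fit_sparse_lda(Xtr, labels[tr], budget_grid[j], ridge = ridge)
      pred <- project_lda(m, Xte)$predicted
      errs[s, j] <- mean(pred != as.character(labels[te]))
    }
  }
  mean_err <- colMeans(errs, na.rm = TRUE)
  best <- budget_grid[which.min(mean_err)]  # which.min takes the first tie
  structure(list(budget_grid = budget_grid, fold_errors = errs,
                 mean_errors = mean_err, best_budget = best,
                 transform = transform),
            class = "treeda_cv")
}

#' @export
print.treeda_cv <- function(x, ...) {
  cat("<treeda_cv> best budget ", x$best_budget, " (mean error ",
      sprintf("%.3f", x$mean_errors[as.character(x$best_budget)]), ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.treeda_cv <- function(x, ...) {
  as_tibble(x$fold_errors, rownames = "subject_id") |>
    tidyr::pivot_longer(-"subject_id", names_to = "budget",
                        values_to = "error") |>
    dplyr::mutate(budget = as.integer(.data$budget))
}

#' @export
autoplot.treeda_cv <- function(object, ...) {
  df <- tibble(budget = object$budget_grid, error = object$mean_errors)
  ggplot(df, aes(x = .data$budget, y = .data$error)) +
    geom_line() + geom_point() +
    labs(x = "active-feature budget", y = "mean LOSO misclassification") +
    theme_bw()
}

#' @export
tidy.treeda_model <- function(x, ...) {
  act <- x$active
  tibble(feature = names(act),
         kind = unname(x$kind[names(act)]),
         coefficient = unname(act),
         clade_size = vapply(names(act), function(f) {
           if (is.null(x$tree)) return(NA_integer_)
           length(clade_leaves(x$tree, f))
         }, integer(1)))
}

#' @export
glance.treeda_model <- function(x, ...) {
  tibble(n_active = x$n_active,
         n_leaves_nonzero = if (!is.null(x$leaf_effects))
           sum(x$leaf_effects != 0) else NA_integer_,
         centroid_gap = unname(abs(diff(x$centroids))),
         training_error = {
           d1 <- abs(x$scores - x$centroids[1])
           d2 <- abs(x$scores - x$centroids[2])
           pred <- ifelse(d1 <= d2, names(x$centroids)[1],
                          names(x$centroids)[2])
           mean(pred != as.character(x$labels))
         },
         iterations = x$iterations)
}

#' @export
autoplot.treeda_model <- function(object, ...) {
  df <- tibble(score = object$scores, class = object$labels)
  ggplot(df, aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    labs(x = "discriminant score", y = "samples") + theme_bw()
}
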