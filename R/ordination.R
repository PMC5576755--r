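#' Bray-Curtis dissimilarity between samples
#'
#' Computed on per-sample relative abundances, so
#' `d(x, y) = sum |x_j - y_j| / sum (x_j + y_j)` with values in `[0, 1]`
#' (0 for identical compositions, 1 for disjoint supports).
#'
#' @param study a [study_table].
#' @return symmetric `n x n` matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
bray_curtis <- function(study) {
  prop <- relative_abundance(study)
  as.matrix(vegan::vegdist(prop, method = "bray"))
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Eigendecomposes the double-centered matrix `-1/2 J D^2 J`. Axes are the
#' top-`k` eigenvectors scaled by the square root of their eigenvalues;
#' negative eigenvalues (non-Euclidean dissimilarities) are reported but never
#' used for axes, and `k` is truncated with a warning when it exceeds the
#' number of positive eigenvalues.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param k number of axes to return.
#' @return an `ordination` object (method `"pcoa"`, no variable loadings).
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("`D` must be symmetric.")
  n <- nrow(D)
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))   # double centering J G J, done in parts:
  G <- sweep(G, 2, colMeans(G))   # second sweep already re-adds the grand mean
  ed <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(ed$values > max(ed$values, 0) * 1e-10 & ed$values > 0)
  if (k > length(pos)) {
    if (length(pos) == 0) {
      warn("no positive eigenvalues; returning zero scores on k axes.")
      scores <- matrix(0, n, k, dimnames = list(rownames(D), paste0("Axis", seq_len(k))))
      return(new_ordination(scores, NULL, rep(0, k), "pcoa",
                            all_eigenvalues = ed$values))
    }
    warn(paste0("k reduced to ", length(pos), " positive eigenvalues."))
    k <- length(pos)
  }
  idx <- pos[seq_len(k)]
  scores <- ed$vectors[, idx, drop = FALSE] %*% diag(sqrt(ed$values[idx]), k)
  rownames(scores) <- rownames(D)
  new_ordination(scores, NULL, ed$values[idx], "pcoa",
                 all_eigenvalues = ed$values)
}

#' Bray-Curtis ordination of a study
#'
#' Convenience wrapper: [bray_curtis()] distances followed by [pcoa()],
#' carrying the sample metadata for plotting.
#'
#' @param study a [study_table].
#' @param k number of axes.
#' @return an `ordination` object.
#' @export
bray_mds <- function(study, k = 2L) {
  ord <- pcoa(bray_curtis(study), k)
  ord$metadata <- study$metadata
  ord
}

#' Generalized principal components analysis
#'
#' PCA of a column-centered matrix `X` under the inner product defined by a
#' positive semidefinite metric `S`: with `S = U D U'` and `W = U D^(1/2)`,
#' the SVD `X W = A Sigma B'` gives sample scores `A Sigma` and variable
#' loadings `v_j = W b_j`, so `X v_j` reproduces score column `j` and
#' full-space score distances are the generalized distances
#' `sqrt((x_i - x_j)' S (x_i - x_j))`. `S = I` recovers ordinary PCA; `S = Q`
#' (the tree covariance) recovers the sample geometry of double principal
#' coordinates analysis.
#'
#' @param X column-centered numeric matrix (`n x p`).
#' @param S `p x p` positive semidefinite metric.
#' @param k number of axes.
#' @return an `ordination` object with eigenvalues (squared singular values
#'   divided by `n - 1`) and per-axis variance fractions.
#' @export
gpca <- function(X, S, k = 2L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (max(abs(colMeans(X))) > 1e-6 * max(1, max(abs(X)))) {
    warn("`X` does not look column-centered.")
  }
  ed <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values))) {
    abort("`S` is not positive semidefinite.")
  }
  d <- pmax(ed$values, 0)
  W <- ed$vectors %*% diag(sqrt(d), p)
  sv <- svd(X %*% W)
  k <- min(k, length(sv$d))
  eig_all <- sv$d^2 / (n - 1)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- W %*% sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude entry of each score column positive
  for (j in seq_len(k)) {
    s <- sign(scores[which.max(abs(scores[, j])), j])
    if (s < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  new_ordination(scores, loadings, eig_all[seq_len(k)], "gpca",
                 all_eigenvalues = eig_all)
}

new_ordination <- function(scores, loadings, eigenvalues, method,
                           all_eigenvalues = NULL, shrinkage = NULL,
                           metadata = NULL) {
  colnames(scores) <- paste0("Axis", seq_len(ncol(scores)))
  if (!is.null(loadings)) colnames(loadings) <- colnames(scores)
  total <- sum(pmax(all_eigenvalues %||% eigenvalues, 0))
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eigenvalues,
                 all_eigenvalues = all_eigenvalues,
                 variance_fraction = if (total > 0) eigenvalues / total
                                     else rep(0, length(eigenvalues)),
                 method = method, shrinkage = shrinkage,
                 metadata = metadata),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination:", x$method, "> ", nrow(x$scores), " samples, ",
      ncol(x$scores), " axes; variance fractions ",
      paste(sprintf("%.3f", x$variance_fraction), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$shrinkage)) {
    cat("  tree-prior weight r =", sprintf("%.3f", x$shrinkage$r), "\n")
  }
  invisible(x)
}

#' Estimate the strength of the tree-structured prior
#'
#' Models the centered rows of `X` as independent zero-mean Gaussians with
#' covariance `sigma2_tree * Q + sigma2_iid * I` and maximizes the marginal
#' likelihood. In the eigenbasis of `Q = V L V'` the coordinates decouple
#' (variance along eigenvector `j` is `sigma2_tree * l_j + sigma2_iid`), so
#' the total variance is profiled in closed form and only the variance ratio
#' `k = sigma2_iid / sigma2_tree` is searched, over `log k` on
#' `[1e-6, 1e6]`.
#'
#' @param X column-centered `n x p` matrix.
#' @param Q `p x p` tree similarity matrix (see [tree_similarity()]).
#' @return object of class `shrinkage_estimate` with fields `sigma2_tree`,
#'   `sigma2_iid`, `k_ratio`, `r = sigma2_tree / (sigma2_tree + sigma2_iid)`,
#'   `log_likelihood`, and `unidentifiable` (`TRUE` when `Q` is a multiple of
#'   the identity, in which case `r = 0` and the ordination falls back to
#'   PCA).
#' @export
estimate_shrinkage <- function(X, Q) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort("need at least 2 samples.")
  ed <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  s <- colMeans((X %*% ed$vectors)^2)  # mean squared coordinate per eigvec

  if (max(lam) - min(lam) < 1e-10 * max(lam)) {
    sig_iid <- mean(s)
    ll <- ll_decoupled(s, rep(sig_iid, p), n)
    return(new_shrinkage(0, sig_iid, ll, unidentifiable = TRUE))
  }

  # profiled negative log-likelihood as a function of log k
  nll <- function(logk) {
    k <- exp(logk)
    d <- lam + k
    sig_t <- mean(s / d)
    sum(log(d)) + p * log(sig_t)
  }
  opt <- optimize(nll, interval = log(c(1e-6, 1e6)), tol = 1e-8)
  k_hat <- exp(opt$minimum)
  sig_t <- mean(s / (lam + k_hat))
  sig_i <- k_hat * sig_t
  ll <- ll_decoupled(s, sig_t * lam + sig_i, n)
  new_shrinkage(sig_t, sig_i, ll, unidentifiable = FALSE)
}

# marginal log-likelihood of n iid rows given per-eigenvector variances v_j,
# where s_j is the mean squared coordinate along eigenvector j
ll_decoupled <- function(s, v, n) {
  -n / 2 * sum(log(2 * pi * v) + s / v)
}

new_shrinkage <- function(sigma2_tree, sigma2_iid, log_likelihood,
                          unidentifiable) {
  structure(list(sigma2_tree = sigma2_tree, sigma2_iid = sigma2_iid,
                 k_ratio = if (sigma2_tree > 0) sigma2_iid / sigma2_tree
                           else Inf,
                 r = if (sigma2_tree + sigma2_iid > 0)
                       sigma2_tree / (sigma2_tree + sigma2_iid) else 0,
                 log_likelihood = log_likelihood,
                 unidentifiable = unidentifiable),
            class = "shrinkage_estimate")
}

#' @export
print.shrinkage_estimate <- function(x, ...) {
  cat("<shrinkage_estimate> sigma2_tree =", signif(x$sigma2_tree, 4),
      " sigma2_iid =", signif(x$sigma2_iid, 4),
      " r =", signif(x$r, 4),
      if (x$unidentifiable) " (unidentifiable; PCA fallback)", "\n")
  invisible(x)
}

#' @export
glance.shrinkage_estimate <- function(x, ...) {
  tibble(sigma2_tree = x$sigma2_tree, sigma2_iid = x$sigma2_iid,
         k_ratio = x$k_ratio, r = x$r, log_likelihood = x$log_likelihood,
         unidentifiable = x$unidentifiable)
}

#' Adaptive generalized PCA
#'
#' Ordination that interpolates between ordinary PCA and the tree-driven
#' geometry of DPCoA, with the interpolation point estimated from the data.
#' The transformed, column-centered counts are modeled with a tree-structured
#' Gaussian prior of unknown strength ([estimate_shrinkage()]); the resulting
#' metric is the posterior-mean operator `S = Q (Q + k I)^(-1)`, which tends
#' to the identity (PCA) as `k -> 0` and to a multiple of `Q` (DPCoA) as
#' `k -> Inf`.
#'
#' @param study a [study_table] aligned with `tree`.
#' @param tree a rooted [ape::phylo] tree.
#' @param k number of axes.
#' @param transform variance-stabilizing transform for the counts.
#' @param k_ratio optional forced variance ratio `sigma2_iid / sigma2_tree`;
#'   by default it is estimated.
#' @return an `ordination` object (method `"agpca"`) carrying the fitted
#'   `shrinkage_estimate` and the sample metadata.
#' @export
adaptive_gpca <- function(study, tree, k = 2L,
                          transform = c("log1p", "asinh"), k_ratio = NULL) {
  transform <- match.arg(transform)
  f <- transform_fun(transform)
  X <- f(study$counts[, tree$tip.label, drop = FALSE])
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- tree_similarity(tree)
  est <- NULL
  if (is.null(k_ratio)) {
    est <- estimate_shrinkage(X, Q)
    k_ratio <- if (est$unidentifiable) 0 else est$k_ratio
  }
  S <- shrinkage_metric(Q, k_ratio)
  ord <- gpca(X, S, k)
  ord$method <- "agpca"
  ord$shrinkage <- est
  ord$k_ratio <- k_ratio
  ord$metadata <- study$metadata
  ord
}

# posterior-mean metric S = Q (Q + k I)^{-1}, computed in Q's eigenbasis;
# k = 0 is the exact PCA endpoint (identity)
shrinkage_metric <- function(Q, k_ratio) {
  if (k_ratio == 0) return(diag(nrow(Q)))
  ed <- eigen((Q + t(Q)) / 2, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  ed$vectors %*% diag(lam / (lam + k_ratio)) %*% t(ed$vectors)
}

#' Subject-centered ordination scores
#'
#' Subtracts each subject's mean score vector, exposing within-subject
#' variation (e.g. the transient post-perturbation excursion) that the strong
#' between-subject differences would otherwise mask.
#'
#' @param ord an `ordination` with sample ids on its scores.
#' @param study the [study_table] providing `subject_id` per sample.
#' @return `n x k` matrix of centered scores.
#' @export
center_scores_by_subject <- function(ord, study) {
  scores <- ord$scores
  subj <- study$metadata$subject_id[match(rownames(scores),
                                          study$metadata$sample_id)]
  if (anyNA(subj)) abort("subjects unknown for some samples.")
  means <- apply(scores, 2, function(col) tapply(col, subj, mean)[subj])
  scores - means
}

#' @export
tidy.ordination <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(axis = seq_along(x$eigenvalues),
                  eigenvalue = x$eigenvalues,
                  variance_fraction = x$variance_fraction))
  }
  m <- x[[matrix]]
  if (is.null(m)) abort(paste0("no ", matrix, " in this ordination."))
  id_col <- if (matrix == "scores") "sample_id" else "taxon_id"
  out <- as_tibble(m, rownames = id_col)
  if (matrix == "scores" && !is.null(x$metadata)) {
    out <- dplyr::left_join(out, x$metadata, by = "sample_id")
  }
  out
}

#' @export
glance.ordination <- function(x, ...) {
  tibble(method = x$method, n_axes = ncol(x$scores),
         var_explained = sum(x$variance_fraction),
         r = if (!is.null(x$shrinkage)) x$shrinkage$r else NA_real_)
}

#' @export
autoplot.ordination <- function(object, axes = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  ax <- paste0("Axis", axes)
  p <- ggplot(sc, aes(x = .data[[ax[1]]], y = .data[[ax[2]]]))
  if ("subject_id" %in% names(sc)) {
    p <- p + geom_point(aes(colour = .data$subject_id,
                            shape = .data$phase))
  } else {
    p <- p + geom_point()
  }
  pct <- round(100 * object$variance_fraction[axes], 1)
  p + labs(x = paste0(ax[1], " (", pct[1], "%)"),
           y = paste0(ax[2], " (", pct[2], "%)"),
           title = paste("Ordination:", object$method)) +
    theme_bw()
}
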