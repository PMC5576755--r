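#' Prepare taxon and gene tables for sparse CCA
#'
#' Applies the standard preprocessing for coupling the two tables: the taxon
#' table is optionally restricted to a genus of interest, `log(1 + x)`
#' transformed and column-centered; the gene table is `asinh` transformed and
#' column-centered. Both transforms reduce the heavy right tails of genomic
#' count data. Constant columns carry no covariation and are dropped with a
#' warning.
#'
#' @param study a [study_table] (with taxonomy when `genus_filter` is set).
#' @param genes a [gene_table] on the same samples.
#' @param genus_filter genus name to restrict taxa to, or `NULL` for all taxa.
#' @return list with centered matrices `X` (taxa) and `Y` (gene terms).
#' @export
prepare_tables <- function(study, genes, genus_filter = "Bacteroides") {
  shared <- intersect(rownames(study$counts), rownames(genes$abundances))
  if (length(shared) == 0) abort("no shared samples between the tables.")
  counts <- study$counts[shared, , drop = FALSE]
  if (!is.null(genus_filter)) {
    if (is.null(study$taxonomy) || is.null(study$taxonomy$genus)) {
      abort("taxonomy with a `genus` rank is required for a genus filter.")
    }
    keep <- !is.na(study$taxonomy$genus) & study$taxonomy$genus == genus_filter
    if (!any(keep)) {
      abort(paste0("genus filter matches no taxa: ", genus_filter))
    }
    counts <- counts[, keep, drop = FALSE]
  }
  X <- scale(log1p(counts), center = TRUE, scale = FALSE)
  Y <- scale(asinh(genes$abundances[shared, , drop = FALSE]),
             center = TRUE, scale = FALSE)
  X <- drop_constant(X, "taxon")
  Y <- drop_constant(Y, "gene-term")
  list(X = X, Y = Y)
}

drop_constant <- function(M, what) {
  const <- apply(M, 2, function(col) all(abs(col - col[1]) < 1e-12))
  if (any(const)) {
    warn(paste0(sum(const), " constant ", what, " column(s) dropped."))
    M <- M[, !const, drop = FALSE]
  }
  M
}

# l2-normalized soft thresholding with the threshold chosen by bisection so
# that the l1 norm of the result is at most c
soft_l1 <- function(a, c) {
  norm2 <- function(x) sqrt(sum(x^2))
  su <- function(delta) {
    x <- sign(a) * pmax(abs(a) - delta, 0)
    n <- norm2(x)
    if (n == 0) x else x / n
  }
  u <- su(0)
  if (sum(abs(u)) <= c) return(u)
  lo <- 0; hi <- max(abs(a))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (sum(abs(su(mid))) > c) lo <- mid else hi <- mid
  }
  su(hi)
}

#' Sparse CCA by penalized matrix decomposition
#'
#' Finds sparse weight vectors `u`, `v` maximizing `u' X'Y v` subject to
#' `||u||_2 <= 1`, `||v||_2 <= 1`, `||u||_1 <= c_u`, `||v||_1 <= c_v`, by
#' alternating soft-threshold updates (the threshold set by bisection to meet
#' the l1 bound). Subsequent components come from rank-one deflation of the
#' cross-product matrix; they are not forced orthogonal in sample space. The
#' reported correlation per component is the Pearson correlation of the score
#' vectors `X u` and `Y v`.
#'
#' @param X,Y column-centered matrices with the same rows (samples).
#' @param c_u,c_v l1 bounds, in `[1, sqrt(ncol)]`.
#' @param n_components number of components.
#' @param max_iter,tol alternation control.
#' @return object of class `scca`: matrices `u` (`p x K`), `v` (`g x K`),
#'   score matrices, per-component `correlations` and objective values `d`.
#' @export
pmd_cca <- function(X, Y, c_u = NULL, c_v = NULL, n_components = 1L,
                    max_iter = 200L, tol = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X); g <- ncol(Y)
  if (is.null(c_u)) c_u <- pmin(sqrt(p), pmax(1, 0.3 * sqrt(p)))
  if (is.null(c_v)) c_v <- pmin(sqrt(g), pmax(1, 0.3 * sqrt(g)))
  if (c_u < 1 || c_u > sqrt(p) + 1e-8) abort("`c_u` must lie in [1, sqrt(p)].")
  if (c_v < 1 || c_v > sqrt(g) + 1e-8) abort("`c_v` must lie in [1, sqrt(g)].")
  Z <- crossprod(X, Y)
  if (max(abs(Z)) == 0) abort("zero cross-covariance matrix.")
  U <- matrix(0, p, n_components, dimnames = list(colnames(X), NULL))
  V <- matrix(0, g, n_components, dimnames = list(colnames(Y), NULL))
  d <- numeric(n_components)
  for (comp in seq_len(n_components)) {
    sv <- svd(Z, nu = 1, nv = 1)
    v <- sv$v[, 1]
    v <- v * sign(v[which.max(abs(v))])  # deterministic orientation
    u <- numeric(p)
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      u_new <- soft_l1(as.numeric(Z %*% v), c_u)
      v_new <- soft_l1(as.numeric(crossprod(Z, u_new)), c_v)
      delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
      u <- u_new; v <- v_new
      trace[it] <- as.numeric(t(u) %*% Z %*% v)
      if (delta < tol) break
    }
    if (comp == 1) obj_trace <- trace
    d[comp] <- as.numeric(t(u) %*% Z %*% v)
    U[, comp] <- u; V[, comp] <- v
    Z <- Z - d[comp] * tcrossprod(u, v)
  }
  xs <- X %*% U; ys <- Y %*% V
  colnames(xs) <- colnames(ys) <- paste0("Comp", seq_len(n_components))
  cors <- vapply(seq_len(n_components), function(j) {
    if (sd(xs[, j]) == 0 || sd(ys[, j]) == 0) return(NA_real_)
    cor(xs[, j], ys[, j])
  }, numeric(1))
  structure(list(u = U, v = V, x_scores = xs, y_scores = ys,
                 correlations = cors, d = d, c_u = c_u, c_v = c_v,
                 obj_trace = obj_trace),
            class = "scca")
}

#' Sparse CCA of a study against a gene table
#'
#' Wrapper around [prepare_tables()] and [pmd_cca()] with l1 bounds expressed
#' as fractions of their maxima (`c = frac * sqrt(dim)`, clamped to
#' `[1, sqrt(dim)]`); the default 0.3 is deliberately aggressive so that few
#' taxa and terms carry each component.
#'
#' @inheritParams prepare_tables
#' @param cu_frac,cv_frac sparsity fractions in (0, 1].
#' @param n_components number of components.
#' @return an `scca` object carrying sample ids on its score matrices.
#' @export
scca <- function(study, genes, cu_frac = 0.3, cv_frac = 0.3,
                 n_components = 2L, genus_filter = "Bacteroides") {
  prep <- prepare_tables(study, genes, genus_filter)
  c_u <- min(sqrt(ncol(prep$X)), max(1, cu_frac * sqrt(ncol(prep$X))))
  c_v <- min(sqrt(ncol(prep$Y)), max(1, cv_frac * sqrt(ncol(prep$Y))))
  pmd_cca(prep$X, prep$Y, c_u, c_v, n_components)
}

#' @export
print.scca <- function(x, ...) {
  cat("<scca> ", ncol(x$u), " component(s); score correlations ",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n", sep = "")
  cat("  non-zero taxon weights: ", paste(colSums(x$u != 0), collapse = ", "),
      "; gene-term weights: ", paste(colSums(x$v != 0), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.scca <- function(x, table = c("u", "v", "scores"), ...) {
  table <- match.arg(table)
  if (table == "scores") {
    xs <- as_tibble(x$x_scores, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "taxon_score")
    ys <- as_tibble(x$y_scores, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "gene_score")
    return(dplyr::left_join(xs, ys, by = c("sample_id", "component")))
  }
  m <- x[[table]]
  colnames(m) <- paste0("Comp", seq_len(ncol(m)))
  out <- as_tibble(m, rownames = if (table == "u") "taxon_id" else "term_id")
  out |>
    tidyr::pivot_longer(-1, names_to = "component", values_to = "weight") |>
    dplyr::filter(.data$weight != 0)
}

#' @export
glance.scca <- function(x, ...) {
  tibble(component = seq_along(x$correlations),
         correlation = x$correlations,
         objective = x$d,
         n_taxa = colSums(x$u != 0),
         n_terms = colSums(x$v != 0))
}

#' @export
autoplot.scca <- function(object, component = 1L, ...) {
  df <- tibble(taxon_score = object$x_scores[, component],
               gene_score = object$y_scores[, component])
  ggplot(df, aes(x = .data$taxon_score, y = .data$gene_score)) +
    geom_point() +
    labs(title = sprintf("sCCA component %d (r = %.3f)", component,
                         object$correlations[component])) +
    theme_bw()
}
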