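#' Configuration for the design power study
#'
#' The hierarchical Gaussian model behind the crossover-versus-parallel
#' comparison: subject means `mu_s ~ N(0, tau2)`, and each observation
#' `y_i = mu_s(i) + beta * 1{s(i) in T and t(i) in effect_days} + e_i` with
#' `e_i ~ N(0, sigma2)`. In the `internal` (crossover) design every subject is
#' treated; in the `external` (parallel) design half the subjects are set
#' aside as never-treated controls.
#'
#' @param n_subjects number of subjects (default 8).
#' @param days integer vector of study days (default `-10:10`, 21 days).
#' @param effect_days days on which the treatment effect is active (default
#'   the five days `0:4`; set `0:5` for a six-day window).
#' @param beta treatment effect size (response units).
#' @param tau2 inter-subject variance.
#' @param sigma2 residual variance (default 1).
#' @param design `"internal"` or `"external"`.
#' @return a `design_config` list.
#' @export
design_config <- function(n_subjects = 8L, days = -10:10, effect_days = 0:4,
                          beta = 0, tau2 = 0, sigma2 = 1,
                          design = c("internal", "external")) {
  design <- match.arg(design)
  stopifnot(n_subjects >= 2, sigma2 > 0, tau2 >= 0)
  treated <- if (design == "internal") seq_len(n_subjects) else
    seq_len(n_subjects %/% 2)
  structure(list(n_subjects = n_subjects, days = days,
                 effect_days = effect_days, beta = beta, tau2 = tau2,
                 sigma2 = sigma2, design = design, treated = treated),
            class = "design_config")
}

#' Simulate one realization of the design model
#'
#' @param config a [design_config()].
#' @param seed optional integer seed (the draw is deterministic given it).
#' @return tibble with columns `y`, `subject`, `day`, `treated_now`.
#' @export
simulate_design_data <- function(config, seed = NULL) {
  draw <- function() {
    s <- rep(seq_len(config$n_subjects), each = length(config$days))
    d <- rep(config$days, config$n_subjects)
    treated_now <- as.integer(s %in% config$treated &
                              d %in% config$effect_days)
    mu <- rnorm(config$n_subjects, 0, sqrt(config$tau2))
    y <- mu[s] + config$beta * treated_now +
      rnorm(length(s), 0, sqrt(config$sigma2))
    tibble(y = y, subject = s, day = d, treated_now = treated_now)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# precomputed design structure for the fast profiled-REML fitter
ri_structure <- function(subject, treated_now) {
  subject <- as.integer(factor(subject))
  X <- cbind(1, treated_now)
  list(subject = subject, X = X, XtX = crossprod(X),
       Xs = rowsum(X, subject), ns = as.numeric(table(subject)),
       n = nrow(X))
}

# REML criterion profiled over sigma2, as a function of gamma = tau2/sigma2;
# per-subject compound symmetry gives O(S) evaluations via Woodbury
ri_crit <- function(gamma, st, ys, Xty, yty) {
  w <- gamma / (1 + st$ns * gamma)
  XtVX <- st$XtX - crossprod(st$Xs, w * st$Xs)
  XtVy <- Xty - crossprod(st$Xs, w * ys)
  ytVy <- yty - sum(w * ys^2)
  beta <- solve(XtVX, XtVy)
  rss <- max(ytVy - sum(beta * XtVy), .Machine$double.xmin)
  sum(log1p(st$ns * gamma)) + determinant(XtVX)$modulus[1] +
    (st$n - 2) * log(rss)
}

ri_fit_fast <- function(y, st) {
  ys <- rowsum(y, st$subject)[, 1]
  Xty <- crossprod(st$X, y)
  yty <- sum(y^2)
  opt <- optimize(function(lg) ri_crit(exp(lg), st, ys, Xty, yty),
                  interval = c(-15, 12), tol = 1e-8)
  gamma <- exp(opt$minimum)
  if (ri_crit(0, st, ys, Xty, yty) < opt$objective) gamma <- 0
  w <- gamma / (1 + st$ns * gamma)
  XtVX <- st$XtX - crossprod(st$Xs, w * st$Xs)
  XtVy <- Xty - crossprod(st$Xs, w * ys)
  ytVy <- yty - sum(w * ys^2)
  beta <- solve(XtVX, XtVy)
  rss <- ytVy - sum(beta * XtVy)
  sigma2 <- rss / (st$n - 2)
  se <- sqrt(sigma2 * solve(XtVX)[2, 2])
  t_stat <- if (se > 0 && is.finite(se)) beta[2] / se else Inf
  list(beta_hat = beta[2], t_statistic = as.numeric(t_stat),
       sigma2_hat = as.numeric(sigma2), tau2_hat = as.numeric(gamma * sigma2),
       gamma = gamma, degenerate = !is.finite(t_stat))
}

#' Random-intercept model via profiled REML
#'
#' Fits `y = b0 + beta * treated_now + u_subject + e` by restricted maximum
#' likelihood, profiling the residual variance and optimizing the variance
#' ratio `tau2/sigma2` in one dimension. Reports the Wald t-statistic for the
#' treatment effect with `n - 2` residual degrees of freedom.
#'
#' @param records data frame with `y`, `subject`, `treated_now` (as produced
#'   by [simulate_design_data()]).
#' @return list with `beta_hat`, `t_statistic`, `sigma2_hat`, `tau2_hat` and
#'   a `degenerate` flag (perfect fit, infinite t).
#' @export
fit_random_intercept <- function(records) {
  if (length(unique(records$subject)) < 2) abort("need at least 2 subjects.")
  if (var(records$y) == 0) abort("degenerate response: zero variance.")
  if (length(unique(records$treated_now)) < 2) {
    abort("`treated_now` is constant; the effect is not estimable.")
  }
  st <- ri_structure(records$subject, records$treated_now)
  ri_fit_fast(records$y, st)
}

ols_fit_fast <- function(y, st) {
  beta <- solve(st$XtX, crossprod(st$X, y))
  r <- y - st$X %*% beta
  sigma2 <- sum(r^2) / (st$n - 2)
  se <- sqrt(sigma2 * solve(st$XtX)[2, 2])
  t_stat <- if (se > 0 && is.finite(se)) beta[2] / se else Inf
  list(beta_hat = as.numeric(beta[2]), t_statistic = as.numeric(t_stat),
       sigma2_hat = as.numeric(sigma2), degenerate = !is.finite(t_stat))
}

#' Ordinary least squares ignoring subjects
#'
#' The comparison model: least squares of `y` on intercept + `treated_now`,
#' with the usual Wald t-statistic. Ignoring the subject structure inflates
#' the type-I error when inter-subject variation is present in a parallel
#' design.
#'
#' @inheritParams fit_random_intercept
#' @return list as in [fit_random_intercept()] (no `tau2_hat`).
#' @export
fit_ols <- function(records) {
  if (length(unique(records$treated_now)) < 2) {
    abort("`treated_now` is constant; the effect is not estimable.")
  }
  st <- ri_structure(records$subject, records$treated_now)
  ols_fit_fast(records$y, st)
}

#' Power study over designs, models, and effect grids
#'
#' Full factorial simulation: for every combination of `tau2`, `beta`,
#' design and replicate, one dataset is drawn and both inference models are
#' fit to the same realization. Power at level `alpha` is the fraction of
#' replicates whose |t| exceeds the two-sided critical value with `n - 2`
#' degrees of freedom; at `beta = 0` this estimates the type-I error.
#'
#' @param tau2_grid,beta_grid numeric grids (the headline comparison uses 12
#'   tau2 values on \[0, 5\] and 30 beta values on \[0, 2\]).
#' @param designs,models subsets of `c("internal", "external")` and
#'   `c("mixed", "ols")`.
#' @param replicates simulated datasets per grid cell.
#' @param alpha two-sided test level.
#' @param seed master seed; per-cell seeds are derived from it, so the whole
#'   grid is reproducible.
#' @param n_subjects,days,effect_days,sigma2 passed to [design_config()].
#' @return object of class `design_power`: long tibble of t-statistics
#'   (`$t_stats`) and the aggregated power table (`$power`).
#' @export
power_study <- function(tau2_grid, beta_grid,
                        designs = c("internal", "external"),
                        models = c("mixed", "ols"),
                        replicates = 10L, alpha = 0.05, seed = 1L,
                        n_subjects = 8L, days = -10:10, effect_days = 0:4,
                        sigma2 = 1) {
  grid <- expand.grid(tau2 = tau2_grid, beta = beta_grid, design = designs,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  cell_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, nrow(grid)))
  structures <- lapply(setNames(designs, designs), function(d) {
    cfg <- design_config(n_subjects, days, effect_days, design = d)
    s <- rep(seq_len(cfg$n_subjects), each = length(cfg$days))
    day <- rep(cfg$days, cfg$n_subjects)
    treated_now <- as.integer(s %in% cfg$treated & day %in% cfg$effect_days)
    list(st = ri_structure(s, treated_now), s = s,
         treated_now = treated_now, cfg = cfg)
  })
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ds <- structures[[g$design]]
    y <- withr::with_seed(cell_seeds[i], {
      mu <- rnorm(n_subjects, 0, sqrt(g$tau2))
      mu[ds$s] + g$beta * ds$treated_now +
        rnorm(length(ds$s), 0, sqrt(sigma2))
    })
    out <- list()
    if ("mixed" %in% models) out$mixed <- ri_fit_fast(y, ds$st)$t_statistic
    if ("ols" %in% models) out$ols <- ols_fit_fast(y, ds$st)$t_statistic
    res[[i]] <- out
  }
  t_stats <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble(tau2 = grid$tau2[i], beta = grid$beta[i],
           design = grid$design[i], replicate = grid$replicate[i],
           model = names(res[[i]]), t = unlist(res[[i]], use.names = FALSE))
  }))
  n_obs <- n_subjects * length(days)
  crit <- qt(1 - alpha / 2, df = n_obs - 2)
  power <- t_stats |>
    dplyr::group_by(.data$tau2, .data$beta, .data$design, .data$model) |>
    dplyr::summarise(power = mean(abs(.data$t) > crit), .groups = "drop")
  structure(list(t_stats = t_stats, power = power, alpha = alpha,
                 critical_value = crit, replicates = replicates,
                 seed = seed),
            class = "design_power")
}

#' @export
print.design_power <- function(x, ...) {
  cat("<design_power> ", nrow(x$t_stats), " t-statistics; alpha = ",
      x$alpha, ", ", x$replicates, " replicates/cell\n", sep = "")
  print(head(x$power, 10))
  invisible(x)
}

#' @export
tidy.design_power <- function(x, ...) x$t_stats

#' @export
glance.design_power <- function(x, ...) {
  tibble(n_cells = nrow(x$power), replicates = x$replicates,
         alpha = x$alpha, critical_value = x$critical_value)
}

#' @export
autoplot.design_power <- function(object, ...) {
  ggplot(object$power,
         aes(x = .data$beta, y = .data$power,
             colour = .data$model, linetype = .data$design)) +
    geom_line() +
    facet_wrap(~tau2, labeller = ggplot2::label_both) +
    geom_hline(yintercept = object$alpha, linetype = 3) +
    labs(x = "treatment effect beta", y = "power") + theme_bw()
}
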