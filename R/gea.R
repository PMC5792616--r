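#' Fit one binomial random-intercept model
#'
#' Bernoulli GLMM \code{y ~ plogis(beta0 [+ beta1 x] + u_g)},
#' \code{u_g ~ N(0, sigma_u^2)}, estimated by Laplace approximation of the
#' marginal likelihood (profiled penalized-Newton inner solve, golden
#' section plus Newton polish on the variance). When the variance is
#' estimated at zero the returned fit is exactly the fixed-effects
#' logistic regression. AIC counts one parameter per fixed effect plus one
#' for the variance component (2 for the constant model, 3 with a
#' covariate).
#'
#' @param y binary response (0/1; NA dropped).
#' @param x optional covariate vector.
#' @param groups grouping vector (factor/integer/character) for the random
#'   intercept.
#' @return list with \code{beta0}, \code{beta1}, \code{se_beta0},
#'   \code{se_beta1}, \code{sigma_u}, \code{loglik}, \code{aic},
#'   \code{converged}, \code{n_obs}, \code{n_groups}, \code{k} (parameter
#'   count).
#' @export
fit_binomial_glmm <- function(y, x = NULL, groups) {
  stopifnot(length(y) == length(groups))
  if (!is.null(x)) {
    stopifnot(length(x) == length(y))
    if (stats::sd(x, na.rm = TRUE) == 0)
      stop("covariate is constant; the effect is inestimable")
  }
  yy <- as.double(y)
  if (!all(stats::na.omit(yy) %in% c(0, 1))) stop("response must be 0/1")
  g <- as.integer(factor(groups))
  ord <- order(g)
  gs <- as.integer(table(g))
  if (max(gs) == 1L)
    warning("all groups are singletons; the random-intercept variance is ",
            "weakly identified")
  fit <- glmm_scan_cpp(matrix(yy[ord], ncol = 1),
                       if (is.null(x)) NULL else as.double(x)[ord], gs)
  k <- if (is.null(x)) 2L else 3L
  g1 <- function(col) unname(fit[1, col])
  list(beta0 = g1("beta0"), beta1 = g1("beta1"),
       se_beta0 = g1("se_beta0"), se_beta1 = g1("se_beta1"),
       sigma_u = g1("sigma_u"), loglik = g1("loglik"),
       aic = 2 * k - 2 * g1("loglik"),
       converged = g1("converged") == 1,
       n_obs = g1("n_obs"), n_groups = g1("n_groups"), k = k)
}

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch nodes/weights for \code{int exp(-x^2) f(x) dx}, used by the
#' adaptive-quadrature cross-check of the Laplace likelihood.
#'
#' @param n number of nodes (>= 2).
#' @return list with \code{nodes} and \code{weights}.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 2)
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

#' Adaptive Gauss-Hermite marginal log-likelihood
#'
#' Evaluates the marginal log-likelihood of the binomial random-intercept
#' model at fixed parameters by adaptive Gauss-Hermite quadrature centred
#' at the conditional modes; with >= 5 nodes this is an independent
#' cross-check of the Laplace value (which is the 1-node special case).
#'
#' @inheritParams fit_binomial_glmm
#' @param beta0,beta1,sigma_u parameter values (use \code{beta1 = NULL}
#'   with \code{x = NULL}).
#' @param n_nodes quadrature nodes (default 9).
#' @return the log-likelihood.
#' @export
glmm_loglik_agq <- function(y, x = NULL, groups, beta0, beta1 = NULL,
                            sigma_u, n_nodes = 9) {
  g <- as.integer(factor(groups))
  ord <- order(g)
  gs <- as.integer(table(g))
  gh <- gauss_hermite(n_nodes)
  par <- if (is.null(x)) c(beta0, log(max(sigma_u, 1e-8)))
  else c(beta0, beta1, log(max(sigma_u, 1e-8)))
  glmm_loglik_agq_cpp(par, as.double(y)[ord],
                      if (is.null(x)) NULL else as.double(x)[ord],
                      gs, gh$nodes, gh$weights)
}

#' Likelihood-ratio test for one added fixed effect
#'
#' @param loglik_full,loglik_null log-likelihoods of the nested fits.
#' @param df degrees of freedom of the test (default 1).
#' @return list with \code{stat} (\code{2 * delta}, clipped at 0) and
#'   \code{p} (upper chi-square tail).
#' @export
lrt_pvalue <- function(loglik_full, loglik_null, df = 1) {
  stopifnot(is.finite(loglik_full), is.finite(loglik_null))
  stat <- max(0, 2 * (loglik_full - loglik_null))
  list(stat = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Recover the likelihood-ratio p-value from a pair of AICs
#'
#' For nested models differing by \code{extra_params} fixed effects,
#' \code{stat = AIC_null - AIC_full + 2 * extra_params}; the p-value is the
#' upper chi-square tail on \code{extra_params} degrees of freedom. This is
#' the internal-consistency identity linking reported AIC pairs to
#' reported likelihood-ratio p-values.
#'
#' @param aic_null,aic_full AIC of the constant and covariate models.
#' @param extra_params number of added fixed effects (default 1).
#' @return list with \code{stat} and \code{p}.
#' @export
lrt_from_aic <- function(aic_null, aic_full, extra_params = 1) {
  stat <- max(0, aic_null - aic_full + 2 * extra_params)
  list(stat = stat,
       p = stats::pchisq(stat, df = extra_params, lower.tail = FALSE))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha familywise level.
#' @param n_tests family size.
#' @return per-test threshold \code{alpha / n_tests}.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Multiscale gene-environment association scan
#'
#' Fits, for every locus, a binomial random-intercept model against each
#' terrain variable at each resolution (random effect: the DEM pixel
#' containing the sample at that resolution) and against measured altitude,
#' the two projected coordinates and the membership coefficient (random
#' effect: the sampling plot). Each model is compared to the matching
#' constant model by a likelihood-ratio test; a single Bonferroni family
#' over all attempted records controls the familywise error.
#'
#' @param gm individuals x loci matrix (after [qc_filter]); rows matched to
#'   \code{samples$id} by rownames.
#' @param env long environment table from [extract_stack]
#'   (\code{id,var,res,value}).
#' @param samples sample table.
#' @param pyr grid pyramid from [build_pyramid] (provides pixel ids per
#'   resolution).
#' @param membership optional per-individual membership coefficient (named
#'   by id) for the membership model.
#' @param assignment optional population labels (named by id) used to
#'   attach per-population band frequencies.
#' @param alpha familywise level (default 0.05).
#' @param standardize centre/scale each covariate before fitting (default
#'   TRUE; recorded in the result attributes).
#' @param extra_vars fit the Alt/X/Y/membership models (default TRUE).
#' @return data frame of association records (one per locus x variable x
#'   resolution): coefficients, random-intercept SD, log-likelihoods, AICs
#'   (constant model k = 2, covariate model k = 3), likelihood-ratio
#'   statistic and p-value, group counts, convergence and significance
#'   flags, and per-population band frequencies when \code{assignment} is
#'   given. Attributes: \code{"alpha"}, \code{"alpha_adj"},
#'   \code{"n_tests"}, \code{"standardize"}.
#' @export
scan_gea <- function(gm, env, samples, pyr, membership = NULL,
                     assignment = NULL, alpha = 0.05, standardize = TRUE,
                     extra_vars = TRUE) {
  gm <- as.matrix(gm)
  if (is.null(rownames(gm))) stop("genotype matrix needs sample-id rownames")
  if (!all(samples$id %in% rownames(gm)))
    stop("genotype matrix does not cover all sample ids")
  gm <- gm[samples$id, , drop = FALSE]
  loci <- colnames(gm)
  if (is.null(loci)) loci <- sprintf("L%03d", seq_len(ncol(gm)))
  storage.mode(gm) <- "double"
  resolutions <- sort(unique(env$res))
  # grouping schemes: one per resolution (pixels) plus the plot scheme
  schemes <- list()
  for (res in resolutions) {
    g <- pyr[[format(res)]]
    if (is.null(g)) stop("pyramid has no level at ", res, " m")
    px <- pixel_id(g, samples$x, samples$y)$pixel
    schemes[[format(res)]] <- px
  }
  schemes[["plot"]] <- samples$plot_id
  fits_null <- list()
  prep <- list()
  for (s in names(schemes)) {
    gf <- as.integer(factor(schemes[[s]]))
    ord <- order(gf)
    gs <- as.integer(table(gf))
    prep[[s]] <- list(ord = ord, gs = gs, n_groups = length(gs))
    fits_null[[s]] <- glmm_scan_cpp(gm[ord, , drop = FALSE], NULL, gs)
  }
  cells <- data.frame(var = character(0), res = numeric(0),
                      scheme = character(0), stringsAsFactors = FALSE)
  for (v in unique(env$var))
    for (res in sort(unique(env$res[env$var == v])))
      cells <- rbind(cells, data.frame(var = v, res = res,
                                       scheme = format(res)))
  if (extra_vars) {
    cells <- rbind(cells,
                   data.frame(var = c("Alt", "X", "Y"), res = NA,
                              scheme = "plot"))
    if (!is.null(membership))
      cells <- rbind(cells, data.frame(var = "membership", res = NA,
                                       scheme = "plot"))
  }
  get_covariate <- function(var, res) {
    if (is.na(res)) {
      switch(var,
             Alt = samples$alt, X = samples$x, Y = samples$y,
             membership = as.numeric(membership[samples$id]))
    } else {
      sub <- env[env$var == var & env$res == res, ]
      as.numeric(sub$value[match(samples$id, sub$id)])
    }
  }
  freq_by_pop <- if (!is.null(assignment)) {
    lab <- assignment[samples$id]
    vapply(c("A", "B", "admixed"), function(g)
      colMeans(gm[lab == g, , drop = FALSE], na.rm = TRUE),
      numeric(ncol(gm)))
  }
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    v <- cells$var[ci]; res <- cells$res[ci]; s <- cells$scheme[ci]
    pp <- prep[[s]]
    xv <- get_covariate(v, res)
    if (standardize && stats::sd(xv, na.rm = TRUE) > 0)
      xv <- as.numeric(scale(xv))
    full <- glmm_scan_cpp(gm[pp$ord, , drop = FALSE], xv[pp$ord], pp$gs)
    nul <- fits_null[[s]]
    ll_f <- full[, "loglik"]; ll_n <- nul[, "loglik"]
    stat <- pmax(0, 2 * (ll_f - ll_n))
    conv <- full[, "converged"] == 1 & nul[, "converged"] == 1
    p <- ifelse(conv, stats::pchisq(stat, 1, lower.tail = FALSE), NA_real_)
    rec <- data.frame(
      locus = loci, variable = v, resolution = res,
      beta0 = full[, "beta0"], beta1 = full[, "beta1"],
      se_beta1 = full[, "se_beta1"], sigma_u = full[, "sigma_u"],
      loglik_full = ll_f, loglik_null = ll_n,
      aic_full = 2 * 3 - 2 * ll_f, aic_null = 2 * 2 - 2 * ll_n,
      lrt_stat = stat, p = p, n_groups = full[, "n_groups"],
      converged = conv, stringsAsFactors = FALSE)
    if (!is.null(assignment)) {
      rec$freq_A <- freq_by_pop[, "A"]
      rec$freq_B <- freq_by_pop[, "B"]
      rec$freq_admixed <- freq_by_pop[, "admixed"]
    }
    out[[ci]] <- rec
  }
  out <- do.call(rbind, out)
  n_tests <- nrow(out)
  thr <- bonferroni_threshold(alpha, n_tests)
  out$significant <- !is.na(out$p) & out$p < thr & out$converged
  attr(out, "alpha") <- alpha
  attr(out, "alpha_adj") <- thr
  attr(out, "n_tests") <- n_tests
  attr(out, "standardize") <- standardize
  out
}

#' Significance profile of one association across resolutions
#'
#' @param records scan records from [scan_gea].
#' @param locus,variable the association to profile.
#' @return data frame (\code{resolution}, \code{p}, \code{neglog10_p})
#'   ordered by resolution, with the Bonferroni threshold of the scan as
#'   attribute \code{"alpha_adj"}.
#' @export
resolution_profile <- function(records, locus, variable) {
  sub <- records[records$locus == locus & records$variable == variable &
                   !is.na(records$resolution), ]
  if (nrow(sub) < 2)
    stop("need records at >= 2 resolutions for a profile")
  sub <- sub[order(sub$resolution), ]
  out <- data.frame(resolution = sub$resolution, p = sub$p,
                    neglog10_p = -log10(sub$p))
  attr(out, "alpha_adj") <- attr(records, "alpha_adj")
  out
}
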