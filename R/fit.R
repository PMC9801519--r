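#' Fit one model under the g-prior
#'
#' Closed-form conjugate inference for a single subset model on a centered
#' study table.  With the intercept and `log sigma` integrated out under flat
#' priors and a Zellner g-prior on the `k` included slopes, the log marginal
#' likelihood of model `M` is
#'
#' `log p(y | M) = lgamma((n-1)/2) - ((n-1)/2) log(pi) - log(n)/2
#'                 - ((n-1)/2) log(TSS)
#'                 + ((n-1-k)/2) log(1+g) - ((n-1)/2) log(1 + g (1 - R^2))`
#'
#' where `TSS` is the centered total sum of squares and `R^2` the in-model
#' coefficient of determination (`R^2 = 0` for the null model).  Conditional
#' on the model, the slopes have a multivariate-t posterior with `n - 1`
#' degrees of freedom, location `g/(1+g)` times the least-squares estimate and
#' scale matrix `(g/(1+g)) (X'X)^-1 TSS (1 - (g/(1+g)) R^2) / (n-1)`.
#'
#' @param tab a centered [study_table()] (see [center_table()]).
#' @param model integer vector of included covariate indices (empty = null
#'   model), e.g. one element of [enumerate_models()].
#' @param prior a [prior_settings()] object.
#' @return An object of class `gprior_fit`: `model`, `k`, `log_marginal`,
#'   `coef_mean`, `coef_var` (full posterior variance of each included slope),
#'   `coef_tscale` (scale of the posterior t), `t_df`, `r_squared`,
#'   `resid_df = n - 1 - k`, plus `n`, `s`, `g`, `var_names`, `xtx_inv` and
#'   the residual quadratic form `q` used by [simulate.bma_lm()].
#' @export
gprior_fit <- function(tab, model, prior = prior_settings("uip")) {
  stopifnot(inherits(tab, "study_table"))
  if (!isTRUE(tab$centered))
    stop("gprior_fit() needs a centered table; call center_table() first",
         call. = FALSE)
  model <- as.integer(model)
  if (anyDuplicated(model) || any(model < 1L) || any(model > tab$s))
    stop("invalid model indices: ", paste(model, collapse = ","), call. = FALSE)

  n <- tab$n
  y <- tab$outcome
  tss <- sum(y^2)
  k <- length(model)
  g <- resolve_g(prior, n, tab$s)
  delta <- g / (1 + g)

  if (k == 0L) {
    r2 <- 0
    beta_hat <- numeric(0)
    xtx_inv <- matrix(numeric(0), 0L, 0L)
  } else {
    X <- tab$covariates[, model, drop = FALSE]
    qx <- qr(X)
    if (qx$rank < k)
      stop("singular design: collinear columns in model {",
           paste(tab$names[model], collapse = ", "), "}", call. = FALSE)
    beta_hat <- qr.coef(qx, y)
    rss <- sum(qr.resid(qx, y)^2)
    r2 <- 1 - rss / tss
    xtx_inv <- chol2inv(qr.R(qx))
  }

  q <- tss * (1 - delta * r2)   # posterior residual quadratic form
  coef_mean <- delta * beta_hat
  d <- if (k) diag(xtx_inv)[seq_len(k)] else numeric(0)
  coef_var <- delta * d * q / (n - 3)          # t with df n-1: scale * df/(df-2)
  coef_tscale <- sqrt(delta * d * q / (n - 1))

  log_marginal <- lgamma((n - 1) / 2) - ((n - 1) / 2) * log(pi) -
    0.5 * log(n) - ((n - 1) / 2) * log(tss) +
    ((n - 1 - k) / 2) * log1p(g) - ((n - 1) / 2) * log1p(g * (1 - r2))

  structure(
    list(model = model, k = k, log_marginal = log_marginal,
         coef_mean = stats::setNames(as.numeric(coef_mean), tab$names[model]),
         coef_var = stats::setNames(as.numeric(coef_var), tab$names[model]),
         coef_tscale = stats::setNames(as.numeric(coef_tscale), tab$names[model]),
         t_df = n - 1, r_squared = r2, resid_df = n - 1 - k,
         n = n, s = tab$s, g = g, q = q, xtx_inv = xtx_inv,
         var_names = tab$names),
    class = "gprior_fit")
}

#' @export
print.gprior_fit <- function(x, ...) {
  cat("g-prior model fit: {",
      paste(x$var_names[x$model], collapse = ", "), "}",
      sprintf("\n  k = %d, R^2 = %.4f, log marginal = %.4f\n",
              x$k, x$r_squared, x$log_marginal))
  invisible(x)
}

#' Posterior model probabilities
#'
#' Normalizes marginal likelihoods times model-prior weights into posterior
#' model probabilities via Bayes' theorem.  All arithmetic happens in log
#' space with a log-sum-exp reduction, so log-marginal spreads of several
#' hundred units neither overflow nor underflow.
#'
#' @param fits list of [gprior_fit()] objects, or a numeric vector of log
#'   marginal likelihoods.
#' @param log_prior optional vector of log model-prior weights (default
#'   uniform).
#' @return Numeric vector of probabilities summing to 1.
#' @export
posterior_model_probs <- function(fits, log_prior = NULL) {
  lm_vec <- if (is.numeric(fits)) fits
            else vapply(fits, function(f) f$log_marginal, numeric(1))
  if (length(lm_vec) == 0L) stop("no model fits supplied", call. = FALSE)
  if (anyNA(lm_vec)) stop("non-finite log marginal likelihood", call. = FALSE)
  lp <- lm_vec + (log_prior %||% 0)
  p <- exp(lp - log_sum_exp(lp))
  p / sum(p)
}

#' Model-averaged posterior summaries
#'
#' Averages per-model conditional posteriors with posterior-model-probability
#' weights.  For covariate `j`:
#' \itemize{
#'   \item PIP: `pip_j = sum of pmp over models containing j`;
#'   \item posterior mean: pmp-weighted conditional means, with the
#'     coefficient exactly 0 in models excluding `j`;
#'   \item posterior SD: by default the law-of-total-variance form
#'     `sqrt(sum pmp (var + mean^2) - post_mean^2)`, which adds the
#'     between-model dispersion of the conditional means to the averaged
#'     within-model variances; `variance = "within"` gives the
#'     within-model-only average for compatibility with reports that omit the
#'     between-model term;
#'   \item sign consistency ("Sig."): the inclusion-weighted probability,
#'     under each conditional posterior t, that the coefficient has the same
#'     sign as the model-averaged mean; defined as 1 for a never-included
#'     covariate.
#' }
#'
#' @param fits list of [gprior_fit()] objects (one per model).
#' @param pmp posterior model probabilities aligned with `fits`.
#' @param variance `"total"` (law of total variance, default) or `"within"`.
#' @param thresholds evidence-grade cut points passed to
#'   [classify_evidence()].
#' @return An object of class `bma_result` with per-variable `pip`,
#'   `post_mean`, `post_sd`, `sign_consistency`, `evidence_grade`, plus `pmp`,
#'   `models` and `model_size_distribution`.
#' @export
bma_average <- function(fits, pmp, variance = c("total", "within"),
                        thresholds = c(0.5, 0.75, 0.95)) {
  variance <- match.arg(variance)
  if (length(fits) != length(pmp))
    stop("fits and pmp lengths differ", call. = FALSE)
  s <- fits[[1L]]$s
  var_names <- fits[[1L]]$var_names

  pip <- m1 <- m2 <- within_var <- numeric(s)
  for (i in seq_along(fits)) {
    f <- fits[[i]]; w <- pmp[i]
    if (f$k == 0L) next
    j <- f$model
    pip[j] <- pip[j] + w
    m1[j] <- m1[j] + w * f$coef_mean
    m2[j] <- m2[j] + w * (f$coef_var + f$coef_mean^2)
    within_var[j] <- within_var[j] + w * f$coef_var
  }
  post_mean <- m1
  post_var <- if (variance == "total") pmax(m2 - post_mean^2, 0)
              else within_var
  post_sd <- sqrt(post_var)

  # sign consistency needs the averaged mean, hence a second pass
  sgn <- sign(post_mean)
  agree <- numeric(s)
  for (i in seq_along(fits)) {
    f <- fits[[i]]; w <- pmp[i]
    if (f$k == 0L || w == 0) next
    j <- f$model
    pj <- stats::pt(sgn[j] * f$coef_mean / f$coef_tscale, df = f$t_df)
    pj[sgn[j] == 0] <- 1
    agree[j] <- agree[j] + w * pj
  }
  sign_consistency <- ifelse(pip > 0, agree / pip, 1)

  models <- lapply(fits, function(f) f$model)
  attr(models, "s") <- s
  structure(
    list(pip = stats::setNames(pip, var_names),
         post_mean = stats::setNames(post_mean, var_names),
         post_sd = stats::setNames(post_sd, var_names),
         sign_consistency = stats::setNames(sign_consistency, var_names),
         evidence_grade = stats::setNames(
           classify_evidence(pip, thresholds), var_names),
         pmp = pmp, models = models, variance = variance,
         model_size_distribution = model_size_distribution(pmp, models)),
    class = "bma_result")
}

#' Posterior distribution of model size
#'
#' Aggregates posterior model probabilities by the number of included
#' covariates, the quantity plotted as a posterior model-size distribution.
#'
#' @param pmp posterior model probabilities.
#' @param models aligned list of integer index vectors with attribute `s`.
#' @return Named numeric vector over sizes `0..s`, summing to 1.
#' @export
model_size_distribution <- function(pmp, models) {
  if (length(pmp) != length(models))
    stop("pmp and models lengths differ", call. = FALSE)
  s <- attr(models, "s") %||% max(c(0L, lengths(models)))
  sizes <- lengths(models)
  out <- vapply(0:s, function(k) sum(pmp[sizes == k]), numeric(1))
  stats::setNames(out, as.character(0:s))
}
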