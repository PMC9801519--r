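#' Bayesian model averaging for a Gaussian linear model
#'
#' Fits all `2^s` subset regressions of the response on `s` candidate
#' covariates (intercept always included) under a Zellner g-prior, weights
#' each model by its posterior model probability, and averages.  This is the
#' model-uncertainty-aware alternative to selecting a single regression:
#' every per-variable conclusion (inclusion probability, coefficient mean and
#' SD, sign consistency, evidence grade) accounts for the full model space.
#'
#' @param formula model formula, e.g. `acuity ~ exercise + diet + bullying`.
#'   All terms must be numeric columns of `data`; the intercept is always
#'   included and never counted in model size.
#' @param data data frame (or [study_table()]; then `formula` is ignored).
#' @param g_rule,g coefficient-prior scale rule, see [prior_settings()].
#' @param variance posterior-SD form, see [bma_average()].
#' @param thresholds evidence-grade cut points, see [classify_evidence()].
#' @param mc3 logical; also run the MC3 sampler as a stochastic cross-check.
#' @param mc3_control a [mc3_settings()] object used when `mc3 = TRUE`.
#' @param stage_label free-text label carried into reports.
#' @param cap enumeration cap on `s` (see [enumerate_models()]).
#' @return An object of class `bma_lm`; see Details.  Methods:
#'   [print.bma_lm()], [summary.bma_lm()], [coef.bma_lm()],
#'   [predict.bma_lm()], [residuals.bma_lm()], [plot.bma_lm()],
#'   [simulate.bma_lm()].
#' @details The returned object contains the [bma_average()] summaries
#'   (`pip`, `post_mean`, `post_sd`, `sign_consistency`, `evidence_grade`,
#'   `pmp`, `model_size_distribution`), the enumerated `models` and their
#'   `fits`, the resolved `g`, the centering report, fitted values and
#'   residuals on the raw scale, and (when requested) the MC3 `trace` with
#'   its convergence diagnostics.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(100), x2 = rnorm(100), x3 = rnorm(100))
#' d$y <- 4.6 + 0.5 * d$x1 + rnorm(100, sd = 0.6)
#' fit <- bma_lm(y ~ x1 + x2 + x3, d)
#' summary(fit)
#' @export
bma_lm <- function(formula, data, g_rule = "uip", g = NULL,
                   variance = c("total", "within"),
                   thresholds = c(0.5, 0.75, 0.95),
                   mc3 = FALSE, mc3_control = mc3_settings(),
                   stage_label = "", cap = 25L) {
  variance <- match.arg(variance)
  if (inherits(data, "study_table")) {
    tab <- data
    cl <- match.call()
  } else {
    cl <- match.call()
    tt <- stats::terms(formula, data = data)
    if (attr(tt, "response") != 1L)
      stop("formula needs a response", call. = FALSE)
    outcome <- deparse(attr(tt, "variables")[[2L]])
    covars <- attr(tt, "term.labels")
    tab <- study_table(data, outcome = outcome, covariates = covars,
                       stage_label = stage_label)
  }
  prior <- prior_settings(g_rule, g)
  core <- bma_core(tab, prior = prior, variance = variance,
                   thresholds = thresholds, cap = cap)
  obj <- c(core, list(call = cl))
  class(obj) <- "bma_lm"

  if (isTRUE(mc3)) {
    obj$trace <- mc3_run(core$table, prior = prior, settings = mc3_control)
    obj$convergence <- convergence_report(obj$trace, exact = core$pmp)
  }
  obj
}

# shared engine behind bma_lm() and run_stage(): centered fit on a study_table
bma_core <- function(tab, prior, variance = "total",
                     thresholds = c(0.5, 0.75, 0.95), cap = 25L) {
  if (!isTRUE(tab$centered)) {
    raw_y <- tab$outcome
    tab <- center_table(tab)
  } else {
    raw_y <- tab$outcome + tab$centering$outcome_mean
  }
  models <- enumerate_models(tab$s, cap = cap)
  fits <- lapply(models, function(m) gprior_fit(tab, m, prior))
  pmp <- posterior_model_probs(fits)
  res <- bma_average(fits, pmp, variance = variance, thresholds = thresholds)

  ybar <- tab$centering$outcome_mean
  xbar <- tab$centering$covariate_means
  fitted <- ybar + as.numeric(tab$covariates %*% res$post_mean)
  list(pip = res$pip, post_mean = res$post_mean, post_sd = res$post_sd,
       sign_consistency = res$sign_consistency,
       evidence_grade = res$evidence_grade,
       pmp = pmp, models = models, fits = fits,
       model_size_distribution = res$model_size_distribution,
       variance = res$variance, thresholds = thresholds,
       g = fits[[1L]]$g, prior = prior,
       n = tab$n, s = tab$s, dropped = tab$dropped,
       var_names = tab$names, stage_label = tab$stage_label,
       centering = tab$centering, table = tab,
       fitted_values = fitted,
       residuals = raw_y - fitted)
}

#' @export
print.bma_lm <- function(x, ...) {
  cat("Bayesian model averaging (g-prior linear regression)\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d, s = %d candidate covariates, %d models, g = %.6g\n",
              x$n, x$s, length(x$models), x$g))
  top <- order(x$pip, decreasing = TRUE)[1L]
  cat(sprintf("Top variable: %s (PIP %.4f, %s evidence)\n",
              x$var_names[top], x$pip[top],
              as.character(x$evidence_grade[top])))
  invisible(x)
}

#' Summarize a BMA fit
#'
#' @param object a [bma_lm()] fit.
#' @param top_m number of top models to tabulate.
#' @param ... unused.
#' @return A `summary.bma_lm` object holding the per-variable table (sorted by
#'   PIP, descending), the top-model table and the model-size distribution.
#' @export
summary.bma_lm <- function(object, top_m = 3L, ...) {
  vt <- variable_table(object)
  structure(list(variable_table = vt,
                 top_models = top_models_table(object, top_m = top_m),
                 size_distribution = object$model_size_distribution,
                 n = object$n, s = object$s, g = object$g,
                 dropped = object$dropped,
                 stage_label = object$stage_label),
            class = "summary.bma_lm")
}

#' @export
print.summary.bma_lm <- function(x, digits = 4, ...) {
  cat("BMA estimation results",
      if (nzchar(x$stage_label)) paste0("[", x$stage_label, "]"), "\n")
  cat(sprintf("n = %d (%d incomplete rows dropped), s = %d, g = %.6g\n\n",
              x$n, x$dropped, x$s, x$g))
  vt <- x$variable_table
  vt[2:5] <- lapply(vt[2:5], signif, digits = digits)
  print(vt, row.names = FALSE)
  cat("\nTop models by posterior probability:\n")
  tm <- x$top_models
  tm$pmp_exact <- signif(tm$pmp_exact, digits)
  print(tm, row.names = FALSE)
  cat("\nPosterior model-size distribution:\n")
  print(signif(x$size_distribution, digits))
  invisible(x)
}

# per-variable report table (the printed-table analog), PIP descending
variable_table <- function(object) {
  df <- data.frame(variable = object$var_names,
                   pip = as.numeric(object$pip),
                   post_mean = as.numeric(object$post_mean),
                   post_sd = as.numeric(object$post_sd),
                   sign_consistency = as.numeric(object$sign_consistency),
                   evidence = as.character(object$evidence_grade),
                   stringsAsFactors = FALSE)
  df[order(-df$pip, df$variable), , drop = FALSE]
}

# top-m models as inclusion indicators + exact (and optional MCMC) PMP
top_models_table <- function(object, top_m = 3L, pmp_mcmc = NULL) {
  ord <- order(object$pmp, decreasing = TRUE)
  m <- min(top_m, length(ord))
  idx <- ord[seq_len(m)]
  inc <- inclusion_matrix(object$models, object$s)[idx, , drop = FALSE]
  df <- data.frame(model_rank = seq_len(m), inc,
                   size = lengths(object$models)[idx],
                   pmp_exact = object$pmp[idx])
  names(df)[2:(1 + object$s)] <- object$var_names
  if (!is.null(pmp_mcmc)) df$pmp_mcmc <- pmp_mcmc[idx]
  df
}

#' @export
coef.bma_lm <- function(object, intercept = TRUE, ...) {
  b <- object$post_mean
  if (!intercept) return(b)
  a <- object$centering$outcome_mean -
    sum(b * object$centering$covariate_means)
  c("(Intercept)" = unname(a), b)
}

#' Model-averaged predictions
#'
#' @param object a [bma_lm()] fit.
#' @param newdata data frame with the covariate columns; default the training
#'   data.
#' @param ... unused.
#' @return Numeric vector of posterior-mean predictions on the raw outcome
#'   scale.
#' @export
predict.bma_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  miss <- setdiff(object$var_names, names(newdata))
  if (length(miss))
    stop("newdata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[, object$var_names, drop = FALSE])
  Xc <- sweep(X, 2L, object$centering$covariate_means, "-")
  object$centering$outcome_mean + as.numeric(Xc %*% object$post_mean)
}

#' @export
fitted.bma_lm <- function(object, ...) object$fitted_values

#' @export
residuals.bma_lm <- function(object, ...) object$residuals

#' Plot BMA diagnostics
#'
#' `which = "size"` draws the posterior model-size distribution (the
#' barplot analog of a posterior model-size figure); `which = "inclusion"`
#' draws the signed inclusion map with models ordered by posterior
#' probability — blue marks a positively signed included coefficient, orange
#' a negatively signed one.
#'
#' @param x a [bma_lm()] fit.
#' @param which `"size"`, `"inclusion"` or both.
#' @param ... passed to the underlying graphics calls.
#' @return `x`, invisibly.
#' @export
plot.bma_lm <- function(x, which = c("size", "inclusion"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if ("size" %in% which) {
    graphics::barplot(x$model_size_distribution,
                      xlab = "model size (number of covariates)",
                      ylab = "posterior probability",
                      main = "Posterior model-size distribution", ...)
  }
  if ("inclusion" %in% which) {
    im <- signed_inclusion_map(x)
    cols <- c("orange", "white", "steelblue")
    graphics::image(seq_len(nrow(im)), seq_len(ncol(im)), im,
                    col = cols, zlim = c(-1, 1),
                    xlab = "models (by posterior probability)",
                    ylab = "", axes = FALSE,
                    main = "Signed variable inclusion", ...)
    graphics::axis(2, at = seq_len(ncol(im)), labels = colnames(im),
                   las = 2, cex.axis = 0.8)
    graphics::box()
  }
  invisible(x)
}

# models x variables matrix: +1 / -1 for included coefficients by conditional
# sign, 0 when excluded; rows ordered by decreasing PMP
signed_inclusion_map <- function(object) {
  ord <- order(object$pmp, decreasing = TRUE)
  out <- matrix(0L, nrow = length(ord), ncol = object$s,
                dimnames = list(NULL, object$var_names))
  for (r in seq_along(ord)) {
    f <- object$fits[[ord[r]]]
    if (f$k) out[r, f$model] <- ifelse(f$coef_mean >= 0, 1L, -1L)
  }
  attr(out, "pmp") <- object$pmp[ord]
  out
}

#' Simulate from the posterior predictive
#'
#' Draws outcome vectors at the training covariates by sampling a model from
#' the posterior model probabilities, then `sigma^2` and slopes from that
#' model's conditional posterior, then Gaussian noise.
#'
#' @param object a [bma_lm()] fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @param ... unused.
#' @return A data frame with `nsim` columns of length `n`.
#' @export
simulate.bma_lm <- function(object, nsim = 1, seed = NULL, ...) {
  draw_all <- function() {
    out <- matrix(NA_real_, nrow = object$n, ncol = nsim)
    Xc <- object$table$covariates
    ybar <- object$centering$outcome_mean
    for (i in seq_len(nsim)) {
      f <- object$fits[[sample.int(length(object$pmp), 1L, prob = object$pmp)]]
      sigma2 <- f$q / stats::rchisq(1L, df = f$t_df)
      eta <- ybar
      if (f$k) {
        delta <- f$g / (1 + f$g)
        ch <- chol(delta * sigma2 * f$xtx_inv)
        beta <- as.numeric(f$coef_mean + drop(crossprod(ch, stats::rnorm(f$k))))
        eta <- eta + as.numeric(Xc[, f$model, drop = FALSE] %*% beta)
      }
      out[, i] <- eta + stats::rnorm(object$n, sd = sqrt(sigma2))
    }
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  }
  if (is.null(seed)) draw_all() else with_seed(seed, draw_all())
}
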