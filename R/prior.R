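#' Prior settings for g-prior model averaging
#'
#' The coefficient prior is a Zellner g-prior on the slopes included in each
#' model, `beta | sigma^2, M ~ N(0, g sigma^2 (X'X)^-1)`, with flat priors on
#' the intercept and on `log sigma`.  `g` controls shrinkage: the conditional
#' posterior mean is `g/(1+g)` times the least-squares estimate.  The model
#' prior is uniform over the enumerated space.
#'
#' Rules for choosing `g`:
#' \describe{
#'   \item{`"uip"`}{unit-information prior, `g = n` (default).}
#'   \item{`"bric"`}{benchmark rule `g = max(n, s^2)`.}
#'   \item{`"fixed"`}{a user-supplied positive constant, via `g`.}
#' }
#'
#' @param g_rule one of `"uip"`, `"bric"`, `"fixed"`.
#' @param g positive scalar, required when `g_rule = "fixed"`.
#' @return An object of class `prior_settings`.
#' @export
prior_settings <- function(g_rule = c("uip", "bric", "fixed"), g = NULL) {
  g_rule <- match.arg(g_rule)
  if (g_rule == "fixed") {
    if (is.null(g) || !is.numeric(g) || length(g) != 1L || g <= 0)
      stop("g_rule = 'fixed' requires a single positive g", call. = FALSE)
  } else if (!is.null(g)) {
    stop("g is only used with g_rule = 'fixed'", call. = FALSE)
  }
  structure(list(g_rule = g_rule, g = g, model_prior = "uniform"),
            class = "prior_settings")
}

resolve_g <- function(prior, n, s) {
  stopifnot(inherits(prior, "prior_settings"))
  g <- switch(prior$g_rule,
              uip = n,
              bric = max(n, s^2),
              fixed = prior$g)
  if (!is.finite(g) || g <= 0) stop("resolved g must be positive", call. = FALSE)
  g
}

#' @export
print.prior_settings <- function(x, ...) {
  cat("g-prior settings: rule =", x$g_rule,
      if (x$g_rule == "fixed") paste0("(g = ", x$g, ")"),
      "| model prior:", x$model_prior, "\n")
  invisible(x)
}
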