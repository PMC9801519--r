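#' Grade evidence from a posterior inclusion probability
#'
#' Raftery-style grading of the posterior probability that a covariate
#' belongs in the model.  Bands are left-closed:
#' `[0, 0.5)` none, `[0.5, 0.75)` weak, `[0.75, 0.95)` positive,
#' `[0.95, 1]` strong.
#'
#' @param pip numeric vector of posterior inclusion probabilities in `[0, 1]`.
#' @param thresholds strictly increasing cut points in `(0, 1)`; default
#'   `c(0.5, 0.75, 0.95)`.
#' @return Factor with levels `none`, `weak`, `positive`, `strong`.
#' @examples
#' classify_evidence(c(0.0431, 0.5, 0.9736))
#' @export
classify_evidence <- function(pip, thresholds = c(0.5, 0.75, 0.95)) {
  if (!is.numeric(pip) || anyNA(pip) || any(pip < 0 | pip > 1))
    stop("pip must lie in [0, 1]", call. = FALSE)
  if (length(thresholds) != 3L || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be three strictly increasing values in (0, 1)",
         call. = FALSE)
  cut(pip, breaks = c(-Inf, thresholds, Inf), right = FALSE,
      labels = c("none", "weak", "positive", "strong"))
}
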