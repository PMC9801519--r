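#' Enumerate the model space
#'
#' With `s` candidate covariates and an always-included intercept there are
#' `2^s` linear models, one per subset of covariates.  The enumeration is
#' deterministic: models are ordered by size and, within a size, in
#' lexicographic order of their (1-based) covariate indices, so the first
#' element is always the null (intercept-only) model and the last the full
#' model.
#'
#' @param s number of candidate covariates.
#' @param cap hard enumeration cap; beyond it only the MC3 sampler is
#'   practical.
#' @return A list of `2^s` integer vectors (possibly empty = null model) with
#'   attribute `s`.
#' @examples
#' length(enumerate_models(5)) # 32
#' @export
enumerate_models <- function(s, cap = 25L) {
  if (!is.numeric(s) || length(s) != 1L || s != round(s))
    stop("s must be a single integer", call. = FALSE)
  s <- as.integer(s)
  if (s < 1L || s > cap)
    stop("s must be in [1, ", cap, "], got ", s, call. = FALSE)
  models <- vector("list", 2L^s)
  models[[1L]] <- integer(0)
  pos <- 2L
  for (k in seq_len(s)) {
    cmb <- utils::combn(s, k)
    for (j in seq_len(ncol(cmb))) {
      models[[pos]] <- as.integer(cmb[, j])
      pos <- pos + 1L
    }
  }
  attr(models, "s") <- s
  models
}

#' Inclusion-indicator matrix for a model list
#'
#' @param models list of integer index vectors, as from [enumerate_models()].
#' @param s number of candidate covariates.
#' @return A `length(models) x s` 0/1 integer matrix.
#' @export
inclusion_matrix <- function(models, s = attr(models, "s")) {
  stopifnot(!is.null(s))
  out <- matrix(0L, nrow = length(models), ncol = s)
  for (i in seq_along(models)) out[i, models[[i]]] <- 1L
  out
}
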