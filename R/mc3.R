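#' MC3 sampler settings
#'
#' @param n_iter total Metropolis iterations.
#' @param burn_in iterations discarded before counting visits
#'   (`burn_in < n_iter`).
#' @param seed integer RNG seed; the chain is deterministic given the seed.
#' @return An object of class `mc3_settings`.
#' @export
mc3_settings <- function(n_iter = 100000L, burn_in = 10000L, seed = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter <= 0L || burn_in < 0L || burn_in >= n_iter)
    stop("need 0 <= burn_in < n_iter", call. = FALSE)
  structure(list(n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed)),
            class = "mc3_settings")
}

#' Metropolis-Hastings chain over the model hypercube
#'
#' The generic engine behind [mc3_run()]: a random walk on inclusion
#' patterns.  Each iteration proposes flipping one uniformly chosen inclusion
#' bit and accepts with probability `min(1, ML(M') / ML(M))` (uniform model
#' prior; the symmetric proposal cancels), computed in log space.  Because
#' only log-marginal differences enter the ratio, adding any constant to all
#' log marginals leaves the chain unchanged.
#'
#' @param log_marginal_fun function taking an integer index vector (a model)
#'   and returning its log marginal likelihood.
#' @param s number of candidate covariates.
#' @param settings a [mc3_settings()] object.
#' @param init integer vector, initial model (default null model).
#' @return An object of class `mc3_trace`: `visit_counts` (named by
#'   inclusion-bit pattern), `states` (post-burn-in pattern per iteration),
#'   `acceptance_rate`, `n_kept`, `s`, `settings`.
#' @export
mc3_chain <- function(log_marginal_fun, s, settings = mc3_settings(),
                      init = integer(0)) {
  stopifnot(is.function(log_marginal_fun), inherits(settings, "mc3_settings"))
  s <- as.integer(s)
  run <- function() {
    n_iter <- settings$n_iter; burn_in <- settings$burn_in
    flips <- sample.int(s, n_iter, replace = TRUE)
    logu <- log(stats::runif(n_iter))
    memo <- new.env(parent = emptyenv())
    lml <- function(bits) {
      key <- paste(as.integer(bits), collapse = "")
      val <- memo[[key]]
      if (is.null(val)) {
        val <- log_marginal_fun(which(bits))
        memo[[key]] <- val
      }
      val
    }
    bits <- rep(FALSE, s); bits[init] <- TRUE
    cur <- lml(bits)
    kept <- character(n_iter - burn_in)
    accepted <- 0L
    for (i in seq_len(n_iter)) {
      j <- flips[i]
      bits[j] <- !bits[j]
      cand <- lml(bits)
      if (logu[i] < cand - cur) {
        cur <- cand
        accepted <- accepted + 1L
      } else {
        bits[j] <- !bits[j]     # reject: undo the flip
      }
      if (i > burn_in)
        kept[i - burn_in] <- paste(as.integer(bits), collapse = "")
    }
    counts <- table(kept)
    structure(
      list(visit_counts = stats::setNames(as.integer(counts), names(counts)),
           states = kept,
           acceptance_rate = accepted / n_iter,
           n_kept = n_iter - burn_in, s = s, settings = settings),
      class = "mc3_trace")
  }
  with_seed(settings$seed, run())
}

#' Run MC3 model composition on a study table
#'
#' Estimates posterior model probabilities by the normalized visit
#' frequencies of a Metropolis chain over inclusion patterns, with marginal
#' likelihoods delegated to [gprior_fit()] and memoized per pattern.  Used as
#' a stochastic cross-check of exact enumeration (the two PMP columns of a
#' per-model report should agree), and as the only feasible route when `s`
#' exceeds the enumeration cap.
#'
#' @param tab a [study_table()] (centered or not).
#' @param prior a [prior_settings()] object.
#' @param settings a [mc3_settings()] object.
#' @return The [mc3_chain()] trace with an extra element `pmp_mcmc`: when
#'   `s <= 25` a full vector aligned with [enumerate_models()] order (zeros
#'   for unvisited models), otherwise the named visit frequencies.
#' @export
mc3_run <- function(tab, prior = prior_settings("uip"),
                    settings = mc3_settings()) {
  stopifnot(inherits(tab, "study_table"))
  if (!isTRUE(tab$centered)) tab <- center_table(tab)
  trace <- mc3_chain(function(m) gprior_fit(tab, m, prior)$log_marginal,
                     s = tab$s, settings = settings)
  freq <- trace$visit_counts / trace$n_kept
  if (tab$s <= 25L && 2^tab$s <= 1e6) {
    models <- enumerate_models(tab$s)
    keys <- vapply(models, model_key, character(1), s = tab$s)
    pmp <- stats::setNames(numeric(length(keys)), keys)
    pmp[names(freq)] <- freq
    trace$pmp_mcmc <- pmp
  } else {
    trace$pmp_mcmc <- freq
  }
  trace
}

#' @export
print.mc3_trace <- function(x, ...) {
  cat(sprintf(paste0("MC3 trace: s = %d, %d kept iterations, ",
                     "%d models visited, acceptance %.3f\n"),
              x$s, x$n_kept, length(x$visit_counts), x$acceptance_rate))
  invisible(x)
}

#' Sampler convergence diagnostics
#'
#' With the exact PMP vector available, reports the total-variation distance
#' `TV = 0.5 * sum |pmp_mcmc - pmp_exact|` and the Pearson correlation of the
#' two estimates over visited models; without it, the correlation of visit
#' frequencies between the two halves of the kept chain.
#'
#' @param trace an [mc3_run()] trace.
#' @param exact optional exact PMP vector aligned with [enumerate_models()]
#'   order.
#' @return A list of class `mc3_convergence` with `tv_distance`,
#'   `correlation`, `split_half_correlation`, `n_visited`.
#' @export
convergence_report <- function(trace, exact = NULL) {
  stopifnot(inherits(trace, "mc3_trace"))
  out <- list(n_visited = length(trace$visit_counts),
              acceptance_rate = trace$acceptance_rate,
              tv_distance = NA_real_, correlation = NA_real_,
              split_half_correlation = NA_real_)
  if (!is.null(exact)) {
    est <- trace$pmp_mcmc
    if (length(est) != length(exact))
      stop("exact pmp length does not match the trace's model space",
           call. = FALSE)
    out$tv_distance <- 0.5 * sum(abs(est - exact))
    visited <- est > 0
    out$correlation <- if (sum(visited) > 1L)
      stats::cor(est[visited], exact[visited]) else NA_real_
  }
  if (!is.null(trace$states)) {
    half <- trace$n_kept %/% 2L
    keys <- unique(trace$states)
    f1 <- table(factor(trace$states[seq_len(half)], levels = keys))
    f2 <- table(factor(trace$states[(half + 1L):trace$n_kept], levels = keys))
    out$split_half_correlation <- if (length(keys) > 1L)
      stats::cor(as.numeric(f1), as.numeric(f2)) else NA_real_
  }
  class(out) <- "mc3_convergence"
  out
}

#' @export
print.mc3_convergence <- function(x, ...) {
  cat(sprintf(paste0("MC3 convergence: %d models visited, acceptance %.3f\n",
                     "  TV distance vs exact: %s\n",
                     "  correlation vs exact: %s\n",
                     "  split-half correlation: %s\n"),
              x$n_visited, x$acceptance_rate,
              format(x$tv_distance), format(x$correlation),
              format(x$split_half_correlation)))
  invisible(x)
}

#' Dump a trace's visit counts as CSV
#'
#' @param trace an [mc3_run()] trace.
#' @param path output CSV path (columns: inclusion bit pattern, count).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "mc3_trace"))
  df <- data.frame(pattern = names(trace$visit_counts),
                   count = as.integer(trace$visit_counts),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pattern), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
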