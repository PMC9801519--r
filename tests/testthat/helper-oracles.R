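# Fixture builders and independent oracles used across the suite.

# random regression table with known coefficients
make_table <- function(n, s, seed = 1, beta = rep(0, s), noise = 1,
                       intercept = 4.6) {
  set.seed(seed)
  X <- matrix(rnorm(n * s), n, s, dimnames = list(NULL, paste0("x", 1:s)))
  data.frame(y = intercept + as.numeric(X %*% beta) + rnorm(n, 0, noise), X)
}

bma_fit_tab <- function(tab, ...) bma_lm(data = tab, ...)

# Independent brute-force BMA: its own enumeration (expand.grid), its own OLS
# (lm), plain normalization and explicit averaging loops.  Shares only the
# closed-form marginal expression, which the quadrature oracle checks
# separately.
brute_force_bma <- function(df, outcome, g) {
  y <- df[[outcome]]
  xn <- setdiff(names(df), outcome)
  s <- length(xn); n <- length(y)
  yc <- y - mean(y)
  Xc <- scale(as.matrix(df[xn]), center = TRUE, scale = FALSE)
  tss <- sum(yc^2)
  delta <- g / (1 + g)
  grid <- as.matrix(expand.grid(rep(list(0:1), s)))
  logml <- numeric(nrow(grid))
  means <- vars <- matrix(0, nrow(grid), s)
  for (r in seq_len(nrow(grid))) {
    inc <- which(grid[r, ] == 1)
    k <- length(inc)
    if (k == 0) {
      r2 <- 0
    } else {
      Xs <- Xc[, inc, drop = FALSE]
      f <- lm(yc ~ 0 + Xs)
      r2 <- 1 - sum(resid(f)^2) / tss
      q <- tss * (1 - delta * r2)
      means[r, inc] <- delta * coef(f)
      vars[r, inc] <- delta * diag(solve(crossprod(Xs))) * q / (n - 3)
    }
    logml[r] <- ((n - 1 - k) / 2) * log(1 + g) -
      ((n - 1) / 2) * log(1 + g * (1 - r2))
  }
  w <- exp(logml - max(logml))
  w <- w / sum(w)
  pip <- colSums(w * grid)
  post_mean <- colSums(w * means)
  m2 <- colSums(w * (vars + means^2))
  list(pip = setNames(pip, xn),
       post_mean = setNames(post_mean, xn),
       post_sd = setNames(sqrt(pmax(m2 - post_mean^2, 0)), xn))
}

# Quadrature oracle for the marginal likelihood of a single-covariate model:
# the flat-prior intercept is integrated analytically, then likelihood x
# g-prior is integrated numerically over (beta, sigma^2).
quad_log_marginal_1cov <- function(y, x, g) {
  n <- length(y)
  yc <- y - mean(y)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  outer_f <- function(t) {         # t = log sigma^2; jacobian cancels 1/sigma^2
    vapply(t, function(tt) {
      s2 <- exp(tt)
      f <- function(beta) {
        ss <- vapply(beta, function(b) sum((yc - b * xc)^2), numeric(1))
        (2 * pi * s2)^(-(n - 1) / 2) * n^(-1 / 2) * exp(-ss / (2 * s2)) *
          dnorm(beta, 0, sqrt(g * s2 / sxx))
      }
      integrate(f, -Inf, Inf, rel.tol = 1e-11)$value
    }, numeric(1))
  }
  mid <- log(var(yc))
  log(integrate(outer_f, mid - 15, mid + 15, rel.tol = 1e-11)$value)
}

quad_log_marginal_null <- function(y) {
  n <- length(y)
  yc <- y - mean(y)
  tss <- sum(yc^2)
  f <- function(t) {
    s2 <- exp(t)
    (2 * pi * s2)^(-(n - 1) / 2) * n^(-1 / 2) * exp(-tss / (2 * s2))
  }
  mid <- log(tss / n)
  log(integrate(f, mid - 15, mid + 15, rel.tol = 1e-12)$value)
}
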