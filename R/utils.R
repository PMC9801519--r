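# numerically stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# canonical string key for an inclusion pattern, e.g. "01001"
model_key <- function(model, s) {
  bits <- integer(s)
  bits[model] <- 1L
  paste(bits, collapse = "")
}

key_to_model <- function(key) which(strsplit(key, "")[[1]] == "1")

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
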