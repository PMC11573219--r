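# internal helpers shared across modules

# log(mean(exp(x))) without overflow; x may contain -Inf
log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# log density of the Laplace distribution (location mu, scale b > 0)
dlaplace_log <- function(x, mu = 0, b = 1) {
  stopifnot(b > 0)
  -log(2 * b) - abs(x - mu) / b
}

# Spawn `n` reproducible child seeds from one master seed. Kept below 2^31
# so they are valid R integer seeds.
spawn_seeds <- function(seed, n) {
  withr_seed <- function() {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  }
  withr_seed()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_betsig <- function(msg, class) {
  rlang::abort(msg, class = c(class, "betsig_error"))
}
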