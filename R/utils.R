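`%||%` <- function(a, b) if (is.null(a)) b else a

# lognormal draws parameterized by mean and coefficient of variation
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

schema_error <- function(msg) {
  stop(structure(class = c("hepflux_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
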