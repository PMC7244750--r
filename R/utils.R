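# internal helpers shared across modules

# 0-based midpoint of 0-based half-open intervals stored as GRanges
# (GRanges itself is 1-based closed; converters in io.R keep the contract)
.midpoint <- function(gr) {
  floor((start(gr) - 1 + end(gr)) / 2)
}

# deterministic per-stage seed derived from the master seed and a stream
# name; keeps all derived seeds in the 32-bit integer range
.substreamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# NB draw with Var = mu + alpha mu^2; alpha -> 0 degenerates to Poisson
.rnb <- function(n, mu, alpha) {
  as.integer(if (alpha < 1e-12) stats::rpois(n, lambda = mu)
             else stats::rnbinom(n, mu = mu, size = 1 / alpha))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
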