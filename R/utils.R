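expit <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

## probability positivity guard; returns clipped values and records how many
## entries were moved (calibration needs weights bounded away from 0/Inf)
clip_prob <- function(p, eps = 1e-8) {
  lo <- sum(p < eps)
  hi <- sum(p > 1 - eps)
  structure(pmin(pmax(p, eps), 1 - eps), clipped = lo + hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## polynomial rolling hash over a deparsed object, for run-log fingerprints
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
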