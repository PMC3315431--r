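#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rnbinom predict plogis sd dnorm binomial
#' @importFrom utils head tail write.table read.delim
NULL

# Stop with a "validation error" class so callers/tests can distinguish
# contract violations from ordinary R errors.
stop_validation <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("littriage_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder apportionment of `n` items into parts with target
# `fractions` (ties go to earlier parts). Returns integer counts summing to n.
apportion <- function(n, fractions) {
  target <- n * fractions
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
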