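stopf <- function(fmt, ..., class = "ftirlcm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

validation_error <- function(fmt, ...) stopf(fmt, ..., class = "ftirlcm_validation_error")
format_error     <- function(fmt, ...) stopf(fmt, ..., class = "ftirlcm_format_error")
structural_error <- function(fmt, ...) stopf(fmt, ..., class = "ftirlcm_structural_error")
range_error      <- function(fmt, ...) stopf(fmt, ..., class = "ftirlcm_range_error")
conditioning_error <- function(fmt, ...) stopf(fmt, ..., class = "ftirlcm_conditioning_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific random seed from a master seed
#'
#' Deterministically maps a master seed and a stream label to a 31-bit
#' integer seed, so that independent pipeline stages draw from decoupled
#' streams while the whole run stays reproducible from one number.
#'
#' @param seed master integer seed.
#' @param stream character label of the consuming stage.
#' @return a single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
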