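#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

# derivative of inv_logit, used for average marginal effects on the
# beta-value scale
dinv_logit <- function(x) {
  p <- inv_logit(x)
  p * (1 - p)
}

#' Derive a reproducible sub-seed for a named simulation stage
#'
#' A single user-facing integer seed drives every stochastic stage; each
#' stage draws from its own substream so that adding a stage never perturbs
#' the others. Kept strictly below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @keywords internal
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
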