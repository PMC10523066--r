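## Internal numeric helpers shared across modules.

## Linear predictors are clamped before the inverse-logit so boundary
## estimates (probabilities numerically at 0 or 1) never produce log(0)
## in the likelihood. plogis(15) differs from 1 by ~3e-7.
ETA_CLAMP <- 15

clamp_eta <- function(eta) pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard score with n-1 denominator; degenerate cells (sd = 0 or n = 1)
## map to 0 so the covariate stays defined everywhere.
zscore <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
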