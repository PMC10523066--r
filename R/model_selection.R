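## AICc multimodel inference: the canonical candidate set, ranking, Akaike
## weights, and weight-based averaging of extinction-selectivity
## coefficients.

## The canonical survival family: 11 structures crossing body size (BS),
## geographic range (GR) and their mass-extinction interactions.
phi_family_terms <- function() {
  list(
    c("time"),
    c("time", "size"),
    c("time", "range"),
    c("time", "size", "range"),
    c("time", "size", "range", "size:range"),
    c("time", "size", "size:me"),
    c("time", "range", "range:me"),
    c("time", "size", "size:me", "range"),
    c("time", "size", "range", "range:me"),
    c("time", "size", "size:me", "range", "range:me"),
    c("time", "size", "range", "size:range", "size:me", "range:me", "size:range:me")
  )
}

gamma_family_terms <- function() {
  lapply(phi_family_terms(), function(tt) sub(":me$", ":rec", tt))
}

#' Enumerate the canonical candidate model set
#'
#' The full crossing of the 11 canonical survival structures (time plus body
#' size, geographic range and mass-extinction interactions) with the 11
#' matching seniority structures (recovery replacing mass extinction) and a
#' single detection structure (`~time + BS`): 121 models, each with a stable
#' identifier.
#'
#' @param gamma_dot Also include an intercept-only (`~1`) seniority variant
#'   for each survival structure (11 extra models; off by default, which
#'   keeps the canonical 121).
#' @return List of `model_spec` objects.
#' @examples
#' length(enumerate_model_set())  # 121
#' @export
enumerate_model_set <- function(gamma_dot = FALSE) {
  phis <- phi_family_terms()
  gams <- gamma_family_terms()
  p_struct <- parameter_structure("p", c("time", "size"))
  specs <- list()
  for (i in seq_along(phis)) {
    for (j in seq_along(gams)) {
      specs[[length(specs) + 1L]] <- model_spec(
        parameter_structure("phi", phis[[i]]),
        parameter_structure("gamma", gams[[j]]),
        p_struct,
        id = sprintf("phi%02d.gam%02d", i, j))
    }
    if (gamma_dot) {
      specs[[length(specs) + 1L]] <- model_spec(
        parameter_structure("phi", phis[[i]]),
        parameter_structure("gamma", character(0)),
        p_struct,
        id = sprintf("phi%02d.gamDot", i))
    }
  }
  specs
}

#' Reduced survival-side model set
#'
#' An 8-model subset used for desk-scale regime-recovery experiments: the
#' additive survival structures and their mass-extinction interaction
#' counterparts (no size-by-range products), all with time-only seniority
#' and `~time + BS` detection.
#'
#' @return List of 8 `model_spec` objects.
#' @export
reduced_model_set <- function() {
  phis <- list(
    c("time"),
    c("time", "size"),
    c("time", "range"),
    c("time", "size", "range"),
    c("time", "size", "size:me"),
    c("time", "range", "range:me"),
    c("time", "size", "range", "range:me"),
    c("time", "size", "size:me", "range", "range:me")
  )
  gam <- parameter_structure("gamma", "time")
  p_struct <- parameter_structure("p", c("time", "size"))
  lapply(seq_along(phis), function(i) {
    model_spec(parameter_structure("phi", phis[[i]]), gam, p_struct,
               id = sprintf("red%02d", i))
  })
}

#' Small-sample-corrected Akaike information criterion
#'
#' @param loglik Natural-log likelihood at the MLE.
#' @param k Number of estimated parameters.
#' @param n Effective sample size.
#' @return AICc value; `Inf` (with a warning) when `n - k - 1 <= 0`.
#' @examples
#' aicc(-100, 5, 50)  # 211.3636...
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) {
    warning(sprintf("AICc undefined for k = %d at n = %d (n - k - 1 <= 0); returning Inf",
                    k, n))
    return(Inf)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1: `exp(-delta/2)` normalized, with
#'   `delta = AICc - min(AICc)`.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Rank fitted models by AICc
#'
#' Builds the model-selection table: AICc, delta-AICc and Akaike weight per
#' converged fit, sorted ascending by AICc. Non-converged fits are excluded
#' (with a message).
#'
#' @param fits List of `pradel_fit` objects.
#' @param ess_rule Effective sample size for the AICc correction:
#'   `"histories"` (number of genera; default), `"detections"` (total
#'   detections), or `"history_occasions"`.
#' @param hist The `capture_history_set` the fits share (used for the
#'   effective sample size); when omitted the size recorded in each fit is
#'   used.
#' @return A `model_table` data.frame with columns `model_id`,
#'   `phi`, `gamma`, `p` (formula labels), `loglik`, `k`, `n_eff`, `AICc`,
#'   `dAICc`, `weight`, `two_regime`.
#' @export
rank_models <- function(fits, ess_rule = "histories", hist = NULL) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    message(sum(!conv), " non-converged model(s) excluded from ranking")
  }
  fits <- fits[conv]
  if (!length(fits)) stop("no converged fits to rank")
  n_eff <- if (!is.null(hist)) effective_n(hist, ess_rule)
           else vapply(fits, function(f) {
             switch(ess_rule, histories = f$n_histories,
                    stop("supply `hist` for ess_rule != 'histories'"))
           }, numeric(1))[1L]
  tab <- data.frame(
    model_id = vapply(fits, function(f) f$spec$id, character(1)),
    phi = vapply(fits, function(f) f$spec$phi$label, character(1)),
    gamma = vapply(fits, function(f) f$spec$gamma$label, character(1)),
    p = vapply(fits, function(f) f$spec$p$label, character(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    n_eff = n_eff,
    stringsAsFactors = FALSE
  )
  tab$AICc <- suppressWarnings(
    mapply(aicc, tab$loglik, tab$k, tab$n_eff))
  if (any(!is.finite(tab$AICc))) {
    warning("model(s) with undefined AICc (n - k - 1 <= 0) set to Inf")
  }
  tab$two_regime <- vapply(fits, function(f)
    any(grepl(":me$", f$spec$phi$terms)), logical(1))
  fin <- is.finite(tab$AICc)
  tab$dAICc <- tab$AICc - min(tab$AICc[fin])
  tab$weight <- 0
  tab$weight[fin] <- akaike_weights(tab$AICc[fin])
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, vapply(fits, function(f) f$spec$id,
                                                    character(1)))[ord]
  class(tab) <- c("model_table", "data.frame")
  tab
}

## per-model coefficient and SE of (main + interaction), covariance included
phi_term_stats <- function(fit, main, inter = NULL) {
  nm_main <- paste0("phi.", main)
  nm_int <- if (!is.null(inter)) paste0("phi.", inter) else NULL
  b <- fit$coefficients
  has_main <- nm_main %in% names(b)
  has_int <- !is.null(nm_int) && nm_int %in% names(b)
  est <- (if (has_main) b[[nm_main]] else 0) + (if (has_int) b[[nm_int]] else 0)
  v <- 0
  if (!is.null(fit$vcov)) {
    if (has_main) v <- v + fit$vcov[nm_main, nm_main]
    if (has_int) v <- v + fit$vcov[nm_int, nm_int]
    if (has_main && has_int) v <- v + 2 * fit$vcov[nm_main, nm_int]
  } else if (has_main || has_int) {
    v <- NA_real_
  }
  list(estimate = est, se = sqrt(v), present = has_main || has_int)
}

#' Model-averaged extinction-selectivity coefficients
#'
#' Averages survival-side trait coefficients over all models whose Akaike
#' weight reaches `min_weight`, weighted by (renormalized) weight, with
#' absent terms contributing zero, and reports them on the
#' log-odds-of-extinction scale (the negated survival-scale value): positive
#' values mean a larger trait value raises extinction risk. The background
#' coefficient averages the trait main effect; the mass-extinction
#' coefficient averages (main effect + ME interaction), so it always equals
#' the background coefficient plus the averaged interaction. Unconditional
#' standard errors follow the multimodel formula
#' \eqn{\sqrt{\sum_i w_i (se_i^2 + (\theta_i - \bar\theta)^2)}}.
#'
#' @param table A `model_table` from [rank_models()] (carries its fits).
#' @param min_weight Minimum Akaike weight for a model to enter the average
#'   (default 0.01).
#' @param renormalize Renormalize weights over the qualifying subset
#'   (default `TRUE`).
#' @param class_name Label for the output rows.
#' @return A `selectivity` data.frame: one row per trait (size, range) and
#'   regime (background, mass_extinction) with `coefficient` (log-odds of
#'   extinction per SD of trait), `se`, `ci_low`, `ci_high`,
#'   `n_models_averaged`.
#' @export
average_coefficients <- function(table, min_weight = 0.01, renormalize = TRUE,
                                 class_name = NA_character_) {
  fits <- attr(table, "fits")
  if (is.null(fits)) stop("table carries no fits; build it with rank_models()")
  qual <- table$weight >= min_weight & is.finite(table$AICc)
  if (!any(qual)) stop("no model reaches min_weight = ", min_weight)
  ids <- table$model_id[qual]
  w <- table$weight[qual]
  if (renormalize) w <- w / sum(w)

  ## drop models whose needed SEs are unavailable (singular information)
  usable <- vapply(ids, function(id) {
    f <- fits[[id]]
    ok <- TRUE
    for (tm in c("size", "range", "size:me", "range:me")) {
      nm <- paste0("phi.", tm)
      if (nm %in% names(f$coefficients) && !is.finite(f$se[[nm]])) ok <- FALSE
    }
    ok
  }, logical(1))
  if (!all(usable)) {
    message(sum(!usable), " model(s) dropped from averaging: ",
            "trait-coefficient SE unavailable")
    ids <- ids[usable]; w <- w[usable]
    if (!length(ids)) stop("no usable models for averaging")
    w <- w / sum(w)
  }

  rows <- list()
  for (trait in c("size", "range")) {
    inter <- paste0(trait, ":me")
    for (regime in c("background", "mass_extinction")) {
      stats_i <- lapply(ids, function(id) {
        if (regime == "background") phi_term_stats(fits[[id]], trait)
        else phi_term_stats(fits[[id]], trait, inter)
      })
      est <- vapply(stats_i, `[[`, numeric(1), "estimate")
      se_i <- vapply(stats_i, `[[`, numeric(1), "se")
      theta <- sum(w * est)
      use <- sum(w * (se_i^2 + (est - theta)^2))
      se_u <- sqrt(use)
      ## extinction scale: logit(q) = -logit(phi)
      coef_ext <- -theta
      rows[[length(rows) + 1L]] <- data.frame(
        class_name = class_name, trait = trait, regime = regime,
        coefficient = coef_ext, se = se_u,
        ci_low = coef_ext - 1.96 * se_u, ci_high = coef_ext + 1.96 * se_u,
        n_models_averaged = length(ids), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("selectivity", "data.frame")
  out
}

#' Summarize support for single- versus two-regime models
#'
#' Classifies each ranked model as single-regime (no mass-extinction term in
#' survival) or two-regime (any ME term in survival) and reports the summed
#' Akaike weight of each class and the class of the best-ranked model.
#'
#' @param table A `model_table` from [rank_models()].
#' @return List with `top_model_regime`, `weight_single_regime`,
#'   `weight_two_regime` and the table of per-model classifications.
#' @export
regime_support_summary <- function(table) {
  w2 <- sum(table$weight[table$two_regime])
  w1 <- sum(table$weight[!table$two_regime])
  list(
    top_model_regime = if (table$two_regime[1L]) "two_regime" else "single_regime",
    weight_single_regime = w1,
    weight_two_regime = w2,
    models = table[, c("model_id", "phi", "two_regime", "AICc", "weight")]
  )
}
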