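## Pradel seniority likelihood: reference R implementation, total likelihood
## via the compiled kernel, maximum-likelihood fitting and diagnostics.

#' Pradel seniority log-likelihood of one capture history
#'
#' Reference (pure-R) evaluation of the per-genus Pradel seniority
#' likelihood. For a history with first detection `f` and last detection `l`
#' the likelihood is
#' \deqn{\xi_f \, p_f \prod_{t=f}^{l-1} \phi_t\, p_{t+1}^{\omega_{t+1}}
#'   (1-p_{t+1})^{1-\omega_{t+1}} \cdot \chi_l}
#' where the backward tail \eqn{\xi} (never detected before `f`) recurses on
#' seniority \eqn{\gamma} and the forward tail \eqn{\chi} (never detected
#' after `l`) recurses on survival \eqn{\phi}. Used as the readable oracle
#' the compiled kernel is tested against.
#'
#' @param phi Survival probabilities over intervals t -> t+1 (length T-1).
#' @param gamma Seniority probabilities at occasions 2..T (length T-1).
#' @param p Detection probabilities at occasions 1..T (length T).
#' @param history 0/1 detection vector of length T with at least one 1.
#' @return The natural-log probability of the history.
#' @examples
#' # T = 3, seen every occasion, certain detection: log(0.5 * 0.5)
#' pradel_loglik(c(0.5, 0.5), c(0.5, 0.5), c(1, 1, 1), c(1, 1, 1))
#' @export
pradel_loglik <- function(phi, gamma, p, history) {
  Tn <- length(history)
  stopifnot(length(phi) == Tn - 1L, length(gamma) == Tn - 1L,
            length(p) == Tn, any(history > 0))
  f <- which(history > 0)[1L]
  l <- max(which(history > 0))

  chi <- rep(1, Tn)                      # chi[t]: never detected after t
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      if (t < l) break
      chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t + 1L]) * chi[t + 1L]
    }
  }
  xi <- rep(1, Tn)                       # xi[t]: never detected before t
  if (f > 1L) {
    for (t in 2L:f) {
      g <- gamma[t - 1L]
      xi[t] <- (1 - g) + g * (1 - p[t - 1L]) * xi[t - 1L]
    }
  }
  ll <- log(xi[f]) + log(p[f]) + log(chi[l])
  if (l > f) {
    for (t in f:(l - 1L)) {
      ll <- ll + log(phi[t]) +
        if (history[t + 1L] > 0) log(p[t + 1L]) else log(1 - p[t + 1L])
    }
  }
  ll
}

## negative log-likelihood (and gradient) for a coefficient vector on a
## prepared design; thin wrapper over the compiled kernel
design_nll <- function(beta, design, hist, fl, want_grad = FALSE,
                       condition = TRUE) {
  pradel_nll_cpp(beta, hist$ch, fl$first - 1L, fl$last - 1L,
                 design$Xphi, design$time_phi,
                 design$Xgam, design$time_gam,
                 design$Xp, design$time_p,
                 if (is.null(design$p_fixed)) -1 else design$p_fixed,
                 condition, want_grad)
}

#' Total Pradel log-likelihood for a model on a history set
#'
#' Sums the per-genus Pradel seniority log-likelihood over all capture
#' histories, with per-genus, per-occasion parameters obtained by the
#' inverse logit of the linear predictors implied by `spec` and
#' `coefficients`.
#'
#' @param spec A `model_spec` (or a prebuilt `design_matrices`).
#' @param coefficients Numeric coefficient vector, ordered phi block, gamma
#'   block, p block (see `design$par_names`).
#' @param hist A `capture_history_set`.
#' @param condition_on_detection Condition each history on its genus being
#'   detected at least once (the full Pradel likelihood; default `TRUE`).
#'   `FALSE` gives the bare kernel sum, which is biased when detection
#'   varies across genera.
#' @param ... Passed to [build_design()] when `spec` is a `model_spec`.
#' @return The natural-log likelihood (a single number, always <= 0).
#' @export
total_loglik <- function(spec, coefficients, hist,
                         condition_on_detection = TRUE, ...) {
  design <- if (inherits(spec, "design_matrices")) spec
            else build_design(spec, hist, ...)
  stopifnot(length(coefficients) == design$k)
  fl <- first_last(hist$ch)
  -design_nll(coefficients, design, hist, fl, want_grad = FALSE,
              condition = condition_on_detection)$nll
}

#' Fit one Pradel seniority model by maximum likelihood
#'
#' Maximizes the total Pradel seniority log-likelihood with BFGS using the
#' analytic gradient, from `starts` starting points (a moment-based
#' empirical start plus seeded perturbations around it). Standard errors come from the inverse of the
#' finite-difference Hessian at the optimum; directions with curvature below
#' tolerance (boundary-confounded occasion parameters are the usual case)
#' get `NA` standard errors via an eigendecomposition-based pseudo-inverse
#' while well-determined coefficients keep finite ones.
#'
#' @param spec A `model_spec`.
#' @param hist A `capture_history_set`.
#' @param starts Number of optimizer starts (default 3).
#' @param seed Integer seed for the start perturbations.
#' @param tol Relative convergence tolerance passed to `optim`.
#' @param hessian Compute the Hessian/SEs (default `TRUE`).
#' @param range_lag,p_fixed Passed to [build_design()].
#' @param condition_on_detection Use the full conditional Pradel likelihood
#'   (default `TRUE`); see [total_loglik()].
#' @param init Optional named coefficient vector (e.g. from a simpler
#'   model's fit) used to warm-start matching parameters.
#' @param ess_rule Effective-sample-size rule used for the fit's own AICc:
#'   `"histories"` (number of genera, default), `"detections"`, or
#'   `"history_occasions"`.
#' @return A `pradel_fit` with coefficient table (both survival and
#'   log-odds-of-extinction scales), log-likelihood, parameter count `k`,
#'   AICc, variance-covariance matrix and convergence flag.
#' @export
fit_model <- function(spec, hist, starts = 3L, seed = 1L, tol = 1e-8,
                      hessian = TRUE, range_lag = "current", p_fixed = NULL,
                      ess_rule = "histories", condition_on_detection = TRUE,
                      init = NULL) {
  design <- build_design(spec, hist, range_lag = range_lag, p_fixed = p_fixed)
  fl <- first_last(hist$ch)
  k <- design$k
  cond <- condition_on_detection
  fn <- function(b) design_nll(b, design, hist, fl, FALSE, cond)$nll
  gr <- function(b) design_nll(b, design, hist, fl, TRUE, cond)$grad

  set.seed(seed)
  b0 <- empirical_start(design, hist, fl)
  if (!is.null(init)) {
    hit <- intersect(names(init), design$par_names)
    b0[match(hit, design$par_names)] <- init[hit]
  }
  start_list <- c(list(b0),
                  replicate(max(0L, starts - 1L),
                            b0 + stats::rnorm(k, 0, 0.25), simplify = FALSE))
  runs <- lapply(start_list, function(b0) {
    tryCatch(
      stats::optim(b0, fn, gr, method = "BFGS",
                   control = list(maxit = 1000L, reltol = tol)),
      error = function(e) NULL)
  })
  runs <- Filter(function(r) !is.null(r) && is.finite(r$value), runs)
  if (!length(runs)) {
    return(structure(list(spec = spec, converged = FALSE,
                          coefficients = NULL, loglik = NA_real_, k = k,
                          n_histories = n_histories(hist)),
                     class = "pradel_fit"))
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  agree <- if (length(runs) > 1L) {
    diff(sort(vals))[1L] < 1e-3 * (1 + abs(min(vals)))
  } else TRUE
  converged <- best$convergence == 0L
  beta <- best$par
  names(beta) <- design$par_names

  vcov <- NULL
  se <- rep(NA_real_, k)
  if (hessian && converged) {
    H <- tryCatch(grad_fd_hessian(gr, beta), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- pseudo_vcov(H)
      se <- sqrt(pmax(diag(vcov), 0))
      se[diag(vcov) < 0 | !is.finite(diag(vcov))] <- NA_real_
      dimnames(vcov) <- list(design$par_names, design$par_names)
    }
  }
  ll <- -best$value
  n_eff <- effective_n(hist, ess_rule)
  coef_tab <- data.frame(
    family = sub("\\..*$", "", design$par_names),
    term = sub("^[^.]*\\.", "", design$par_names),
    estimate = unname(beta),
    se = unname(se),
    stringsAsFactors = FALSE
  )
  ## trait coefficients re-expressed on the log-odds-of-extinction scale:
  ## extinction q = 1 - phi, so logit(q) = -logit(phi) and every
  ## survival-scale coefficient negates
  coef_tab$estimate_extinction <- ifelse(coef_tab$family == "phi",
                                         -coef_tab$estimate, NA_real_)
  structure(list(
    spec = spec, design_info = list(
      par_names = design$par_names, dropped = design$dropped,
      p_fixed = design$p_fixed, range_lag = range_lag),
    coefficients = beta, se = stats::setNames(se, design$par_names),
    coef_table = coef_tab, vcov = vcov,
    loglik = ll, k = k, n_histories = n_histories(hist),
    n_eff = n_eff, AICc = aicc(ll, k, n_eff),
    converged = converged, starts_agree = agree, seed = seed,
    condition_on_detection = cond
  ), class = "pradel_fit")
}

## Observed-information estimate: forward-difference Jacobian of the
## analytic gradient, symmetrized. k + 1 gradient evaluations.
grad_fd_hessian <- function(gr, par, h = 1e-6) {
  k <- length(par)
  g0 <- gr(par)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * (1 + abs(par[j]))
    pj <- par
    pj[j] <- pj[j] + hj
    H[, j] <- (gr(pj) - g0) / hj
  }
  (H + t(H)) / 2
}

## Moment-based starting values: occasion effects initialized at the logit
## of naive persistence / seniority / detection fractions computed from the
## observed spans; covariate coefficients at 0. Cuts optimizer iterations
## severalfold relative to an all-zero start without changing the optimum.
empirical_start <- function(design, hist, fl) {
  Tn <- ncol(hist$ch)
  f <- fl$first; l <- fl$last
  clamp01 <- function(x) pmin(pmax(x, 0.05), 0.95)
  rate <- function(num, den) clamp01(ifelse(den > 0, num / den, 0.5))
  present <- vapply(seq_len(Tn), function(t) sum(f <= t & l >= t), numeric(1))
  persist <- vapply(seq_len(Tn), function(t) sum(f <= t & l > t), numeric(1))
  senior <- vapply(seq_len(Tn), function(t) sum(f < t & l >= t), numeric(1))
  detect <- vapply(seq_len(Tn), function(t)
    sum(hist$ch[f <= t & l >= t, t]), numeric(1))
  b0 <- stats::setNames(rep(0, design$k), design$par_names)
  fill <- function(prefix, values, occ) {
    nm <- paste0(prefix, ".occ", occ)
    hit <- nm %in% names(b0)
    b0[nm[hit]] <<- logit(values[hit])
  }
  if (design$time_phi)
    fill("phi", rate(persist[-Tn], present[-Tn]), seq_len(Tn - 1L))
  if (design$time_gam)
    fill("gamma", rate(senior[-1L], present[-1L]), 2:Tn)
  if (design$time_p)
    fill("p", rate(detect, present), seq_len(Tn))
  b0
}

## Moore-Penrose style inverse of the observed information; eigenvalues below
## tolerance (flat, boundary-confounded directions) are treated as singular
## so their variances come out non-finite rather than wildly negative.
pseudo_vcov <- function(H, tol = 1e-8) {
  eg <- eigen(H, symmetric = TRUE)
  lam <- eg$values
  thr <- max(abs(lam)) * tol
  inv <- ifelse(lam > thr, 1 / lam, NA_real_)
  ## keep the well-determined subspace; flat directions contribute NA
  ok <- !is.na(inv)
  V <- eg$vectors[, ok, drop = FALSE] %*%
    (inv[ok] * t(eg$vectors[, ok, drop = FALSE]))
  if (any(!ok)) {
    flat <- abs(eg$vectors[, !ok, drop = FALSE])
    touched <- rowSums(flat > 1e-4) > 0
    V[touched, ] <- NA_real_
    V[, touched] <- NA_real_
  }
  V
}

effective_n <- function(hist, ess_rule = c("histories", "detections",
                                           "history_occasions")) {
  ess_rule <- match.arg(ess_rule)
  switch(ess_rule,
         histories = nrow(hist$ch),
         detections = sum(hist$ch),
         history_occasions = nrow(hist$ch) * ncol(hist$ch))
}

#' @export
print.pradel_fit <- function(x, ...) {
  cat(sprintf("<pradel_fit> %s\n", x$spec$id))
  cat(sprintf("  logLik %.3f | k %d | AICc %.2f | converged %s\n",
              x$loglik, x$k, x$AICc, x$converged))
  invisible(x)
}

#' Fill in standard errors for a fitted model
#'
#' Computes the observed-information variance-covariance matrix and standard
#' errors at the stored MLE for a fit produced with `hessian = FALSE`.
#' Useful when many candidate models are fitted but only the few entering
#' the model average need uncertainty estimates.
#'
#' @param fit A converged `pradel_fit`.
#' @param hist The `capture_history_set` it was fitted to.
#' @return The fit with `vcov`, `se` and `coef_table$se` filled.
#' @export
refit_hessian <- function(fit, hist) {
  stopifnot(inherits(fit, "pradel_fit"), fit$converged)
  if (!is.null(fit$vcov)) return(fit)
  design <- build_design(fit$spec, hist,
                         range_lag = fit$design_info$range_lag,
                         p_fixed = fit$design_info$p_fixed)
  fl <- first_last(hist$ch)
  gr <- function(b) design_nll(b, design, hist, fl, TRUE,
                               fit$condition_on_detection %||% TRUE)$grad
  H <- grad_fd_hessian(gr, fit$coefficients)
  vcov <- pseudo_vcov(H)
  se <- sqrt(pmax(diag(vcov), 0))
  se[diag(vcov) < 0 | !is.finite(diag(vcov))] <- NA_real_
  dimnames(vcov) <- list(design$par_names, design$par_names)
  fit$vcov <- vcov
  fit$se <- stats::setNames(se, design$par_names)
  fit$coef_table$se <- unname(se)
  fit
}

#' Per-genus extinction probability from a fitted model
#'
#' The probability of extinction over the interval starting at `occasion` is
#' the complement of fitted survival, `1 - phi_hat`, evaluated at the
#' supplied covariate values.
#'
#' @param fit A converged `pradel_fit`.
#' @param occasion Interval index (1 .. T-1).
#' @param covariates Named list with `z_size`, `z_range` (defaults 0, i.e.
#'   class-mean trait values).
#' @return Extinction probability in (0, 1).
#' @export
extinction_probability <- function(fit, occasion,
                                   covariates = list(z_size = 0, z_range = 0)) {
  stopifnot(fit$converged)
  beta <- fit$coefficients
  phi_names <- names(beta)[startsWith(names(beta), "phi.")]
  terms <- sub("^phi\\.", "", phi_names)
  if (any(grepl("^occ", terms))) {
    occ_terms <- as.integer(sub("occ", "", terms[grepl("^occ", terms)]))
    if (!(occasion %in% occ_terms)) stop("occasion out of range: ", occasion)
  }
  zs <- covariates$z_size %||% 0
  zr <- covariates$z_range %||% 0
  me <- covariates$me %||% 0
  val <- vapply(terms, function(tm) {
    switch(tm,
           "(Intercept)" = 1,
           "size" = zs, "range" = zr, "size:range" = zs * zr,
           "size:me" = zs * me, "range:me" = zr * me,
           "size:range:me" = zs * zr * me,
           if (grepl("^occ", tm)) as.numeric(as.integer(sub("occ", "", tm)) == occasion)
           else stop("unhandled term ", tm))
  }, numeric(1))
  eta <- sum(val * beta[phi_names])
  1 - inv_logit(clamp_eta(eta))
}

#' Time-reversal diagnostic for the Pradel likelihood
#'
#' The Pradel seniority model is symmetric under time reversal: fitting the
#' reversed histories must (at the optimum) swap the survival and seniority
#' estimate sequences, each read in reversed occasion order, and reverse the
#' detection sequence. This double-fit check exercises likelihood, gradient
#' and optimizer together; it requires time-only structures in all families.
#'
#' @param hist A `capture_history_set`.
#' @param spec A `model_spec` with time-only structures (default built
#'   internally).
#' @param tol Tolerance on the maximum absolute probability-scale difference.
#' @param fit_tol Optimizer tolerance for the two fits (tighter than the
#'   fitting default so optimizer noise stays well below `tol`).
#' @param ... Passed to [fit_model()].
#' @return List with `pass`, `max_abs_diff`, and the compared sequences.
#' @export
time_reversal_check <- function(hist, spec = NULL, tol = 1e-4,
                                fit_tol = 1e-12, ...) {
  if (ncol(hist$ch) < 2L) {
    return(list(pass = NA, max_abs_diff = NA_real_,
                note = "single-occasion data: check undefined, skipped"))
  }
  if (is.null(spec)) {
    spec <- model_spec(parameter_structure("phi", "time"),
                       parameter_structure("gamma", "time"),
                       parameter_structure("p", "time"))
  }
  all_time_only <- all(vapply(list(spec$phi, spec$gamma, spec$p),
                              function(s) identical(s$terms, "time"), logical(1)))
  if (!all_time_only) stop("time_reversal_check requires time-only structures")

  fwd <- fit_model(spec, hist, hessian = FALSE, tol = fit_tol, ...)
  rev_ <- fit_model(spec, reverse_histories(hist), hessian = FALSE,
                    tol = fit_tol, ...)
  if (!fwd$converged || !rev_$converged) {
    return(list(pass = FALSE, max_abs_diff = NA_real_,
                note = "one of the two fits failed to converge"))
  }
  seqs <- function(fit, fam) {
    b <- fit$coefficients
    inv_logit(clamp_eta(unname(b[startsWith(names(b), paste0(fam, "."))])))
  }
  d_phi <- abs(seqs(rev_, "phi") - rev(seqs(fwd, "gamma")))
  d_gam <- abs(seqs(rev_, "gamma") - rev(seqs(fwd, "phi")))
  d_p <- abs(seqs(rev_, "p") - rev(seqs(fwd, "p")))
  mx <- max(c(d_phi, d_gam, d_p))
  list(pass = mx < tol, max_abs_diff = mx,
       phi_fwd = seqs(fwd, "phi"), gamma_rev = seqs(rev_, "gamma"),
       gamma_fwd = seqs(fwd, "gamma"), phi_rev = seqs(rev_, "phi"))
}
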