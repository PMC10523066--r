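## Symbolic covariate structures for the three Pradel parameter families and
## their translation into per-genus, per-occasion design matrices.
##
## Families: phi (survival over interval t -> t+1), gamma (seniority at
## occasion t, i.e. the probability of having already been extant at t-1),
## p (detection at occasion t). Structures are term sets on the logit scale:
##   time        occasion fixed effects (one indicator per occasion, no
##               intercept); when absent an intercept column is used
##   size        standardized body size (static per genus)
##   range       standardized log10 geographic range (time-varying)
##   size:range  product of the two
##   *:me        interaction with the 0/1 mass-extinction stage flag (phi only)
##   *:rec       interaction with the 0/1 recovery stage flag (gamma only)
## Mass-extinction and recovery main effects are never separate columns: with
## occasion fixed effects present they are linear combinations of the time
## columns, so the regime contrast lives entirely in the interactions.

PHI_TERMS <- c("time", "size", "range", "size:range",
               "size:me", "range:me", "size:range:me")
GAM_TERMS <- c("time", "size", "range", "size:range",
               "size:rec", "range:rec", "size:range:rec")
P_TERMS <- c("time", "size", "range", "size:range")

#' Define a covariate structure for one parameter family
#'
#' @param family One of `"phi"`, `"gamma"`, `"p"`.
#' @param terms Character vector of terms (see Details); `character(0)` gives
#'   an intercept-only structure.
#' @param label Optional display label in the field's formula notation
#'   (e.g. `"~time + BS + GR x ME"`); derived from the terms when omitted.
#' @details Valid terms are `time`, `size`, `range`, `size:range` for all
#'   families, plus mass-extinction interactions (`size:me`, `range:me`,
#'   `size:range:me`) for survival and recovery interactions (`size:rec`,
#'   `range:rec`, `size:range:rec`) for seniority.
#' @return A `parameter_structure`.
#' @export
parameter_structure <- function(family = c("phi", "gamma", "p"),
                                terms = "time", label = NULL) {
  family <- match.arg(family)
  terms <- unique(as.character(terms))
  valid <- switch(family, phi = PHI_TERMS, gamma = GAM_TERMS, p = P_TERMS)
  bad <- setdiff(terms, valid)
  if (length(bad)) {
    stop(sprintf("invalid term(s) for family %s: %s", family,
                 paste(bad, collapse = ", ")))
  }
  structure(list(family = family, terms = terms,
                 label = label %||% render_terms(terms)),
            class = "parameter_structure")
}

## Display labels in the conventional shorthand: BS = body size,
## GR = geographic range, ME = mass extinction, Rec = recovery.
render_terms <- function(terms) {
  canon <- list(
    "~time" = "time",
    "~time + BS" = c("time", "size"),
    "~time + GR" = c("time", "range"),
    "~time + BS + GR" = c("time", "size", "range"),
    "~time + BS x GR" = c("time", "size", "range", "size:range"),
    "~time + BS x ME" = c("time", "size", "size:me"),
    "~time + GR x ME" = c("time", "range", "range:me"),
    "~time + BS x ME + GR" = c("time", "size", "size:me", "range"),
    "~time + BS + GR x ME" = c("time", "size", "range", "range:me"),
    "~time + BS x ME + GR x ME" = c("time", "size", "size:me", "range", "range:me"),
    "~time + BS x GR x ME" = c("time", "size", "range", "size:range",
                               "size:me", "range:me", "size:range:me"),
    "~time + BS x Rec" = c("time", "size", "size:rec"),
    "~time + GR x Rec" = c("time", "range", "range:rec"),
    "~time + BS x Rec + GR" = c("time", "size", "size:rec", "range"),
    "~time + BS + GR x Rec" = c("time", "size", "range", "range:rec"),
    "~time + BS x Rec + GR x Rec" = c("time", "size", "size:rec", "range", "range:rec"),
    "~time + BS x GR x Rec" = c("time", "size", "range", "size:range",
                                "size:rec", "range:rec", "size:range:rec")
  )
  for (lab in names(canon)) {
    if (setequal(terms, canon[[lab]])) return(lab)
  }
  if (!length(terms)) return("~1")
  paste0("~", paste(terms, collapse = " + "))
}

#' @export
print.parameter_structure <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$family, x$label))
  invisible(x)
}

#' Define one candidate model
#'
#' A model is a triple of covariate structures for survival (`phi`),
#' seniority (`gamma`) and detection (`p`).
#'
#' @param phi,gamma,p `parameter_structure` objects of matching family.
#' @param id Optional stable identifier string.
#' @return A `model_spec`.
#' @export
model_spec <- function(phi, gamma, p, id = NULL) {
  stopifnot(inherits(phi, "parameter_structure"), phi$family == "phi",
            inherits(gamma, "parameter_structure"), gamma$family == "gamma",
            inherits(p, "parameter_structure"), p$family == "p")
  id <- id %||% paste0("phi(", phi$label, ").gam(", gamma$label, ").p(", p$label, ")")
  structure(list(phi = phi, gamma = gamma, p = p, id = id),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> phi: %s | gamma: %s | p: %s\n",
              x$phi$label, x$gamma$label, x$p$label))
  invisible(x)
}

## Covariate values for one family at its occasions.
## phi occasions: intervals t -> t+1, t = 1..T-1; gamma occasions: 2..T;
## p occasions: 1..T. `range_lag = "current"` feeds interval t -> t+1 with
## the stage-t range value; `"next"` uses stage t+1 (phi and gamma only).
family_occasions <- function(family, Tn) {
  switch(family, phi = seq_len(Tn - 1L), gamma = 2:Tn, p = seq_len(Tn))
}

build_family_design <- function(struct, hist, me_flag, rec_flag,
                                range_lag = "current") {
  Tn <- ncol(hist$ch)
  n <- nrow(hist$ch)
  occ <- family_occasions(struct$family, Tn)
  no <- length(occ)
  ## covariate stage per occasion
  cov_stage <- switch(struct$family,
    phi = if (range_lag == "next") occ + 1L else occ,
    gamma = occ,
    p = occ)
  flag <- switch(struct$family,
                 phi = me_flag[occ],        # extinction pulse at flagged stage
                 gamma = rec_flag[occ],     # recruitment into flagged stage
                 p = rep(0, no))
  ## rows genus-major: row (i-1)*no + j for genus i, occasion occ[j]
  zs <- rep(hist$z_size, each = no)
  zr <- as.vector(t(hist$z_range[, cov_stage, drop = FALSE]))
  fl <- rep(flag, times = n)

  ## occasion fixed effects are handled sparsely by the likelihood kernel
  ## (never materialized as indicator columns)
  has_time <- "time" %in% struct$terms
  cols <- list()
  if (!has_time) {
    cols$int <- matrix(1, n * no, 1, dimnames = list(NULL, "(Intercept)"))
  }
  add <- function(nm, v) {
    m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    cols[[nm]] <<- m
  }
  tset <- struct$terms
  if ("size" %in% tset) add("size", zs)
  if ("range" %in% tset) add("range", zr)
  if ("size:range" %in% tset) add("size:range", zs * zr)
  if ("size:me" %in% tset) add("size:me", zs * fl)
  if ("range:me" %in% tset) add("range:me", zr * fl)
  if ("size:range:me" %in% tset) add("size:range:me", zs * zr * fl)
  if ("size:rec" %in% tset) add("size:rec", zs * fl)
  if ("range:rec" %in% tset) add("range:rec", zr * fl)
  if ("size:range:rec" %in% tset) add("size:range:rec", zs * zr * fl)
  X <- if (length(cols)) do.call(cbind, unname(cols))
       else matrix(0, n * no, 0)

  ## prune columns identically zero over the data (e.g. an ME interaction
  ## when no flagged stage falls inside the window)
  keep <- if (ncol(X)) colSums(abs(X)) > 0 else logical(0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  list(X = X, dropped = dropped, has_time = has_time,
       par_names = c(if (has_time) paste0("occ", occ), colnames(X)))
}

#' Build design matrices for a model on a set of histories
#'
#' Translates the three covariate structures of a [model_spec()] into
#' per-genus, per-occasion design matrices on the logit scale. Interaction
#' columns are the product of the covariate with the stage's 0/1
#' mass-extinction (phi) or recovery (gamma) flag; columns identically zero
#' over the data (e.g. an ME interaction in a window with no flagged stage)
#' are pruned and recorded.
#'
#' @param spec A `model_spec`.
#' @param hist A `capture_history_set`.
#' @param range_lag Which stage's range value feeds the survival interval
#'   t -> t+1: `"current"` (stage t, default) or `"next"`.
#' @param p_fixed Optional probability at which detection is held fixed
#'   (no p columns are built); `NULL` to estimate detection.
#' @return A `design_matrices` list with elements `Xphi`, `Xgam`, `Xp`,
#'   column bookkeeping and the total parameter count `k`.
#' @export
build_design <- function(spec, hist, range_lag = c("current", "next"),
                         p_fixed = NULL) {
  range_lag <- match.arg(range_lag)
  st <- hist$stage_table
  me_flag <- as.numeric(st$is_mass_extinction[hist$window])
  rec_flag <- as.numeric(st$is_recovery[hist$window])

  dphi <- build_family_design(spec$phi, hist, me_flag, rec_flag, range_lag)
  dgam <- build_family_design(spec$gamma, hist, me_flag, rec_flag, range_lag)
  if (is.null(p_fixed)) {
    dp <- build_family_design(spec$p, hist, me_flag, rec_flag, range_lag)
  } else {
    stopifnot(p_fixed > 0, p_fixed <= 1)
    dp <- list(X = matrix(0, nrow(hist$ch) * ncol(hist$ch), 0),
               dropped = character(0), has_time = FALSE,
               par_names = character(0))
  }
  Tn <- ncol(hist$ch)
  kfam <- function(d, no) (if (d$has_time) no else 0L) + ncol(d$X)
  structure(list(
    spec = spec, Xphi = dphi$X, Xgam = dgam$X, Xp = dp$X,
    time_phi = dphi$has_time, time_gam = dgam$has_time, time_p = dp$has_time,
    p_fixed = p_fixed,
    dropped = list(phi = dphi$dropped, gamma = dgam$dropped, p = dp$dropped),
    k = kfam(dphi, Tn - 1L) + kfam(dgam, Tn - 1L) + kfam(dp, Tn),
    par_names = c(paste0("phi.", dphi$par_names),
                  paste0("gamma.", dgam$par_names),
                  if (length(dp$par_names)) paste0("p.", dp$par_names)),
    n = nrow(hist$ch), T = Tn
  ), class = "design_matrices")
}
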