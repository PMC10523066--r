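test_that("with certain detection, survival MLE is the persistence fraction", {
  ## complete histories (p = 1): the likelihood factorizes and the
  ## occasion-wise survival MLE has a closed form
  cfg <- sim_config(n_genera = 400L, stage_table = make_stage_table(8L),
                    alpha_p_t = 15, delta_size_p = 0, delta_range_p = 0,
                    beta_size_bg = 0.3, beta_range_bg = 0.3, seed = 21)
  sim <- simulate_fossil_record(cfg, emit_occurrences = FALSE)
  h <- truth_histories(sim)
  sp <- model_spec(parameter_structure("phi", "time"),
                   parameter_structure("gamma", "time"),
                   parameter_structure("p", "time"))
  fit <- fit_model(sp, h, starts = 1, tol = 1e-13, hessian = FALSE,
                   p_fixed = 1)
  expect_true(fit$converged)
  fl <- paleoCMR:::first_last(h$ch)
  for (t in seq_len(ncol(h$ch) - 1L)) {
    present <- fl$first <= t & fl$last >= t
    frac <- sum(fl$first <= t & fl$last > t) / sum(present)
    phi_hat <- plogis(min(max(fit$coefficients[[paste0("phi.occ", t)]], -15), 15))
    expect_equal(phi_hat, frac, tolerance = 1e-6)
  }
})

test_that("negating the size covariate flips its coefficient exactly", {
  h <- small_histories(n = 150, Tn = 8, me = 5L, seed = 12)
  sp <- model_spec(parameter_structure("phi", c("time", "size")),
                   parameter_structure("gamma", "time"),
                   parameter_structure("p", c("time", "size")))
  f1 <- fit_model(sp, h, starts = 1, hessian = FALSE)
  h2 <- h
  h2$z_size <- -h$z_size
  f2 <- fit_model(sp, h2, starts = 1, hessian = FALSE)
  expect_lt(abs(f1$coefficients[["phi.size"]] + f2$coefficients[["phi.size"]]),
            1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("extinction probability is the survival complement on the logit link", {
  h <- small_histories(n = 100, Tn = 6, me = 4L, seed = 5)
  sp <- model_spec(parameter_structure("phi", c("time", "size", "range")),
                   parameter_structure("gamma", "time"),
                   parameter_structure("p", c("time", "size")))
  fit <- fit_model(sp, h, starts = 1, hessian = FALSE)
  ## at class-mean covariates the linear predictor is the occasion effect
  q <- extinction_probability(fit, 2, list(z_size = 0, z_range = 0))
  expect_equal(q, 1 - plogis(fit$coefficients[["phi.occ2"]]), tolerance = 1e-9)
  ## complement identity at arbitrary covariates
  q2 <- extinction_probability(fit, 3, list(z_size = 1.2, z_range = -0.4))
  eta <- fit$coefficients[["phi.occ3"]] + 1.2 * fit$coefficients[["phi.size"]] -
    0.4 * fit$coefficients[["phi.range"]]
  expect_equal(q2, 1 - plogis(eta), tolerance = 1e-9)
  ## monotone in range when the range coefficient is positive on survival
  if (fit$coefficients[["phi.range"]] > 0) {
    qs <- vapply(c(-1, 0, 1), function(z)
      extinction_probability(fit, 2, list(z_size = 0, z_range = z)), numeric(1))
    expect_true(all(diff(qs) < 0))
  }
  expect_error(extinction_probability(fit, 99), "out of range")
})

test_that("fitting reversed histories swaps survival and seniority", {
  h <- small_histories(n = 250, Tn = 7, me = integer(0), seed = 9)
  chk <- time_reversal_check(h, tol = 1e-4, starts = 1)
  expect_true(chk$pass)
  expect_lt(chk$max_abs_diff, 1e-4)
  ## non-time-only structures are rejected
  badspec <- model_spec(parameter_structure("phi", c("time", "size")),
                        parameter_structure("gamma", "time"),
                        parameter_structure("p", "time"))
  expect_error(time_reversal_check(h, badspec), "time-only")
})

test_that("standard errors can be filled in after fitting", {
  h <- small_histories(n = 120, Tn = 6, me = 4L, seed = 15)
  sp <- model_spec(parameter_structure("phi", c("time", "size")),
                   parameter_structure("gamma", "time"),
                   parameter_structure("p", c("time", "size")))
  f0 <- fit_model(sp, h, starts = 1, hessian = FALSE)
  expect_null(f0$vcov)
  f1 <- refit_hessian(f0, h)
  f2 <- fit_model(sp, h, starts = 1, hessian = TRUE)
  expect_equal(f1$se[["phi.size"]], f2$se[["phi.size"]], tolerance = 1e-6)
  expect_true(is.finite(f1$se[["phi.size"]]))
})
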