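## minimal stand-in for a converged fit, for selection-layer tests that do
## not need a real likelihood maximization
mock_fit <- function(id, loglik, k, coefs = numeric(0), ses = NULL,
                     vcov = NULL, converged = TRUE,
                     phi_terms = "time", n = 100L) {
  spec <- model_spec(parameter_structure("phi", phi_terms),
                     parameter_structure("gamma", "time"),
                     parameter_structure("p", c("time", "size")), id = id)
  if (is.null(ses)) ses <- rep(0.1, length(coefs))
  if (is.null(vcov) && length(coefs)) {
    vcov <- diag(ses^2, length(coefs))
    dimnames(vcov) <- list(names(coefs), names(coefs))
  }
  structure(list(spec = spec, coefficients = coefs,
                 se = stats::setNames(ses, names(coefs)), vcov = vcov,
                 loglik = loglik, k = k, n_histories = n,
                 converged = converged),
            class = "pradel_fit")
}

test_that("the canonical candidate set enumerates 121 distinct models", {
  specs <- enumerate_model_set()
  expect_length(specs, 121L)
  expect_equal(anyDuplicated(vapply(specs, `[[`, character(1), "id")), 0L)
  phi_labels <- unique(vapply(specs, function(s) s$phi$label, character(1)))
  gam_labels <- unique(vapply(specs, function(s) s$gamma$label, character(1)))
  expect_length(phi_labels, 11L)
  expect_length(gam_labels, 11L)
  ## every published top-model formula is generable
  expect_in(c("~time + BS + GR x ME", "~time + BS x GR x ME",
              "~time + BS x ME + GR x ME", "~time + BS x GR", "~time + GR",
              "~time + BS x ME + GR"), phi_labels)
  expect_in(c("~time + BS x Rec + GR x Rec", "~time + BS x GR x Rec",
              "~time + BS x Rec + GR"), gam_labels)
  expect_true(all(vapply(specs, function(s) s$p$label, character(1)) ==
                    "~time + BS"))
  ## optional intercept-only seniority extension
  expect_length(enumerate_model_set(gamma_dot = TRUE), 132L)
  expect_length(reduced_model_set(), 8L)
})

test_that("AICc and Akaike weights follow the textbook arithmetic", {
  expect_equal(aicc(-100, 5, 50), 211.363636, tolerance = 1e-6)
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  expect_equal(round(w, 5), c(0.73106, 0.26894))
  expect_equal(sum(akaike_weights(runif(20, 100, 150))), 1, tolerance = 1e-9)
  expect_warning(expect_equal(aicc(-10, 10, 11), Inf), "AICc undefined")
})

test_that("ranking sorts by AICc, excludes failures and is shift-invariant", {
  fits <- list(mock_fit("m1", -100, 5), mock_fit("m2", -98, 8),
               mock_fit("m3", -120, 5),
               mock_fit("bad", NA_real_, 5, converged = FALSE))
  tab <- suppressMessages(rank_models(fits))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$model_id[1L], "m1")
  expect_equal(tab$dAICc[1L], 0)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  ## adding a constant to every log-likelihood leaves ranks and weights alone
  fits2 <- list(mock_fit("m1", -100 + 7, 5), mock_fit("m2", -98 + 7, 8),
                mock_fit("m3", -120 + 7, 5))
  tab2 <- rank_models(fits2)
  expect_equal(tab2$model_id, tab$model_id[1:3])
  expect_equal(tab2$weight, tab$weight[1:3], tolerance = 1e-9)
})

test_that("coefficient averaging follows the weighted zero-substitution rule", {
  ## single qualifying model: the average is that model's coefficient
  f1 <- mock_fit("m1", -100, 5,
                 coefs = c(phi.size = -0.10), ses = 0.05)
  tab1 <- rank_models(list(f1))
  sel1 <- average_coefficients(tab1, class_name = "X")
  got <- sel1$coefficient[sel1$trait == "size" & sel1$regime == "background"]
  expect_equal(got, 0.10, tolerance = 1e-9)  # extinction scale negates

  ## two models, same k, weights 0.6/0.4: w1/w2 = exp(dAICc/2) = exp(dll)
  f2 <- mock_fit("m2", -100 - log(0.6 / 0.4), 5,
                 coefs = c(phi.size = 0.05), ses = 0.05)
  tab2 <- rank_models(list(f1, f2))
  expect_equal(tab2$weight, c(0.6, 0.4), tolerance = 1e-9)
  sel2 <- average_coefficients(tab2, class_name = "X")
  got2 <- sel2$coefficient[sel2$trait == "size" & sel2$regime == "background"]
  expect_equal(got2, -(0.6 * -0.10 + 0.4 * 0.05), tolerance = 1e-9)  # +0.04

  ## a model lacking the term contributes zero for it
  f3 <- mock_fit("m3", -100, 5, coefs = c(phi.range = 0.2), ses = 0.05)
  tab3 <- rank_models(list(f1, f3))
  sel3 <- average_coefficients(tab3, class_name = "X")
  got3 <- sel3$coefficient[sel3$trait == "size" & sel3$regime == "background"]
  expect_equal(got3, -0.5 * -0.10, tolerance = 1e-9)

  ## mass-extinction coefficient = background + averaged interaction
  f4 <- mock_fit("m4", -100, 6,
                 coefs = c(phi.size = -0.10, `phi.size:me` = 0.30),
                 ses = c(0.05, 0.08), phi_terms = c("time", "size", "size:me"))
  tab4 <- rank_models(list(f4))
  sel4 <- average_coefficients(tab4, class_name = "X")
  bg <- sel4$coefficient[sel4$trait == "size" & sel4$regime == "background"]
  me <- sel4$coefficient[sel4$trait == "size" & sel4$regime == "mass_extinction"]
  expect_equal(me, bg + -(0.30), tolerance = 1e-9)

  ## unconditional SE: Burnham-Anderson formula reproduced independently
  tabB <- rank_models(list(f1, f2))
  selB <- average_coefficients(tabB, min_weight = 0, class_name = "X")
  th <- c(-0.10, 0.05); se <- c(0.05, 0.05); w <- c(0.6, 0.4)
  thbar <- sum(w * th)
  use <- sqrt(sum(w * (se^2 + (th - thbar)^2)))
  expect_equal(selB$se[selB$trait == "size" & selB$regime == "background"],
               use, tolerance = 1e-9)
})

test_that("regime support summary partitions the total weight", {
  f1 <- mock_fit("single", -100, 5, phi_terms = c("time", "size"))
  f2 <- mock_fit("double", -99, 6,
                 coefs = c(phi.size = 0, `phi.size:me` = 0.1),
                 phi_terms = c("time", "size", "size:me"))
  tab <- rank_models(list(f1, f2))
  rs <- regime_support_summary(tab)
  expect_equal(rs$weight_single_regime + rs$weight_two_regime, 1,
               tolerance = 1e-9)
  expect_equal(rs$top_model_regime,
               if (tab$two_regime[1L]) "two_regime" else "single_regime")
})
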