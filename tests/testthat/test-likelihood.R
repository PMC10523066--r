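test_that("kernel reproduces hand-computed worked examples", {
  ## complete detection: likelihood is just the survival run
  expect_equal(pradel_loglik(c(.5, .5), c(.3, .7), c(1, 1, 1), c(1, 1, 1)),
               log(0.25), tolerance = 1e-12)
  ## one missed interior detection at p = 0.5
  expect_equal(pradel_loglik(c(.8, .8), c(.3, .7), c(1, .5, 1), c(1, 0, 1)),
               log(0.8 * 0.5 * 0.8), tolerance = 1e-12)
})

test_that("recursions equal the unrolled latent-interval oracle (T <= 6)", {
  set.seed(42)
  worst <- 0
  for (Tn in 2:6) {
    hs <- all_histories(Tn)
    for (draw in 1:3) {
      phi <- runif(Tn - 1, 0.05, 0.95)
      gam <- runif(Tn - 1, 0.05, 0.95)
      p <- runif(Tn, 0.05, 0.95)
      for (r in seq_len(nrow(hs))) {
        a <- pradel_loglik(phi, gam, p, hs[r, ])
        b <- unrolled_pradel(phi, gam, p, hs[r, ])
        worst <- max(worst, abs(a - b))
        expect_true(a <= 0)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("compiled total equals the summed R reference kernel", {
  h <- small_histories(n = 40, Tn = 7, me = 4L)
  sp <- model_spec(parameter_structure("phi", c("time", "size", "range:me", "range")),
                   parameter_structure("gamma", c("time", "size")),
                   parameter_structure("p", c("time", "size")))
  d <- build_design(sp, h)
  set.seed(8)
  b <- rnorm(d$k, 0, 0.4)
  llC <- total_loglik(d, b, h, condition_on_detection = FALSE)

  Tn <- ncol(h$ch)
  kphi <- sum(startsWith(d$par_names, "phi."))
  kgam <- sum(startsWith(d$par_names, "gamma."))
  probs <- function(Xcov, bt, bc, no) {
    eta <- matrix(bt, nrow(h$ch), no, byrow = TRUE) +
      matrix(Xcov %*% bc, ncol = no, byrow = TRUE)
    plogis(pmin(pmax(eta, -15), 15))
  }
  phi <- probs(d$Xphi, b[1:(Tn - 1)], b[Tn:(kphi)], Tn - 1)
  gam <- probs(d$Xgam, b[kphi + 1:(Tn - 1)], b[(kphi + Tn):(kphi + kgam)], Tn - 1)
  pdet <- probs(d$Xp, b[kphi + kgam + 1:Tn], b[(kphi + kgam + Tn + 1):d$k], Tn)
  llR <- sum(vapply(seq_len(nrow(h$ch)), function(i)
    pradel_loglik(phi[i, ], gam[i, ], pdet[i, ], h$ch[i, ]), numeric(1)))
  expect_equal(llC, llR, tolerance = 1e-9)
})

test_that("conditional likelihood is a proper distribution over histories", {
  ## single genus, all observable histories: probabilities must sum to 1
  Tn <- 5L
  st <- make_stage_table(Tn, 3L)
  hs <- all_histories(Tn)
  sp <- model_spec(parameter_structure("phi", c("size", "range")),
                   parameter_structure("gamma", character(0)),
                   parameter_structure("p", "size"))
  set.seed(4)
  for (draw in 1:3) {
    b <- rnorm(6, 0, 0.6)   # phi: int+size+range; gamma: int; p: int+size
    total <- 0
    for (r in seq_len(nrow(hs))) {
      h1 <- capture_history_set(matrix(hs[r, ], 1), z_size = 0.7,
                                z_range = matrix(rnorm(Tn, 0, 0) + 0.3, 1),
                                genus = "g", class_name = "X",
                                stage_table = st, window = seq_len(Tn))
      total <- total + exp(total_loglik(sp, b, h1))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("total log-likelihood is additive and exchangeable", {
  h <- small_histories(n = 12, Tn = 6, me = 4L)
  sp <- model_spec(parameter_structure("phi", c("time", "size")),
                   parameter_structure("gamma", "time"),
                   parameter_structure("p", "time"))
  d <- build_design(sp, h)
  set.seed(1)
  b <- rnorm(d$k, 0, 0.3)
  ll_all <- total_loglik(d, b, h)
  ## single history equals its own contribution; duplication doubles it
  sub1 <- capture_history_set(h$ch[1, , drop = FALSE], h$z_size[1],
                              h$z_range[1, , drop = FALSE], h$genus[1],
                              h$class_name, h$stage_table, h$window)
  dup <- capture_history_set(h$ch[c(1, 1), ], h$z_size[c(1, 1)],
                             h$z_range[c(1, 1), ], c("a", "b"),
                             h$class_name, h$stage_table, h$window)
  expect_equal(total_loglik(sp, b, dup), 2 * total_loglik(sp, b, sub1),
               tolerance = 1e-10)
  ## permutation invariance
  perm <- sample(nrow(h$ch))
  hp <- capture_history_set(h$ch[perm, ], h$z_size[perm], h$z_range[perm, ],
                            h$genus[perm], h$class_name, h$stage_table,
                            h$window)
  expect_equal(total_loglik(sp, b, hp), ll_all, tolerance = 1e-10)
  expect_lt(ll_all, 0)
})

test_that("analytic gradient matches numerical differentiation", {
  h <- small_histories(n = 25, Tn = 6, me = 4L)
  sp <- model_spec(parameter_structure("phi", c("time", "size", "range", "range:me")),
                   parameter_structure("gamma", c("time", "size")),
                   parameter_structure("p", c("time", "size")))
  d <- build_design(sp, h)
  fl <- paleoCMR:::first_last(h$ch)
  set.seed(6)
  b <- rnorm(d$k, 0, 0.4)
  for (cond in c(FALSE, TRUE)) {
    got <- paleoCMR:::design_nll(b, d, h, fl, TRUE, cond)
    num <- pracma::grad(function(x)
      paleoCMR:::design_nll(x, d, h, fl, FALSE, cond)$nll, b)
    expect_lt(max(abs(got$grad - num)), 1e-6)
  }
  ## detection fixed at 1 (complete histories)
  keep <- rowSums(h$ch) == (fl$last - fl$first + 1L)
  if (sum(keep) >= 3) {
    hc <- capture_history_set(h$ch[keep, , drop = FALSE], h$z_size[keep],
                              h$z_range[keep, , drop = FALSE], h$genus[keep],
                              h$class_name, h$stage_table, h$window)
    dpf <- build_design(model_spec(parameter_structure("phi", "time"),
                                   parameter_structure("gamma", "time"),
                                   parameter_structure("p", "time")),
                        hc, p_fixed = 1)
    flc <- paleoCMR:::first_last(hc$ch)
    b2 <- rnorm(dpf$k, 0, 0.3)
    got <- paleoCMR:::design_nll(b2, dpf, hc, flc, TRUE, TRUE)
    num <- pracma::grad(function(x)
      paleoCMR:::design_nll(x, dpf, hc, flc, FALSE, TRUE)$nll, b2)
    expect_lt(max(abs(got$grad - num)), 1e-6)
  }
})
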