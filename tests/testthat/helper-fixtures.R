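## Shared helpers: small simulated datasets and an independent latent-interval
## expansion of the Pradel kernel used as the likelihood oracle.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

## small history set built from the truth log of a seeded simulation
small_histories <- function(n = 60, Tn = 8, me = 5L, seed = 3) {
  cfg <- sim_config(n_genera = n, stage_table = make_stage_table(Tn, me),
                    seed = seed)
  sim <- simulate_fossil_record(cfg, emit_occurrences = FALSE)
  truth_histories(sim)
}

## Independent oracle for the per-history Pradel kernel: explicit sum over
## latent origination occasion a <= f and extinction occasion b >= l of
## entry weight (gamma chain) x survival run (phi chain, with death after b)
## x detection outcomes over [a, b]. Never uses the xi/chi recursions.
unrolled_pradel <- function(phi, gamma, p, history) {
  Tn <- length(history)
  f <- which(history > 0)[1L]
  l <- max(which(history > 0))
  total <- 0
  for (a in seq_len(f)) {
    entry <- if (a == 1L) {
      if (f > 1L) prod(gamma[seq(2L, f) - 1L]) else 1
    } else {
      (1 - gamma[a - 1L]) * (if (a < f) prod(gamma[seq(a + 1L, f) - 1L]) else 1)
    }
    for (b in seq(l, Tn)) {
      surv <- if (b > f) prod(phi[f:(b - 1L)]) else 1
      death <- if (b < Tn) 1 - phi[b] else 1
      det <- 1
      for (t in a:b) {
        det <- det * if (history[t] > 0) p[t] else 1 - p[t]
      }
      total <- total + entry * surv * death * det
    }
  }
  log(total)
}

## all 0/1 detection vectors of length Tn with at least one detection
all_histories <- function(Tn) {
  m <- as.matrix(expand.grid(rep(list(0:1), Tn)))
  m[rowSums(m) > 0, , drop = FALSE]
}
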