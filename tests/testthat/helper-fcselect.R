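# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately naive (loops, dense grids, explicit refits) and
# never call the code paths they check.

# A seeded cohort with planted diagnosis and site-linked connections.
make_planted_cohort <- function(n = 120, p = 300, n_diag = 10, n_site = 20,
                                effect = 1, seed = 101) {
  attrs <- generate_attributes(n, asd_fraction = 0.5, seed = seed)
  truth <- default_ground_truth(p, n_diagnosis_fc = n_diag,
                                n_site_fc = n_site, effect_size = effect,
                                seed = seed + 1)
  cohort <- generate_fc_cohort(attrs, p, truth, seed = seed + 2)
  list(attrs = attrs, fc = cohort$fc, truth = cohort$truth)
}

# A cohort with no planted structure at all.
make_noise_cohort <- function(n = 60, p = 100, seed = 301) {
  attrs <- generate_attributes(n, asd_fraction = 0.5, seed = seed)
  truth <- ground_truth(p, diagnosis_fc_indices = integer(),
                        nuisance_map = list(), noise_sd = 0.1)
  cohort <- generate_fc_cohort(attrs, p, truth, seed = seed + 2)
  list(attrs = attrs, fc = cohort$fc, truth = truth)
}

# Reduced protocol for fast unit tests.
small_plan <- function(seed = 7, n_outer = 3, n_inner = 3,
                       lambdas = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  fs_plan(n_outer = n_outer, n_inner = n_inner,
          grid = lambda_grid(lambdas), seed = seed)
}

# Dense two-stage grid search over the soft threshold: coarse pass, then a
# 1e-6-step refinement around the bracketing interval.
grid_project_oracle <- function(a, c) {
  ratio <- function(delta) {
    s <- sign(a) * pmax(abs(a) - delta, 0)
    sn <- sqrt(sum(s^2))
    if (sn == 0) return(Inf)
    sum(abs(s)) / sn
  }
  hi <- max(abs(a))
  coarse <- seq(0, hi, length.out = 2001)
  ok <- vapply(coarse, function(d) ratio(d) <= c, logical(1))
  first <- which(ok)[1]
  lo <- if (first > 1) coarse[first - 1] else 0
  fine <- seq(lo, coarse[first], by = 1e-6)
  ok2 <- vapply(fine, function(d) ratio(d) <= c, logical(1))
  delta <- fine[which(ok2)[1]]
  s <- sign(a) * pmax(abs(a) - delta, 0)
  s / sqrt(sum(s^2))
}

# Direct Newton solver for the penalized logistic problem restricted to a
# fixed feature set with fixed per-weight precisions.
newton_logistic_oracle <- function(x, y, alphas, w0 = NULL, iters = 200) {
  w <- w0 %||% rep(0, ncol(x))
  for (i in seq_len(iters)) {
    eta <- drop(x %*% w)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, y - p)) - alphas * w
    b <- pmax(p * (1 - p), 1e-10)
    h <- crossprod(x * b, x)
    diag(h) <- diag(h) + alphas
    step <- solve(h, g)
    w <- w + step
    if (max(abs(step)) < 1e-12) break
  }
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive case-control pair counting for the AUC.
pair_count_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (ca in cases) {
    for (co in controls) {
      total <- total + (ca > co) + 0.5 * (ca == co)
    }
  }
  total / (length(cases) * length(controls))
}
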