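#' Confusion-matrix summary with diagnostic odds ratio
#'
#' Cross-tabulates binary labels and predictions and reports accuracy,
#' sensitivity (TP / (TP + FN)), specificity (TN / (TN + FP)) and the
#' diagnostic odds ratio DOR = (TP * TN) / (FN * FP). When any cell is
#' zero the DOR uses the Haldane-Anscombe +0.5 continuity correction and
#' the `dor_corrected` flag is set.
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `dor`, `dor_corrected`.
#' @export
confusion_metrics <- function(labels, predictions) {
  assert_that(length(labels) > 0, "empty input")
  assert_that(length(labels) == length(predictions),
              "`labels` and `predictions` must have equal length")
  assert_that(all(labels %in% c(0, 1)) && all(predictions %in% c(0, 1)),
              "inputs must be binary 0/1")
  tp <- sum(labels == 1 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  corrected <- any(c(tp, fn, tn, fp) == 0)
  dor <- if (corrected) {
    ((tp + 0.5) * (tn + 0.5)) / ((fn + 0.5) * (fp + 0.5))
  } else {
    (tp * tn) / (fn * fp)
  }
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(labels),
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         dor = dor, dor_corrected = corrected)
}

#' Rank-based area under the ROC curve
#'
#' The Mann-Whitney formulation: the probability that a randomly drawn case
#' scores above a randomly drawn control, with ties contributing half
#' credit.
#'
#' @param scores Numeric classifier scores (larger = more case-like).
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact one-sided binomial tail probability
#'
#' Upper-tail probability of observing at least `k` successes in `n`
#' Bernoulli trials with success probability `p0` - e.g. the chance of a
#' classifier labelling `k` of `n` subjects correctly by guessing.
#'
#' @param k Observed successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @return The tail probability `P(X >= k)`.
#' @export
binomial_pvalue <- function(k, n, p0 = 0.5) {
  assert_that(p0 > 0 && p0 < 1, "`p0` must lie in (0, 1)")
  assert_that(k >= 0 && k <= n, "`k` must lie in 0..n")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Permutation test of the nested-LOOCV accuracy
#'
#' Permutes the diagnosis labels across subjects and reruns the entire
#' nested feature selection and LOOCV for each replicate - the conservative
#' scheme in which the selection also sees only permuted labels. The
#' p-value uses the add-one estimator
#' `p = (1 + #\{permuted accuracy >= observed\}) / (1 + n_perm)`.
#' Replicates dominate the cost; reduced grids or fold counts can be set
#' through `plan`.
#'
#' @inheritParams nested_loocv
#' @param n_perm Number of permutation replicates.
#' @param seed Seed for the permutations.
#' @param observed Optional precomputed observed [nested_loocv()] result.
#' @param refit_selection Set `FALSE` to freeze the observed feature sets
#'   across replicates; faster but anticonservative, since the selection has
#'   seen the true labels.
#' @return A list: `p_value`, `observed_accuracy`, `permuted_accuracy`.
#' @export
permutation_test <- function(attributes, fc, plan = fs_plan(), n_perm = 99,
                             seed = 1, observed = NULL,
                             refit_selection = TRUE) {
  assert_that(n_perm >= 1, "`n_perm` must be at least 1")
  fc <- as.matrix(fc)
  if (is.null(observed)) observed <- nested_loocv(attributes, fc, plan)
  obs_acc <- observed$metrics$accuracy
  perms <- withr::with_seed(seed, {
    replicate(n_perm, sample.int(nrow(fc)), simplify = FALSE)
  })
  perm_acc <- map_dbl(perms, function(ord) {
    perm_attr <- attributes
    perm_attr$diagnosis <- attributes$diagnosis[ord]
    if (refit_selection) {
      nested_loocv(perm_attr, fc, plan)$metrics$accuracy
    } else {
      labels <- perm_attr$diagnosis
      preds <- integer(nrow(fc))
      for (g in seq_len(plan$n_outer)) {
        sel <- observed$feature_sets[[g]]
        z_all <- project_features(fc, sel)
        for (s in which(observed$outer_folds == g)) {
          model <- slr_fit(z_all[-s, , drop = FALSE], labels[-s])
          preds[s] <- wls_score(model, z_all[s, , drop = FALSE])$label
        }
      }
      mean(preds == labels)
    }
  })
  list(p_value = (1 + sum(perm_acc >= obs_acc)) / (1 + n_perm),
       observed_accuracy = obs_acc,
       permuted_accuracy = perm_acc)
}

#' Cross-disorder generalization of a classifier's WLS scores
#'
#' For each dataset, compares the WLS distributions of the disorder and
#' control groups with the two-sample Kolmogorov-Smirnov test and computes
#' the disorder-vs-control AUC; KS p-values are corrected across datasets by
#' the Benjamini-Hochberg procedure. The exact KS null distribution is used
#' when both groups have fewer than 25 subjects, the asymptotic one
#' otherwise.
#'
#' @param wls_by_group Named list; each element is a dataset given as a list
#'   with numeric `disorder` and `control` WLS vectors.
#' @return Tibble with one row per dataset: group sizes, `auc`,
#'   `ks_statistic`, `p_value`, `p_adjusted`.
#' @export
disorder_generalization <- function(wls_by_group) {
  assert_that(length(wls_by_group) > 0, "no datasets supplied")
  rows <- imap(wls_by_group, function(grp, name) {
    d <- grp$disorder
    ctrl <- grp$control
    assert_that(length(d) > 0 && length(ctrl) > 0,
                "each dataset needs both groups")
    if (length(d) < 3 || length(ctrl) < 3)
      warn(sprintf("dataset `%s` has fewer than 3 subjects in a group", name))
    exact <- length(d) < 25 && length(ctrl) < 25
    ks <- suppressWarnings(ks.test(d, ctrl, exact = exact))
    tibble(dataset = name,
           n_disorder = length(d), n_control = length(ctrl),
           auc = roc_auc(c(d, ctrl),
                         c(rep(1, length(d)), rep(0, length(ctrl)))),
           ks_statistic = unname(ks$statistic),
           p_value = ks$p.value)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
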