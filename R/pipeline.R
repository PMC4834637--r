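#' The sparseness-parameter grid of the nested feature selection
#'
#' All pairs (lambda1, lambda2) with `lambda1 <= lambda2`, each ranging over
#' 0.1 to 0.9 in steps of 0.1 - 45 combinations in total.
#'
#' @param values Grid values for each parameter.
#' @return Tibble with columns `lambda1`, `lambda2`.
#' @export
lambda_grid <- function(values = seq(0.1, 0.9, by = 0.1)) {
  g <- expand.grid(lambda1 = values, lambda2 = values)
  as_tibble(g[g$lambda1 <= g$lambda2 + 1e-12, c("lambda1", "lambda2")])
}

#' Plan for the 9 x 9 nested feature-selection + LOOCV protocol
#'
#' @param n_outer,n_inner Numbers of outer and inner stratified folds.
#' @param grid Sparseness grid from [lambda_grid()].
#' @param seed Integer seed governing every fold split.
#' @param q Number of canonical components per fit (default `min(p1, p2)`).
#' @param scca_max_iter,scca_tol Alternation controls passed to [scca_fit()].
#' @return An object of class `fc_fs_plan`.
#' @export
fs_plan <- function(n_outer = 9, n_inner = 9, grid = lambda_grid(),
                    seed = 1, q = NULL, scca_max_iter = 200,
                    scca_tol = 1e-6) {
  assert_that(n_outer >= 2 && n_inner >= 2, "need at least 2 folds")
  structure(list(n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner),
                 grid = grid, seed = as.integer(seed), q = q,
                 scca_max_iter = scca_max_iter, scca_tol = scca_tol),
            class = "fc_fs_plan")
}

site_of <- function(attributes) {
  m <- attribute_matrix(attributes)
  c("A", "B", "C")[max.col(m[, c("site_a", "site_b", "site_c"), drop = FALSE],
                           ties.method = "first")]
}

#' Stratified k-fold assignment balanced over diagnosis, sex and site
#'
#' Subjects are grouped into (diagnosis, sex, site) cells; each cell is
#' shuffled under the seed and dealt round-robin onto the folds, with the
#' starting fold rotating across cells so remainders spread evenly. Within
#' every cell the per-fold counts differ by at most one.
#'
#' @param attributes Attribute table with the ten [attribute_columns()].
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per subject.
#' @export
stratified_kfold <- function(attributes, k = 9, seed = 1) {
  n <- nrow(attributes)
  assert_that(k <= n, "`k` cannot exceed the number of subjects")
  key <- paste(attributes$diagnosis, attributes$sex, site_of(attributes),
               sep = "|")
  folds <- integer(n)
  offset <- 0L
  withr::with_seed(seed, {
    for (cell in sort(unique(key))) {
      members <- which(key == cell)
      members <- members[sample.int(length(members))]
      folds[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
      offset <- (offset + length(members)) %% k
    }
  })
  folds
}

#' Inner-loop nested feature selection on a training cohort
#'
#' Splits the training cohort into `n_inner` stratified folds; for every
#' fold, the remaining subjects are standardized and a sparse CCA is fitted
#' at each grid combination. Features tied to diagnostic canonical variables
#' are accumulated by [diagnostic_feature_union()] semantics across all
#' `n_inner x nrow(grid)` fits.
#'
#' @param attributes Attribute table of the training cohort only.
#' @param fc Connectivity matrix of the training cohort only.
#' @param plan An [fs_plan()].
#' @param seed Seed for the inner fold split.
#' @return An `fc_feature_selection` over the connectivity indices.
#' @export
inner_feature_selection <- function(attributes, fc, plan, seed = plan$seed) {
  fc <- as.matrix(fc)
  x1 <- attribute_matrix(attributes)
  p1 <- ncol(x1)
  p2 <- ncol(fc)
  q <- plan$q %||% min(p1, p2)
  inner <- stratified_kfold(attributes, plan$n_inner, seed)
  xi <- numeric(p2)
  n_compliant <- 0L
  n_fits <- 0L
  for (f in seq_len(plan$n_inner)) {
    rows <- which(inner != f)
    cohort <- standardize_cohort(x1, fc, rows = rows)
    s <- crossprod(cohort$x1, cohort$x2)
    for (r in seq_len(nrow(plan$grid))) {
      c1 <- lambda_bound(plan$grid$lambda1[r], p1)
      c2 <- lambda_bound(plan$grid$lambda2[r], p2)
      core <- .scca_core_cpp(s, c1, c2, as.integer(q),
                             as.integer(plan$scca_max_iter), plan$scca_tol,
                             20L)
      n_fits <- n_fits + 1L
      dc <- which(core$v1[1, ] != 0 &
                    colSums(abs(core$v1[-1, , drop = FALSE])) == 0)
      if (length(dc) == 0) next
      n_compliant <- n_compliant + 1L
      xi <- xi + rowSums(abs(core$v2[, dc, drop = FALSE]))
    }
  }
  feature_selection(xi, n_fits = n_fits, n_compliant = n_compliant)
}

#' Nested 9 x 9 feature selection with leave-one-out cross-validation
#'
#' Each outer fold serves as a testing pool whose feature set is selected by
#' [inner_feature_selection()] on the other folds only - the held-out
#' subjects never enter standardization, sparse CCA, or relevance
#' determination for their own predictions. Every subject is then scored by
#' an ARD sparse logistic model trained on all other subjects restricted to
#' its pool's feature set; subjects of the same pool share that reduced
#' feature set.
#'
#' @param attributes Attribute table (N rows).
#' @param fc Connectivity matrix (N x p2).
#' @param plan An [fs_plan()].
#' @return An object of class `fc_loocv`: `per_subject` tibble (WLS,
#'   probability, predicted label, active-feature count per LOOCV
#'   iteration), `feature_sets` per outer fold, `outer_folds`, `metrics`
#'   (confusion summary) and `auc`.
#' @export
nested_loocv <- function(attributes, fc, plan = fs_plan()) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  assert_that(nrow(attributes) == n, "`attributes` and `fc` must share rows")
  outer <- stratified_kfold(attributes, plan$n_outer, plan$seed)
  labels <- attributes$diagnosis
  feature_sets <- vector("list", plan$n_outer)
  rows_out <- vector("list", n)
  for (g in seq_len(plan$n_outer)) {
    train <- which(outer != g)
    feature_sets[[g]] <- inner_feature_selection(
      attributes[train, , drop = FALSE], fc[train, , drop = FALSE], plan,
      seed = plan$seed + g)
    sel <- feature_sets[[g]]
    z_all <- project_features(fc, sel)
    for (s in which(outer == g)) {
      model <- slr_fit(z_all[-s, , drop = FALSE], labels[-s])
      score <- wls_score(model, z_all[s, , drop = FALSE])
      rows_out[[s]] <- tibble(
        subject = s, outer_fold = g, label = labels[s],
        wls = score$wls, probability = score$probability,
        predicted = score$label,
        n_active = length(model$active_set),
        n_selected = sel$m)
    }
  }
  per_subject <- bind_rows(rows_out) %>% arrange(.data$subject)
  structure(list(per_subject = per_subject,
                 feature_sets = feature_sets,
                 outer_folds = outer,
                 metrics = confusion_metrics(per_subject$label,
                                             per_subject$predicted),
                 auc = roc_auc(per_subject$wls, per_subject$label),
                 plan = plan),
            class = "fc_loocv")
}

#' @export
print.fc_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "Nested FS + LOOCV over %d subjects: accuracy %.1f%%, sens %.1f%%, spec %.1f%%, AUC %.3f\n",
    nrow(x$per_subject), 100 * m$accuracy, 100 * m$sensitivity,
    100 * m$specificity, x$auc))
  cat(sprintf("mean active features per iteration: %.1f\n",
              mean(x$per_subject$n_active)))
  invisible(x)
}

#' @rdname nested_loocv
#' @param x An `fc_loocv` object.
#' @param ... Unused.
#' @method tidy fc_loocv
#' @export
tidy.fc_loocv <- function(x, ...) x$per_subject

#' @rdname nested_loocv
#' @method glance fc_loocv
#' @export
glance.fc_loocv <- function(x, ...) {
  bind_cols(x$metrics,
            tibble(auc = x$auc,
                   mean_active = mean(x$per_subject$n_active)))
}

#' Train the final classifier on the whole cohort
#'
#' Combines the feature sets of all outer folds (summing their accumulation
#' vectors, i.e. the union of supports) and fits the ARD sparse logistic
#' model on every subject restricted to that union. The result can be
#' serialized and applied to external cohorts without retuning.
#'
#' @inheritParams nested_loocv
#' @param loocv Optional completed [nested_loocv()] result whose per-fold
#'   feature sets are reused; otherwise the nested selection is recomputed.
#' @return An object of class `fc_final_model`: the fitted `model`, the
#'   union `selection`, and the expected connectivity length `n_fc`.
#' @export
train_final <- function(attributes, fc, plan = fs_plan(), loocv = NULL) {
  fc <- as.matrix(fc)
  if (is.null(loocv)) loocv <- nested_loocv(attributes, fc, plan)
  xi <- reduce(map(loocv$feature_sets, "xi"), `+`)
  selection <- feature_selection(xi)
  z <- project_features(fc, selection)
  model <- slr_fit(z, attributes$diagnosis)
  structure(list(model = model, selection = selection, n_fc = ncol(fc),
                 loocv = loocv),
            class = "fc_final_model")
}

#' @export
print.fc_final_model <- function(x, ...) {
  cat(sprintf(
    "Final classifier: %d active of %d union features (of %d connections)\n",
    length(x$model$active_set), x$selection$m, x$n_fc))
  invisible(x)
}

#' Indices of the connectivity features used by the final classifier
#' @param final An `fc_final_model`.
#' @return Integer indices into the original connectivity vector.
#' @export
final_active_fc <- function(final) {
  final$selection$selected_indices[final$model$active_set]
}

#' Apply a trained classifier to an external cohort
#'
#' No refitting and no re-selection: the stored feature indices and training
#' standardization statistics are applied as-is to the new connectivity
#' matrix, which must share the index map (same number of connections in the
#' same order).
#'
#' @param final An `fc_final_model` (or one loaded by [slr_load()]).
#' @param fc External connectivity matrix, subjects x connections.
#' @return Tibble of per-subject scores (`wls`, `probability`, `label`).
#' @export
apply_to_cohort <- function(final, fc) {
  fc <- as.matrix(fc)
  assert_that(ncol(fc) == final$n_fc,
              sprintf("connectivity index-map mismatch: got %d columns, expected %d",
                      ncol(fc), final$n_fc))
  wls_score(final$model, project_features(fc, final$selection))
}
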