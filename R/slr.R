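#' Sparse logistic regression with automatic relevance determination
#'
#' Fits a logistic classifier whose weights carry independent Gaussian
#' priors N(0, 1/alpha_i), estimated by hierarchical-Bayes marginal-
#' likelihood (evidence) maximization under the Laplace approximation.
#' The model is built constructively from the bias-only configuration: at
#' each step the per-feature sparsity statistics (s_i, q_i) of the locally
#' Gaussianized likelihood decide whether a feature enters the model, has
#' its relevance precision re-estimated (`alpha_i = s_i^2 / (q_i^2 - s_i)`),
#' or is deleted because its evidence-optimal precision is infinite - the
#' prior peaks sharply at zero and the weight is set exactly to 0. Features
#' are standardized internally with training statistics that are stored in
#' the model and applied to any subsequent input. The bias term rides on an
#' augmented constant input with a fixed broad prior and is never pruned.
#'
#' @param z Numeric matrix, subjects x features (zero columns allowed; a
#'   0-column matrix yields a bias-only model).
#' @param labels Binary 0/1 outcome; both classes must be present.
#' @param max_iter Cap on add / re-estimate / delete iterations.
#' @param tol Convergence tolerance on the relative alpha change.
#' @param prune_threshold Precision above which a weight is pruned to zero.
#' @param alpha_bias Fixed broad precision of the bias prior.
#' @param max_newton Newton steps per Laplace refit.
#' @param add_gain_tol Smallest evidence gain that justifies adding a
#'   feature. The default `log(m)` is the Occam penalty of a `1/m` prior
#'   inclusion probability per feature, which keeps the expected number of
#'   spurious inclusions of order one however large the candidate pool.
#' @return An object of class `fc_slr`: `weights` (standardized scale, bias
#'   last), `alphas`, `active_set` (feature indices with surviving weights),
#'   standardization statistics, and a `fit_log`.
#' @export
slr_fit <- function(z, labels, max_iter = 500, tol = 1e-4,
                    prune_threshold = 1e8, alpha_bias = 1e-6,
                    max_newton = 25, add_gain_tol = NULL) {
  z <- as.matrix(z)
  labels <- as.numeric(labels)
  assert_that(all(labels %in% c(0, 1)), "`labels` must be 0/1")
  assert_that(length(unique(labels)) == 2, "both classes must be present")
  assert_that(nrow(z) == length(labels), "`z` rows must match `labels`")
  m <- ncol(z)
  ctr <- if (m > 0) colMeans(z) else numeric(0)
  scl <- if (m > 0) apply(z, 2, sd) else numeric(0)
  scl[!is.finite(scl) | scl == 0] <- 1
  zs <- if (m > 0) sweep(sweep(z, 2, ctr), 2, scl, "/") else z
  phi <- cbind(zs, 1)
  add_gain_tol <- add_gain_tol %||% log(max(m, 2))
  fit <- .ard_logistic_cpp(phi, labels, as.integer(m), alpha_bias,
                           as.integer(max_iter), tol, prune_threshold,
                           as.integer(max_newton), add_gain_tol)
  # a hit iteration cap is recorded in fit_log$converged rather than warned
  structure(list(
    weights = drop(fit$weights), alphas = drop(fit$alphas),
    active_set = as.integer(setdiff(drop(fit$active), m + 1L)),
    m = m, center = ctr, scale = scl,
    n_case = sum(labels == 1), n_control = sum(labels == 0),
    fit_log = list(iterations = fit$iterations,
                   converged = fit$converged,
                   evidence = fit$evidence)),
    class = "fc_slr")
}

#' @export
print.fc_slr <- function(x, ...) {
  cat(sprintf("ARD sparse logistic model: %d of %d features active (bias %.3f)\n",
              length(x$active_set), x$m, x$weights[x$m + 1]))
  invisible(x)
}

#' Weighted linear summation score of a fitted classifier
#'
#' Standardizes the input with the training statistics stored in the model,
#' augments it with the constant input, and evaluates the discriminant
#' `wls = w' z_hat`. A subject with positive WLS is labelled a case (1),
#' negative a control (0); the class probability is `plogis(wls)`.
#'
#' @param model An `fc_slr` model.
#' @param z Feature vector of length `m`, or a subjects x `m` matrix.
#' @return A tibble with columns `wls`, `probability`, `label`.
#' @export
wls_score <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  assert_that(ncol(z) == model$m,
              sprintf("`z` has %d features; model expects %d", ncol(z), model$m))
  zs <- if (model$m > 0)
    sweep(sweep(z, 2, model$center), 2, model$scale, "/") else z
  wls <- drop(cbind(zs, 1) %*% model$weights)
  tibble(wls = wls, probability = plogis(wls),
         label = as.integer(wls > 0))
}

#' @export
predict.fc_slr <- function(object, newdata, ...) {
  wls_score(object, newdata)
}

#' @rdname slr_fit
#' @param x An `fc_slr` object.
#' @param ... Unused.
#' @method tidy fc_slr
#' @export
tidy.fc_slr <- function(x, ...) {
  term <- c(paste0("z", seq_len(x$m)), "(bias)")
  tibble(term = term, estimate = x$weights, alpha = x$alphas,
         active = c(seq_len(x$m) %in% x$active_set, TRUE))
}

#' @rdname slr_fit
#' @method glance fc_slr
#' @export
glance.fc_slr <- function(x, ...) {
  tibble(n_features = x$m, n_active = length(x$active_set),
         iterations = x$fit_log$iterations,
         converged = x$fit_log$converged,
         evidence = x$fit_log$evidence)
}

#' Serialize a fitted classifier to JSON
#'
#' Stores weights, relevance precisions, active indices, standardization
#' statistics and the connectivity index map (when present) at full decimal
#' precision, so a trained classifier can be re-applied to external cohorts
#' bit-reproducibly.
#'
#' @param model An `fc_slr` model or an `fc_final_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
slr_save <- function(model, path) {
  payload <- if (inherits(model, "fc_final_model")) {
    list(kind = "fc_final_model",
         model = unclass(model$model),
         selected_indices = model$selection$selected_indices,
         xi = model$selection$xi,
         n_fc = model$n_fc)
  } else {
    list(kind = "fc_slr", model = unclass(model))
  }
  payload$model$fit_log <- NULL
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a classifier serialized by [slr_save()]
#' @param path JSON path.
#' @return An `fc_slr` or `fc_final_model` object.
#' @export
slr_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(ml) {
    ml$weights <- as.numeric(ml$weights)
    ml$alphas <- as.numeric(ml$alphas)  # "Inf" strings back to numeric
    ml$active_set <- as.integer(ml$active_set)
    ml$m <- as.integer(ml$m)
    ml$center <- as.numeric(ml$center %||% numeric(0))
    ml$scale <- as.numeric(ml$scale %||% numeric(0))
    ml$fit_log <- list(iterations = NA_integer_, converged = NA,
                       evidence = NA_real_)
    structure(ml, class = "fc_slr")
  }
  if (identical(payload$kind, "fc_final_model")) {
    structure(list(model = rebuild(payload$model),
                   selection = feature_selection(as.numeric(payload$xi)),
                   n_fc = as.integer(payload$n_fc)),
              class = "fc_final_model")
  } else {
    rebuild(payload$model)
  }
}
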