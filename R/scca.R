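#' Standardize an attribute / connectivity cohort on training rows
#'
#' Centers every column to mean zero and scales it to unit variance using
#' statistics learned on the training rows only, so held-out rows can be
#' mapped through the same transform without leakage. Constant training
#' columns (e.g. a site flag in single-site training data) keep scale 1 and
#' are flagged; they end up identically zero and therefore inert.
#'
#' @param x1 Attribute block: data frame with the ten [attribute_columns()]
#'   or a numeric matrix in that column order.
#' @param x2 Connectivity block, subjects x connections.
#' @param rows Training row indices used to learn the statistics (default:
#'   all rows).
#' @return An object of class `fc_cohort` holding the standardized training
#'   blocks, the learned centers/scales, and the constant-column flags.
#' @export
standardize_cohort <- function(x1, x2, rows = NULL) {
  if (is.data.frame(x1)) x1 <- attribute_matrix(x1)
  x2 <- as.matrix(x2)
  assert_that(nrow(x1) == nrow(x2), "`x1` and `x2` must share rows")
  rows <- rows %||% seq_len(nrow(x1))
  std <- function(x) {
    ctr <- colMeans(x[rows, , drop = FALSE])
    scl <- apply(x[rows, , drop = FALSE], 2, sd)
    const <- !is.finite(scl) | scl == 0
    scl[const] <- 1
    list(x = sweep(sweep(x[rows, , drop = FALSE], 2, ctr), 2, scl, "/"),
         center = ctr, scale = scl, constant = const)
  }
  s1 <- std(x1)
  s2 <- std(x2)
  structure(list(x1 = s1$x, x2 = s2$x,
                 center1 = s1$center, scale1 = s1$scale,
                 center2 = s2$center, scale2 = s2$scale,
                 constant1 = s1$constant, constant2 = s2$constant,
                 rows = rows),
            class = "fc_cohort")
}

#' Projection onto the unit L2 ball intersected with an L1 bound
#'
#' Soft-thresholds `a` with the smallest threshold (found by bisection) such
#' that the L2-normalized result has L1 norm at most `c`, the elementary step
#' of the sparse CCA alternation. Feasibility requires `c >= 1` because any
#' unit-L2 vector has L1 norm at least 1; at `c = 1` the solution is a single
#' nonzero at the largest-magnitude coordinate.
#'
#' @param a Numeric vector (not all zero for a meaningful result).
#' @param c L1 bound, >= 1.
#' @return Unit-L2 vector with `sum(abs(v)) <= c`; the all-zero input returns
#'   the zero vector with attribute `all_zero = TRUE`.
#' @export
l1_l2_project <- function(a, c) {
  assert_that(c >= 1, "`c` must be at least 1")
  n2 <- sqrt(sum(a^2))
  if (n2 == 0) {
    out <- a
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  v <- a / n2
  if (sum(abs(v)) <= c) return(v)
  lo <- 0
  hi <- max(abs(a))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- sign(a) * pmax(abs(a) - mid, 0)
    sn <- sqrt(sum(s^2))
    if (sn == 0 || sum(abs(s)) / sn <= c) hi <- mid else lo <- mid
  }
  s <- sign(a) * pmax(abs(a) - hi, 0)
  s[abs(s) <= 1e-12 * max(abs(s))] <- 0  # machine-noise survivors are not support
  sn <- sqrt(sum(s^2))
  if (sn == 0) {
    out <- numeric(length(a))
    i <- which.max(abs(a))
    out[i] <- sign(a[i])
    return(out)
  }
  s / sn
}

#' Map a sparseness parameter to its L1 bound
#'
#' `lambda` in (0, 1] interpolates from the maximally sparse bound `c = 1`
#' (single nonzero) to the unconstrained bound `sqrt(p)`:
#' `c = max(1, lambda * sqrt(p))`.
#'
#' @param lambda Sparseness parameter in (0, 1].
#' @param p Vector dimension.
#' @return The L1 bound.
#' @export
lambda_bound <- function(lambda, p) {
  assert_that(lambda > 0 && lambda <= 1, "`lambda` must lie in (0, 1]")
  max(1, lambda * sqrt(p))
}

#' L1-regularized sparse canonical correlation analysis
#'
#' Fits all `q = min(p1, p2)` canonical components between the standardized
#' attribute block and connectivity block by alternating L1-bounded
#' projections on the cross-product matrix `S = X1' X2`, with rank-1
#' deflation between components. Each projection vector has unit L2 norm and
#' L1 norm at most `max(1, lambda * sqrt(p))`.
#'
#' @param cohort An `fc_cohort` from [standardize_cohort()], or a list with
#'   standardized matrices `x1`, `x2`.
#' @param lambda1,lambda2 Sparseness of the attribute-side and
#'   connectivity-side projections, each in (0, 1].
#' @param q Number of components (default `min(p1, p2)`).
#' @param max_iter Alternation cap per component.
#' @param tol Relative objective-change convergence tolerance.
#' @return An object of class `fc_scca`: projection matrices `v1`
#'   (p1 x q), `v2` (p2 x q), `canonical_values`, the bounds used, and
#'   per-component iteration counts.
#' @export
scca_fit <- function(cohort, lambda1, lambda2, q = NULL, max_iter = 200,
                     tol = 1e-6) {
  x1 <- cohort$x1
  x2 <- cohort$x2
  p1 <- ncol(x1)
  p2 <- ncol(x2)
  q <- q %||% min(p1, p2)
  c1 <- lambda_bound(lambda1, p1)
  c2 <- lambda_bound(lambda2, p2)
  s <- crossprod(x1, x2)
  core <- .scca_core_cpp(s, c1, c2, as.integer(q), as.integer(max_iter),
                         tol, 20L)
  if (!all(core$converged))
    warn(sprintf("%d sparse-CCA component(s) hit the iteration cap; last iterate kept",
                 sum(!core$converged)))
  structure(list(v1 = core$v1, v2 = core$v2,
                 canonical_values = drop(core$canonical_values),
                 lambda1 = lambda1, lambda2 = lambda2, c1 = c1, c2 = c2,
                 q = q, iterations = drop(core$iterations),
                 converged = core$converged),
            class = "fc_scca")
}

#' @export
print.fc_scca <- function(x, ...) {
  cat(sprintf("Sparse CCA fit: %d components (lambda1 = %.2f, lambda2 = %.2f)\n",
              x$q, x$lambda1, x$lambda2))
  cat("feature-side support sizes:",
      paste(colSums(x$v2 != 0), collapse = " "), "\n")
  invisible(x)
}

#' @rdname scca_fit
#' @param x An `fc_scca` object.
#' @param ... Unused.
#' @method tidy fc_scca
#' @export
tidy.fc_scca <- function(x, ...) {
  tibble(component = seq_len(x$q),
         canonical_value = x$canonical_values,
         attribute_support = colSums(x$v1 != 0),
         feature_support = colSums(x$v2 != 0),
         iterations = x$iterations)
}

#' Which components satisfy the diagnostic canonical constraint
#'
#' A component is diagnostic when its attribute-side projection loads on the
#' diagnosis column (row 1) and on nothing else; such components isolate
#' diagnosis-linked connectivity from nuisance-linked connectivity.
#'
#' @param result An `fc_scca` object.
#' @return Integer vector of diagnostic component indices (possibly empty).
#' @export
diagnostic_components <- function(result) {
  v1 <- result$v1
  which(v1[1, ] != 0 & colSums(abs(v1[-1, , drop = FALSE])) == 0)
}

#' Union of diagnosis-linked features across sparse CCA fits
#'
#' For every fit, the feature-side columns of the diagnostic components are
#' collapsed by summing absolute loadings into a nonnegative accumulation
#' vector; fits with no diagnostic component contribute nothing. Vectors are
#' summed across fits, and the selected indices are the support of the total.
#'
#' @param results A single `fc_scca` or a list of them.
#' @return An object of class `fc_feature_selection`: the accumulation
#'   vector `xi`, the ordered `selected_indices`, their count `m`, and the
#'   number of contributing (compliant) fits.
#' @export
diagnostic_feature_union <- function(results) {
  if (inherits(results, "fc_scca")) results <- list(results)
  assert_that(length(results) > 0, "`results` must contain at least one fit")
  p2 <- nrow(results[[1]]$v2)
  xi <- numeric(p2)
  compliant <- 0L
  for (res in results) {
    dc <- diagnostic_components(res)
    if (length(dc) == 0) next
    compliant <- compliant + 1L
    xi <- xi + rowSums(abs(res$v2[, dc, drop = FALSE]))
  }
  feature_selection(xi, n_fits = length(results), n_compliant = compliant)
}

#' Construct a feature selection from an accumulation vector
#'
#' @param xi Nonnegative accumulation vector over connectivity indices.
#' @param n_fits,n_compliant Bookkeeping: fits inspected / fits contributing.
#' @return An `fc_feature_selection` object.
#' @export
feature_selection <- function(xi, n_fits = NA_integer_,
                              n_compliant = NA_integer_) {
  assert_that(all(xi >= 0), "`xi` must be nonnegative")
  structure(list(xi = xi, selected_indices = which(xi > 0),
                 m = sum(xi > 0), n_fits = n_fits,
                 n_compliant = n_compliant),
            class = "fc_feature_selection")
}

#' @export
print.fc_feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d of %d connections", x$m, length(x$xi)))
  if (!is.na(x$n_fits))
    cat(sprintf(" (%d of %d fits compliant)", x$n_compliant, x$n_fits))
  cat("\n")
  invisible(x)
}

#' @rdname diagnostic_feature_union
#' @param x An `fc_feature_selection` object.
#' @param ... Unused.
#' @method tidy fc_feature_selection
#' @export
tidy.fc_feature_selection <- function(x, ...) {
  tibble(index = x$selected_indices, xi = x$xi[x$selected_indices])
}

#' Project connectivity vectors onto the selected subspace
#'
#' Keeps exactly the selected coordinates in ascending index order: for a
#' single vector `z[k] = x2[i_k]`; for a matrix, each row is projected.
#'
#' @param x2 Connectivity vector or subjects-x-connections matrix.
#' @param selection An `fc_feature_selection`.
#' @return Reduced vector of length `m`, or matrix with `m` columns.
#' @export
project_features <- function(x2, selection) {
  idx <- selection$selected_indices
  if (is.matrix(x2)) {
    assert_that(length(idx) == 0 || max(idx) <= ncol(x2),
                "selected index out of range")
    x2[, idx, drop = FALSE]
  } else {
    assert_that(length(idx) == 0 || max(idx) <= length(x2),
                "selected index out of range")
    x2[idx]
  }
}
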