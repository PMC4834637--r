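#' Annotation table of an identified connectivity set
#'
#' Loads a per-connection annotation table: the two terminal regions with
#' laterality (L / R / M for medial), intrinsic-network labels
#' (CO, DM, FP, SM, OC, CB), Brodmann areas, group-mean correlations for the
#' control (`r_td`) and case (`r_asd`) populations, and the classifier
#' weight. The bundled default transcribes the 16-connection set of the
#' published multi-site adult ASD classifier.
#'
#' @param path CSV path; NULL loads the bundled 16-connection table.
#' @return Tibble with one row per connection.
#' @export
fc_annotations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fc16_annotations.csv",
                                package = "fcselect")
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  ok <- c("L", "R", "M")
  assert_that(all(out$lat1 %in% ok) && all(out$lat2 %in% ok),
              "unknown laterality code (expected L, R or M)")
  out
}

#' Hemispheric classification of connections
#'
#' A connection with both terminals in the left hemisphere is
#' left-intra-hemispheric; both right, right-intra-hemispheric; every other
#' combination - including a medial terminal - is counted as
#' inter-hemispheric.
#'
#' @param annotations Annotation tibble as from [fc_annotations()].
#' @return Tibble with `category`, `count`, `fraction` for left-intra,
#'   right-intra and inter.
#' @export
laterality_counts <- function(annotations) {
  ok <- c("L", "R", "M")
  assert_that(all(annotations$lat1 %in% ok) && all(annotations$lat2 %in% ok),
              "unknown laterality code (expected L, R or M)")
  cls <- ifelse(annotations$lat1 == "L" & annotations$lat2 == "L",
                "left_intra",
                ifelse(annotations$lat1 == "R" & annotations$lat2 == "R",
                       "right_intra", "inter"))
  cats <- c("left_intra", "right_intra", "inter")
  counts <- vapply(cats, function(k) sum(cls == k), integer(1),
                   USE.NAMES = FALSE)
  tibble(category = cats, count = counts,
         fraction = counts / nrow(annotations))
}

#' Depletion test for a hemispheric connection category
#'
#' One-sided binomial test that a laterality category (typically
#' left-intra-hemispheric) is underrepresented: the probability of observing
#' at most the actual count under a null selection probability. The natural
#' null for intra-hemispheric categories is the share of same-hemisphere
#' pairs among all region pairs, `choose(n_hemi, 2) / choose(n_total, 2)`
#' (the default with 70 of 140 regions per hemisphere, about 0.248); a
#' symmetric-category null (1/3) is a stricter alternative - both are
#' stated because the choice is a modelling decision, not data.
#'
#' @param annotations Annotation tibble.
#' @param category One of `"left_intra"`, `"right_intra"`, `"inter"`.
#' @param null_fraction Null probability that a connection falls in the
#'   category.
#' @return One-row tibble: `observed`, `n`, `null_fraction`, `p_value`
#'   (`P(X <= observed)`).
#' @export
laterality_absence_test <- function(annotations, category = "left_intra",
                                    null_fraction =
                                      choose(70, 2) / choose(140, 2)) {
  lc <- laterality_counts(annotations)
  assert_that(category %in% lc$category, "unknown laterality category")
  observed <- lc$count[lc$category == category]
  n <- nrow(annotations)
  tibble(category = category, observed = observed, n = n,
         null_fraction = null_fraction,
         p_value = pbinom(observed, n, null_fraction))
}

#' Network enrichment of the connection terminals
#'
#' Counts how many of the `2 * nrow(annotations)` terminal regions
#' (duplicates allowed) carry the given network label and tests the count
#' against the anatomically expected fraction
#' `n_network_regions / n_total_regions` with a one-sided binomial test.
#'
#' @param annotations Annotation tibble.
#' @param network One of the network labels (e.g. `"CO"`).
#' @param n_network_regions Number of atlas regions in that network.
#' @param n_total_regions Total number of atlas regions.
#' @return One-row tibble: `observed`, `n_terminals`, `observed_fraction`,
#'   `expected_fraction`, `p_value`.
#' @export
network_enrichment <- function(annotations, network, n_network_regions,
                               n_total_regions) {
  vocab <- c("CO", "DM", "FP", "SM", "OC", "CB")
  assert_that(network %in% vocab,
              paste("unknown network; expected one of",
                    paste(vocab, collapse = ", ")))
  assert_that(n_network_regions > 0 && n_total_regions > 0,
              "region counts must be positive")
  terminals <- c(annotations$net1, annotations$net2)
  observed <- sum(terminals == network)
  p0 <- n_network_regions / n_total_regions
  tibble(network = network, observed = observed,
         n_terminals = length(terminals),
         observed_fraction = observed / length(terminals),
         expected_fraction = p0,
         p_value = binomial_pvalue(observed, length(terminals), p0))
}

#' Under- versus over-connectivity balance
#'
#' Counts connections whose case-group mean correlation is below
#' (under-connectivity) or above (over-connectivity) the control-group mean,
#' and tests the split against equal expected counts with a Pearson
#' chi-squared goodness-of-fit test (df = 1). Exact ties are excluded from
#' the test and reported separately.
#'
#' @param annotations Annotation tibble with `r_td` and `r_asd` columns.
#' @return One-row tibble: `under`, `over`, `ties`, `chi_squared`,
#'   `p_value`.
#' @export
under_over_test <- function(annotations) {
  assert_that(all(c("r_td", "r_asd") %in% names(annotations)),
              "annotations need `r_td` and `r_asd` columns")
  under <- sum(annotations$r_asd < annotations$r_td)
  over <- sum(annotations$r_asd > annotations$r_td)
  ties <- sum(annotations$r_asd == annotations$r_td)
  ct <- suppressWarnings(chisq.test(c(under, over), p = c(0.5, 0.5)))
  tibble(under = under, over = over, ties = ties,
         chi_squared = unname(ct$statistic), p_value = ct$p.value)
}

#' Pooled two-sample t-test from summary statistics
#'
#' @param mean1,sd1,n1 First group: mean, standard deviation, size.
#' @param mean2,sd2,n2 Second group.
#' @return One-row tibble: `t`, `df`, `p_value` (two-sided).
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' Distance analyses of a connectivity set
#'
#' Computes the Euclidean distance between the two terminal centroids of
#' each connection, correlates it with the group difference in connectivity
#' (`r_asd - r_td`) and with the difference in absolute strength
#' (`|r_asd| - |r_td|`), and compares the mean distances of the
#' under-connected versus over-connected subsets with a pooled two-sample
#' t-test. When centroid coordinates are unavailable, per-group summary
#' statistics can be supplied instead and only the t-test is computed.
#'
#' @param annotations Annotation tibble with centroid columns
#'   `x1, y1, z1, x2, y2, z2` (mm), or NULL when `summary` is given.
#' @param summary Optional list with elements `under` and `over`, each
#'   `c(mean, sd, n)` of the connection distances in mm.
#' @return A list with `correlations` (tibble, absent for summary input) and
#'   `group_test` (tibble from [pooled_t_summary()]).
#' @export
distance_stats <- function(annotations = NULL, summary = NULL) {
  if (!is.null(summary)) {
    u <- summary$under
    o <- summary$over
    return(list(correlations = NULL,
                group_test = pooled_t_summary(u[1], u[2], u[3],
                                              o[1], o[2], o[3])))
  }
  need <- c("x1", "y1", "z1", "x2", "y2", "z2", "r_td", "r_asd")
  assert_that(!is.null(annotations) && all(need %in% names(annotations)),
              "need centroid columns x1..z2 (or supply `summary`)")
  d <- sqrt((annotations$x1 - annotations$x2)^2 +
              (annotations$y1 - annotations$y2)^2 +
              (annotations$z1 - annotations$z2)^2)
  diff_r <- annotations$r_asd - annotations$r_td
  diff_abs <- abs(annotations$r_asd) - abs(annotations$r_td)
  ct1 <- cor.test(d, diff_r)
  ct2 <- cor.test(d, diff_abs)
  correlations <- tibble(
    contrast = c("r_asd - r_td", "|r_asd| - |r_td|"),
    r = c(unname(ct1$estimate), unname(ct2$estimate)),
    p_value = c(ct1$p.value, ct2$p.value))
  under <- d[diff_r < 0]
  over <- d[diff_r > 0]
  gt <- pooled_t_summary(mean(under), sd(under), length(under),
                         mean(over), sd(over), length(over))
  list(correlations = correlations, group_test = gt, distances = d)
}

loocv_ols_predict <- function(x, y) {
  # exact leave-one-out OLS predictions via the hat-matrix identity:
  # e_(-i) = e_i / (1 - h_ii), pred_(-i) = y_i - e_(-i)
  qx <- qr(x)
  res <- qr.resid(qx, y)
  h <- rowSums(qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]^2)
  y - res / (1 - h)
}

#' Predict a clinical domain score from a connectivity subset
#'
#' Leave-one-out prediction of a measured clinical score: for each subject,
#' an ordinary least-squares model with the selected connectivity values
#' plus age and sex (and an intercept) as explanatory variables is fitted on
#' the other subjects, and the held-out score is predicted. Agreement is
#' summarized by the Pearson correlation between measured and predicted
#' scores. Subjects with a missing score are dropped (listwise per domain).
#'
#' @param fc_subset Subjects x k matrix of the selected connectivity values.
#' @param age,sex Subject covariates.
#' @param scores Measured domain scores (NA allowed).
#' @return A list: `predictions` tibble (`subject`, `measured`,
#'   `predicted`), `pearson_r`, `p_value`, `n`.
#' @export
predict_domain_score <- function(fc_subset, age, sex, scores) {
  fc_subset <- as.matrix(fc_subset)
  keep <- which(complete.cases(fc_subset) & !is.na(scores) &
                  !is.na(age) & !is.na(sex))
  x <- cbind(1, fc_subset[keep, , drop = FALSE], age[keep], sex[keep])
  y <- scores[keep]
  assert_that(length(keep) > ncol(x) + 2,
              "need more subjects than predictors + 2")
  assert_that(sd(y) > 0, "measured scores are constant; correlation undefined")
  pred <- loocv_ols_predict(x, y)
  ct <- suppressWarnings(cor.test(y, pred))
  list(predictions = tibble(subject = keep, measured = y, predicted = pred),
       pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n = length(keep))
}

#' Bootstrap null for clinical-score prediction from random subsets
#'
#' Repeatedly draws `n_sample` connections uniformly without replacement
#' from the pool of connections never selected by the classifier, reruns the
#' leave-one-out score prediction for every clinical domain, and records the
#' maximum of the per-domain correlations. The bootstrap p-value of an
#' observed correlation is the fraction of replicates whose pooled maximum
#' reaches it.
#'
#' @param fc Full connectivity matrix, subjects x connections.
#' @param excluded_indices Connections excluded from the pool (those ever
#'   selected by the classifier).
#' @param age,sex Subject covariates.
#' @param domain_scores Data frame or matrix of domain scores, one column
#'   per domain (NA allowed; listwise deletion per domain).
#' @param observed_r Observed correlation to test.
#' @param n_boot Number of replicates (10,000 in the full analysis).
#' @param n_sample Connections drawn per replicate.
#' @param seed Integer seed.
#' @return A list: `p_value`, `observed_r`, `max_correlations` (length
#'   `n_boot`), `pool_size`.
#' @export
bootstrap_score_null <- function(fc, excluded_indices, age, sex,
                                 domain_scores, observed_r, n_boot = 10000,
                                 n_sample = 16, seed = 1) {
  fc <- as.matrix(fc)
  excluded_indices <- as.integer(excluded_indices)
  assert_that(all(excluded_indices >= 1 & excluded_indices <= ncol(fc)),
              "`excluded_indices` out of range")
  pool <- setdiff(seq_len(ncol(fc)), excluded_indices)
  assert_that(length(pool) >= n_sample,
              sprintf("fewer than %d eligible connections", n_sample))
  domain_scores <- as.data.frame(domain_scores)
  draws <- withr::with_seed(seed, {
    replicate(n_boot, sample(pool, n_sample), simplify = FALSE)
  })
  max_r <- map_dbl(draws, function(idx) {
    sub <- fc[, idx, drop = FALSE]
    rs <- map_dbl(domain_scores, function(y) {
      keep <- which(!is.na(y))
      x <- cbind(1, sub[keep, , drop = FALSE], age[keep], sex[keep])
      pred <- loocv_ols_predict(x, y[keep])
      suppressWarnings(cor(y[keep], pred))
    })
    max(rs, na.rm = TRUE)
  })
  list(p_value = mean(max_r >= observed_r), observed_r = observed_r,
       max_correlations = max_r, pool_size = length(pool))
}
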