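ann <- fc_annotations()

test_that("the bundled annotation table reproduces the published connection set", {
  expect_equal(nrow(ann), 16)
  lat <- laterality_counts(ann)
  expect_equal(lat$count[lat$category == "right_intra"], 5L)
  expect_equal(lat$count[lat$category == "left_intra"], 0L)
  expect_equal(lat$count[lat$category == "inter"], 11L)
  expect_equal(round(100 * lat$fraction[lat$category == "right_intra"]), 31)
  expect_equal(round(100 * lat$fraction[lat$category == "inter"]), 69)
})

test_that("laterality classification handles medial terminals as inter", {
  toy <- tibble::tibble(lat1 = c("L", "M", "R", "L"),
                        lat2 = c("L", "R", "R", "R"))
  lc <- laterality_counts(toy)
  expect_equal(lc$count, c(1L, 1L, 2L))  # left-intra, right-intra, inter
  bad <- tibble::tibble(lat1 = "X", lat2 = "R")
  expect_error(laterality_counts(bad), class = "fcselect_input_error")
})

test_that("absent left-intra connections are improbable under the pair-share null", {
  # 70 of 140 regions per hemisphere: P(left-left pair) = C(70,2)/C(140,2)
  at <- laterality_absence_test(ann)
  expect_equal(at$observed, 0)
  expect_equal(at$null_fraction, 2415 / 9730)
  expect_equal(round(at$p_value, 2), 0.01)
  # direct closed form: zero successes in 16 draws
  expect_equal(at$p_value, (1 - 2415 / 9730)^16, tolerance = 1e-12)
  # the stricter symmetric null is even smaller
  at3 <- laterality_absence_test(ann, null_fraction = 1 / 3)
  expect_lt(at3$p_value, at$p_value)
})

test_that("cingulo-opercular enrichment matches the printed counts", {
  en <- network_enrichment(ann, "CO", n_network_regions = 33,
                           n_total_regions = 140)
  expect_equal(en$observed, 13)
  expect_equal(en$n_terminals, 32)
  expect_equal(round(100 * en$observed_fraction), 41)
  expect_equal(round(100 * en$expected_fraction), 24)
  expect_equal(round(en$p_value, 2), 0.02)
  expect_error(network_enrichment(ann, "XX", 10, 100),
               class = "fcselect_input_error")
})

test_that("under/over-connectivity balance matches the chi-squared test", {
  uo <- under_over_test(ann)
  expect_equal(uo$under, 9)
  expect_equal(uo$over, 7)
  expect_equal(uo$ties, 0)
  expect_equal(uo$chi_squared, 0.25)
  expect_equal(round(uo$p_value, 2), 0.62)

  even <- tibble::tibble(r_td = c(rep(0.5, 8), rep(0, 8)),
                         r_asd = c(rep(0, 8), rep(0.5, 8)))
  uo2 <- under_over_test(even)
  expect_equal(uo2$chi_squared, 0)
  expect_equal(uo2$p_value, 1)

  # df = 1 closed form
  expect_equal(uo$p_value, 2 * pnorm(-sqrt(uo$chi_squared)),
               tolerance = 1e-10)
})

test_that("distance statistics reproduce the summary-level group test", {
  ds <- distance_stats(summary = list(under = c(64.6, 51.1, 9),
                                      over = c(92.8, 33.9, 7)))
  expect_equal(ds$group_test$df, 14)
  expect_equal(round(abs(ds$group_test$t), 1), 1.3)
  expect_equal(round(ds$group_test$p_value, 2), 0.23)

  same <- distance_stats(summary = list(under = c(50, 10, 8),
                                        over = c(50, 10, 8)))
  expect_equal(same$group_test$t, 0)
})

test_that("centroid-based distances correlate as constructed", {
  set.seed(51)
  n <- 12
  d_target <- runif(n, 20, 120)
  toy <- tibble::tibble(
    x1 = 0, y1 = 0, z1 = 0,
    x2 = d_target, y2 = 0, z2 = 0,
    r_td = 0.2, r_asd = 0.2 + d_target / 200)  # diff exactly proportional
  ds <- distance_stats(toy)
  expect_equal(ds$distances, d_target)
  expect_equal(ds$correlations$r[1], 1, tolerance = 1e-12)
  expect_error(distance_stats(tibble::tibble(r_td = 1, r_asd = 0)),
               class = "fcselect_input_error")
})

test_that("leave-one-out score regression uses the exact refit arithmetic", {
  set.seed(52)
  n <- 40
  x <- cbind(1, matrix(rnorm(n * 4), n, 4))
  y <- drop(x %*% c(1, 0.5, -0.3, 0.2, 0)) + rnorm(n)
  shortcut <- fcselect:::loocv_ols_predict(x, y)
  explicit <- vapply(seq_len(n), function(i) {
    fit <- lm.fit(x[-i, , drop = FALSE], y[-i])
    drop(x[i, ] %*% fit$coefficients)
  }, numeric(1))
  expect_equal(shortcut, explicit, tolerance = 1e-10)
})

test_that("clinical scores are predicted when and only when signal exists", {
  set.seed(53)
  n <- 100
  fc16 <- matrix(rnorm(n * 16, 0, 0.2), n, 16)
  age <- runif(n, 20, 45)
  sex <- rbinom(n, 1, 0.7)
  w <- rnorm(16)

  # noise-free linear scores are recovered essentially perfectly
  scores <- drop(fc16 %*% w) + 0.05 * age + 0.3 * sex
  res <- predict_domain_score(fc16, age, sex, scores)
  expect_gte(res$pearson_r, 0.999)

  # independent scores: correlations scatter around zero
  rs <- vapply(1:20, function(i) {
    predict_domain_score(fc16, age, sex, rnorm(n))$pearson_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)

  # signal-to-noise one: attenuation into a predictable band
  set.seed(54)
  n2 <- 60
  fcb <- matrix(rnorm(n2 * 16, 0, 0.2), n2, 16)
  signal <- drop(fcb %*% w)
  signal <- signal / sd(signal)
  res2 <- predict_domain_score(fcb, runif(n2, 20, 45), rbinom(n2, 1, 0.7),
                               signal + rnorm(n2, 0, 1))
  expect_gte(res2$pearson_r, 0.4)
  expect_lte(res2$pearson_r, 0.85)

  # missing scores are dropped listwise
  scores_na <- scores
  scores_na[1:10] <- NA
  res3 <- predict_domain_score(fc16, age, sex, scores_na)
  expect_equal(res3$n, 90)

  expect_error(predict_domain_score(fc16, age, sex, rep(3, n)),
               class = "fcselect_input_error")
})

test_that("the bootstrap null pools the best of the eight domains", {
  set.seed(55)
  n <- 60
  p <- 500
  fc <- matrix(rnorm(n * p, 0, 0.2), n, p)
  age <- runif(n, 20, 45)
  sex <- rbinom(n, 1, 0.7)
  true_idx <- 1:16
  w <- rnorm(16)
  scores <- as.data.frame(replicate(8, rnorm(n)))
  # one domain is driven by the true subset
  scores[[1]] <- drop(fc[, true_idx] %*% w) + rnorm(n, 0, 0.3)
  obs <- predict_domain_score(fc[, true_idx], age, sex, scores[[1]])

  bn <- bootstrap_score_null(fc, excluded_indices = true_idx, age, sex,
                             scores, observed_r = obs$pearson_r,
                             n_boot = 500, seed = 9)
  expect_equal(bn$pool_size, p - 16)
  expect_lt(bn$p_value, 0.05)
  expect_length(bn$max_correlations, 500)

  # an observed correlation below the null floor is never significant
  bn2 <- bootstrap_score_null(fc, true_idx, age, sex, scores,
                              observed_r = min(bn$max_correlations) - 0.1,
                              n_boot = 50, seed = 10)
  expect_equal(bn2$p_value, 1)

  expect_error(bootstrap_score_null(fc[, 1:20], 1:10, age, sex, scores,
                                    observed_r = 0.5, n_boot = 10),
               class = "fcselect_input_error")
})

test_that("the eligible-pool arithmetic matches the full connectivity count", {
  # 9,730 connections minus 42 ever-selected leaves 9,688 eligible
  n_fc <- choose(140, 2)
  expect_equal(n_fc, 9730)
  sel42 <- seq_len(42)
  expect_equal(n_fc - length(sel42), 9688)
  fc <- matrix(rnorm(20 * n_fc, 0, 0.1), 20, n_fc)
  bn <- bootstrap_score_null(fc, sel42, age = runif(20, 20, 45),
                             sex = rbinom(20, 1, 0.5),
                             domain_scores = data.frame(a = rnorm(20)),
                             observed_r = 2, n_boot = 2, seed = 1)
  expect_equal(bn$pool_size, 9688)
})

test_that("bootstrap p-values are seed-stable at the full replicate count", {
  set.seed(56)
  n <- 50
  fc <- matrix(rnorm(n * 300, 0, 0.2), n, 300)
  age <- runif(n, 20, 45)
  sex <- rbinom(n, 1, 0.7)
  scores <- as.data.frame(replicate(4, rnorm(n)))
  p1 <- bootstrap_score_null(fc, 1:16, age, sex, scores, observed_r = 0.45,
                             n_boot = 10000, seed = 1)$p_value
  p2 <- bootstrap_score_null(fc, 1:16, age, sex, scores, observed_r = 0.45,
                             n_boot = 10000, seed = 2)$p_value
  se <- sqrt(p1 * (1 - p1) / 10000)
  expect_lt(abs(p1 - p2), 3 * max(se, sqrt(p2 * (1 - p2) / 10000)) + 1e-6)
})
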