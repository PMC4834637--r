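#' Ground truth for a planted-effect connectivity cohort
#'
#' Describes which connectivity indices carry a true diagnosis effect, which
#' are driven by nuisance attributes (site, age, sex, eye condition,
#' medication), and the residual noise level, so that recovery of the planted
#' structure can be scored after selection and classification.
#'
#' @param n_fc Number of connectivity features in the cohort.
#' @param diagnosis_fc_indices Integer indices (1-based) of connections
#'   carrying a true group-mean difference between diagnosed and control
#'   subjects.
#' @param effect_size Standardized mean difference planted at each diagnosis
#'   connection (unitless; the latent-scale shift is `effect_size * noise_sd`).
#' @param nuisance_map Named list keyed by attribute column name
#'   (e.g. `"site_b"`, `"age"`); each element is a list with `indices`
#'   (connectivity indices influenced by that attribute) and `effect`
#'   (latent-scale shift per unit of the attribute).
#' @param noise_sd Residual standard deviation of the latent connectivity
#'   values (> 0).
#' @param baseline Optional per-connection latent baseline vector (length
#'   `n_fc`). When NULL, [generate_fc_cohort()] draws one and records it in
#'   the truth it returns, so further cohorts generated from that truth
#'   share the same population baselines.
#'
#' @return An object of class `fc_ground_truth`.
#' @export
ground_truth <- function(n_fc, diagnosis_fc_indices = integer(),
                         effect_size = 1, nuisance_map = list(),
                         noise_sd = 0.1, baseline = NULL) {
  assert_that(is.numeric(n_fc) && length(n_fc) == 1 && n_fc >= 1,
              "`n_fc` must be a positive count")
  diagnosis_fc_indices <- as.integer(diagnosis_fc_indices)
  assert_that(all(diagnosis_fc_indices >= 1 & diagnosis_fc_indices <= n_fc),
              "`diagnosis_fc_indices` must lie within 1..n_fc")
  assert_that(is.finite(effect_size), "`effect_size` must be finite")
  assert_that(is.numeric(noise_sd) && noise_sd > 0, "`noise_sd` must be > 0")
  for (nm in names(nuisance_map)) {
    entry <- nuisance_map[[nm]]
    idx <- as.integer(entry$indices)
    assert_that(all(idx >= 1 & idx <= n_fc),
                paste0("nuisance indices for `", nm, "` out of range"))
    assert_that(is.finite(entry$effect),
                paste0("nuisance effect for `", nm, "` must be finite"))
    nuisance_map[[nm]]$indices <- idx
  }
  if (!is.null(baseline))
    assert_that(length(baseline) == n_fc,
                "`baseline` must have length `n_fc`")
  structure(
    list(n_fc = as.integer(n_fc),
         diagnosis_fc_indices = diagnosis_fc_indices,
         effect_size = effect_size, nuisance_map = nuisance_map,
         noise_sd = noise_sd, baseline = baseline),
    class = "fc_ground_truth")
}

#' Default planted-effect layout for a synthetic cohort
#'
#' Draws disjoint random index sets for diagnosis-linked and site-linked
#' connections. The site effect defaults to twice the noise standard
#' deviation so a site-linked connection is clearly correlated with its site
#' flag while remaining independent of diagnosis.
#'
#' @inheritParams ground_truth
#' @param n_diagnosis_fc,n_site_fc Number of planted diagnosis and site-linked
#'   connections.
#' @param site_column Attribute column receiving the site effect.
#' @param site_effect Latent shift per unit of the site flag.
#' @param seed Integer seed for the index draw.
#' @return An `fc_ground_truth` object.
#' @export
default_ground_truth <- function(n_fc, n_diagnosis_fc = 15, n_site_fc = 50,
                                 effect_size = 1, noise_sd = 0.1,
                                 site_column = "site_b",
                                 site_effect = 2 * noise_sd, seed = 1) {
  assert_that(n_diagnosis_fc + n_site_fc <= n_fc,
              "planted index sets exceed `n_fc`")
  withr::with_seed(seed, {
    idx <- sample.int(n_fc, n_diagnosis_fc + n_site_fc)
  })
  nuis <- list()
  if (n_site_fc > 0) {
    nuis[[site_column]] <- list(indices = idx[(n_diagnosis_fc + 1):(n_diagnosis_fc + n_site_fc)],
                                effect = site_effect)
  }
  ground_truth(n_fc, diagnosis_fc_indices = idx[seq_len(n_diagnosis_fc)],
               effect_size = effect_size, nuisance_map = nuis,
               noise_sd = noise_sd)
}

#' Head-motion specification for synthetic scan series
#'
#' @param n_frames Number of frames in the series.
#' @param spike_frames Frame indices (1-based) receiving a transient
#'   displacement jump across all six motion parameters.
#' @param spike_magnitude Displacement added at each spike frame, expressed
#'   in mm per parameter; rotation columns receive the equivalent angle on a
#'   50 mm sphere so every parameter contributes `spike_magnitude` mm of
#'   frame displacement.
#' @param baseline_jitter_sd Standard deviation of the frame-to-frame random
#'   walk of each parameter, in mm-equivalents (rotations scaled as above).
#' @return An object of class `fc_motion_spec`.
#' @export
motion_spec <- function(n_frames, spike_frames = integer(),
                        spike_magnitude = 0.3, baseline_jitter_sd = 0.01) {
  spike_frames <- as.integer(spike_frames)
  assert_that(all(spike_frames >= 1 & spike_frames <= n_frames),
              "`spike_frames` must lie within 1..n_frames")
  assert_that(spike_magnitude >= 0 && baseline_jitter_sd >= 0,
              "motion magnitudes must be nonnegative")
  structure(list(n_frames = as.integer(n_frames), spike_frames = spike_frames,
                 spike_magnitude = spike_magnitude,
                 baseline_jitter_sd = baseline_jitter_sd),
            class = "fc_motion_spec")
}

#' Column order of the attribute matrix
#'
#' The demographic / nuisance-variable block has ten columns in a fixed,
#' documented order: diagnosis (1 = case), three one-hot site flags, age
#' (years), sex (1 = male), eye condition (1 = open), and three binary
#' medication flags.
#' @return Character vector of the ten column names.
#' @export
attribute_columns <- function() {
  c("diagnosis", "site_a", "site_b", "site_c", "age", "sex", "eye",
    "med1", "med2", "med3")
}

#' Generate a synthetic subject-attribute table
#'
#' Simulates the ten-column demographic block of a multi-site cohort:
#' diagnosis, one-hot site membership, age, sex, eye condition during the
#' scan, and three medication flags. Medication is only assigned to diagnosed
#' subjects, mirroring clinical cohorts where controls are unmedicated.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param site_proportions Three fractions summing to 1, the expected share
#'   of subjects per site.
#' @param asd_fraction Expected fraction of diagnosed subjects.
#' @param seed Integer seed; the table is reproducible bit-for-bit.
#' @param age_range Uniform age range in years.
#' @param female_fraction Expected fraction of female subjects (sex code 0).
#' @param eye_open_fraction Expected fraction scanned with eyes open.
#' @param medication_rates Per-medication assignment probability among
#'   diagnosed subjects.
#' @param control_only_site Optional site name (`"site_a"`, `"site_b"`,
#'   `"site_c"`) that contributes only control subjects; diagnosed subjects
#'   drawn there are reassigned to the other sites. Mirrors multi-site
#'   cohorts in which one site recruits no patients.
#' @return A tibble with `n_subjects` rows and the ten [attribute_columns()].
#' @export
generate_attributes <- function(n_subjects, site_proportions = rep(1 / 3, 3),
                                asd_fraction = 0.5, seed = 1,
                                age_range = c(20, 45), female_fraction = 0.3,
                                eye_open_fraction = 0.5,
                                medication_rates = c(0.25, 0.2, 0.2),
                                control_only_site = NULL) {
  assert_that(n_subjects >= 4, "`n_subjects` must be at least 4")
  assert_that(length(site_proportions) == 3 && all(site_proportions >= 0) &&
                abs(sum(site_proportions) - 1) < 1e-8,
              "`site_proportions` must be three nonnegative fractions summing to 1")
  assert_that(asd_fraction >= 0 && asd_fraction <= 1,
              "`asd_fraction` must be a fraction")
  sites <- c("site_a", "site_b", "site_c")
  if (!is.null(control_only_site))
    assert_that(control_only_site %in% sites, "unknown `control_only_site`")
  withr::with_seed(seed, {
    diagnosis <- rbinom(n_subjects, 1, asd_fraction)
    site <- sample(sites, n_subjects, replace = TRUE, prob = site_proportions)
    if (!is.null(control_only_site)) {
      clash <- diagnosis == 1 & site == control_only_site
      others <- setdiff(sites, control_only_site)
      pr <- site_proportions[match(others, sites)]
      if (sum(pr) <= 0) pr <- c(1, 1)
      site[clash] <- sample(others, sum(clash), replace = TRUE, prob = pr)
    }
    age <- runif(n_subjects, age_range[1], age_range[2])
    sex <- rbinom(n_subjects, 1, 1 - female_fraction)
    eye <- rbinom(n_subjects, 1, eye_open_fraction)
    meds <- vapply(medication_rates,
                   function(r) rbinom(n_subjects, 1, r) * diagnosis,
                   integer(n_subjects))
  })
  tibble(
    diagnosis = as.integer(diagnosis),
    site_a = as.integer(site == "site_a"),
    site_b = as.integer(site == "site_b"),
    site_c = as.integer(site == "site_c"),
    age = age,
    sex = as.integer(sex),
    eye = as.integer(eye),
    med1 = as.integer(meds[, 1]),
    med2 = as.integer(meds[, 2]),
    med3 = as.integer(meds[, 3]))
}

#' Coerce an attribute table to the standardized numeric matrix layout
#'
#' @param attributes A data frame containing the ten [attribute_columns()].
#' @return Numeric matrix with columns in the enforced order.
#' @export
attribute_matrix <- function(attributes) {
  cols <- attribute_columns()
  missing <- setdiff(cols, names(attributes))
  assert_that(length(missing) == 0,
              paste("attribute table lacks columns:",
                    paste(missing, collapse = ", ")))
  as.matrix(attributes[, cols])
}

#' Generate a connectivity cohort with planted effects
#'
#' Each connectivity value is built on a latent Gaussian scale as
#' baseline + diagnosis effect (for planted connections of diagnosed
#' subjects) + nuisance contributions + noise, then squashed into `[-1, 1]`
#' through `tanh`, a monotone bounded map that leaves rank order intact.
#' Baselines are drawn once per connection from N(0, 0.25^2) so most values
#' sit in the near-linear range of `tanh` and the planted standardized mean
#' difference survives the squashing to within a few percent.
#'
#' @param attributes Attribute table from [generate_attributes()].
#' @param n_fc Number of connectivity features.
#' @param truth An [ground_truth()] object; its index sets must fit `n_fc`.
#' @param seed Integer seed.
#' @return A list with `fc` (numeric matrix, subjects by connections) and
#'   `truth` (the ground truth used).
#' @export
generate_fc_cohort <- function(attributes, n_fc, truth, seed = 1) {
  assert_that(inherits(truth, "fc_ground_truth"), "`truth` must be fc_ground_truth")
  planted_max <- max(c(0L, truth$diagnosis_fc_indices,
                       unlist(lapply(truth$nuisance_map, `[[`, "indices"))))
  assert_that(n_fc >= planted_max,
              "`n_fc` must cover the largest planted index")
  x1 <- attribute_matrix(attributes)
  n <- nrow(x1)
  withr::with_seed(seed, {
    drawn <- rnorm(n_fc, 0, 0.25)
    latent <- matrix(rnorm(n * n_fc, 0, truth$noise_sd), n, n_fc)
  })
  baseline <- truth$baseline %||% drawn
  truth$baseline <- baseline
  latent <- sweep(latent, 2, baseline, "+")
  if (length(truth$diagnosis_fc_indices) > 0) {
    shift <- truth$effect_size * truth$noise_sd
    latent[, truth$diagnosis_fc_indices] <-
      latent[, truth$diagnosis_fc_indices] + outer(x1[, "diagnosis"],
                                                   rep(shift, length(truth$diagnosis_fc_indices)))
  }
  for (nm in names(truth$nuisance_map)) {
    entry <- truth$nuisance_map[[nm]]
    assert_that(nm %in% colnames(x1),
                paste0("nuisance column `", nm, "` not in attribute table"))
    latent[, entry$indices] <- latent[, entry$indices] +
      outer(x1[, nm], rep(entry$effect, length(entry$indices)))
  }
  fc <- tanh(latent)
  colnames(fc) <- paste0("fc", seq_len(n_fc))
  list(fc = fc, truth = truth)
}

#' Generate synthetic ROI time series with motion and tissue regressors
#'
#' Draws multivariate Gaussian frames whose population correlation equals
#' `target_correlation`, a six-parameter head-motion series (random-walk
#' jitter plus transient spikes), and three smooth tissue signals (white
#' matter, CSF, whole brain) built as low-pass filtered noise. The tissue
#' signals are plausible nuisance regressors, not physiological simulations.
#'
#' @param n_frames Number of frames (>= 12).
#' @param n_regions Number of regions.
#' @param target_correlation Symmetric positive semidefinite matrix with unit
#'   diagonal; defaults to the identity (independent regions).
#' @param motion A [motion_spec()]; defaults to spike-free jitter.
#' @param seed Integer seed.
#' @param tr Repetition time, seconds per frame.
#' @return A list with `series` (frames x regions), `motion` (frames x 6),
#'   `tissue` (frames x 3), and `tr`.
#' @export
generate_timeseries <- function(n_frames, n_regions,
                                target_correlation = NULL,
                                motion = motion_spec(n_frames), seed = 1,
                                tr = 2) {
  assert_that(n_frames >= 12, "`n_frames` must be at least 12")
  if (is.null(target_correlation)) target_correlation <- diag(n_regions)
  assert_that(nrow(target_correlation) == n_regions &&
                ncol(target_correlation) == n_regions,
              "`target_correlation` has wrong dimensions")
  assert_that(max(abs(target_correlation - t(target_correlation))) < 1e-8,
              "`target_correlation` must be symmetric")
  assert_that(max(abs(diag(target_correlation) - 1)) < 1e-8,
              "`target_correlation` must have unit diagonal")
  ev <- eigen(target_correlation, symmetric = TRUE)
  assert_that(min(ev$values) > -1e-8,
              "`target_correlation` must be positive semidefinite")
  assert_that(motion$n_frames == n_frames,
              "`motion` frame count must match `n_frames`")
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  rot_scale <- 1 / 50  # mm-equivalent -> radians on a 50 mm sphere
  withr::with_seed(seed, {
    z <- matrix(rnorm(n_frames * n_regions), n_frames, n_regions)
    series <- z %*% root
    mot <- apply(matrix(rnorm(n_frames * 6, 0, motion$baseline_jitter_sd),
                        n_frames, 6), 2, cumsum)
    tissue <- matrix(rnorm(n_frames * 3), n_frames, 3)
  })
  mot[, 4:6] <- mot[, 4:6] * rot_scale
  if (length(motion$spike_frames) > 0)
    mot[motion$spike_frames, ] <- mot[motion$spike_frames, ] +
      rep(motion$spike_magnitude * c(1, 1, 1, rot_scale, rot_scale, rot_scale),
          each = length(motion$spike_frames))
  lp <- signal::butter(2, 0.2, type = "low")
  tissue <- apply(tissue, 2, function(x) signal::filtfilt(lp, x))
  colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
  colnames(tissue) <- c("white_matter", "csf", "global")
  colnames(series) <- paste0("roi", seq_len(n_regions))
  list(series = series, motion = mot, tissue = tissue, tr = tr)
}

#' Write a synthetic cohort to disk
#'
#' Writes the attribute table as CSV, the connectivity matrix as TSV, and the
#' ground truth as a JSON sidecar, the plain-text layout consumed by the
#' command-line interface.
#'
#' @param attributes Attribute tibble.
#' @param fc Connectivity matrix (subjects x connections).
#' @param truth `fc_ground_truth` or NULL.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(attributes, fc, truth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(attributes = file.path(dir, "attributes.csv"),
             fc = file.path(dir, "fc.tsv"))
  write.csv(attributes, paths[["attributes"]], row.names = FALSE)
  write.table(fc, paths[["fc"]], sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

#' Read a connectivity matrix written by [write_cohort()]
#' @param path TSV file, subjects in rows, connections in columns.
#' @return Numeric matrix.
#' @export
read_fc_matrix <- function(path) {
  as.matrix(read.csv(path, sep = "\t", check.names = FALSE))
}

#' Read an attribute table written by [write_cohort()]
#' @param path CSV file with the ten [attribute_columns()].
#' @return Tibble.
#' @export
read_attributes <- function(path) {
  as_tibble(read.csv(path))
}
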