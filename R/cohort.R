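#' Reference microstate dynamics presets
#'
#' Per-class mean durations and the embedded transition chain used as the
#' package's reference conditions: an interictal migraine-without-aura-like
#' profile (`"mwoa"`) and a matched healthy-control-like profile
#' (`"control"`).  The embedded chain is the row-normalisation of the
#' corresponding 12-cell transition-percentage table and the segment weights
#' are its stationary distribution, which makes durations, occurrences,
#' coverages and joint transition percentages mutually consistent.
#'
#' @param group `"mwoa"` or `"control"`.
#' @return A [semi_markov_spec].
#' @examples
#' preset_dynamics("mwoa")$mean_durations
#' @export
preset_dynamics <- function(group = c("mwoa", "control")) {
  group <- match.arg(group)
  if (group == "mwoa") {
    durs <- c(65.13, 64.99, 61.44, 63.61)
    cells <- matrix(c(0,    7.92, 7.00, 8.67,
                      8.06, 0,    7.38, 8.88,
                      6.99, 7.30, 0,    8.24,
                      8.53, 9.14, 8.15, 0), 4, 4, byrow = TRUE)
  } else {
    durs <- c(68.06, 64.74, 69.45, 67.25)
    cells <- matrix(c(0,    7.42, 8.58, 7.92,
                      7.33, 0,    8.54, 7.29,
                      8.71, 8.51, 0,    8.29,
                      7.88, 7.34, 8.36, 0), 4, 4, byrow = TRUE)
  }
  semi_markov_spec(durs, cells / rowSums(cells))
}

#' Cohort specification for the synthetic study
#'
#' Bundles everything needed to generate a two-group synthetic cohort:
#' group sizes, per-group dynamics, recording parameters, and the clinical
#' model (a headache-impact score drawn so that, within the patient group,
#' it correlates with the subject's planted class-C mean duration at level
#' `rho`).
#'
#' @param n_per_group integer(2), subjects per group (patients, controls).
#' @param dynamics list of two [semi_markov_spec]s; defaults to
#'   `preset_dynamics("mwoa")` and `preset_dynamics("control")`.
#' @param fs sampling rate of the generated recordings (Hz).
#' @param length_s recording length (s).
#' @param snr signal-to-noise ratio as in [render_eeg()].
#' @param clinical_mean,clinical_sd moments of the headache-impact score
#'   (HIT-6 scale).
#' @param rho target correlation between a patient's planted class-C mean
#'   duration and the clinical score.
#' @param duration_sd between-subject SD (ms) of the planted class-C mean
#'   duration; 0 gives identical dynamics for all subjects of a group.
#' @param age_mean,age_sd numeric(2) each, per-group age moments.
#' @param female_frac numeric(2), per-group proportion of female subjects.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(61, 66),
                        dynamics = list(preset_dynamics("mwoa"),
                                        preset_dynamics("control")),
                        fs = 500, length_s = 240, snr = 5,
                        clinical_mean = 65.85, clinical_sd = 6.91,
                        rho = -0.27, duration_sd = 8.70,
                        age_mean = c(32.79, 31.44), age_sd = c(6.83, 4.63),
                        female_frac = c(50 / 61, 50 / 66)) {
  if (length(n_per_group) != 2L || any(n_per_group < 0) ||
      any(n_per_group != round(n_per_group)))
    .stopf("n_per_group must be two non-negative integers")
  stopifnot(length(dynamics) == 2L)
  lapply(dynamics, function(d) stopifnot(inherits(d, "semi_markov_spec")))
  if (fs <= 0 || length_s <= 0 || snr <= 0) .stopf("fs, length_s and snr must be positive")
  if (abs(rho) > 1) .stopf("|rho| must be at most 1")
  if (abs(rho) == 1 && duration_sd == 0)
    .stopf("|rho| = 1 requires non-zero between-subject duration variance")
  structure(list(n_per_group = as.integer(n_per_group), dynamics = dynamics,
                 fs = fs, length_s = length_s, snr = snr,
                 clinical_mean = clinical_mean, clinical_sd = clinical_sd,
                 rho = rho, duration_sd = duration_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 female_frac = female_frac),
            class = "cohort_spec")
}

#' Plant a clinical score correlated with a microstate parameter
#'
#' Draws subject-level planted class-C mean durations
#' `N(dur_mean, dur_sd^2)` and a clinical score from the conditional
#' Gaussian that yields population correlation `rho` with those durations.
#'
#' @param n number of subjects.
#' @param rho target correlation.
#' @param dur_mean,dur_sd duration moments (ms); `dur_sd > 0` unless `rho = 0`.
#' @param clin_mean,clin_sd clinical-score moments.
#' @param seed integer seed.
#' @return A data frame with columns `duration_C` and `score`.
#' @examples
#' d <- plant_clinical(61, -0.27, 61.44, 8.70, 65.85, 6.91, seed = 1)
#' cor(d$duration_C, d$score)
#' @export
plant_clinical <- function(n, rho, dur_mean, dur_sd, clin_mean, clin_sd, seed = 1) {
  if (abs(rho) > 1) .stopf("|rho| must be at most 1")
  if (rho != 0 && dur_sd <= 0) .stopf("rho != 0 requires dur_sd > 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- stats::rnorm(n, dur_mean, dur_sd)
  z <- if (dur_sd > 0) (d - dur_mean) / dur_sd else rep(0, n)
  score <- clin_mean + clin_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  data.frame(duration_C = d, score = score)
}

#' Generate a synthetic two-group cohort
#'
#' For every subject, draws a class sequence from the group's dynamics
#' (with the subject's class-C mean duration jittered by
#' `spec$duration_sd`), renders the EEG at the requested SNR, and fills a
#' clinical table (subject id, group, sex, age, and - for the patient
#' group - a headache-impact score correlated with the subject's planted
#' class-C duration at level `spec$rho`).
#'
#' One master seed drives everything; per-subject seeds are derived by a
#' fixed splitting rule so the cohort is reproducible subject by subject.
#'
#' @param spec a [cohort_spec].
#' @param seed integer master seed.
#' @param montage montage for the recordings (default [montage_1010_64()]).
#' @param templates template maps (default [canonical_templates()] of the
#'   montage).
#' @return A list with elements `recordings` (list of [ms_recording]),
#'   `clinical` (data frame), and `planted_duration_C` (numeric).
#' @export
generate_cohort <- function(spec, seed = 1, montage = montage_1010_64(),
                            templates = canonical_templates(montage)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n1 <- spec$n_per_group[1]; n2 <- spec$n_per_group[2]
  n <- n1 + n2
  seeds <- .derive_seeds(seed, 3L * n + 1L)
  group <- rep(c("patient", "control"), c(n1, n2))
  # clinical scores: conditional on the subject's jittered class-C duration
  recs <- vector("list", n)
  durC <- numeric(n)
  sex <- character(n); age <- numeric(n)
  for (i in seq_len(n)) {
    g <- if (i <= n1) 1L else 2L
    dyn <- spec$dynamics[[g]]
    base_dur <- dyn$mean_durations
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seeds[i])
    dC <- stats::rnorm(1, base_dur[3], spec$duration_sd)
    dC <- max(dC, 25)                       # keep resolvable
    age[i] <- stats::rnorm(1, spec$age_mean[g], spec$age_sd[g])
    sex[i] <- if (stats::runif(1) < spec$female_frac[g]) "F" else "M"
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    durC[i] <- dC
    dyn_i <- semi_markov_spec(replace(base_dur, 3, dC),
                              dyn$embedded_transitions,
                              dyn$segment_weights, dyn$duration_shape)
    labs <- sample_state_sequence(dyn_i, spec$length_s, spec$fs,
                                  seed = seeds[n + i])
    recs[[i]] <- render_eeg(labs, templates, fs = spec$fs, snr = spec$snr,
                            seed = seeds[2L * n + i], montage = montage)
  }
  # clinical score for patients, conditional-Gaussian on the planted duration
  hit6 <- rep(NA_real_, n)
  if (n1 > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seeds[3L * n + 1L])
    z <- if (spec$duration_sd > 0) {
      (durC[seq_len(n1)] - spec$dynamics[[1]]$mean_durations[3]) / spec$duration_sd
    } else rep(0, n1)
    hit6[seq_len(n1)] <- spec$clinical_mean +
      spec$clinical_sd * (spec$rho * z + sqrt(1 - spec$rho^2) * stats::rnorm(n1))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  clinical <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    sex = sex,
    age = round(age, 1),
    HIT6 = round(hit6, 2),
    stringsAsFactors = FALSE
  )
  list(recordings = recs, clinical = clinical, planted_duration_C = durC)
}
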