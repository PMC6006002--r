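default_organ_ranges <- function() {
  data.frame(
    organ     = c("kidneys", "liver", "spleen", "remainder", "tumor", "blood"),
    c0_min    = c(150,  50, 100,  5, 300, 20),
    c0_max    = c(450, 120, 300, 10, 900, 45),
    t_eff_min = c(35, 60, 55, 30,  70, 20),
    t_eff_max = c(65, 90, 85, 50, 110, 40),
    mass_min  = c(0.25, 1.3, 0.12, NA, 0.02, NA),
    mass_max  = c(0.40, 2.0, 0.30, NA, 0.40, NA),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic PRRT cohort generator. The defaults
#' emulate the clinical conditions the analysis targets: administered
#' activity 7400 +/- 250 MBq per cycle, 1-4 cycles per patient with a
#' median of 4 and a mean near 3.5, organ and blood kinetics that are
#' mono-exponential with effective half-lives capped at the 177Lu
#' physical half-life, kidney uptake sized to give per-cycle kidney
#' doses of roughly 2-12 Gy (mean near 5-6 Gy) and marrow doses of tens
#' of mGy, 5% multiplicative (lognormal) measurement noise, and a 6%
#' per-cycle single-CT perturbation. Per-organ kinetic ranges are
#' uniform between the bounds given in `organ_ranges`.
#'
#' @param n_patients Number of patients (default 24).
#' @param cycle_probs Probabilities of a patient receiving 1, 2, 3, or 4
#'   cycles.
#' @param a_adm_mean,a_adm_sd Administered-activity distribution, MBq.
#' @param organ_ranges Data frame with columns `organ`, `c0_min`,
#'   `c0_max` (MBq/kg), `t_eff_min`, `t_eff_max` (hours),
#'   `mass_min`, `mass_max` (kg; NA for concentration-only regions).
#' @param noise_sd Standard deviation of the lognormal measurement
#'   noise on the log scale (default 0.05, i.e. ~5% multiplicative).
#' @param perturb_sd Standard deviation of the per-cycle single-CT
#'   perturbation factor on the log scale (default 0.06).
#' @param seed Master seed; each patient derives an independent
#'   sub-seed from it (see [generate_cohort()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 24,
                          cycle_probs = c(0.05, 0.12, 0.15, 0.68),
                          a_adm_mean = 7400, a_adm_sd = 250,
                          organ_ranges = default_organ_ranges(),
                          noise_sd = 0.05, perturb_sd = 0.06,
                          seed = 1L) {
  if (n_patients < 1) abort_prrt("n_patients must be >= 1", "prrtdose_config_error")
  if (length(cycle_probs) != 4L || any(cycle_probs < 0) || sum(cycle_probs) <= 0) {
    abort_prrt("cycle_probs must be 4 non-negative weights", "prrtdose_config_error")
  }
  if (a_adm_mean <= 0 || a_adm_sd < 0) {
    abort_prrt("administered-activity parameters must be positive", "prrtdose_config_error")
  }
  r <- organ_ranges
  if (any(r$c0_min <= 0) || any(r$c0_max < r$c0_min) ||
      any(r$t_eff_min <= 0) || any(r$t_eff_max < r$t_eff_min)) {
    abort_prrt("organ ranges must be positive with max >= min", "prrtdose_config_error")
  }
  if (noise_sd < 0 || perturb_sd < 0) {
    abort_prrt("noise parameters must be >= 0", "prrtdose_config_error")
  }
  structure(list(n_patients = as.integer(n_patients),
                 cycle_probs = cycle_probs / sum(cycle_probs),
                 a_adm_mean = a_adm_mean, a_adm_sd = a_adm_sd,
                 organ_ranges = r, noise_sd = noise_sd,
                 perturb_sd = perturb_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# Seed-splitting: patient k always draws from sub-seed
# (seed + 104729 * k) mod (2^31 - 1), so patient k is identical for any
# cohort size >= k and can be regenerated in isolation.
patient_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

#' Generate a synthetic patient cohort with known kinetics
#'
#' Draws, per patient: sex (1:1), number of cycles, per-cycle
#' administered activity, and per-organ true mono-exponential kinetics
#' `(c0, lambda)` plus VOI masses, uniformly within the configured
#' ranges. Effective half-lives are clamped at the 177Lu physical
#' half-life, so `lambda >= LU177_LAMBDA_H` always. Generation is
#' deterministic given the master seed, and patient `k` is identical
#' regardless of cohort size.
#'
#' @param config A [cohort_config].
#' @return List of `true_patient` objects: each a list with
#'   `patient_id`, `sex`, `organs` (data frame `organ`, `c0`,
#'   `t_eff_h`, `lambda`, `voi_mass_kg`), `a_adm` (per-cycle MBq),
#'   `n_cycles`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  lapply(seq_len(config$n_patients), function(k) {
    ps <- patient_seed(config$seed, k)
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
    set.seed(ps)
    sex <- if (stats::runif(1) < 0.5) "male" else "female"
    n_cycles <- sample.int(4L, 1L, prob = config$cycle_probs)
    a_adm <- pmax(stats::rnorm(n_cycles, config$a_adm_mean, config$a_adm_sd), 1)
    r <- config$organ_ranges
    c0 <- stats::runif(nrow(r), r$c0_min, r$c0_max)
    t_eff <- pmin(stats::runif(nrow(r), r$t_eff_min, r$t_eff_max),
                  LU177_HALF_LIFE_H)
    mass <- rep(NA_real_, nrow(r))
    has_mass <- !is.na(r$mass_min)
    mass[has_mass] <- stats::runif(sum(has_mass), r$mass_min[has_mass],
                                   r$mass_max[has_mass])
    structure(list(
      patient_id = sprintf("P%02d", k),
      sex = sex,
      organs = data.frame(organ = r$organ, c0 = c0, t_eff_h = t_eff,
                          lambda = log(2) / t_eff, voi_mass_kg = mass,
                          stringsAsFactors = FALSE),
      a_adm = a_adm,
      n_cycles = n_cycles,
      seed = ps
    ), class = "true_patient")
  })
}

#' Simulate the measurement schedule for one cycle
#'
#' Emulates the acquisition schedule: cycle 1 has SPECT quantification
#' of every organ at 18 h, 25 h, and 168 h (7 days) plus blood counts at
#' 18 h and 25 h; later cycles have a single SPECT organ sample and a
#' single blood sample at 20 h. Each sample is the true curve value
#' times lognormal noise (`exp(N(0, noise_sd))`). Under the single-CT
#' protocol, the organ samples of cycles >= 2 are additionally
#' multiplied by one per-cycle perturbation factor
#' (`exp(N(0, perturb_sd))`) standing in for the attenuation-map
#' mismatch and VOI misregistration of reusing the first CT; blood
#' counting is CT-independent and is never perturbed. Classical and
#' single-CT simulations of the same (patient, cycle) share the same
#' noise draws, so protocol differences isolate the perturbation.
#'
#' @param patient A `true_patient`.
#' @param cycle Cycle number, 1..`n_cycles`.
#' @param protocol `"classical"` or `"single_ct"`.
#' @param noise_sd,perturb_sd Override the generator noise levels
#'   (defaults 0.05 / 0.06).
#' @param perturb_factor Fix the perturbation factor instead of drawing
#'   it (testing hook).
#' @param seed Base seed for this (patient, cycle); defaults to a value
#'   derived from the patient sub-seed and the cycle.
#' @return A [timed_samples] data frame.
#' @export
simulate_measurements <- function(patient, cycle,
                                  protocol = c("classical", "single_ct"),
                                  noise_sd = 0.05, perturb_sd = 0.06,
                                  perturb_factor = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  if (!cycle %in% seq_len(patient$n_cycles)) {
    abort_prrt(sprintf("patient %s has no cycle %s", patient$patient_id, cycle),
               "prrtdose_input_error")
  }
  if (is.null(seed)) seed <- (patient$seed + 1000 * cycle) %% 2147483647
  org <- patient$organs
  solid <- org[org$organ != "blood", , drop = FALSE]
  blood <- org[org$organ == "blood", , drop = FALSE]

  if (cycle == 1L) {
    t_org <- c(18, 25, 168); t_blood <- c(18, 25)
  } else {
    t_org <- 20; t_blood <- 20
  }
  grid <- expand.grid(i = seq_len(nrow(solid)), t = t_org)
  organ_lbl <- solid$organ[grid$i]
  true_org <- solid$c0[grid$i] * exp(-solid$lambda[grid$i] * grid$t)
  true_blood <- if (nrow(blood) == 1) {
    blood$c0 * exp(-blood$lambda * t_blood)
  } else numeric(0)

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  set.seed(seed)
  noise_org <- exp(stats::rnorm(length(true_org), 0, noise_sd))
  noise_blood <- exp(stats::rnorm(length(true_blood), 0, noise_sd))

  pf <- 1
  if (cycle >= 2L && protocol == "single_ct") {
    if (!is.null(perturb_factor)) {
      pf <- perturb_factor
    } else {
      set.seed((seed + 499) %% 2147483647)
      pf <- exp(stats::rnorm(1, 0, perturb_sd))
    }
  }

  rbind(
    timed_samples(organ_lbl, grid$t, true_org * noise_org * pf, cycle, "spect"),
    if (length(true_blood) > 0) {
      timed_samples("blood", t_blood, true_blood * noise_blood, cycle,
                    "blood_counter")
    }
  )
}

#' @rdname simulate_measurements
#' @param ... Passed on to `simulate_measurements()`.
#' @export
simulate_course <- function(patient, protocol = c("classical", "single_ct"), ...) {
  protocol <- match.arg(protocol)
  do.call(rbind, lapply(seq_len(patient$n_cycles), function(cyc) {
    simulate_measurements(patient, cyc, protocol, ...)
  }))
}

#' Analytic true doses for a synthetic patient
#'
#' Oracle for the dose pipeline: residence times are computed in closed
#' form from the true kinetic parameters
#' (`t_r = c0 * 3600 / (lambda * a_adm)`, no curve fitting involved)
#' and pushed through the same self/cross dose arithmetic as the
#' engine. On noiseless measurements the full fitting pipeline must
#' reproduce these doses to within numerical precision.
#'
#' @param patient A `true_patient`.
#' @param table A [dose_factor_table].
#' @param target_organs Dose targets (default kidneys and bone marrow).
#' @return Data frame with columns `cycle`, one column per target organ
#'   (dose in mGy).
#' @export
true_dose <- function(patient, table,
                      target_organs = c("kidneys", "bone_marrow")) {
  org <- patient$organs
  out <- lapply(seq_len(patient$n_cycles), function(cyc) {
    a <- patient$a_adm[cyc]
    tr <- org$c0 * 3600 / (org$lambda * a)
    names(tr) <- org$organ
    mass <- stats::setNames(org$voi_mass_kg, org$organ)
    mass <- mass[!is.na(mass)]
    rts <- residence_time_set(tr[setdiff(names(tr), "blood")], mass)
    d <- vapply(target_organs, function(tg) {
      if (tg == "bone_marrow") {
        marrow_dose(a, tr[["blood"]], rts, table)$total_mGy
      } else if (tg == "tumor") {
        tumor_dose(a, tr[["tumor"]], table)
      } else {
        organ_dose(a, tg, rts, table)$total_mGy
      }
    }, numeric(1))
    c(cycle = cyc, d)
  })
  as.data.frame(do.call(rbind, out))
}
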