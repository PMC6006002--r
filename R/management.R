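#' Patient-management configuration
#'
#' Safety limits for the organs at risk and the margin of the
#' treatment-withholding rule. Treatment is withheld when the expected
#' cumulative dose after the next cycle would exceed the limit by more
#' than the margin, i.e. with the defaults 25.3 Gy for the kidneys and
#' 2.2 Gy for the bone marrow. Only the kidneys and bone marrow drive
#' management by default (doses to other organs do not influence it),
#' but the organ set is configurable. An `override` flag records the
#' rare clinical decision to continue beyond the limits; it is never
#' applied automatically.
#'
#' @param limit_Gy Named numeric vector organ -> safety limit in Gy.
#' @param margin Fractional margin on the limits, default 0.10.
#' @param override Logical; informational only.
#' @return An object of class `management_config`.
#' @export
management_config <- function(limit_Gy = c(kidneys = 23, bone_marrow = 2),
                              margin = 0.10, override = FALSE) {
  limit_Gy <- unlist(limit_Gy)
  if (is.null(names(limit_Gy)) || any(names(limit_Gy) == "")) {
    abort_prrt("`limit_Gy` must be a named vector", "prrtdose_config_error")
  }
  if (any(!is.finite(limit_Gy)) || any(limit_Gy <= 0)) {
    abort_prrt("all limits must be > 0", "prrtdose_config_error")
  }
  stopifnot_scalar_number(margin, "margin")
  if (margin < 0) abort_prrt("margin must be >= 0", "prrtdose_config_error")
  structure(list(limit_Gy = limit_Gy, margin = margin,
                 threshold_Gy = limit_Gy * (1 + margin),
                 override = isTRUE(override)),
            class = "management_config")
}

#' Expected cumulative dose after the next cycle
#'
#' Given the doses of the previous `p` cycles for one organ, the
#' expected cumulative dose after cycle `p + 1` is the cumulative dose
#' plus the mean per-cycle dose: `sum(d) * (p + 1) / p`.
#'
#' @param cycle_doses Numeric vector of per-cycle doses (any unit; the
#'   result is in the same unit); length >= 1.
#' @return Expected cumulative dose after the next cycle.
#' @examples
#' expected_after_next(c(4, 6))  # 15
#' expected_after_next(5)        # 10
#' @export
expected_after_next <- function(cycle_doses) {
  cycle_doses <- as.numeric(cycle_doses)
  p <- length(cycle_doses)
  if (p < 1L) {
    abort_prrt("need at least one completed cycle", "prrtdose_insufficient_history")
  }
  if (any(!is.finite(cycle_doses)) || any(cycle_doses < 0)) {
    abort_prrt("cycle doses must be finite and >= 0", "prrtdose_domain_error")
  }
  sum(cycle_doses) * (p + 1) / p
}

#' Treatment-continuation decision
#'
#' Withholds further treatment if and only if the expected cumulative
#' dose of any managed organ strictly exceeds `limit * (1 + margin)`
#' ("will exceed": boundary equality continues treatment). All
#' triggering organs are reported.
#'
#' @param expected_Gy Named numeric vector organ -> expected cumulative
#'   dose after the next cycle, Gy; must cover every organ in `config`.
#' @param config A [management_config].
#' @return List with `decision` (`"continue"` or `"withhold"`),
#'   `triggering` (character vector of organs over threshold) and
#'   `threshold_Gy`.
#' @examples
#' decide_continuation(c(kidneys = 20, bone_marrow = 1), management_config())
#' @export
decide_continuation <- function(expected_Gy, config = management_config()) {
  expected_Gy <- unlist(expected_Gy)
  miss <- setdiff(names(config$limit_Gy), names(expected_Gy))
  if (length(miss) > 0) {
    abort_prrt(sprintf("expected doses missing for: %s",
                       paste(miss, collapse = ", ")), "prrtdose_input_error")
  }
  organs <- names(config$limit_Gy)
  over <- expected_Gy[organs] > config$threshold_Gy[organs]
  trig <- organs[over]
  list(decision = if (length(trig) > 0) "withhold" else "continue",
       triggering = trig,
       threshold_Gy = config$threshold_Gy)
}

#' CT acquisitions required by each protocol
#'
#' The classical protocol performs full dosimetry after the first cycle
#' with three SPECT/CT acquisitions and one SPECT/CT per later cycle:
#' `3 + (n_cycles - 1)` CTs (6 for a typical 4-cycle course). The
#' single-CT protocol acquires one CT (with the first scan) and
#' registers it to all subsequent SPECTs. `ct_reduction()` gives the
#' fractional reduction `1 - single/classical` (5/6 ~ 83% for 4 cycles).
#'
#' @param protocol `"classical"` or `"single_ct"`.
#' @param n_cycles Number of treatment cycles, integer >= 1.
#' @return Number of CT acquisitions (`ct_count`) or the fractional
#'   reduction (`ct_reduction`).
#' @examples
#' ct_count("classical", 4)  # 6
#' ct_reduction(4)           # 5/6
#' @export
ct_count <- function(protocol = c("classical", "single_ct"), n_cycles) {
  protocol <- match.arg(protocol)
  stopifnot_scalar_number(n_cycles, "n_cycles")
  if (n_cycles < 1) abort_prrt("n_cycles must be >= 1", "prrtdose_domain_error")
  if (protocol == "classical") 3 + (n_cycles - 1) else 1
}

#' @rdname ct_count
#' @export
ct_reduction <- function(n_cycles) {
  1 - ct_count("single_ct", n_cycles) / ct_count("classical", n_cycles)
}

#' Run the full dosimetry course for one patient
#'
#' Composes the pipeline for one patient: cycle-1 mono-exponential fits
#' for every sampled organ (blood included), propagation of the cycle-1
#' effective half-lives to later cycles from their single ~20 h sample,
#' residence-time integration, MIRD dose calculation per target organ,
#' cumulative-dose tracking, and the withholding decision after every
#' cycle. Once a withhold is issued, later cycles in the input are not
#' processed.
#'
#' @param samples A [timed_samples] data frame for one patient, all
#'   cycles; cycle 1 must have >= 2 time points per fitted organ.
#' @param voi_masses Named numeric vector organ -> VOI mass (kg) applied
#'   to every cycle, or a data frame with columns `cycle`, `organ`,
#'   `mass_kg` (cycles missing from it fall back to the cycle-1 masses).
#' @param a_adm Numeric vector of administered activities (MBq), one per
#'   cycle in cycle order, or a data frame with columns `cycle`,
#'   `a_adm_MBq`.
#' @param table A [dose_factor_table].
#' @param config A [management_config].
#' @param target_organs Dose targets to compute; decisions use the
#'   organs in `config` (which must be a subset).
#' @param patient_id Optional identifier carried into the report.
#' @return An object of class `patient_course`: list with `patient_id`,
#'   `phantom_sex`, per-cycle records (`cycle`, `a_adm_MBq`,
#'   `dose_mGy`, `cumulative_mGy`, `expected_Gy`, `decision`,
#'   `triggering`), `decisions`, and `final_decision`.
#' @export
run_course <- function(samples, voi_masses, a_adm, table,
                       config = management_config(),
                       target_organs = c("kidneys", "bone_marrow"),
                       patient_id = NA_character_) {
  samples <- validate_timed_samples(as.data.frame(samples))
  cycles <- sort(unique(samples$cycle))
  if (cycles[1] != 1L) {
    abort_prrt("cycle 1 measurements are required", "prrtdose_input_error")
  }
  miss <- setdiff(names(config$limit_Gy), target_organs)
  if (length(miss) > 0) {
    abort_prrt(sprintf("managed organ(s) not among target_organs: %s",
                       paste(miss, collapse = ", ")), "prrtdose_input_error")
  }

  if (is.data.frame(a_adm)) {
    a_vec <- stats::setNames(a_adm$a_adm_MBq, a_adm$cycle)
  } else {
    a_vec <- stats::setNames(as.numeric(a_adm), seq_along(a_adm))
  }

  mass_for_cycle <- function(cyc) {
    if (is.data.frame(voi_masses)) {
      m <- voi_masses[voi_masses$cycle == cyc, , drop = FALSE]
      if (nrow(m) == 0) m <- voi_masses[voi_masses$cycle == 1L, , drop = FALSE]
      stats::setNames(m$mass_kg, m$organ)
    } else {
      unlist(voi_masses)
    }
  }

  # cycle-1 reference fits, one per sampled organ
  s1 <- samples[samples$cycle == 1L, , drop = FALSE]
  ref_fits <- lapply(split(s1, s1$organ), fit_monoexp)

  records <- list()
  decisions <- character(0)
  doses_by_organ <- stats::setNames(
    rep(list(numeric(0)), length(target_organs)), target_organs)

  for (cyc in cycles) {
    a <- a_vec[[as.character(cyc)]]
    if (is.null(a) || is.na(a)) {
      abort_prrt(sprintf("no administered activity for cycle %d", cyc),
                 "prrtdose_input_error")
    }
    sc <- samples[samples$cycle == cyc, , drop = FALSE]
    fits <- if (cyc == 1L) ref_fits else {
      lapply(split(sc, sc$organ), function(sub) {
        ref <- ref_fits[[sub$organ[1]]]
        if (is.null(ref)) {
          abort_prrt(sprintf("organ '%s' appears in cycle %d but not cycle 1",
                             sub$organ[1], cyc), "prrtdose_input_error")
        }
        if (nrow(sub) >= 2L) fit_monoexp(sub) else rescale_to_cycle(ref, sub[1, ])
      })
    }
    rts_all <- lapply(fits, residence_time, a_adm = a)
    organ_rts <- rts_all[setdiff(names(rts_all), "blood")]
    rts <- residence_time_set(organ_rts, mass_for_cycle(cyc))

    dose <- vapply(target_organs, function(tg) {
      if (tg == "bone_marrow") {
        if (is.null(rts_all$blood)) {
          abort_prrt("bone marrow dose requires blood samples",
                     "prrtdose_input_error")
        }
        marrow_dose(a, rts_all$blood, rts, table)$total_mGy
      } else if (tg == "tumor") {
        if (is.null(rts$rt[["tumor"]])) 0 else tumor_dose(a, rts$rt[["tumor"]], table)
      } else {
        organ_dose(a, tg, rts, table)$total_mGy
      }
    }, numeric(1))

    for (tg in target_organs) {
      doses_by_organ[[tg]] <- c(doses_by_organ[[tg]], dose[[tg]])
    }
    cumulative <- vapply(doses_by_organ, sum, numeric(1))
    expected_Gy <- vapply(doses_by_organ, function(d) {
      mgy_to_gy(expected_after_next(d))
    }, numeric(1))
    dec <- decide_continuation(expected_Gy[names(config$limit_Gy)], config)
    decisions <- c(decisions, dec$decision)

    records[[length(records) + 1L]] <- list(
      cycle = cyc, a_adm_MBq = a,
      dose_mGy = as.list(dose),
      cumulative_mGy = as.list(cumulative),
      expected_Gy = as.list(expected_Gy),
      decision = dec$decision,
      triggering = dec$triggering)

    if (dec$decision == "withhold") break
  }

  structure(list(
    patient_id = patient_id,
    phantom_sex = table$phantom_sex,
    config = list(limit_Gy = as.list(config$limit_Gy), margin = config$margin),
    cycles = records,
    decisions = decisions,
    final_decision = decisions[length(decisions)]
  ), class = "patient_course")
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf("PRRT course %s: %d cycle(s), final decision '%s'\n",
              x$patient_id, length(x$cycles), x$final_decision))
  for (r in x$cycles) {
    cat(sprintf("  cycle %d (%.0f MBq):", r$cycle, r$a_adm_MBq))
    for (o in names(r$dose_mGy)) {
      cat(sprintf(" %s %.3g Gy", o, mgy_to_gy(r$dose_mGy[[o]])))
    }
    cat(sprintf(" -> %s\n", r$decision))
  }
  invisible(x)
}
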