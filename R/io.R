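require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort_prrt(sprintf("%s: missing column(s): %s", path,
                       paste(miss, collapse = ", ")), "prrtdose_parse_error")
  }
}

#' Read / write activity-concentration sample files
#'
#' The samples CSV has one measurement per row with a mandatory header:
#' `patient_id, sex, cycle, organ, time_h, conc_MBq_per_kg, source`.
#' Unknown organ labels, negative concentrations, non-positive times and
#' duplicate (patient, cycle, organ, time) rows are rejected with the
#' offending row number.
#'
#' @param path CSV file path.
#' @param samples Data frame as returned by `read_samples()` (columns
#'   as above).
#' @return `read_samples()` returns a data frame with columns
#'   `patient_id`, `sex`, `cycle`, `organ`, `time_h`, `conc`, `source`;
#'   `write_samples()` returns `path` invisibly.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) {
    abort_prrt(sprintf("samples file not found: %s", path), "prrtdose_input_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("patient_id", "sex", "cycle", "organ", "time_h",
                        "conc_MBq_per_kg", "source"), path)
  bad <- which(!df$organ %in% SAMPLE_ORGANS)
  if (length(bad) > 0) {
    abort_prrt(sprintf("%s: unknown organ '%s' at row %d", path,
                       df$organ[bad[1]], bad[1]), "prrtdose_parse_error")
  }
  bad <- which(!is.finite(df$conc_MBq_per_kg) | df$conc_MBq_per_kg < 0)
  if (length(bad) > 0) {
    abort_prrt(sprintf("%s: invalid concentration at row %d", path, bad[1]),
               "prrtdose_parse_error")
  }
  bad <- which(!is.finite(df$time_h) | df$time_h <= 0)
  if (length(bad) > 0) {
    abort_prrt(sprintf("%s: invalid time at row %d", path, bad[1]),
               "prrtdose_parse_error")
  }
  key <- paste(df$patient_id, df$cycle, df$organ, df$time_h)
  if (anyDuplicated(key)) {
    abort_prrt(sprintf("%s: duplicate (patient, cycle, organ, time) at row %d",
                       path, anyDuplicated(key)), "prrtdose_parse_error")
  }
  names(df)[names(df) == "conc_MBq_per_kg"] <- "conc"
  df$cycle <- as.integer(df$cycle)
  df
}

#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  df <- as.data.frame(samples)
  if ("conc" %in% names(df) && !"conc_MBq_per_kg" %in% names(df)) {
    names(df)[names(df) == "conc"] <- "conc_MBq_per_kg"
  }
  cols <- c("patient_id", "sex", "cycle", "organ", "time_h",
            "conc_MBq_per_kg", "source")
  utils::write.csv(df[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read VOI-mass and administered-activity tables
#'
#' `read_voi_masses()` expects columns `patient_id, cycle, organ,
#' mass_kg` (masses > 0, density 1.0 g/cm3 so SPECT/CT VOI volume in L
#' equals mass in kg). `read_administered()` expects `patient_id,
#' cycle, a_adm_MBq` (> 0).
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_voi_masses <- function(path) {
  if (!file.exists(path)) {
    abort_prrt(sprintf("VOI mass file not found: %s", path), "prrtdose_input_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("patient_id", "cycle", "organ", "mass_kg"), path)
  bad <- which(!is.finite(df$mass_kg) | df$mass_kg <= 0)
  if (length(bad) > 0) {
    abort_prrt(sprintf("%s: invalid mass at row %d", path, bad[1]),
               "prrtdose_parse_error")
  }
  df$cycle <- as.integer(df$cycle)
  df
}

#' @rdname read_voi_masses
#' @export
read_administered <- function(path) {
  if (!file.exists(path)) {
    abort_prrt(sprintf("administered-activity file not found: %s", path),
               "prrtdose_input_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("patient_id", "cycle", "a_adm_MBq"), path)
  bad <- which(!is.finite(df$a_adm_MBq) | df$a_adm_MBq <= 0)
  if (length(bad) > 0) {
    abort_prrt(sprintf("%s: invalid activity at row %d", path, bad[1]),
               "prrtdose_parse_error")
  }
  df$cycle <- as.integer(df$cycle)
  df
}

#' Write a synthetic cohort as pipeline input files
#'
#' Materializes a generated cohort as the CSV files the analysis
#' consumes — `samples.csv`, `voi_masses.csv`, `administered.csv` —
#' plus `truth.json` holding the true kinetic parameters and analytic
#' per-cycle doses for oracle comparisons.
#'
#' @param cohort List of `true_patient` objects from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param table [dose_factor_table] used for the truth doses.
#' @param protocol Simulation protocol for the samples.
#' @param ... Passed to [simulate_measurements()] (e.g. `noise_sd`).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort_inputs <- function(cohort, dir, table,
                                protocol = c("classical", "single_ct"), ...) {
  protocol <- match.arg(protocol)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- do.call(rbind, lapply(cohort, function(p) {
    s <- simulate_course(p, protocol, ...)
    cbind(patient_id = p$patient_id, sex = p$sex, s)
  }))
  masses <- do.call(rbind, lapply(cohort, function(p) {
    org <- p$organs[!is.na(p$organs$voi_mass_kg), ]
    expand.grid(patient_id = p$patient_id, cycle = seq_len(p$n_cycles),
                organ = org$organ, stringsAsFactors = FALSE) |>
      merge(data.frame(organ = org$organ, mass_kg = org$voi_mass_kg))
  }))
  adm <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, cycle = seq_len(p$n_cycles),
               a_adm_MBq = p$a_adm, stringsAsFactors = FALSE)
  }))
  truth <- lapply(cohort, function(p) {
    list(patient_id = p$patient_id, sex = p$sex, seed = p$seed,
         organs = p$organs, a_adm_MBq = p$a_adm,
         true_dose_mGy = true_dose(p, table))
  })
  paths <- c(samples = file.path(dir, "samples.csv"),
             voi_masses = file.path(dir, "voi_masses.csv"),
             administered = file.path(dir, "administered.csv"),
             truth = file.path(dir, "truth.json"))
  write_samples(samples, paths[["samples"]])
  utils::write.csv(masses[c("patient_id", "cycle", "organ", "mass_kg")],
                   paths[["voi_masses"]], row.names = FALSE)
  utils::write.csv(adm, paths[["administered"]], row.names = FALSE)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Run the dosimetry course for every patient in the input files
#'
#' Convenience wrapper grouping the samples by patient and calling
#' [run_course()] per patient.
#'
#' @param samples,voi_masses,adm Data frames as returned by
#'   [read_samples()], [read_voi_masses()], [read_administered()].
#' @param table A [dose_factor_table].
#' @param config A [management_config].
#' @param target_organs Dose targets passed to [run_course()].
#' @return List of `patient_course` objects, named by patient id.
#' @export
run_cohort <- function(samples, voi_masses, adm, table,
                       config = management_config(),
                       target_organs = c("kidneys", "bone_marrow")) {
  ids <- unique(samples$patient_id)
  out <- lapply(ids, function(id) {
    run_course(samples[samples$patient_id == id, ],
               voi_masses[voi_masses$patient_id == id,
                          c("cycle", "organ", "mass_kg")],
               adm[adm$patient_id == id, c("cycle", "a_adm_MBq")],
               table, config, target_organs, patient_id = id)
  })
  stats::setNames(out, ids)
}

#' Write / read a course report
#'
#' The JSON report nests per-cycle doses (mGy), cumulative doses,
#' expected doses after the next cycle (Gy), the decision and its
#' triggering organs, plus the management configuration used. The flat
#' CSV companion has one row per (patient, cycle).
#'
#' @param courses A `patient_course` or list of them.
#' @param json_path,csv_path Output paths (`NULL` skips that format).
#' @param path JSON report path for `read_course_report()`.
#' @return Invisibly, the written paths; `read_course_report()` returns
#'   the list of course records.
#' @export
write_course_report <- function(courses, json_path = NULL, csv_path = NULL) {
  if (inherits(courses, "patient_course")) courses <- list(courses)
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(courses, unclass), json_path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(courses, function(crs) {
      do.call(rbind, lapply(crs$cycles, function(r) {
        row <- data.frame(patient_id = crs$patient_id, cycle = r$cycle,
                          a_adm_MBq = r$a_adm_MBq, stringsAsFactors = FALSE)
        for (o in names(r$dose_mGy)) {
          row[[paste0("dose_", o, "_mGy")]] <- r$dose_mGy[[o]]
          row[[paste0("cumulative_", o, "_Gy")]] <- mgy_to_gy(r$cumulative_mGy[[o]])
          row[[paste0("expected_", o, "_Gy")]] <- r$expected_Gy[[o]]
        }
        row$decision <- r$decision
        row$triggering <- paste(r$triggering, collapse = ";")
        row
      }))
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(c(json = json_path, csv = csv_path))
}

#' @rdname write_course_report
#' @export
read_course_report <- function(path) {
  if (!file.exists(path)) {
    abort_prrt(sprintf("course report not found: %s", path), "prrtdose_input_error")
  }
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

course_cumulative <- function(course, organ) {
  last <- course$cycles[[length(course$cycles)]]
  as.numeric(last$cumulative_mGy[[organ]])
}

#' Compare two protocols' course reports
#'
#' Pairs the courses of two protocol runs by patient id and summarizes
#' their agreement: Bland-Altman relative differences and Pearson
#' correlation of the cumulative doses per managed organ, and the
#' concordance of the final management decisions.
#'
#' @param courses_a,courses_b Lists of `patient_course` objects (or
#'   course records read back by [read_course_report()]), same patients.
#' @param organs Organs to compare (default kidneys, bone marrow).
#' @param signed Passed to [bland_altman()].
#' @return An object of class `protocol_comparison`: list with one
#'   entry per organ (`bland_altman`, `pearson`, `cumulative_Gy_a/b`),
#'   `concordance`, and `patient_ids`.
#' @export
compare_courses <- function(courses_a, courses_b,
                            organs = c("kidneys", "bone_marrow"),
                            signed = TRUE) {
  ids_a <- vapply(courses_a, function(x) x$patient_id, character(1))
  ids_b <- vapply(courses_b, function(x) x$patient_id, character(1))
  ids <- intersect(ids_a, ids_b)
  if (length(ids) < 2L) {
    abort_prrt("need at least 2 common patients to compare", "prrtdose_input_error")
  }
  ca <- courses_a[match(ids, ids_a)]
  cb <- courses_b[match(ids, ids_b)]
  per_organ <- lapply(organs, function(o) {
    a <- vapply(ca, course_cumulative, numeric(1), organ = o)
    b <- vapply(cb, course_cumulative, numeric(1), organ = o)
    list(bland_altman = bland_altman(a, b, labels = ids, signed = signed),
         pearson = pearson_agreement(a, b),
         cumulative_Gy_a = mgy_to_gy(a), cumulative_Gy_b = mgy_to_gy(b))
  })
  names(per_organ) <- organs
  conc <- decision_concordance(
    vapply(ca, function(x) x$final_decision, character(1)),
    vapply(cb, function(x) x$final_decision, character(1)))
  structure(list(organs = per_organ, concordance = conc, patient_ids = ids),
            class = "protocol_comparison")
}

#' @rdname compare_courses
#' @param comparison A `protocol_comparison`.
#' @param json_path,csv_path Output paths (`NULL` skips).
#' @export
write_comparison <- function(comparison, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    summ <- lapply(comparison$organs, function(x) {
      list(mean_diff_pct = x$bland_altman$mean_pct,
           sd_diff_pct = x$bland_altman$sd_pct,
           loa_low_pct = x$bland_altman$loa_low_pct,
           loa_high_pct = x$bland_altman$loa_high_pct,
           pearson_r = x$pearson$r, pearson_p = x$pearson$p,
           n = x$bland_altman$n)
    })
    jsonlite::write_json(list(organs = summ,
                              concordance = comparison$concordance,
                              patient_ids = comparison$patient_ids),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(names(comparison$organs), function(o) {
      x <- comparison$organs[[o]]
      data.frame(patient_id = comparison$patient_ids, organ = o,
                 cumulative_Gy_a = x$cumulative_Gy_a,
                 cumulative_Gy_b = x$cumulative_Gy_b,
                 diff_pct = x$bland_altman$differences$diff_pct,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(c(json = json_path, csv = csv_path))
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat(sprintf("Protocol comparison over %d patients\n", length(x$patient_ids)))
  for (o in names(x$organs)) {
    ba <- x$organs[[o]]$bland_altman
    pe <- x$organs[[o]]$pearson
    cat(sprintf("  %s: mean diff %.2f +/- %.2f%%, r = %.3f (p = %.2g)\n",
                o, ba$mean_pct, ba$sd_pct, pe$r, pe$p))
  }
  cat(sprintf("  management concordance: %d/%d discordant\n",
              x$concordance$discordant, x$concordance$n))
  invisible(x)
}
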