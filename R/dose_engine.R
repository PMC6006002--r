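#' Residence-time set for one cycle
#'
#' Bundles the concentration residence times of all source regions of
#' one treatment cycle with the delineated VOI masses (tissue density
#' 1.0 g/cm3, so VOI volume in cm3 equals mass in grams). Organs whose
#' factors are concentration-kind (blood, remainder) need no VOI mass.
#'
#' @param rt Named numeric vector organ -> residence time in
#'   (MBq.s)/(MBq.kg), or a list of `residence_time` objects.
#' @param voi_mass_kg Named numeric vector organ -> delineated VOI mass
#'   in kg; may omit blood/remainder.
#' @return An object of class `residence_time_set`.
#' @export
residence_time_set <- function(rt, voi_mass_kg = numeric(0)) {
  if (is.list(rt) && !is.data.frame(rt) && length(rt) > 0 &&
      inherits(rt[[1]], "residence_time")) {
    v <- vapply(rt, function(r) r$value, numeric(1))
    names(v) <- vapply(rt, function(r) r$organ, character(1))
    rt <- v
  }
  rt <- unlist(rt)
  if (length(rt) > 0 && (is.null(names(rt)) || any(names(rt) == ""))) {
    abort_prrt("`rt` must be a named vector", "prrtdose_input_error")
  }
  if (any(!is.finite(rt)) || any(rt < 0)) {
    abort_prrt("residence times must be finite and >= 0", "prrtdose_domain_error")
  }
  voi_mass_kg <- unlist(voi_mass_kg)
  if (length(voi_mass_kg) > 0 && any(voi_mass_kg <= 0)) {
    abort_prrt("VOI masses must be > 0", "prrtdose_domain_error")
  }
  structure(list(rt = rt, voi_mass_kg = voi_mass_kg),
            class = "residence_time_set")
}

# Look up one factor row; NULL when absent. Tumors radiate with the
# liver's factors (tumors are predominantly hepatic), paired with the
# tumor's own VOI mass.
lookup_factor <- function(table, source, target) {
  src <- if (source == "tumor") "liver" else source
  f <- table$factors
  row <- f[f$source == src & f$target == target, , drop = FALSE]
  if (nrow(row) == 0) NULL else row[1, ]
}

cross_contribution <- function(a_adm, s, rts, table, target) {
  row <- lookup_factor(table, s, target)
  if (is.null(row)) {
    warn_prrt(sprintf("no dose factor for source '%s' -> target '%s'; contributes 0",
                      s, target), "prrtdose_missing_factor")
    return(0)
  }
  tr <- rts$rt[[s]]
  if (row$kind == "organ_level") {
    m <- if (s %in% names(rts$voi_mass_kg)) rts$voi_mass_kg[[s]] else NA_real_
    if (is.na(m)) {
      abort_prrt(sprintf("organ-level source '%s' has no VOI mass", s),
                 "prrtdose_config_error")
    }
    a_adm * tr * m * row$value
  } else {
    a_adm * tr * row$value
  }
}

new_dose_result <- function(target, self, cross) {
  structure(list(target = target,
                 self_dose_mGy = self,
                 cross_dose_mGy = cross,
                 total_mGy = self + sum(unlist(cross))),
            class = "organ_dose_result")
}

#' Absorbed dose to an organ (MIRD self- plus cross-dose)
#'
#' Computes the absorbed dose to a target organ for one cycle as
#' `D = A_adm * (t_r(target) * DF(target<-target) + sum_s t_r(s) * DF(target<-s))`
#' with concentration residence times in (MBq.s)/(MBq.kg) and the
#' mass-scaling convention: an organ-level source term is
#' `t_r(s) * m_voi(s)`, while the organ-level *self* S value is rescaled
#' by `m_phantom/m_voi` (standard inverse-mass scaling of the
#' self-absorbed fraction), so the VOI mass cancels and the self term is
#' `A_adm * t_r(target) * DF_self * m_phantom(target)`. Concentration-kind
#' factors (mGy.kg/(MBq.s)) multiply the residence time directly.
#' Tumor sources use the liver's factors with the tumor VOI mass.
#' Sources with no factor in the table contribute zero with a warning.
#'
#' @param a_adm Administered activity of the cycle, MBq.
#' @param target Target organ label.
#' @param rts A [residence_time_set] for the cycle.
#' @param table A [dose_factor_table].
#' @return An `organ_dose_result`: list with `target`, `self_dose_mGy`,
#'   `cross_dose_mGy` (named list, one entry per source), `total_mGy`
#'   (exact sum of the components).
#' @examples
#' tab <- dose_factor_table("male", c(kidneys = 300),
#'   data.frame(source = "kidneys", target = "kidneys",
#'              value = 1e-5, kind = "organ_level"))
#' rts <- residence_time_set(c(kidneys = 100), c(kidneys = 0.28))
#' organ_dose(1000, "kidneys", rts, tab)$total_mGy  # 0.3
#' @export
organ_dose <- function(a_adm, target, rts, table) {
  stopifnot_scalar_number(a_adm, "a_adm")
  if (!target %in% names(rts$rt)) {
    abort_prrt(sprintf("no residence time for target '%s'", target),
               "prrtdose_input_error")
  }
  self_row <- lookup_factor(table, target, target)
  if (is.null(self_row)) {
    abort_prrt(sprintf("no self dose factor for '%s' in table", target),
               "prrtdose_config_error")
  }
  tr_t <- rts$rt[[target]]
  if (self_row$kind == "organ_level") {
    m_ph <- table$phantom_mass_g[[target]]
    if (is.null(m_ph) || is.na(m_ph)) {
      abort_prrt(sprintf("no phantom mass for '%s'", target),
                 "prrtdose_config_error")
    }
    self <- a_adm * tr_t * self_row$value * (m_ph / 1000)
  } else {
    self <- a_adm * tr_t * self_row$value
  }
  sources <- setdiff(names(rts$rt), c(target, "blood"))
  cross <- lapply(sources, cross_contribution,
                  a_adm = a_adm, rts = rts, table = table, target = target)
  names(cross) <- sources
  new_dose_result(target, self, cross)
}

#' Absorbed dose to the bone marrow
#'
#' The marrow self-dose is derived from the blood curve: the activity
#' concentration in the marrow is taken equal to that in the blood, so
#' the self term is `A_adm * t_r(blood) * DF_marrow_self` with a
#' concentration-kind marrow self factor. The remainder-of-body
#' cross-dose uses the table's replacement factor
#' `df_remainder_to_marrow` (30.3 nGy.kg/(MBq.s) male, 35.8 female by
#' default). All other sources contribute cross-doses exactly as in
#' [organ_dose()].
#'
#' @param a_adm Administered activity, MBq.
#' @param blood_rt Blood residence time: a `residence_time` object or a
#'   number in (MBq.s)/(MBq.kg).
#' @param rts A [residence_time_set] with the other source organs
#'   (may be empty).
#' @param table A [dose_factor_table] with a concentration-kind
#'   bone_marrow self factor.
#' @return An `organ_dose_result` for target `bone_marrow`.
#' @export
marrow_dose <- function(a_adm, blood_rt, rts = residence_time_set(numeric(0)),
                        table) {
  stopifnot_scalar_number(a_adm, "a_adm")
  if (inherits(blood_rt, "residence_time")) blood_rt <- blood_rt$value
  if (is.null(blood_rt) || !is.finite(blood_rt)) {
    abort_prrt("blood residence time is missing", "prrtdose_input_error")
  }
  f <- table$factors
  self_row <- f[f$source == "bone_marrow" & f$target == "bone_marrow" &
                  f$kind == "concentration", , drop = FALSE]
  if (nrow(self_row) == 0) {
    abort_prrt("table has no concentration-kind bone_marrow self factor",
               "prrtdose_config_error")
  }
  self <- a_adm * blood_rt * self_row$value[1]
  sources <- setdiff(names(rts$rt), c("bone_marrow", "blood"))
  cross <- lapply(sources, function(s) {
    if (s == "remainder") {
      a_adm * rts$rt[[s]] * table$df_remainder_to_marrow
    } else {
      cross_contribution(a_adm, s, rts, table, "bone_marrow")
    }
  })
  names(cross) <- sources
  new_dose_result("bone_marrow", self, cross)
}

#' Absorbed dose to a tumor
#'
#' Tumor self-dose only: the concentration residence time is multiplied
#' by the tumor dose concentration factor (default 0.0236 mGy.g/(MBq.s);
#' the factor 1e-3 converts g to kg so the product with the residence
#' time in (MBq.s)/(MBq.kg) closes to mGy) and by the administered
#' activity.
#'
#' @param a_adm Administered activity, MBq; > 0.
#' @param tumor_rt Tumor residence time: `residence_time` object or
#'   number, >= 0.
#' @param table A [dose_factor_table] (supplies `dcf_tumor`).
#' @return Tumor absorbed dose, mGy.
#' @examples
#' tab <- dose_factor_table("male", c(kidneys = 300),
#'   data.frame(source = "kidneys", target = "kidneys",
#'              value = 1e-5, kind = "organ_level"))
#' tumor_dose(7400, 1000, tab)  # 174.64
#' @export
tumor_dose <- function(a_adm, tumor_rt, table) {
  stopifnot_scalar_number(a_adm, "a_adm")
  if (a_adm <= 0) abort_prrt("a_adm must be > 0", "prrtdose_domain_error")
  if (inherits(tumor_rt, "residence_time")) tumor_rt <- tumor_rt$value
  if (!is.finite(tumor_rt) || tumor_rt < 0) {
    abort_prrt("tumor residence time must be >= 0", "prrtdose_domain_error")
  }
  a_adm * tumor_rt * table$dcf_tumor * 1e-3
}

#' @export
print.organ_dose_result <- function(x, ...) {
  cat(sprintf("Dose to %s: %.4g mGy (self %.4g, cross %.4g)\n",
              x$target, x$total_mGy, x$self_dose_mGy,
              sum(unlist(x$cross_dose_mGy))))
  invisible(x)
}
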