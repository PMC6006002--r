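FACTOR_KINDS <- c("organ_level", "concentration")
TABLE_ORGANS <- c("kidneys", "liver", "spleen", "remainder", "tumor",
                  "blood", "bone_marrow")

#' Dose-factor table for one reference phantom
#'
#' Container for the source-to-target dose factors (S values) of one
#' anthropomorphic phantom sex, the phantom organ masses used for mass
#' scaling, the tumor dose concentration factor, and the replacement
#' remainder-of-body to bone-marrow dose factor. Two factor kinds are
#' distinguished and close the unit bookkeeping of the dose equation:
#'
#' * `organ_level` factors are in mGy/(MBq.s) and are paired with a
#'   source organ mass (kg) to turn a concentration residence time into
#'   an organ-level time-integrated activity;
#' * `concentration` factors are in mGy.kg/(MBq.s) and multiply the
#'   concentration residence time directly (blood/marrow, remainder).
#'
#' Dose factors are user-supplied input. The tables shipped with the
#' package (`synthetic_dose_factors()`) are synthetic fixtures with
#' plausible magnitudes, not values from any published phantom library.
#'
#' @param phantom_sex `"male"` or `"female"`.
#' @param phantom_mass_g Named numeric vector, organ -> phantom organ
#'   mass in grams; all > 0.
#' @param factors Data frame with columns `source`, `target`, `value`
#'   (>= 0) and `kind` (`"organ_level"` or `"concentration"`);
#'   (source, target) pairs must be unique.
#' @param dcf_tumor Tumor dose concentration factor, mGy.g/(MBq.s);
#'   default 0.0236.
#' @param df_remainder_to_marrow Remainder-of-body to bone-marrow dose
#'   factor, mGy.kg/(MBq.s). Defaults to 3.03e-5 for the male phantom
#'   and 3.58e-5 for the female phantom (30.3 / 35.8 nGy.kg/(MBq.s)),
#'   replacing the phantom value which overestimates the marrow
#'   cross-dose when there is no bone uptake.
#' @return An object of class `dose_factor_table`.
#' @export
dose_factor_table <- function(phantom_sex, phantom_mass_g, factors,
                              dcf_tumor = 0.0236,
                              df_remainder_to_marrow = NULL) {
  phantom_sex <- match.arg(phantom_sex, c("male", "female"))
  if (is.null(df_remainder_to_marrow)) {
    df_remainder_to_marrow <- if (phantom_sex == "male") 3.03e-5 else 3.58e-5
  }
  phantom_mass_g <- unlist(phantom_mass_g)
  if (is.null(names(phantom_mass_g)) || any(names(phantom_mass_g) == "")) {
    abort_prrt("`phantom_mass_g` must be a named vector", "prrtdose_config_error")
  }
  bad <- setdiff(names(phantom_mass_g), TABLE_ORGANS)
  if (length(bad) > 0) {
    abort_prrt(sprintf("unknown organ(s) in phantom masses: %s",
                       paste(bad, collapse = ", ")), "prrtdose_config_error")
  }
  if (any(!is.finite(phantom_mass_g)) || any(phantom_mass_g <= 0)) {
    abort_prrt("all phantom masses must be > 0", "prrtdose_config_error")
  }
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  need <- c("source", "target", "value", "kind")
  miss <- setdiff(need, names(factors))
  if (length(miss) > 0) {
    abort_prrt(sprintf("factor table missing column(s): %s",
                       paste(miss, collapse = ", ")), "prrtdose_config_error")
  }
  bad <- setdiff(unique(c(factors$source, factors$target)), TABLE_ORGANS)
  if (length(bad) > 0) {
    abort_prrt(sprintf("unknown organ(s) in factors: %s",
                       paste(bad, collapse = ", ")), "prrtdose_config_error")
  }
  if (!all(factors$kind %in% FACTOR_KINDS)) {
    abort_prrt("factor `kind` must be 'organ_level' or 'concentration'",
               "prrtdose_config_error")
  }
  if (any(!is.finite(factors$value)) || any(factors$value < 0)) {
    abort_prrt("all factor values must be >= 0", "prrtdose_config_error")
  }
  if (anyDuplicated(factors[c("source", "target")])) {
    abort_prrt("duplicate (source, target) pair in factor table",
               "prrtdose_config_error")
  }
  stopifnot_scalar_number(dcf_tumor, "dcf_tumor")
  stopifnot_scalar_number(df_remainder_to_marrow, "df_remainder_to_marrow")
  structure(list(
    phantom_sex = phantom_sex,
    phantom_mass_g = phantom_mass_g,
    factors = factors[need],
    dcf_tumor = dcf_tumor,
    df_remainder_to_marrow = df_remainder_to_marrow
  ), class = "dose_factor_table")
}

#' Read / write a dose-factor table as JSON
#'
#' The on-disk format is a JSON object with keys `phantom_sex`,
#' `phantom_mass_g` (object organ -> grams), `dcf_tumor`,
#' `df_remainder_to_marrow`, and `factors` (array of objects with
#' `source`, `target`, `value`, `kind`, and an optional informational
#' `units` string). Unknown organs or kinds are rejected.
#'
#' @param path File path.
#' @param table A `dose_factor_table`.
#' @return `read_dose_factor_table()` returns a `dose_factor_table`;
#'   `write_dose_factor_table()` returns `path` invisibly.
#' @export
read_dose_factor_table <- function(path) {
  if (!file.exists(path)) {
    abort_prrt(sprintf("dose-factor table not found: %s", path),
               "prrtdose_input_error")
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("phantom_sex", "phantom_mass_g", "factors")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort_prrt(sprintf("dose-factor JSON missing key(s): %s",
                       paste(miss, collapse = ", ")), "prrtdose_parse_error")
  }
  dose_factor_table(
    phantom_sex = x$phantom_sex,
    phantom_mass_g = unlist(x$phantom_mass_g),
    factors = x$factors,
    dcf_tumor = if (!is.null(x$dcf_tumor)) x$dcf_tumor else 0.0236,
    df_remainder_to_marrow = x$df_remainder_to_marrow
  )
}

#' @rdname read_dose_factor_table
#' @export
write_dose_factor_table <- function(table, path) {
  stopifnot(inherits(table, "dose_factor_table"))
  jsonlite::write_json(list(
    phantom_sex = table$phantom_sex,
    phantom_mass_g = as.list(table$phantom_mass_g),
    dcf_tumor = table$dcf_tumor,
    df_remainder_to_marrow = table$df_remainder_to_marrow,
    factors = table$factors
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Synthetic dose-factor tables shipped with the package
#'
#' Returns the synthetic fixture table for the requested phantom sex,
#' read from the JSON files under `inst/extdata/`. The factor
#' magnitudes are chosen so that typical 177Lu-DOTA-TATE kinetics give
#' realistic organ doses (kidneys a few Gy per 7.4 GBq cycle, bone
#' marrow tens of mGy), but they are synthetic stand-ins, not values
#' from OLINDA/EXM or any other phantom library.
#'
#' @param phantom_sex `"male"` or `"female"`.
#' @return A `dose_factor_table`.
#' @export
synthetic_dose_factors <- function(phantom_sex = c("male", "female")) {
  phantom_sex <- match.arg(phantom_sex)
  path <- system.file("extdata",
                      sprintf("synthetic_dose_factors_%s.json", phantom_sex),
                      package = "prrtdose", mustWork = TRUE)
  read_dose_factor_table(path)
}
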