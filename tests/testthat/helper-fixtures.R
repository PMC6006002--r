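# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Minimal table with hand-picked round numbers so expected doses can be
# verified on paper.
minimal_table <- function(sex = "male", marrow_self = 1e-5, ...) {
  dose_factor_table(
    sex,
    phantom_mass_g = c(kidneys = 300, liver = 1800, spleen = 180,
                       bone_marrow = 1100),
    factors = data.frame(
      source = c("kidneys", "liver", "bone_marrow"),
      target = c("kidneys", "kidneys", "bone_marrow"),
      value = c(1e-5, 1e-7, marrow_self),
      kind = c("organ_level", "organ_level", "concentration"),
      stringsAsFactors = FALSE),
    ...
  )
}

# Noiseless samples for one patient from explicit kinetics, on the
# clinical schedule (organs 18/25/168 h + blood 18/25 h in cycle 1, one
# 20 h sample each afterwards).
noiseless_samples <- function(kin, n_cycles) {
  do.call(rbind, lapply(seq_len(n_cycles), function(cyc) {
    t_org <- if (cyc == 1) c(18, 25, 168) else 20
    t_blood <- if (cyc == 1) c(18, 25) else 20
    do.call(rbind, lapply(names(kin), function(o) {
      tt <- if (o == "blood") t_blood else t_org
      timed_samples(o, tt, kin[[o]]$c0 * exp(-kin[[o]]$lambda * tt), cyc)
    }))
  }))
}

# Simulate + analyze one synthetic patient; returns NULL if the noisy
# blood curve is non-decaying (a specced error path at small n).
run_patient <- function(p, table, protocol = "classical",
                        config = management_config(), ...) {
  s <- simulate_course(p, protocol, ...)
  vm <- stats::setNames(p$organs$voi_mass_kg, p$organs$organ)
  vm <- vm[!is.na(vm)]
  tryCatch(
    suppressWarnings(run_course(s, vm, p$a_adm, table, config,
                                patient_id = p$patient_id)),
    prrtdose_nonphysical_fit = function(e) NULL)
}
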