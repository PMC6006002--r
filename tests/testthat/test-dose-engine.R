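test_that("organ self- and cross-doses follow the MIRD arithmetic", {
  tab <- minimal_table()
  # self term only: A * t_r * S_self * m_phantom
  rts <- residence_time_set(c(kidneys = 100), c(kidneys = 0.28))
  d <- organ_dose(1000, "kidneys", rts, tab)
  expect_equal(d$self_dose_mGy, 1000 * 100 * 1e-5 * 0.3)
  expect_equal(d$total_mGy, 0.3)

  # plus a liver cross term: A * (t_r * m_voi) * DF
  rts2 <- residence_time_set(c(kidneys = 100, liver = 50),
                             c(kidneys = 0.28, liver = 1.8))
  d2 <- organ_dose(1000, "kidneys", rts2, tab)
  expect_equal(d2$cross_dose_mGy$liver, 1000 * 50 * 1.8 * 1e-7)
  expect_equal(d2$total_mGy, 0.309)
  # components sum to total exactly
  expect_identical(d2$total_mGy,
                   d2$self_dose_mGy + sum(unlist(d2$cross_dose_mGy)))
})

test_that("the self term is independent of the drawn VOI mass", {
  # inverse-mass scaling of the self S value cancels the VOI mass at
  # fixed concentration residence time
  tab <- minimal_table()
  rts_a <- residence_time_set(c(kidneys = 100), c(kidneys = 0.30))
  rts_b <- residence_time_set(c(kidneys = 100), c(kidneys = 0.15))
  expect_equal(organ_dose(1000, "kidneys", rts_a, tab)$self_dose_mGy,
               organ_dose(1000, "kidneys", rts_b, tab)$self_dose_mGy)
})

test_that("marrow dose uses blood kinetics and the replacement remainder factor", {
  tab <- minimal_table()
  d <- marrow_dose(7400, 10, residence_time_set(numeric(0)), tab)
  expect_equal(d$total_mGy, 7400 * 10 * 1e-5)
  expect_equal(d$total_mGy, 0.74)

  # remainder cross-dose with the male replacement factor, self zeroed
  tab0 <- minimal_table(marrow_self = 0)
  dm <- marrow_dose(7400, 10, residence_time_set(c(remainder = 100)), tab0)
  expect_equal(dm$cross_dose_mGy$remainder, 7400 * 100 * 3.03e-5)
  expect_equal(dm$total_mGy, 22.422)

  # female phantom: 35.8 nGy.kg/(MBq.s), strictly larger
  tabf <- minimal_table(sex = "female", marrow_self = 0)
  df <- marrow_dose(7400, 10, residence_time_set(c(remainder = 100)), tabf)
  expect_equal(df$total_mGy, 26.492)
  expect_gt(df$total_mGy, dm$total_mGy)

  expect_error(marrow_dose(7400, NULL, residence_time_set(numeric(0)), tab),
               class = "prrtdose_input_error")
})

test_that("the nGy to mGy conversion of the remainder factor is exact", {
  expect_identical(30.3e-9 * 1e3, 3.03e-5)  # nGy.kg/(MBq.s) -> mGy.kg/(MBq.s)
  expect_identical(35.8e-9 * 1e3, 3.58e-5)
})

test_that("tumor dose is the concentration-factor product", {
  tab <- minimal_table()
  expect_equal(tumor_dose(7400, 1000, tab), 7400 * 1000 * 0.0236e-3)
  expect_equal(tumor_dose(7400, 1000, tab), 174.64)
  expect_equal(tumor_dose(7400, 0, tab), 0)
  expect_equal(tumor_dose(2 * 7400, 1000, tab), 2 * tumor_dose(7400, 1000, tab))
})

test_that("doses are homogeneous in activity and residence times", {
  tab <- minimal_table()
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 1000, 9000)
    k <- runif(1, 0.5, 3)
    tr <- runif(2, 10, 500)
    rts <- residence_time_set(c(kidneys = tr[1], liver = tr[2]),
                              c(kidneys = 0.3, liver = 1.6))
    rts_k <- residence_time_set(k * c(kidneys = tr[1], liver = tr[2]),
                                c(kidneys = 0.3, liver = 1.6))
    d <- organ_dose(a, "kidneys", rts, tab)$total_mGy
    expect_equal(organ_dose(k * a, "kidneys", rts, tab)$total_mGy, k * d)
    expect_equal(organ_dose(a, "kidneys", rts_k, tab)$total_mGy, k * d)
  }
})

test_that("tumor sources radiate with liver factors and the tumor VOI mass", {
  tab <- minimal_table()
  rts <- residence_time_set(c(kidneys = 100, tumor = 200),
                            c(kidneys = 0.3, tumor = 0.05))
  d <- organ_dose(1000, "kidneys", rts, tab)
  expect_equal(d$cross_dose_mGy$tumor, 1000 * 200 * 0.05 * 1e-7)
})

test_that("missing factors and masses are handled as specced", {
  tab <- minimal_table()
  # missing self factor -> configuration error
  expect_error(
    organ_dose(1000, "liver", residence_time_set(c(liver = 10), c(liver = 1.5)),
               tab),
    class = "prrtdose_config_error")
  # organ-level source without VOI mass -> configuration error
  expect_error(
    organ_dose(1000, "kidneys",
               residence_time_set(c(kidneys = 100, liver = 10),
                                  c(kidneys = 0.3)), tab),
    class = "prrtdose_config_error")
  # source absent from the table contributes 0 with a warning
  rts <- residence_time_set(c(kidneys = 100, spleen = 10),
                            c(kidneys = 0.3, spleen = 0.2))
  expect_warning(d <- organ_dose(1000, "kidneys", rts, tab),
                 class = "prrtdose_missing_factor")
  expect_equal(d$cross_dose_mGy$spleen, 0)
  expect_equal(d$total_mGy, d$self_dose_mGy)
})

test_that("dose-factor tables validate and round-trip through JSON", {
  tab <- minimal_table()
  path <- withr::local_tempfile(fileext = ".json")
  write_dose_factor_table(tab, path)
  tab2 <- read_dose_factor_table(path)
  expect_equal(tab2$phantom_mass_g, tab$phantom_mass_g)
  expect_equal(tab2$factors, tab$factors)
  expect_equal(tab2$df_remainder_to_marrow, tab$df_remainder_to_marrow)

  expect_error(
    dose_factor_table("male", c(pancreas = 100),
                      data.frame(source = "kidneys", target = "kidneys",
                                 value = 1e-5, kind = "organ_level")),
    class = "prrtdose_config_error")
  expect_error(
    dose_factor_table("male", c(kidneys = 300),
                      data.frame(source = c("kidneys", "kidneys"),
                                 target = c("kidneys", "kidneys"),
                                 value = c(1e-5, 2e-5),
                                 kind = "organ_level")),
    class = "prrtdose_config_error")
})

test_that("the shipped synthetic tables load and differ by phantom sex", {
  m <- synthetic_dose_factors("male")
  f <- synthetic_dose_factors("female")
  expect_s3_class(m, "dose_factor_table")
  expect_equal(m$df_remainder_to_marrow, 3.03e-5)
  expect_equal(f$df_remainder_to_marrow, 3.58e-5)
  expect_equal(m$dcf_tumor, 0.0236)
})
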