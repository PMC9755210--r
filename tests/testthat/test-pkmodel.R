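test_that("covariate model reproduces the typical individual parameters", {
  m <- ppk_model()
  p <- individual_params(m, 70, "NM")
  expect_equal(p$cl_f, 3.06)
  expect_equal(p$vd_f, 219.91)
  expect_equal(p$clm_fm, 8.86)
  expect_equal(p$vdm_fm, 423.78)
  expect_equal(p$ka, 1.06)

  p_im <- individual_params(m, 70, "IM")
  expect_equal(p_im$cl_f, 3.06 * exp(-0.23), tolerance = 1e-10)
  p_um <- individual_params(m, 70, "UM")
  expect_equal(p_um$cl_f, 3.06 * exp(0.21), tolerance = 1e-10)

  p36 <- individual_params(m, 36, "NM")
  expect_equal(p36$cl_f, 3.06 * (36 / 70)^0.64, tolerance = 1e-10)
  expect_equal(p36$vd_f, 219.91 * 36 / 70, tolerance = 1e-10)
  expect_equal(p36$clm_fm, 8.86 * (36 / 70)^0.75, tolerance = 1e-10)

  # random effects act multiplicatively on the log scale
  pe <- individual_params(m, 70, "NM", eta = c(cl = 0.5))
  expect_equal(pe$cl_f, 3.06 * exp(0.5), tolerance = 1e-10)
  expect_equal(pe$vd_f, 219.91)
})

test_that("phenotype handling rejects unknowns and unconfigured PMs", {
  m <- ppk_model()
  expect_error(individual_params(m, 70, "XX"), "phenotype")
  expect_error(individual_params(m, 70, "PM"), "poor metabolizers")
  expect_error(individual_params(m, -5, "NM"))
  # a PM coefficient can be configured explicitly
  m_pm <- ppk_model(terms = list(
    cov_power("vd", "WT", 1, fixed = TRUE, ref = 70),
    cov_power("cl", "WT", 0.64, fixed = FALSE, ref = 70),
    cov_cat("cl", "PHEN",
            coef = c(NM = 0, IM = -0.23, UM = 0.21, PM = -0.69)),
    cov_power("vdm", "WT", 1, fixed = TRUE, ref = 70),
    cov_power("clm", "WT", 0.75, fixed = TRUE, ref = 70)))
  expect_equal(individual_params(m_pm, 70, "PM")$cl_f, 3.06 * exp(-0.69),
               tolerance = 1e-10)
})

test_that("closed-form profile agrees with the numerical ODE oracle", {
  p <- typical_params()
  reg <- regimen(5, n_doses = 1)
  pr0 <- concentration_profile(p, reg, 0)
  expect_equal(pr0$ari, 0)
  expect_equal(pr0$dari, 0)

  tt <- c(1, 6, 24)
  pr <- concentration_profile(p, reg, tt)
  sol <- oracle_ode(p, 5, 24, 1, tt)
  expect_equal(pr$ari, 1000 * sol[, "parent"] / p$vd_f, tolerance = 1e-6)
  expect_equal(pr$dari, 1000 * sol[, "metab"] / p$vdm_fm, tolerance = 1e-6)

  # multi-dose
  regm <- regimen(5, n_doses = 12)
  tt2 <- c(2, 30, 100, 280)
  prm <- concentration_profile(p, regm, tt2)
  solm <- oracle_ode(p, 5, 24, 12, tt2)
  expect_equal(prm$ari, 1000 * solm[, "parent"] / p$vd_f, tolerance = 1e-6)
  expect_equal(prm$dari, 1000 * solm[, "metab"] / p$vdm_fm,
               tolerance = 1e-6)
})

test_that("closed form matches the ODE across random physiological draws", {
  set.seed(11)
  for (i in 1:100) {
    p <- structural_params(ka = runif(1, 0.5, 2), vd_f = runif(1, 50, 500),
                           cl_f = runif(1, 0.5, 8),
                           vdm_fm = runif(1, 50, 800),
                           clm_fm = runif(1, 1, 15))
    tt <- sort(runif(3, 0.5, 72))
    pr <- concentration_profile(p, regimen(7.5, n_doses = 3), tt)
    sol <- oracle_ode(p, 7.5, 24, 3, tt)
    expect_equal(pr$ari, 1000 * sol[, "parent"] / p$vd_f, tolerance = 1e-6)
    expect_equal(pr$dari, 1000 * sol[, "metab"] / p$vdm_fm,
                 tolerance = 1e-6)
  }
})

test_that("mass balance holds when conversion and mass ratios are unity", {
  p <- structural_params(ka = 1.06, vd_f = 219.91, cl_f = 3.06,
                         vdm_fm = 423.78, clm_fm = 8.86, kn = 1)
  sol <- oracle_ode(p, 10, 24, 2, c(5, 20, 48))
  total <- rowSums(sol[, c("depot", "parent", "metab", "elim")])
  doses_given <- ifelse(sol[, "time"] >= 24, 20, 10)
  expect_equal(unname(total), doses_given, tolerance = 1e-7)
})

test_that("dose linearity: concentrations and AUC scale, ratios do not", {
  p <- typical_params(36)
  tt <- c(2, 12, 24)
  c1 <- concentration_profile(p, regimen(5, n_doses = 5), tt)
  c3 <- concentration_profile(p, regimen(15, n_doses = 5), tt)
  expect_equal(3 * c1$ari, c3$ari, tolerance = 1e-12)
  expect_equal(3 * c1$dari, c3$dari, tolerance = 1e-12)
  m1 <- steady_state_metrics(p, regimen(5))
  m3 <- steady_state_metrics(p, regimen(15))
  expect_equal(3 * m1$auc24_ari, m3$auc24_ari, tolerance = 1e-10)
  expect_equal(m1$mr_auc, m3$mr_auc, tolerance = 1e-10)
  expect_equal(m1$mr_cmin, m3$mr_cmin, tolerance = 1e-8)
})

test_that("steady-state metrics satisfy the analytic AUC identities", {
  m <- ppk_model()
  p36 <- individual_params(m, 36, "NM")
  met <- steady_state_metrics(p36, regimen(5))
  expect_equal(met$auc24_ari, 1000 * 5 / p36$cl_f, tolerance = 1e-8)
  expect_equal(met$auc24_dari, 1000 * 0.995 * 5 / p36$clm_fm,
               tolerance = 1e-8)
  # 36 kg NM typical at 5 mg qd: AUC = dose / CL
  expect_equal(met$auc24_ari, 1000 * 5 / (3.06 * (36 / 70)^0.64),
               tolerance = 1e-8)
  expect_lt(met$cmin_ari, met$cmax_ari)
  expect_lt(met$cmin_dari, met$cmax_dari)

  # typical NM metabolic ratio, any weight and dose
  met70 <- steady_state_metrics(typical_params(), regimen(10))
  expect_equal(met70$mr_auc, 0.995 * 3.06 / 8.86, tolerance = 1e-8)
})

test_that("zero dose yields zero metrics with flagged undefined ratios", {
  met <- steady_state_metrics(typical_params(), regimen(0))
  expect_equal(met$auc24_ari, 0)
  expect_equal(met$cmax_dari, 0)
  expect_true(is.nan(met$mr_auc))
  expect_true(attr(met, "undefined_mr"))
})

test_that("steady-state trough ordering across phenotypes is IM > NM > UM", {
  m <- ppk_model()
  tr <- vapply(c("IM", "NM", "UM"), function(ph) {
    steady_state_metrics(individual_params(m, 36, ph),
                         regimen(5))$cmin_ari
  }, numeric(1))
  expect_gt(tr[["IM"]], tr[["NM"]])
  expect_gt(tr[["NM"]], tr[["UM"]])
})

test_that("near-coincident rate constants fall back to the ODE path", {
  # ka == ke triggers catastrophic cancellation in the closed form
  p <- structural_params(ka = 1.06, vd_f = 100, cl_f = 106,
                         vdm_fm = 400, clm_fm = 8)
  expect_true(aripopk:::rate_coincident(p))
  pr <- concentration_profile(p, regimen(5, n_doses = 2), c(1, 6, 30))
  sol <- oracle_ode(p, 5, 24, 2, c(1, 6, 30))
  expect_equal(pr$ari, 1000 * sol[, "parent"] / p$vd_f, tolerance = 1e-6)
  met <- steady_state_metrics(p, regimen(5))
  expect_equal(met$auc24_ari, 1000 * 5 / p$cl_f, tolerance = 1e-4)
})
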