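test_that("residuals vanish on noise-free data and standardize otherwise", {
  spec <- rich_spec(8)
  spec$lloq <- c(ari = 0, dari = 0)
  d0 <- generate_synthetic_study(spec, quiet_model(), efficacy_link = NULL,
                                 seed = 9)
  # replace observations by the exact model predictions (zero noise)
  pre <- gof_residuals(quiet_model(), d0)
  d0$events$DV[d0$events$EVID == 0] <- pre$pred
  g0 <- gof_residuals(quiet_model(), d0)
  expect_equal(g0$cwres, rep(0, nrow(g0)), tolerance = 1e-3)
  expect_equal(g0$pred, g0$ipred, tolerance = 1e-8)
  expect_equal(g0$pred, g0$dv, tolerance = 1e-3)

  # correct model: CWRES approximately standardized
  m <- ppk_model()
  spec2 <- cohort_spec(n_subjects = 60, samples_per_subject = 4:5,
                       sample_probs = c(0.5, 0.5))
  d <- generate_synthetic_study(spec2, m, efficacy_link = NULL, seed = 10)
  g <- gof_residuals(m, d)
  expect_gte(nrow(g), 500)
  expect_lt(abs(mean(g$cwres)), 0.1)
  expect_gt(var(g$cwres), 0.8)
  expect_lt(var(g$cwres), 1.2)
})

test_that("single-observation CWRES matches the scalar formula", {
  m <- ppk_model()
  ev <- rbind(
    data.frame(ID = 1L, TIME = (0:19) * 24, EVID = 1L, AMT = 5,
               DV = NA_real_, DVID = NA_integer_),
    data.frame(ID = 1L, TIME = 350, EVID = 0L, AMT = NA_real_,
               DV = 150, DVID = 1L))
  ev$WT <- 36; ev$PHEN <- "NM"
  g <- gof_residuals(m, list(events = ev))
  # oracle: conditional mode by direct 2-D optimization (clm carries no
  # information for a parent-only observation), then the scalar
  # linearized covariance
  qf2 <- function(ee) {
    pars <- individual_params(m, 36, "NM", c(vd = ee[1], cl = ee[2]))
    f <- concentration_profile(pars, regimen(5, n_doses = 20), 350)$ari
    g2 <- (m$sigma[["ari"]] * f)^2
    (150 - f)^2 / g2 + log(g2) +
      ee[1]^2 / m$omega2[["vd"]] + ee[2]^2 / m$omega2[["cl"]]
  }
  opt <- optim(c(0, 0), qf2, method = "BFGS")
  eta_hat <- c(vd = opt$par[1], cl = opt$par[2], clm = 0)
  f_hat <- {
    pars <- individual_params(m, 36, "NM", eta_hat)
    concentration_profile(pars, regimen(5, n_doses = 20), 350)$ari
  }
  h <- 1e-4
  Fv <- vapply(c("vd", "cl", "clm"), function(p) {
    ep <- eta_hat; ep[p] <- ep[p] + h
    em <- eta_hat; em[p] <- em[p] - h
    fp <- concentration_profile(individual_params(m, 36, "NM", ep),
                                regimen(5, n_doses = 20), 350)$ari
    fm <- concentration_profile(individual_params(m, 36, "NM", em),
                                regimen(5, n_doses = 20), 350)$ari
    (fp - fm) / (2 * h)
  }, numeric(1))
  V <- sum(Fv^2 * m$omega2[c("vd", "cl", "clm")]) +
    (m$sigma[["ari"]] * f_hat)^2
  r <- 150 - f_hat + sum(Fv * eta_hat)
  expect_equal(g$cwres, r / sqrt(V), tolerance = 1e-3)
})

test_that("VPC bands behave: collapse without variability, cover with it", {
  spec <- rich_spec(10)
  spec$lloq <- c(ari = 0, dari = 0)
  d0 <- generate_synthetic_study(spec, quiet_model(), efficacy_link = NULL,
                                 seed = 21)
  v0 <- vpc(quiet_model(), d0, n_sim = 50, bins = 3, seed = 1)
  expect_true(all(abs(v0$hi - v0$lo) / pmax(v0$observed, 1) < 1e-3))

  m <- ppk_model()
  d <- generate_synthetic_study(cohort_spec(n_subjects = 40,
                                            samples_per_subject = 3:4,
                                            sample_probs = c(.5, .5)),
                                m, efficacy_link = NULL, seed = 22)
  v1 <- vpc(m, d, n_sim = 200, bins = 4, seed = 5)
  inside <- with(v1, observed >= lo & observed <= hi)
  expect_gte(mean(inside), 0.8)
  # observed percentiles are seed-independent
  v2 <- vpc(m, d, n_sim = 50, bins = 4, seed = 99)
  expect_identical(v1$observed, v2$observed)
})

test_that("npde reduces to the marginal rank transform for one observation", {
  m <- ppk_model()
  ev <- rbind(
    data.frame(ID = 1L, TIME = (0:19) * 24, EVID = 1L, AMT = 5,
               DV = NA_real_, DVID = NA_integer_),
    data.frame(ID = 1L, TIME = 350, EVID = 0L, AMT = NA_real_,
               DV = 150, DVID = 1L))
  ev$WT <- 36; ev$PHEN <- "NM"
  set.seed(33)
  res <- npde(m, list(events = ev), n_sim = 4000)
  # oracle: fraction of simulated concentrations below the observation
  set.seed(33)
  sims <- replicate(4000, {
    eta <- drop(sample_etas(m$omega2, 1))
    pars <- individual_params(m, 36, "NM", eta)
    f <- concentration_profile(pars, regimen(5, n_doses = 20), 350)$ari
    f * (1 + rnorm(1, 0, m$sigma[["ari"]]))
  })
  expect_equal(res$table$npde, qnorm(mean(sims < 150)), tolerance = 0.05)
})

test_that("npde battery is well calibrated and detects misspecification", {
  m <- ppk_model()
  spec <- cohort_spec(n_subjects = 25, samples_per_subject = 2:3,
                      sample_probs = c(.5, .5))
  # under the correct model the global test should rarely reject
  set.seed(55)
  p_null <- replicate(8, {
    d <- generate_synthetic_study(spec, m, efficacy_link = NULL,
                                  seed = sample.int(1e6, 1))
    npde(m, d, n_sim = 200)$tests[["global"]]
  })
  expect_lte(sum(p_null < 0.05), 3)
  # halved clearance at evaluation time must be flagged; power comes from
  # the parent observations (steady-state metabolite formation is nearly
  # clearance-invariant), so use the full-size study design
  m_bad <- ppk_model(theta = c(ka = 1.06, vd = 219.91, cl = 3.06 / 2,
                               vdm = 423.78, clm = 8.86))
  set.seed(56)
  p_bad <- replicate(3, {
    d <- generate_synthetic_study(cohort_spec(), m, efficacy_link = NULL,
                                  seed = sample.int(1e6, 1))
    npde(m_bad, d, n_sim = 200)$tests[["global"]]
  })
  expect_true(all(p_bad < 0.05))
})

test_that("npde errors on too few replicates", {
  d <- generate_synthetic_study(cohort_spec(n_subjects = 4), seed = 2)
  expect_error(npde(ppk_model(), d, n_sim = 50), "at least 100")
})
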