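test_that("CYP2D6 diplotypes classify by allele function counts", {
  expect_equal(classify_cyp2d6("*1/*2"), "UM")
  expect_equal(classify_cyp2d6("*1/*1"), "UM")
  expect_equal(classify_cyp2d6("*39/*39"), "UM")
  expect_equal(classify_cyp2d6("*1/*10"), "NM")
  expect_equal(classify_cyp2d6("*1/*33"), "NM")
  expect_equal(classify_cyp2d6("*10/*34"), "NM")
  expect_equal(classify_cyp2d6("*10/*10"), "IM")
  expect_equal(classify_cyp2d6("*3/*10"), "IM")
  expect_equal(classify_cyp2d6("*10/*14"), "IM")
  expect_equal(classify_cyp2d6("*3/*3"), "PM")
  # symmetric in allele order
  expect_equal(classify_cyp2d6(c("*10", "*1")),
               classify_cyp2d6(c("*1", "*10")))
  expect_error(classify_cyp2d6("*1/*999"), "\\*999")
})

test_that("allele table overrides are validated and applied", {
  tab <- cyp2d6_allele_table(c("*14" = "decreased"))
  expect_equal(classify_cyp2d6("*10/*14", tab), "IM")  # unchanged class
  expect_error(cyp2d6_allele_table(c("*14" = "super")), "invalid")
})

test_that("phenotype census reproduces the cohort distribution exactly", {
  cs <- phenotype_census(td_genotype_counts())
  expect_equal(cs$n[cs$phenotype == "UM"], 15L)
  expect_equal(cs$n[cs$phenotype == "NM"], 34L)
  expect_equal(cs$n[cs$phenotype == "IM"], 35L)
  expect_equal(cs$n[cs$phenotype == "PM"], 0L)
  expect_equal(cs$pct[cs$phenotype == "IM"], 41.7)

  empty <- phenotype_census(c("*1/*1" = 0))
  expect_true(all(empty$n == 0))
  one <- phenotype_census(c("*1/*1" = 1))
  expect_equal(one$pct[one$phenotype == "UM"], 100)
})

test_that("YGTSS reduction uses the strict >50% responder rule", {
  r <- ygtss_reduction(40, 10)
  expect_equal(r$reduction_rate, 75)
  expect_true(r$responder)
  expect_false(ygtss_reduction(40, 40)$responder)
  expect_equal(ygtss_reduction(40, 40)$reduction_rate, 0)
  # exactly 50% is a non-responder
  half <- ygtss_reduction(40, 20)
  expect_equal(half$reduction_rate, 50)
  expect_false(half$responder)
  expect_error(ygtss_reduction(0, 0), "positive")
})

test_that("trapezoid AUC equals the all-pairs concordance oracle", {
  pairs_auc <- function(x, lab) {
    pos <- x[lab]; neg <- x[!lab]
    grid <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(grid)
  }
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(40), 1)  # rounding forces ties
    lab <- rbinom(40, 1, 0.4) == 1
    if (!any(lab) || all(lab)) next
    r <- roc_analysis(x, lab)
    expect_equal(r$auc, pairs_auc(x, lab), tolerance = 1e-12)
  }
})

test_that("ROC handles separation, monotone transforms and direction", {
  x <- c(1, 2, 3, 10, 11, 12)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(x, lab)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$cutoff > 3 && r$cutoff <= 10)

  # AUC invariant under strictly monotone transform
  set.seed(8)
  v <- rexp(30); lb <- rbinom(30, 1, 0.5) == 1
  expect_equal(roc_analysis(v, lb)$auc, roc_analysis(log(v), lb)$auc,
               tolerance = 1e-12)

  expect_error(roc_analysis(v, rep(TRUE, 30)), "both")

  # cross-check against an independent ROC implementation
  pr <- pROC::roc(lb, v, direction = "<", quiet = TRUE)
  expect_equal(roc_analysis(v, lb)$auc, as.numeric(pROC::auc(pr)),
               tolerance = 1e-12)
})

test_that("MR discrimination reports UM as >= and IM as <= cutoffs", {
  # hand-built toy: IMs low, NMs middle, UMs high
  mr <- c(0.20, 0.25, 0.33, 0.36, 0.50, 0.55)
  ph <- c("IM", "IM", "NM", "NM", "UM", "UM")
  um <- mr_phenotype_discrimination(mr, ph, "UM")
  expect_equal(um$direction, ">=")
  expect_equal(um$auc, 1)
  expect_true(um$cutoff > 0.36 && um$cutoff <= 0.50)
  im <- mr_phenotype_discrimination(mr, ph, "IM")
  expect_equal(im$direction, "<=")
  expect_equal(im$auc, 1)
  expect_true(im$cutoff >= 0.25 && im$cutoff < 0.33)
  expect_error(mr_phenotype_discrimination(mr, ph, "PM"))

  # shuffled labels carry no signal
  set.seed(30)
  mr2 <- runif(300, 0.2, 0.6)
  ph2 <- sample(c("IM", "NM", "UM"), 300, replace = TRUE)
  expect_equal(mr_phenotype_discrimination(mr2, ph2, "UM")$auc, 0.5,
               tolerance = 0.1)
})

test_that("exposure-response cutoff recovers the generating optimum", {
  # Under a logistic response in log trough, Youden's J is maximized where
  # the responder probability equals the responder prevalence, i.e. at
  # midpoint * exp(logit(prevalence)/slope) -- the midpoint itself exactly
  # when classes are balanced.
  set.seed(17)
  reps <- replicate(9, {
    d <- generate_synthetic_study(cohort_spec(n_subjects = 200),
                                  seed = sample.int(1e6, 1))
    eff <- d$efficacy
    resp <- ygtss_reduction(eff$ygtss_baseline, eff$ygtss_week12)$responder
    oracle <- 101.6 * exp(qlogis(mean(resp)) / 2.5)
    c(cut = roc_analysis(eff$trough_true, resp)$cutoff, oracle = oracle)
  })
  expect_equal(median(reps["cut", ]), median(reps["oracle", ]),
               tolerance = 15 / 101.6)
})

test_that("pediatric covariate formulas match hand arithmetic", {
  expect_equal(bsa_mosteller(142, 36), sqrt(142 * 36 / 3600),
               tolerance = 1e-12)
  expect_equal(round(bsa_mosteller(142, 36), 3), 1.192)
  expect_equal(egfr_schwartz(142, 42.05), 0.413 * 142 / (42.05 / 88.4),
               tolerance = 1e-12)
  expect_equal(egfr_schwartz(142, 42.05 / 88.4, "mg/dL"),
               egfr_schwartz(142, 42.05))
  expect_error(bsa_mosteller(0, 36), "positive")
  expect_error(egfr_schwartz(142, 0), "positive")
})
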