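# Stochastic layer: inter-individual variability, residual error, virtual
# cohorts and the synthetic sparse-sampling study generator.

#' Draw inter-individual random effects
#'
#' Independent normal log-scale random effects eta per parameter,
#' mean 0 and variance omega^2 (diagonal Omega: the model reports no
#' covariances).
#'
#' @param omega2 named vector of log-scale variances (e.g. `vd`, `cl`, `clm`).
#' @param n number of subjects.
#' @param seed optional integer seed for reproducibility.
#' @return An `n` x `length(omega2)` matrix of eta values.
#' @export
sample_etas <- function(omega2, n, seed = NULL) {
  stopifnot(n >= 1)
  if (any(omega2 < 0)) stop("omega^2 variances must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  m <- vapply(omega2, function(v) rnorm(n, 0, sqrt(v)), numeric(n))
  if (n == 1) m <- matrix(m, 1, dimnames = list(NULL, names(omega2)))
  m
}

#' Apply proportional residual error
#'
#' Observed = predicted * (1 + eps), eps ~ N(0, cv^2), truncated below at
#' `floor_eps` so observed concentrations stay positive. At the fitted
#' residual magnitudes (~35% CV) the truncation probability is negligible;
#' the number of truncated draws is returned as an attribute.
#'
#' @param conc predicted concentrations (ng/ml), non-negative.
#' @param sigma a named vector of proportional SDs per analyte
#'   (`ari`, `dari`), or a single number.
#' @param analyte "ari" or "dari" (ignored when `sigma` is scalar).
#' @param seed optional integer seed.
#' @param floor_eps lower truncation bound for eps (default -0.999).
#' @return Perturbed concentrations, same length as `conc`.
#' @export
apply_residual_error <- function(conc, sigma, analyte = "ari", seed = NULL,
                                 floor_eps = -0.999) {
  stopifnot(all(conc >= 0))
  cv <- if (length(sigma) > 1) sigma[[analyte]] else sigma
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(length(conc), 0, cv)
  n_trunc <- sum(eps < floor_eps)
  eps <- pmax(eps, floor_eps)
  structure(conc * (1 + eps), n_truncated = n_trunc)
}

#' Cohort design specification
#'
#' Describes the virtual population: a truncated log-normal body-weight
#' distribution, CYP2D6 phenotype probabilities, a per-weight once-daily
#' dose policy and the sparse sampling policy. Defaults emulate the
#' pediatric tic-disorder cohort: 84 subjects, weights with median 36 kg
#' truncated to 17.90-100.00 kg, phenotype mix UM/NM/IM = 15/34/35 out of
#' 84 (no PM), doses on the 2.5-20 mg grid, 1-5 samples per subject drawn
#' at least 14 days after the start of dosing.
#'
#' @param n_subjects number of subjects.
#' @param wt_median,wt_sdlog median (kg) and log-scale SD of body weight.
#' @param wt_range truncation bounds (kg).
#' @param phenotype_probs named probabilities for UM/NM/IM (and optionally
#'   PM); must sum to 1.
#' @param dose_per_kg target mg/kg/day, rounded to `dose_grid`.
#' @param dose_grid allowed once-daily doses (mg).
#' @param samples_per_subject integer support of the per-subject sample
#'   count (probabilities `sample_probs`).
#' @param sample_probs probabilities matching `samples_per_subject`; the
#'   default gives a mean close to the observed 143/84 samples per subject.
#' @param day_range sampling-day window after the first dose (days).
#' @param lloq lower limits of quantification (ng/ml) per analyte; values
#'   below are dropped from generated datasets.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 84,
                        wt_median = 36, wt_sdlog = 0.4,
                        wt_range = c(17.90, 100.00),
                        phenotype_probs = c(UM = 15, NM = 34, IM = 35) / 84,
                        dose_per_kg = 0.15,
                        dose_grid = seq(2.5, 20, by = 2.5),
                        samples_per_subject = 1:5,
                        sample_probs = c(0.55, 0.25, 0.12, 0.05, 0.03),
                        day_range = c(14, 30),
                        lloq = c(ari = 10, dari = 15)) {
  stopifnot(n_subjects >= 1, wt_range[1] > 0, wt_range[2] >= wt_range[1],
            abs(sum(phenotype_probs) - 1) < 1e-8,
            length(sample_probs) == length(samples_per_subject),
            day_range[1] >= 14)
  if (!length(phenotype_probs) || all(phenotype_probs == 0))
    stop("phenotype support is empty")
  structure(list(n_subjects = n_subjects, wt_median = wt_median,
                 wt_sdlog = wt_sdlog, wt_range = wt_range,
                 phenotype_probs = phenotype_probs,
                 dose_per_kg = dose_per_kg, dose_grid = dose_grid,
                 samples_per_subject = samples_per_subject,
                 sample_probs = sample_probs / sum(sample_probs),
                 day_range = day_range, lloq = lloq),
            class = "cohort_spec")
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  p_lo <- plnorm_safe(lower, meanlog, sdlog)
  p_hi <- plnorm_safe(upper, meanlog, sdlog)
  u <- runif(n, p_lo, p_hi)
  exp(meanlog + sdlog * qnorm(u))
}

plnorm_safe <- function(q, meanlog, sdlog) {
  if (sdlog == 0) return(as.numeric(q >= exp(meanlog)))
  pnorm((log(q) - meanlog) / sdlog)
}

policy_dose <- function(spec, wt) {
  g <- spec$dose_grid
  target <- spec$dose_per_kg * wt
  vapply(target, function(d) g[which.min(abs(g - d))], numeric(1))
}

#' Generate a virtual cohort
#'
#' Draws body weights (truncated log-normal), CYP2D6 phenotypes
#' (multinomial) and random effects for `spec$n_subjects` virtual subjects.
#'
#' @param spec a [cohort_spec()].
#' @param model a [ppk_model()] supplying `omega2` for the eta draws.
#' @param seed optional integer seed.
#' @return A data.frame with columns `id`, `WT`, `PHEN`, `dose` and one
#'   `eta_*` column per random effect.
#' @export
generate_virtual_cohort <- function(spec, model = ppk_model(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  if (spec$wt_sdlog == 0 || spec$wt_range[1] == spec$wt_range[2]) {
    wt <- rep(min(max(spec$wt_median, spec$wt_range[1]), spec$wt_range[2]), n)
  } else {
    wt <- rlnorm_trunc(n, log(spec$wt_median), spec$wt_sdlog,
                       spec$wt_range[1], spec$wt_range[2])
  }
  ph <- sample(names(spec$phenotype_probs), n, replace = TRUE,
               prob = spec$phenotype_probs)
  etas <- sample_etas(model$omega2, n)
  colnames(etas) <- paste0("eta_", colnames(etas))
  data.frame(id = seq_len(n), WT = wt, PHEN = ph,
             dose = policy_dose(spec, wt), etas)
}

# Table-2-style diplotype frequencies conditional on phenotype, used to
# attach a plausible CYP2D6 diplotype label to each simulated subject
diplotype_pool <- function() {
  list(
    UM = c("*1/*1" = 1, "*1/*2" = 6, "*39/*39" = 8),
    NM = c("*1/*10" = 27, "*1/*41" = 3, "*1/*14" = 1, "*10/*34" = 1,
           "*10/*35" = 1, "*1/*33" = 1),
    IM = c("*10/*10" = 30, "*10/*14" = 3, "*10/*41" = 2))
}

#' Generate a synthetic sparse-sampling study
#'
#' Builds a complete synthetic dataset in the study's design: once-daily
#' dosing for at least 14 days, 1-5 sparse dual-analyte samples per subject
#' at random within-interval offsets, concentrations from the structural
#' model with inter-individual and proportional residual error, and an
#' optional efficacy record in which the responder status (>50% YGTSS
#' reduction at week 12) is generated from a logistic link on each
#' subject's true steady-state ARI trough.
#'
#' Observations below the assay quantification limits are dropped; the
#' count is recorded in attribute `n_lloq_dropped`.
#'
#' @param spec a [cohort_spec()].
#' @param model the generating ("true") [ppk_model()].
#' @param efficacy_link `c(midpoint, slope)`: responder probability
#'   `plogis(slope * (log(trough) - log(midpoint)))`; the default crosses
#'   0.5 at a trough of 101.6 ng/ml. `NULL` omits efficacy records.
#' @param seed optional integer seed.
#' @return An object of class `ppk_data`: list with `events` (NONMEM-style
#'   data.frame), `efficacy` (per-subject YGTSS records or NULL) and
#'   `subjects` (the generating cohort, including true etas).
#' @export
generate_synthetic_study <- function(spec = cohort_spec(),
                                     model = ppk_model(),
                                     efficacy_link = c(midpoint = 101.6,
                                                       slope = 2.5),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_virtual_cohort(spec, model)
  n <- nrow(cohort)
  eta_cols <- grep("^eta_", names(cohort), value = TRUE)
  # treatment long enough that every sample falls after >= day_range[1]
  # full days of dosing
  n_days <- sample(seq(spec$day_range[1] + 1, spec$day_range[2]), n,
                   replace = TRUE)
  sp <- spec$samples_per_subject
  n_samp <- sp[sample.int(length(sp), n, replace = TRUE,
                          prob = spec$sample_probs)]
  age <- pmin(pmax(9.62 * (cohort$WT / 40.25)^0.8 *
                     exp(rnorm(n, 0, 0.12)), 4.83), 17.33)
  sex <- sample(c(1, 0), n, replace = TRUE, prob = c(64, 20) / 84)
  pool <- diplotype_pool()
  diplo <- vapply(cohort$PHEN, function(ph) {
    p <- pool[[ph]]
    sample(names(p), 1, prob = p)
  }, character(1))

  ev_list <- vector("list", n)
  troughs <- numeric(n)
  n_dropped <- 0
  for (i in seq_len(n)) {
    eta <- unlist(cohort[i, eta_cols])
    names(eta) <- sub("^eta_", "", eta_cols)
    pars <- individual_params(model, cohort$WT[i], cohort$PHEN[i], eta)
    reg <- regimen(cohort$dose[i], tau = 24, n_doses = n_days[i])
    # sampling times: a random dosing interval once >= 14 full days of
    # dosing are complete, uniform offset within the interval
    days_ok <- seq(spec$day_range[1] + 1, n_days[i])
    day <- days_ok[sample.int(length(days_ok), n_samp[i], replace = TRUE)]
    t_obs <- sort((day - 1) * 24 + runif(n_samp[i], 0, 24))
    pred <- concentration_profile(pars, reg, t_obs)
    dv_ari <- apply_residual_error(pred$ari, model$sigma, "ari")
    dv_dari <- apply_residual_error(pred$dari, model$sigma, "dari")
    dose_rows <- data.frame(
      ID = cohort$id[i], TIME = (seq_len(n_days[i]) - 1) * 24, EVID = 1L,
      AMT = cohort$dose[i], DV = NA_real_, DVID = NA_integer_)
    obs <- data.frame(
      ID = cohort$id[i], TIME = rep(t_obs, 2), EVID = 0L, AMT = NA_real_,
      DV = c(dv_ari, dv_dari), DVID = rep(c(1L, 2L), each = n_samp[i]))
    keep <- ifelse(obs$DVID == 1, obs$DV >= spec$lloq[["ari"]],
                   obs$DV >= spec$lloq[["dari"]])
    n_dropped <- n_dropped + sum(!keep)
    rows <- rbind(dose_rows, obs[keep, ])
    rows <- rows[order(rows$TIME, rows$EVID, rows$DVID), ]
    rows$WT <- cohort$WT[i]; rows$AGE <- age[i]; rows$SEX <- sex[i]
    rows$PHEN <- cohort$PHEN[i]; rows$DIPLO <- diplo[i]
    ev_list[[i]] <- rows
    troughs[i] <- steady_state_metrics(pars, regimen(cohort$dose[i]))$cmin_ari
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL

  efficacy <- NULL
  if (!is.null(efficacy_link)) {
    p_resp <- plogis(efficacy_link[["slope"]] *
                       (log(troughs) - log(efficacy_link[["midpoint"]])))
    resp <- rbinom(n, 1, p_resp) == 1
    baseline <- round(runif(n, 25, 48))
    red <- ifelse(resp, runif(n, 0.55, 0.90), runif(n, 0.05, 0.45))
    week12 <- round(baseline * (1 - red))
    # rounding must not flip responder status across the 50% boundary
    week12 <- ifelse(resp & week12 >= baseline / 2,
                     pmax(floor(baseline / 2) - 1, 0), week12)
    week12 <- ifelse(!resp & week12 < baseline / 2,
                     ceiling(baseline / 2), week12)
    efficacy <- data.frame(ID = cohort$id, ygtss_baseline = baseline,
                           ygtss_week12 = week12, trough_true = troughs)
  }
  structure(list(events = events, efficacy = efficacy, subjects = cohort),
            class = "ppk_data", n_lloq_dropped = n_dropped)
}

#' @export
print.ppk_data <- function(x, ...) {
  nobs <- sum(x$events$EVID == 0)
  cat(sprintf("ppk_data: %d subjects, %d observations (%d dose records)\n",
              length(unique(x$events$ID)), nobs, sum(x$events$EVID == 1)))
  invisible(x)
}
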