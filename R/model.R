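#' Individual structural pharmacokinetic parameters
#'
#' Container for the per-individual apparent constants of the oral
#' depot -> parent (ARI) -> metabolite (DARI) one-compartment chain.
#' All parameters are bioavailability-scaled ("apparent"): the oral
#' bioavailability F and the parent-to-metabolite conversion fraction Fm are
#' fixed at 1 by convention and absorbed into the volumes and clearances.
#'
#' @param ka first-order absorption rate constant (1/h).
#' @param vd_f apparent parent volume of distribution Vd/F (L).
#' @param cl_f apparent parent clearance CL/F (L/h).
#' @param vdm_fm apparent metabolite volume Vdm/Fm (L).
#' @param clm_fm apparent metabolite clearance CLm/Fm (L/h).
#' @param kn DARI/ARI molecular-mass ratio (dimensionless, default 0.995).
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(ka = 1.06, vd_f, cl_f, vdm_fm, clm_fm,
                              kn = 0.995) {
  x <- list(ka = ka, vd_f = vd_f, cl_f = cl_f, vdm_fm = vdm_fm,
            clm_fm = clm_fm, kn = kn, f = 1, fm = 1)
  vals <- unlist(x[c("ka", "vd_f", "cl_f", "vdm_fm", "clm_fm", "kn")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all structural parameters must be finite and strictly positive")
  class(x) <- "structural_params"
  x
}

#' Oral dosing regimen
#'
#' @param dose amount per administration (mg).
#' @param tau dosing interval (h), default 24 (once daily).
#' @param n_doses number of doses; `Inf` denotes steady state.
#' @param start_time time of the first dose (h).
#' @return An object of class `regimen`.
#' @export
regimen <- function(dose, tau = 24, n_doses = Inf, start_time = 0) {
  stopifnot(dose >= 0, tau > 0, n_doses >= 1, start_time >= 0)
  structure(list(dose = dose, tau = tau, n_doses = n_doses,
                 start_time = start_time), class = "regimen")
}

cov_power <- function(param, cov, beta, fixed = FALSE, ref) {
  list(param = param, cov = cov, form = "power", beta = beta,
       fixed = fixed, ref = ref)
}

cov_linear <- function(param, cov, beta, fixed = FALSE, ref) {
  list(param = param, cov = cov, form = "linear", beta = beta,
       fixed = fixed, ref = ref)
}

cov_cat <- function(param, cov, coef, fixed = NULL) {
  if (is.null(fixed)) {
    fixed <- rep(FALSE, length(coef))
    names(fixed) <- names(coef)
    fixed[1] <- TRUE  # reference level
  }
  list(param = param, cov = cov, form = "cat", beta = coef, fixed = fixed)
}

# Sigmoid maturation term on a covariate (usually age): multiplier
# cov^gamma / (beta^gamma + cov^gamma) with half-maturation point beta
# estimated on the log scale and the Hill exponent gamma fixed.
cov_hill <- function(param, cov, beta, gamma = 3, fixed = FALSE) {
  list(param = param, cov = cov, form = "hill", beta = beta, gamma = gamma,
       fixed = fixed)
}

#' Population pharmacokinetic model
#'
#' Holds typical values, covariate effects, inter-individual variability
#' (diagonal log-normal Omega) and proportional residual error for the
#' combined ARI/DARI model. The default arguments are the final published
#' estimates for the pediatric tic-disorder population: typical values at
#' 70 kg with an estimated weight exponent 0.64 on CL/F, fixed exponents
#' 1.0/1.0/0.75 on the volumes and metabolite clearance, and additive
#' log-scale CYP2D6 phenotype effects on CL/F (NM reference 0, IM -0.23,
#' UM 0.21).
#'
#' Inter-individual variances are on the log scale: `omega2` of 0.1207 on
#' CL/F corresponds to roughly 35% CV. Residual error is proportional per
#' analyte (`sigma` as SD fractions).
#'
#' @param theta named typical values: `ka` (1/h), `vd` (L), `cl` (L/h),
#'   `vdm` (L), `clm` (L/h), referenced to `ref_weight`.
#' @param fixed_theta logical, which entries of `theta` stay fixed when
#'   fitting (`ka` fixed by default).
#' @param terms list of covariate terms; use the default for the final model.
#' @param omega2 named log-scale variances for `vd`, `cl`, `clm`
#'   (no random effect on `vdm`).
#' @param fixed_omega,fixed_sigma logical vectors marking fixed variance
#'   components.
#' @param sigma proportional residual SD per analyte (`ari`, `dari`).
#' @param kn DARI/ARI molecular-mass ratio.
#' @param ref_weight reference body weight (kg) of the typical values.
#' @return An object of class `ppk_model`.
#' @export
ppk_model <- function(theta = c(ka = 1.06, vd = 219.91, cl = 3.06,
                                vdm = 423.78, clm = 8.86),
                      fixed_theta = c(ka = TRUE, vd = FALSE, cl = FALSE,
                                      vdm = FALSE, clm = FALSE),
                      terms = list(
                        cov_power("vd",  "WT", 1.00, fixed = TRUE,  ref = 70),
                        cov_power("cl",  "WT", 0.64, fixed = FALSE, ref = 70),
                        cov_cat("cl", "PHEN",
                                coef  = c(NM = 0, IM = -0.23, UM = 0.21),
                                fixed = c(NM = TRUE, IM = FALSE, UM = FALSE)),
                        cov_power("vdm", "WT", 1.00, fixed = TRUE,  ref = 70),
                        cov_power("clm", "WT", 0.75, fixed = TRUE,  ref = 70)),
                      omega2 = c(vd = 0.7999, cl = 0.1207, clm = 0.1531),
                      fixed_omega = c(vd = FALSE, cl = FALSE, clm = FALSE),
                      sigma = c(ari = 0.3545, dari = 0.3537),
                      fixed_sigma = c(ari = FALSE, dari = FALSE),
                      kn = 0.995, ref_weight = 70) {
  stopifnot(all(c("ka", "vd", "cl", "vdm", "clm") %in% names(theta)),
            all(theta > 0), all(omega2 >= 0), all(sigma > 0), all(sigma < 1),
            ref_weight > 0)
  m <- list(theta = theta, fixed_theta = fixed_theta, terms = terms,
            omega2 = omega2, fixed_omega = fixed_omega,
            sigma = sigma, fixed_sigma = fixed_sigma,
            kn = kn, ref_weight = ref_weight)
  class(m) <- "ppk_model"
  m
}

#' @export
print.ppk_model <- function(x, ...) {
  cat("Combined ARI/DARI population PK model\n")
  cat("Typical values (at", x$ref_weight, "kg):\n")
  print(round(x$theta, 4))
  if (length(x$terms)) {
    cat("Covariate terms:\n")
    for (tm in x$terms) {
      b <- paste(signif(tm$beta, 4), collapse = "/")
      cat(sprintf("  %s on %s: %s (%s)\n", tm$cov, tm$param, tm$form, b))
    }
  }
  cat("omega^2:", paste(names(x$omega2), round(x$omega2, 4),
                        sep = "=", collapse = " "), "\n")
  cat("sigma (prop.):", paste(names(x$sigma), round(x$sigma, 4),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

term_multiplier <- function(tm, covs) {
  v <- covs[[tm$cov]]
  if (is.null(v) || (length(v) == 1 && is.na(v)))
    stop("covariate '", tm$cov, "' required by the model is missing")
  switch(tm$form,
    power  = (v / tm$ref)^tm$beta,
    linear = pmax(1 + tm$beta * (v - tm$ref) / tm$ref, 1e-6),
    cat    = {
      if (!v %in% names(tm$beta))
        stop("no coefficient configured for ", tm$cov, " level '", v, "'")
      exp(tm$beta[[v]])
    },
    hill   = v^tm$gamma / (tm$beta^tm$gamma + v^tm$gamma),
    stop("unknown covariate form: ", tm$form))
}

#' Individual parameters from covariates and random effects
#'
#' Applies the covariate model and log-normal random effects to the typical
#' values: for example CL/F_i = theta_cl * (WT/70)^0.64 *
#' exp(theta_phenotype) * exp(eta_cl).
#'
#' @param model a [ppk_model()].
#' @param weight body weight (kg), or a list/one-row data.frame of covariates
#'   including `WT` (and any other covariates the model's terms require).
#' @param phenotype CYP2D6 phenotype, one of "UM", "NM", "IM" (or "PM" when a
#'   PM coefficient has been configured).
#' @param eta named log-scale random effects (`vd`, `cl`, `clm`); default 0.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(model, weight, phenotype = "NM",
                              eta = c(vd = 0, cl = 0, clm = 0)) {
  if (is.list(weight)) covs <- weight
  else covs <- list(WT = weight, PHEN = phenotype)
  if (is.null(covs$PHEN)) covs$PHEN <- phenotype
  stopifnot(covs$WT > 0)
  ph <- as.character(covs$PHEN)
  if (!ph %in% c("UM", "NM", "IM", "PM"))
    stop("unknown CYP2D6 phenotype: ", ph)
  has_phen_term <- any(vapply(model$terms, function(tm)
    tm$cov == "PHEN", logical(1)))
  if (ph == "PM" && has_phen_term) {
    cfg <- lapply(model$terms, function(tm)
      if (tm$cov == "PHEN") names(tm$beta) else NULL)
    if (!"PM" %in% unlist(cfg))
      stop("no PM coefficient configured: the reference population ",
           "contained no poor metabolizers")
  }
  e <- c(vd = 0, cl = 0, clm = 0)
  if (length(eta)) e[names(eta)] <- eta
  p <- model$theta[c("vd", "cl", "vdm", "clm")]
  for (tm in model$terms)
    p[tm$param] <- p[tm$param] * term_multiplier(tm, covs)
  structural_params(ka = model$theta[["ka"]],
                    vd_f = p[["vd"]] * exp(e[["vd"]]),
                    cl_f = p[["cl"]] * exp(e[["cl"]]),
                    vdm_fm = p[["vdm"]],
                    clm_fm = p[["clm"]] * exp(e[["clm"]]),
                    kn = model$kn)
}
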