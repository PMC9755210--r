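# FOCE-ELS estimation: first-order conditional estimation with interaction
# (residual variance evaluated at the individual prediction), extended
# least-squares objective.
#
# Per subject, the conditional mode eta-hat of the random effects is found
# by quasi-Newton search; the model is linearized around eta-hat and the
# subject's contribution to -2 log marginal likelihood accumulated from the
# resulting Gaussian approximation:
#   V = F Omega F' + diag(g^2),  r = y - f(eta-hat) + F eta-hat,
#   OFV_i = n log(2 pi) + log|V| + r' V^-1 r
# with F the Jacobian of the prediction in eta and g the residual SD at the
# individual prediction.

BIG_OFV <- 1e10

as_subjects <- function(data) {
  if (inherits(data, "ppk_data") || is.data.frame(data) ||
      (is.list(data) && !is.null(data$events))) parse_subjects(data)
  else data
}

fd_jacobian <- function(fn, x, f0 = NULL, h = 1e-4) {
  if (is.null(f0)) f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

# Core single-subject FOCE contribution. pred_fn(eta) returns predictions
# for the subject's observations; g_fn(f) their residual SDs. omega2 is the
# named vector of (free) eta variances.
foce_subject <- function(y, pred_fn, g_fn, omega2, eta_start = NULL) {
  n <- length(y)
  free <- omega2 > 0
  if (!any(free)) {
    f0 <- pred_fn(setNames(numeric(length(omega2)), names(omega2)))
    g <- g_fn(f0)
    if (any(!is.finite(f0)) || any(g <= 0)) return(list(ofv = BIG_OFV))
    return(list(ofv = n * log(2 * pi) + sum(log(g^2) + (y - f0)^2 / g^2),
                eta = setNames(numeric(length(omega2)), names(omega2)),
                f = f0, g = g, r = y - f0))
  }
  w_inv <- 1 / omega2[free]
  full_eta <- function(ef) {
    e <- setNames(numeric(length(omega2)), names(omega2))
    e[names(omega2)[free]] <- ef
    e
  }
  qfun <- function(ef) {
    f <- pred_fn(full_eta(ef))
    g <- g_fn(f)
    if (any(!is.finite(f)) || any(!is.finite(g)) || any(g <= 0))
      return(BIG_OFV * (1 + sum(ef^2)))
    sum(log(g^2) + (y - f)^2 / g^2) + sum(w_inv * ef^2)
  }
  start <- if (is.null(eta_start)) numeric(sum(free)) else
    eta_start[names(omega2)[free]]
  if (!all(is.finite(qfun(start)))) start <- start / 2
  opt <- tryCatch(
    suppressWarnings(nlminb(start, qfun,
                            control = list(iter.max = 100,
                                           rel.tol = 1e-10))),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) {
    # damped retry from the prior mode
    opt <- tryCatch(suppressWarnings(
      nlminb(numeric(sum(free)), qfun, control = list(iter.max = 100))),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective))
      return(list(ofv = Inf))
  }
  ef_hat <- opt$par
  eta_hat <- full_eta(ef_hat)
  f_hat <- pred_fn(eta_hat)
  g_hat <- g_fn(f_hat)
  Ff <- fd_jacobian(function(ef) pred_fn(full_eta(ef)), ef_hat, f_hat)
  V <- Ff %*% (omega2[free] * t(Ff)) + diag(g_hat^2, n)
  r <- y - f_hat + drop(Ff %*% ef_hat)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- V + diag(1e-8 * mean(diag(V)), n)
    ch <- chol(V)
  }
  z <- backsolve(ch, r, transpose = TRUE)
  list(ofv = n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2),
       eta = eta_hat, f = f_hat, g = g_hat, Ff = Ff, chol_V = ch, r = r)
}

# Build a fast per-subject prediction closure: covariate multipliers do not
# depend on eta, so they are applied once; the repeated-dose closed form is
# then evaluated inline for each eta proposal. Regular once-daily regimens
# use the O(1) geometric-accumulation path.
make_subject_pred <- function(subj, model) {
  base <- individual_params(model, subj$covs)
  if (!subj$regular)
    return(function(eta) subject_pred(subj, model, eta))
  ka <- base$ka; kn <- base$kn
  D <- subj$dose; tau <- subj$tau
  m <- pmin(subj$n_doses, floor(subj$times / tau) + 1)
  s <- subj$times - (m - 1) * tau
  is_ari <- subj$analyte == "ari"
  i_vd <- match("vd", names(model$omega2))
  i_cl <- match("cl", names(model$omega2))
  i_clm <- match("clm", names(model$omega2))
  function(eta) {
    vd <- base$vd_f * if (is.na(i_vd)) 1 else exp(eta[i_vd])
    cl <- base$cl_f * if (is.na(i_cl)) 1 else exp(eta[i_cl])
    clm <- base$clm_fm * if (is.na(i_clm)) 1 else exp(eta[i_clm])
    vdm <- base$vdm_fm
    ke <- cl / vd; kem <- clm / vdm
    A <- ka / (ka - ke)
    e_ka <- exp(-ka * s) * (1 - exp(-ka * m * tau)) / (1 - exp(-ka * tau))
    e_ke <- exp(-ke * s) * (1 - exp(-ke * m * tau)) / (1 - exp(-ke * tau))
    e_km <- exp(-kem * s) * (1 - exp(-kem * m * tau)) /
      (1 - exp(-kem * tau))
    parent <- D * A * (e_ke - e_ka)
    K <- kn * ke * A * D
    metab <- K * ((e_ke - e_km) / (kem - ke) - (e_ka - e_km) / (kem - ka))
    ifelse(is_ari, MG_TO_NGML * parent / vd, MG_TO_NGML * metab / vdm)
  }
}

subject_foce_parts <- function(subj, model, eta_start = NULL) {
  sig <- unname(model$sigma[subj$analyte])
  foce_subject(
    y = subj$dv,
    pred_fn = make_subject_pred(subj, model),
    g_fn = function(f) sig * pmax(f, 1e-10),
    omega2 = model$omega2,
    eta_start = eta_start)
}

#' FOCE-ELS objective function value
#'
#' Minus twice the approximate log marginal likelihood of the dataset under
#' the model, by first-order conditional estimation with interaction. The
#' value is additive over subjects and invariant to subject ordering.
#'
#' @param data a `ppk_data` object (or events data.frame).
#' @param model a [ppk_model()].
#' @param eta_env optional environment for warm-starting the per-subject
#'   conditional modes between calls (used internally during fitting).
#' @return The OFV (numeric scalar) with attribute `etas`, the matrix of
#'   per-subject conditional modes.
#' @export
foce_objective <- function(data, model, eta_env = NULL) {
  subjects <- as_subjects(data)
  if (!length(subjects)) stop("no subjects with observations")
  st <- build_foce_stack(subjects)
  if (!is.null(st)) {
    E0 <- if (!is.null(eta_env) && !is.null(eta_env$.E) &&
              nrow(eta_env$.E) == st$n_subj) eta_env$.E else NULL
    res <- stack_foce_ofv(st, model, E0, subjects)
    if (!is.null(eta_env)) eta_env$.E <- res$etas
    etas <- res$etas
    dimnames(etas) <- list(names(subjects), c("vd", "cl", "clm"))
    return(structure(res$ofv,
                     etas = etas[, names(model$omega2), drop = FALSE]))
  }
  total <- 0
  etas <- matrix(0, length(subjects), length(model$omega2),
                 dimnames = list(names(subjects), names(model$omega2)))
  for (k in seq_along(subjects)) {
    s <- subjects[[k]]
    key <- as.character(s$id)
    start <- if (!is.null(eta_env) && !is.null(eta_env[[key]]))
      eta_env[[key]] else NULL
    parts <- subject_foce_parts(s, model, start)
    if (!is.finite(parts$ofv)) return(structure(BIG_OFV, etas = etas))
    total <- total + parts$ofv
    etas[k, ] <- parts$eta
    if (!is.null(eta_env)) eta_env[[key]] <- parts$eta
  }
  structure(total, etas = etas)
}

# --- model parameter packing for optimization ----------------------------

pack_model <- function(model) {
  par <- c()
  add <- function(par, v, nm) {
    if (!length(v)) return(par)
    names(v) <- nm[seq_along(v)]
    c(par, v)
  }
  est_t <- names(model$theta)[!model$fixed_theta[names(model$theta)]]
  par <- add(par, log(model$theta[est_t]), paste0("theta.", est_t))
  for (i in seq_along(model$terms)) {
    tm <- model$terms[[i]]
    if (tm$form == "cat") {
      free <- names(tm$beta)[!tm$fixed]
      if (length(free))
        par <- add(par, unlist(tm$beta[free]),
                   paste0("term", i, ".", free))
    } else if (!tm$fixed) {
      v <- if (tm$form == "hill") log(tm$beta) else tm$beta
      par <- add(par, v, paste0("term", i, ".beta"))
    }
  }
  est_o <- names(model$omega2)[!model$fixed_omega[names(model$omega2)] &
                                 model$omega2 > 0]
  par <- add(par, log(model$omega2[est_o]), paste0("omega2.", est_o))
  est_s <- names(model$sigma)[!model$fixed_sigma[names(model$sigma)]]
  par <- add(par, log(model$sigma[est_s]), paste0("sigma.", est_s))
  par
}

unpack_model <- function(model, par) {
  nm <- names(par)
  for (j in seq_along(par)) {
    parts <- strsplit(nm[j], ".", fixed = TRUE)[[1]]
    what <- parts[1]
    if (what == "theta") {
      model$theta[parts[2]] <- exp(par[j])
    } else if (grepl("^term", what)) {
      i <- as.integer(sub("term", "", what))
      tm <- model$terms[[i]]
      if (tm$form == "cat") model$terms[[i]]$beta[parts[2]] <-
          unname(par[j])
      else model$terms[[i]]$beta <-
          if (tm$form == "hill") exp(unname(par[j])) else unname(par[j])
    } else if (what == "omega2") {
      model$omega2[parts[2]] <- exp(par[j])
    } else if (what == "sigma") {
      model$sigma[parts[2]] <- exp(par[j])
    }
  }
  model
}

n_estimated <- function(model) length(pack_model(model))

#' Fit the population model by FOCE-ELS
#'
#' Minimizes [foce_objective()] over the estimated fixed effects, covariate
#' coefficients, inter-individual variances and residual SDs. Positive
#' parameters are optimized on the log scale; fixed parameters (per the
#' model's fixed flags) never move. Relative standard errors come from the
#' finite-difference observed information of the objective.
#'
#' @param data a `ppk_data` object.
#' @param model_init starting [ppk_model()].
#' @param compute_rse compute the observed-information RSEs (adds a Hessian
#'   evaluation; switch off inside resampling loops).
#' @param control list: `iter.max`, `eval.max`, `rel.tol` passed to the
#'   outer quasi-Newton optimizer.
#' @return An object of class `ppk_fit`: list with `model` (estimates),
#'   `ofv`, `aic`, `bic`, `rse` (%), `se`, `ebes`, `convergence`,
#'   `n_obs`, `n_subjects`.
#' @export
fit_ppk <- function(data, model_init = ppk_model(), compute_rse = TRUE,
                    control = list()) {
  ctrl <- list(iter.max = 200, rel.tol = 1e-8, fd_step = 1e-4,
               restarts = 4)
  ctrl[names(control)] <- control
  if (!is.null(control$maxit)) ctrl$iter.max <- control$maxit
  subjects <- as_subjects(data)
  n_obs <- sum(vapply(subjects, function(s) length(s$dv), integer(1)))
  par0 <- pack_model(model_init)
  if (!length(par0)) stop("no parameters are estimated")
  # Outer optimization is a BFGS with an explicit forward-difference
  # gradient (step fd_step on the log/packed scale): the inner
  # iteration's discrete stopping makes the objective piecewise-smooth at
  # a much finer scale, which corrupts machine-epsilon differences. The
  # conditional-mode store is held fixed while probing around an iterate
  # (keeping the objective a pure function there) and re-primed at every
  # accepted step, so probe evaluations stay warm.
  objE <- function(p, E) {
    env <- new.env(parent = emptyenv())
    if (!is.null(E)) env$.E <- E
    v <- foce_objective(subjects, unpack_model(model_init, p), env)
    list(f = as.numeric(v), E = env$.E)
  }
  gradE <- function(p, E, f0) {
    vapply(seq_along(p), function(j) {
      pp <- p
      pp[j] <- pp[j] + ctrl$fd_step
      (objE(pp, E)$f - f0) / ctrl$fd_step
    }, numeric(1))
  }
  np <- length(par0)
  x <- par0
  cur <- objE(x, NULL)
  if (!is.finite(cur$f) || cur$f >= BIG_OFV)
    stop("objective not finite at the initial estimates")
  fx <- cur$f
  Ek <- cur$E
  g <- gradE(x, Ek, fx)
  H <- diag(np) / max(1, sqrt(sum(g^2)))
  converged <- FALSE
  n_small <- 0
  for (it in seq_len(ctrl$iter.max)) {
    d <- -drop(H %*% g)
    if (sum(d * g) >= 0) {   # reset on a non-descent proposal
      H <- diag(np) / max(1, sqrt(sum(g^2)))
      d <- -drop(H %*% g)
    }
    line_search <- function(d) {
      alpha <- 1
      slope <- sum(d * g)
      for (half in 1:25) {
        ev <- objE(x + alpha * d, Ek)
        if (is.finite(ev$f) && ev$f <= fx + 1e-4 * alpha * slope)
          return(list(ev = ev, alpha = alpha, d = d))
        alpha <- alpha / 2
      }
      NULL
    }
    ls <- line_search(d)
    if (is.null(ls)) {
      # rescue along steepest descent with a reset Hessian
      H <- diag(np) / max(1, sqrt(sum(g^2)))
      ls <- line_search(-drop(H %*% g))
      if (is.null(ls)) {
        converged <- TRUE   # no descent direction improves: at a minimum
        break
      }
    }
    cand <- ls$ev
    alpha <- ls$alpha
    d <- ls$d
    x_new <- x + alpha * d
    g_new <- gradE(x_new, cand$E, cand$f)
    s <- alpha * d
    yv <- g_new - g
    sy <- sum(s * yv)
    if (it == 1 && sy > 0) H <- diag(np) * sy / sum(yv * yv)
    if (sy > 1e-10) {
      rho <- 1 / sy
      Vm <- diag(np) - rho * outer(s, yv)
      H <- Vm %*% H %*% t(Vm) + rho * outer(s, s)
    }
    n_small <- if (fx - cand$f < ctrl$rel.tol * (abs(cand$f) + 1))
      n_small + 1 else 0
    x <- x_new
    fx <- cand$f
    g <- g_new
    Ek <- cand$E
    if (n_small >= 3) {
      converged <- TRUE
      break
    }
  }
  par <- setNames(x, names(par0))
  opt <- list(par = x, objective = fx,
              convergence = if (converged) 0L else 1L,
              message = if (converged) "relative convergence"
                        else "iteration limit reached")
  obj <- function(p) objE(p, Ek)$f   # for the observed-information Hessian
  model <- unpack_model(model_init, par)
  final_env <- new.env(parent = emptyenv())
  final_env$.E <- Ek
  final <- foce_objective(subjects, model, final_env)
  ofv <- as.numeric(final)
  p <- length(par0)
  se <- rse <- setNames(rep(NA_real_, p), names(par0))
  if (compute_rse) {
    H <- tryCatch(optimHess(par, obj, control = list(
      ndeps = rep(1e-3, length(par)))), error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cv) && all(diag(cv) > 0)) {
        se_packed <- sqrt(diag(cv))
        # log-scale parameters: SE on the log scale ~ relative SE
        is_log <- grepl("^(theta|omega2|sigma)\\.", names(par0)) |
          vapply(seq_along(par0), function(j) {
            grepl("^term", names(par0)[j]) && {
              i <- as.integer(sub("term([0-9]+)\\..*", "\\1", names(par0)[j]))
              model$terms[[i]]$form == "hill"
            }
          }, logical(1))
        rse <- ifelse(is_log, 100 * se_packed,
                      100 * se_packed / abs(opt$par))
        se <- ifelse(is_log, se_packed * exp(opt$par), se_packed)
        names(se) <- names(rse) <- names(par0)
      }
    }
  }
  structure(list(model = model, ofv = ofv, aic = ofv + 2 * p,
                 bic = ofv + p * log(n_obs), rse = rse, se = se,
                 ebes = attr(final, "etas"),
                 convergence = opt$convergence == 0,
                 message = opt$message, n_obs = n_obs,
                 n_subjects = length(subjects), n_par = p),
            class = "ppk_fit")
}

#' @export
print.ppk_fit <- function(x, ...) {
  cat(sprintf("FOCE-ELS fit: %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("OFV %.2f  AIC %.2f  BIC %.2f  (%d estimated parameters)%s\n",
              x$ofv, x$aic, x$bic, x$n_par,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  print(parameter_table(x))
  invisible(x)
}

#' Flat parameter table of a fit
#'
#' One row per model parameter (fixed and estimated) with estimate, fixed
#' flag and RSE%, mirroring the conventional population-PK reporting
#' layout. Bootstrap columns can be merged in by [bootstrap_ppk()].
#'
#' @param fit a `ppk_fit`.
#' @return data.frame with `parameter`, `estimate`, `fixed`, `rse_pct`.
#' @export
parameter_table <- function(fit) {
  m <- fit$model
  packed <- pack_model(m)
  rows <- list()
  for (tn in names(m$theta))
    rows[[paste0("theta.", tn)]] <-
      c(m$theta[[tn]], m$fixed_theta[[tn]])
  for (i in seq_along(m$terms)) {
    tm <- m$terms[[i]]
    if (tm$form == "cat") {
      for (lv in names(tm$beta))
        rows[[paste0("term", i, ".", lv)]] <- c(tm$beta[[lv]], tm$fixed[[lv]])
    } else rows[[paste0("term", i, ".beta")]] <- c(tm$beta, tm$fixed)
  }
  for (on in names(m$omega2))
    rows[[paste0("omega2.", on)]] <-
      c(m$omega2[[on]], isTRUE(m$fixed_omega[[on]]) || m$omega2[[on]] == 0)
  for (sn in names(m$sigma))
    rows[[paste0("sigma.", sn)]] <- c(m$sigma[[sn]], m$fixed_sigma[[sn]])
  df <- data.frame(parameter = names(rows),
                   estimate = vapply(rows, `[`, numeric(1), 1),
                   fixed = as.logical(vapply(rows, `[`, numeric(1), 2)))
  df$rse_pct <- fit$rse[df$parameter]
  rownames(df) <- NULL
  df
}

#' Write a fit report
#'
#' Serializes a fit as structured JSON (fit statistics plus the flat
#' parameter table with estimates, fixed flags and RSEs) next to which
#' bootstrap columns can be reported.
#'
#' @param fit a `ppk_fit`.
#' @param path output JSON path.
#' @param bootstrap optional result of [bootstrap_ppk()] whose summary
#'   columns (median, CI bounds) are merged into the parameter table.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, bootstrap = NULL) {
  tab <- parameter_table(fit)
  if (!is.null(bootstrap)) {
    bs <- bootstrap$summary[, c("parameter", "median", "lo", "hi")]
    names(bs) <- c("parameter", "boot_median", "boot_lo", "boot_hi")
    tab <- merge(tab, bs, by = "parameter", all.x = TRUE, sort = FALSE)
  }
  report <- list(
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    n_parameters = fit$n_par, ofv = fit$ofv, aic = fit$aic,
    bic = fit$bic, converged = fit$convergence, parameters = tab)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Empirical-Bayes individual estimates and trough correction
#'
#' Maximizes each subject's joint posterior (likelihood times eta prior) to
#' obtain MAP random effects, individual predictions, and the
#' model-corrected steady-state metrics (the "Bayesian corrected" trough:
#' concentrations sampled away from the pre-dose time are mapped to the
#' subject's predicted interval-end trough at steady state). Subjects
#' without observations get eta = 0 and a `population_prediction` flag.
#'
#' @param data a `ppk_data` object.
#' @param model a fitted or assumed [ppk_model()].
#' @return data.frame, one row per subject: `id`, `eta_*`, `cmin_ari`,
#'   `cmin_dari`, `cmax_ari`, `cmax_dari`, `auc24_ari`, `auc24_dari`,
#'   `mr_auc`, `mr_cmin`, `mr_cmax`, `population_prediction`. The
#'   per-observation individual predictions are in attribute `ipred`.
#' @export
map_etas <- function(data, model) {
  ev <- as_events(data)
  subjects <- parse_subjects(data)
  ids <- unique(ev$ID)
  rows <- vector("list", length(ids))
  ipred_list <- list()
  for (k in seq_along(ids)) {
    id <- as.character(ids[k])
    s <- subjects[[id]]
    if (is.null(s)) {
      sub <- ev[ev$ID == ids[k], ]
      covs <- as.list(sub[1, setdiff(names(sub), EVENT_COLS), drop = FALSE])
      eta <- setNames(numeric(length(model$omega2)), names(model$omega2))
      dose <- sub$AMT[sub$EVID == 1][1]
      pop_flag <- TRUE
    } else {
      parts <- subject_foce_parts(s, model)
      eta <- parts$eta
      covs <- s$covs
      dose <- s$dose
      pop_flag <- FALSE
      ipred_list[[id]] <- data.frame(ID = s$id, TIME = s$times,
                                     analyte = s$analyte, dv = s$dv,
                                     ipred = parts$f)
    }
    pars <- individual_params(model, covs, eta = eta)
    met <- steady_state_metrics(pars, regimen(dose))
    rows[[k]] <- data.frame(id = ids[k], t(eta),
                            cmin_ari = met$cmin_ari, cmin_dari = met$cmin_dari,
                            cmax_ari = met$cmax_ari, cmax_dari = met$cmax_dari,
                            auc24_ari = met$auc24_ari,
                            auc24_dari = met$auc24_dari,
                            mr_auc = met$mr_auc, mr_cmin = met$mr_cmin,
                            mr_cmax = met$mr_cmax,
                            population_prediction = pop_flag)
  }
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(model$omega2))] <-
    paste0("eta_", names(model$omega2))
  attr(out, "ipred") <- do.call(rbind, ipred_list)
  out
}
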