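# Stepwise covariate model building: greedy forward inclusion on the
# chi-square 5% criterion (dOFV > 3.84, df = 1), backward deletion on the
# 1% criterion (removal must raise OFV by at least 6.64 to keep the
# covariate).

#' Build a default covariate candidate registry
#'
#' Candidate covariate-parameter pairs screened by [stepwise_search()].
#' Body weight enters as one developmental candidate — allometric scaling
#' of clearances and volumes as a unit (fixed exponents 1.0 on the
#' volumes and 0.75 on metabolite clearance, estimated exponent on
#' parent clearance) — because a weight term on clearance alone
#' misstates the weight dependence of trough concentrations when the
#' volumes scale too. Other continuous covariates enter as a power of
#' covariate/median on the screened parameter; categorical covariates as
#' exp(coefficient) per non-reference level.
#'
#' @param data a `ppk_data` object (used for medians and level sets).
#' @param params structural parameters screened for the per-parameter
#'   candidates (default CL/F and Vd/F).
#' @param continuous,categorical covariate column names; defaults cover
#'   the columns present in the dataset among WT/AGE (continuous) and
#'   PHEN/SEX (categorical).
#' @return list of candidate descriptors for [stepwise_search()].
#' @export
covariate_candidates <- function(data, params = c("cl", "vd"),
                                 continuous = NULL, categorical = NULL) {
  ev <- as_events(data)
  first <- ev[!duplicated(ev$ID), ]
  if (is.null(continuous))
    continuous <- intersect(c("WT", "AGE"), names(ev))
  if (is.null(categorical))
    categorical <- intersect(c("PHEN", "SEX"), names(ev))
  out <- list()
  if ("WT" %in% continuous) {
    out[["WT_developmental"]] <- list(
      cov = "WT",
      terms = list(
        cov_power("vd", "WT", 1.00, fixed = TRUE, ref = 70),
        cov_power("cl", "WT", 0.75, fixed = FALSE, ref = 70),
        cov_power("vdm", "WT", 1.00, fixed = TRUE, ref = 70),
        cov_power("clm", "WT", 0.75, fixed = TRUE, ref = 70)))
    continuous <- setdiff(continuous, "WT")
  }
  for (p in params) {
    for (cv in continuous) {
      out[[paste(cv, p, sep = "_on_")]] <- list(
        param = p, cov = cv, form = "power",
        ref = median(first[[cv]], na.rm = TRUE))
    }
    for (cv in categorical) {
      lv <- as.character(sort(unique(first[[cv]])))
      ref <- names(which.max(table(first[[cv]])))
      lv <- c(ref, setdiff(lv, ref))
      if (length(lv) < 2) next
      out[[paste(cv, p, sep = "_on_")]] <- list(
        param = p, cov = cv, form = "cat", levels = lv)
    }
  }
  out
}

candidate_terms <- function(cand) {
  if (!is.null(cand$terms)) return(cand$terms)
  list(candidate_term(cand))
}

candidate_term <- function(cand) {
  if (cand$form == "cat") {
    coef <- setNames(rep(0, length(cand$levels)), cand$levels)
    fixed <- setNames(c(TRUE, rep(FALSE, length(cand$levels) - 1)),
                      cand$levels)
    cov_cat(cand$param, cand$cov, coef, fixed)
  } else if (cand$form == "power") {
    cov_power(cand$param, cand$cov, 0, fixed = FALSE, ref = cand$ref)
  } else if (cand$form == "linear") {
    cov_linear(cand$param, cand$cov, 0, fixed = FALSE, ref = cand$ref)
  } else if (cand$form == "hill") {
    cov_hill(cand$param, cand$cov, cand$ref, gamma = cand$gamma %||% 3)
  } else stop("unknown candidate form")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

add_candidate <- function(model, cand) {
  model$terms <- c(model$terms, candidate_terms(cand))
  model
}

#' Forward-backward stepwise covariate search
#'
#' Greedy forward selection: at each round, every not-yet-included
#' candidate is added to the current model and refitted; the candidate with
#' the largest OFV drop is included if the drop exceeds `forward_cut`
#' (ties broken by fewer added parameters, then input order). Backward
#' deletion then removes, one at a time, any included covariate whose
#' removal raises the OFV by less than `backward_cut`.
#'
#' @param data a `ppk_data` object.
#' @param base_model covariate-free starting [ppk_model()].
#' @param candidates registry from [covariate_candidates()].
#' @param forward_cut OFV drop required for inclusion (3.84 = chi-square
#'   5%, df 1).
#' @param backward_cut OFV rise required for retention (6.64 = chi-square
#'   1%, df 1).
#' @param control optimizer control passed to [fit_ppk()].
#' @return list with `model` (final fitted model), `fit` (final `ppk_fit`),
#'   `retained` (names of retained candidates) and `log` (one row per
#'   tested step: phase, candidate, delta OFV, action).
#' @export
stepwise_search <- function(data, base_model, candidates,
                            forward_cut = 3.84, backward_cut = 6.64,
                            control = list(iter.max = 80)) {
  subjects <- as_subjects(data)
  log_rows <- list()
  push_log <- function(phase, cand, dofv, action)
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      phase = phase, candidate = cand, delta_ofv = dofv, action = action)
  safe_fit <- function(model) {
    tryCatch(fit_ppk(subjects, model, compute_rse = FALSE,
                     control = control),
             error = function(e) NULL)
  }
  current_fit <- safe_fit(base_model)
  if (is.null(current_fit)) stop("base model failed to fit")
  current <- current_fit$model
  included <- character(0)
  pool <- names(candidates)

  repeat {  # forward
    best <- NULL
    for (nm in setdiff(pool, included)) {
      f <- safe_fit(add_candidate(current, candidates[[nm]]))
      if (is.null(f) || !is.finite(f$ofv)) {
        push_log("forward", nm, NA_real_, "fit_failed")
        next
      }
      dofv <- current_fit$ofv - f$ofv
      push_log("forward", nm, dofv, "tested")
      npar <- f$n_par
      if (dofv > forward_cut &&
          (is.null(best) || dofv > best$dofv + 1e-9 ||
             (abs(dofv - best$dofv) <= 1e-9 && npar < best$npar)))
        best <- list(nm = nm, fit = f, dofv = dofv, npar = npar)
    }
    if (is.null(best)) break
    push_log("forward", best$nm, best$dofv, "included")
    included <- c(included, best$nm)
    current_fit <- best$fit
    current <- current_fit$model
  }

  repeat {  # backward
    worst <- NULL
    for (nm in included) {
      reduced <- current
      pairs <- vapply(candidate_terms(candidates[[nm]]), function(tm)
        paste(tm$param, tm$cov), character(1))
      reduced$terms <- current$terms[
        !vapply(current$terms, function(tm)
          paste(tm$param, tm$cov) %in% pairs, logical(1))]
      f <- safe_fit(reduced)
      if (is.null(f)) next
      rise <- f$ofv - current_fit$ofv
      push_log("backward", nm, rise, "tested")
      if (rise < backward_cut && (is.null(worst) || rise < worst$rise))
        worst <- list(nm = nm, fit = f, rise = rise)
    }
    if (is.null(worst)) break
    push_log("backward", worst$nm, worst$rise, "removed")
    included <- setdiff(included, worst$nm)
    current_fit <- worst$fit
    current <- current_fit$model
  }

  list(model = current, fit = current_fit, retained = included,
       log = do.call(rbind, log_rows))
}

#' Candidate developmental models for the weight effect on clearance
#'
#' The screened structural alternatives for how physiological development
#' scales CL/F: fixed-exponent allometry (0.75 on clearances, 1.0 on
#' volumes), an estimated-exponent power of weight (the form retained in
#' the final model), a linear weight effect, a power of age, and allometric
#' weight combined with a sigmoid age-maturation term.
#'
#' @param wt_median,age_median covariate medians used as references.
#' @return Named list; each element is a list of covariate terms that can
#'   replace the CL/F weight term of a [ppk_model()].
#' @export
developmental_models <- function(wt_median = 36, age_median = 9.17) {
  list(
    allometric_fixed = list(
      cov_power("cl", "WT", 0.75, fixed = TRUE, ref = 70)),
    power_estimated = list(
      cov_power("cl", "WT", 0.75, fixed = FALSE, ref = 70)),
    linear_weight = list(
      cov_linear("cl", "WT", 0.01, fixed = FALSE, ref = wt_median)),
    age_power = list(
      cov_power("cl", "AGE", 0.5, fixed = FALSE, ref = age_median)),
    weight_maturation = list(
      cov_power("cl", "WT", 0.75, fixed = TRUE, ref = 70),
      cov_hill("cl", "AGE", age_median, gamma = 3, fixed = FALSE)))
}
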