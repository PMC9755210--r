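#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement (same size as the original dataset),
#' refits each resample by FOCE-ELS starting from the original estimates,
#' and summarizes each estimated parameter by its bootstrap median and
#' 2.5/97.5 percentiles. Parameters whose bootstrap median deviates more
#' than 10% from the original estimate are flagged (the conventional
#' stability criterion). Resamples whose fit fails or does not converge are
#' excluded and counted.
#'
#' @param data a `ppk_data` object.
#' @param model fitted [ppk_model()] (starting values and layout).
#' @param n_resamples number of bootstrap resamples (1000 in the full
#'   analysis; smaller values keep simulation studies cheap).
#' @param seed optional integer seed.
#' @param control optimizer control for the resample fits.
#' @return list with `summary` (data.frame: parameter, original, median,
#'   lo, hi, deviation_pct, flagged), `n_failed`, `failure_rate`,
#'   `estimates` (matrix of per-resample estimates).
#' @export
bootstrap_ppk <- function(data, model, n_resamples = 1000, seed = NULL,
                          control = list(iter.max = 60)) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- as_subjects(data)
  n <- length(subjects)
  par_names <- names(pack_model(model))
  first_fit <- fit_ppk(subjects, model, compute_rse = FALSE,
                       control = control)
  start_model <- first_fit$model
  # the reference estimates replay exactly the run a resample performs
  # (same starting values, same subject relabeling), so the identity
  # resample reproduces them bit for bit
  ident <- subjects
  for (k in seq_along(ident)) ident[[k]]$id <- k
  names(ident) <- seq_along(ident)
  orig_fit <- fit_ppk(ident, start_model, compute_rse = FALSE,
                      control = control)
  orig <- pack_to_natural(pack_model(orig_fit$model), orig_fit$model)
  est <- matrix(NA_real_, n_resamples, length(par_names),
                dimnames = list(NULL, par_names))
  n_failed <- 0
  for (b in seq_len(n_resamples)) {
    pick <- if (n_resamples == 1) seq_len(n) else
      sample(seq_len(n), n, replace = TRUE)
    res <- subjects[pick]
    for (k in seq_along(res)) res[[k]]$id <- k
    names(res) <- seq_along(res)
    f <- tryCatch(fit_ppk(res, start_model, compute_rse = FALSE,
                          control = control),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$ofv)) {
      n_failed <- n_failed + 1
      next
    }
    est[b, ] <- pack_to_natural(pack_model(f$model), f$model)
  }
  ok <- stats::complete.cases(est)
  med <- apply(est[ok, , drop = FALSE], 2, median)
  lo <- apply(est[ok, , drop = FALSE], 2, quantile, 0.025)
  hi <- apply(est[ok, , drop = FALSE], 2, quantile, 0.975)
  dev <- 100 * (med - orig) / ifelse(orig == 0, 1, abs(orig))
  summ <- data.frame(parameter = par_names, original = orig, median = med,
                     lo = lo, hi = hi, deviation_pct = dev,
                     flagged = abs(dev) > 10)
  rownames(summ) <- NULL
  list(summary = summ, n_failed = n_failed,
       failure_rate = n_failed / n_resamples, estimates = est,
       original_fit = orig_fit)
}

# packed (transformed) parameters back to the natural scale
pack_to_natural <- function(par, model) {
  out <- par
  for (j in seq_along(par)) {
    nm <- names(par)[j]
    if (grepl("^(theta|omega2|sigma)\\.", nm)) out[j] <- exp(par[j])
    else if (grepl("^term", nm)) {
      i <- as.integer(sub("term([0-9]+)\\..*", "\\1", nm))
      if (model$terms[[i]]$form == "hill") out[j] <- exp(par[j])
    }
  }
  out
}
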