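# Model qualification: goodness-of-fit residuals, visual predictive check,
# normalized prediction distribution errors.

# simulate one replicate of the design: same subjects, doses, times and
# covariates; fresh random effects and residual error
simulate_design_dv <- function(subjects, model) {
  lapply(subjects, function(s) {
    eta <- drop(sample_etas(model$omega2, 1))
    f <- subject_pred(s, model, eta)
    eps <- pmax(rnorm(length(f), 0, model$sigma[s$analyte]), -0.999)
    f * (1 + eps)
  })
}

#' Goodness-of-fit table
#'
#' Population predictions (eta = 0), individual predictions (at the
#' conditional mode) and FOCE conditional weighted residuals (the residual
#' vector decorrelated by the per-subject approximate covariance at the
#' conditional mode) for every observation.
#'
#' @param fit a `ppk_fit` (or a [ppk_model()]).
#' @param data the fitted `ppk_data`.
#' @return data.frame: `ID`, `time`, `tad` (time after dose), `analyte`,
#'   `dv`, `pred`, `ipred`, `cwres`.
#' @export
gof_residuals <- function(fit, data) {
  model <- if (inherits(fit, "ppk_fit")) fit$model else fit
  subjects <- as_subjects(data)
  out <- lapply(subjects, function(s) {
    zero <- setNames(numeric(length(model$omega2)), names(model$omega2))
    pred <- subject_pred(s, model, zero)
    parts <- subject_foce_parts(s, model)
    cwres <- if (is.null(parts$chol_V)) {
      (s$dv - parts$f) / parts$g
    } else {
      drop(backsolve(parts$chol_V, parts$r, transpose = TRUE))
    }
    data.frame(ID = s$id, time = s$times, tad = s$times %% s$tau,
               analyte = s$analyte, dv = s$dv, pred = pred,
               ipred = parts$f, cwres = cwres)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under its own design (same
#' doses, sampling times and covariates), and compares the observed 5th,
#' 50th and 95th concentration percentiles per time-after-dose bin and
#' analyte with the 90% prediction interval of the same percentiles across
#' replicates. Binning is equal-count on time after dose; the observed
#' percentiles do not depend on the seed.
#'
#' @param fit a `ppk_fit` or [ppk_model()].
#' @param data the `ppk_data` to check.
#' @param n_sim number of simulation replicates (1000 in the full
#'   analysis).
#' @param bins number of equal-count time-after-dose bins.
#' @param seed optional integer seed.
#' @return An object of class `vpc_result`: data.frame with `bin`,
#'   `tad_lo`, `tad_hi`, `analyte`, `pctile`, `observed`, `lo`, `hi`,
#'   `n_obs`; attribute `n_sim`. Bins holding fewer than 5 observations
#'   are flagged in column `sparse_bin`.
#' @export
vpc <- function(fit, data, n_sim = 1000, bins = 6, seed = NULL) {
  model <- if (inherits(fit, "ppk_fit")) fit$model else fit
  subjects <- as_subjects(data)
  tad <- unlist(lapply(subjects, function(s) s$times %% s$tau))
  analyte <- unlist(lapply(subjects, function(s) s$analyte))
  dv <- unlist(lapply(subjects, function(s) s$dv))
  brk <- unique(quantile(tad, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(tad, brk, include.lowest = TRUE, labels = FALSE)
  probs <- c(0.05, 0.5, 0.95)
  stat <- function(values) {
    out <- expand.grid(bin = sort(unique(bin)), analyte = c("ari", "dari"),
                       pctile = probs, stringsAsFactors = FALSE)
    out$value <- mapply(function(b, a, p) {
      v <- values[bin == b & analyte == a]
      if (length(v)) quantile(v, p, names = FALSE) else NA_real_
    }, out$bin, out$analyte, out$pctile)
    out
  }
  obs_stat <- stat(dv)
  if (!is.null(seed)) set.seed(seed)
  sim_stats <- replicate(n_sim, {
    stat(unlist(simulate_design_dv(subjects, model)))$value
  })
  res <- obs_stat
  names(res)[names(res) == "value"] <- "observed"
  res$lo <- apply(sim_stats, 1, quantile, 0.05, na.rm = TRUE)
  res$hi <- apply(sim_stats, 1, quantile, 0.95, na.rm = TRUE)
  counts <- table(bin, analyte)
  res$n_obs <- mapply(function(b, a) counts[as.character(b), a],
                      res$bin, res$analyte)
  res$sparse_bin <- res$n_obs < 5
  res$tad_lo <- brk[res$bin]
  res$tad_hi <- brk[res$bin + 1]
  class(res) <- c("vpc_result", "data.frame")
  attr(res, "n_sim") <- n_sim
  res
}

#' Normalized prediction distribution errors
#'
#' Per subject, `n_sim` replicates of the observation vector are simulated
#' under the model; observed and simulated vectors are decorrelated by the
#' Cholesky factor of the simulated covariance; each decorrelated
#' observation is converted to a prediction discrepancy by its rank among
#' the simulated values (uniform-jittered to break ties) and
#' inverse-normal transformed. Under a correct model the NPDE are standard
#' normal; the battery tests mean 0 (t-test), normality (Shapiro-Wilk),
#' variance 1 (Fisher chi-square variance test) and a Bonferroni global
#' combination of the three.
#'
#' @param fit a `ppk_fit` or [ppk_model()].
#' @param data the `ppk_data` to check.
#' @param n_sim simulation replicates (at least 100).
#' @param seed optional integer seed.
#' @return An object of class `npde_result`: list with `table` (per
#'   observation: ID, time, analyte, npde) and `tests` (named p-values:
#'   `mean`, `normality`, `variance`, `global`).
#' @export
npde <- function(fit, data, n_sim = 1000, seed = NULL) {
  if (n_sim < 100)
    stop("n_sim must be at least 100 for a stable simulated covariance")
  model <- if (inherits(fit, "ppk_fit")) fit$model else fit
  subjects <- as_subjects(data)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(subjects, function(s) {
    n <- length(s$dv)
    sims <- matrix(0, n_sim, n)
    for (k in seq_len(n_sim)) {
      eta <- drop(sample_etas(model$omega2, 1))
      f <- subject_pred(s, model, eta)
      eps <- pmax(rnorm(n, 0, model$sigma[s$analyte]), -0.999)
      sims[k, ] <- f * (1 + eps)
    }
    Ebar <- colMeans(sims)
    V <- stats::cov(sims)
    ch <- tryCatch(chol(V), error = function(e)
      chol(V + diag(1e-8 * mean(diag(V)), n)))
    dec_obs <- backsolve(ch, s$dv - Ebar, transpose = TRUE)
    dec_sim <- backsolve(ch, t(sims) - Ebar, transpose = TRUE)
    pde <- vapply(seq_len(n), function(j) {
      (sum(dec_sim[j, ] < dec_obs[j]) + runif(1)) / (n_sim + 1)
    }, numeric(1))
    data.frame(ID = s$id, time = s$times, analyte = s$analyte,
               npde = qnorm(pde))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  x <- tab$npde
  n <- length(x)
  if (n >= 3) {
    p_mean <- t.test(x)$p.value
    p_norm <- shapiro.test(if (n <= 5000) x else sample(x, 5000))$p.value
    v_stat <- (n - 1) * var(x)
    p_var <- 2 * min(pchisq(v_stat, n - 1), 1 - pchisq(v_stat, n - 1))
    p_global <- min(1, 3 * min(p_mean, p_norm, p_var))
  } else {
    p_mean <- p_norm <- p_var <- p_global <- NA_real_
  }
  structure(list(table = tab,
                 tests = c(mean = p_mean, normality = p_norm,
                           variance = p_var, global = p_global)),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat("NPDE over", nrow(x$table), "observations\n")
  cat(sprintf(
    "tests: mean p=%.3g, normality p=%.3g, variance p=%.3g, global p=%.3g\n",
    x$tests["mean"], x$tests["normality"], x$tests["variance"],
    x$tests["global"]))
  invisible(x)
}
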