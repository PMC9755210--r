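# Forward population simulation: concentration-band profiles, steady-state
# exposure distributions and metabolic ratios, probability of target
# attainment (PTA), and dose-regimen optimization over the weight x
# CYP2D6-phenotype grid.

#' Simulated concentration bands during repeated dosing
#'
#' Simulates `n_sim` virtual subjects of a given weight and phenotype
#' (inter-individual variability only: the bands describe true individual
#' concentrations, not assay-noisy observations) and summarizes ARI and
#' DARI profiles as the median and 10th-90th percentile band.
#'
#' @param model a [ppk_model()].
#' @param weight body weight (kg); @param phenotype CYP2D6 phenotype.
#' @param dose once-daily dose (mg); @param days treatment days.
#' @param n_sim number of virtual subjects.
#' @param seed optional integer seed.
#' @param dt output grid resolution (h).
#' @return data.frame: `time`, `analyte`, `p10`, `median`, `p90`.
#' @export
simulate_profiles <- function(model, weight, phenotype, dose, days = 30,
                              n_sim = 1000, seed = NULL, dt = 2) {
  stopifnot(days >= 1)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, days * 24, by = dt)
  reg <- regimen(dose, tau = 24, n_doses = days)
  etas <- sample_etas(model$omega2, n_sim)
  ari <- matrix(0, n_sim, length(times))
  dari <- matrix(0, n_sim, length(times))
  for (i in seq_len(n_sim)) {
    pars <- individual_params(model, weight, phenotype, etas[i, ])
    pr <- concentration_profile(pars, reg, times)
    ari[i, ] <- pr$ari
    dari[i, ] <- pr$dari
  }
  band <- function(m, analyte) data.frame(
    time = times, analyte = analyte,
    p10 = apply(m, 2, quantile, 0.10),
    median = apply(m, 2, quantile, 0.50),
    p90 = apply(m, 2, quantile, 0.90))
  rbind(band(ari, "ari"), band(dari, "dari"))
}

#' Per-subject steady-state metrics for a virtual cohort
#'
#' Evaluates [steady_state_metrics()] at every subject's individual
#' parameters and dose.
#'
#' @param model a [ppk_model()].
#' @param cohort data.frame from [generate_virtual_cohort()] (columns `WT`,
#'   `PHEN`, `dose`, `eta_*`).
#' @param dose optional single dose (mg) overriding the cohort's `dose`
#'   column.
#' @return The cohort data.frame with the nine steady-state metric columns
#'   appended.
#' @export
population_ss_metrics <- function(model, cohort, dose = NULL) {
  doses <- if (is.null(dose)) cohort$dose else rep(dose, nrow(cohort))
  eta_cols <- grep("^eta_", names(cohort), value = TRUE)
  mets <- lapply(seq_len(nrow(cohort)), function(i) {
    eta <- unlist(cohort[i, eta_cols])
    names(eta) <- sub("^eta_", "", eta_cols)
    pars <- individual_params(model, cohort$WT[i], cohort$PHEN[i], eta)
    m <- steady_state_metrics(pars, regimen(doses[i]))
    as.data.frame(unclass(m))
  })
  cbind(cohort, do.call(rbind, mets))
}

#' Compare metabolic ratios between CYP2D6 phenotype groups
#'
#' Group means and SDs of the steady-state DARI/ARI ratios (AUC24, Cmin,
#' Cmax) per phenotype, with pairwise Mann-Whitney tests per metric.
#' Groups with fewer than 2 subjects are excluded with a warning.
#'
#' @param metrics data.frame from [population_ss_metrics()] (needs `PHEN`,
#'   `mr_auc`, `mr_cmin`, `mr_cmax`).
#' @return list with `summary` (phenotype x metric mean/sd/n) and `tests`
#'   (pairwise Wilcoxon p-values per metric).
#' @export
compare_mr_groups <- function(metrics) {
  keep <- names(which(table(metrics$PHEN) >= 2))
  dropped <- setdiff(unique(metrics$PHEN), keep)
  if (length(dropped))
    warning("excluding phenotype group(s) with n < 2: ",
            paste(dropped, collapse = ", "))
  metrics <- metrics[metrics$PHEN %in% keep, ]
  if (length(keep) < 2) stop("at least 2 phenotype groups required")
  mrs <- c("mr_auc", "mr_cmin", "mr_cmax")
  summ <- do.call(rbind, lapply(keep, function(g) {
    sub <- metrics[metrics$PHEN == g, ]
    data.frame(phenotype = g, metric = mrs,
               mean = vapply(mrs, function(m) mean(sub[[m]]), numeric(1)),
               sd = vapply(mrs, function(m) sd(sub[[m]]), numeric(1)),
               median = vapply(mrs, function(m) median(sub[[m]]),
                               numeric(1)),
               n = nrow(sub))
  }))
  rownames(summ) <- NULL
  pairs <- utils::combn(keep, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(mrs, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      p <- wilcox.test(metrics[[m]][metrics$PHEN == pr[1]],
                       metrics[[m]][metrics$PHEN == pr[2]],
                       exact = FALSE)$p.value
      data.frame(metric = m, group1 = pr[1], group2 = pr[2], p_value = p)
    }))
  }))
  list(summary = summ, tests = tests)
}

#' Trough-concentration target criteria
#'
#' The default set mirrors the therapeutic-window targets used for the
#' dose optimization: efficacy floors P(ARI trough >= 100 ng/ml) >= 0.75
#' and P(ARI+DARI trough >= 150 ng/ml) >= 0.75; safety caps
#' P(ARI trough >= 350) <= 0.05, P(ARI+DARI trough >= 500) <= 0.05 and
#' P(ARI trough >= 1000) <= 0.01.
#'
#' @param criteria a data.frame with columns `analyte` ("ari" or
#'   "ari_dari"), `threshold` (ng/ml), `type` ("floor" or "cap") and
#'   `prob` (required probability).
#' @return The validated criteria data.frame (class `pta_criteria`).
#' @export
pta_criteria <- function(criteria = NULL) {
  if (is.null(criteria))
    criteria <- data.frame(
      analyte = c("ari", "ari_dari", "ari", "ari_dari", "ari"),
      threshold = c(100, 150, 350, 500, 1000),
      type = c("floor", "floor", "cap", "cap", "cap"),
      prob = c(0.75, 0.75, 0.05, 0.05, 0.01))
  stopifnot(all(criteria$threshold > 0),
            all(criteria$prob >= 0 & criteria$prob <= 1),
            all(criteria$analyte %in% c("ari", "ari_dari")),
            all(criteria$type %in% c("floor", "cap")))
  class(criteria) <- c("pta_criteria", "data.frame")
  criteria
}

#' Monte-Carlo probability of target attainment
#'
#' Draws `n_sim` random-effect vectors for a weight/phenotype scenario,
#' computes each virtual subject's analytic steady-state troughs of ARI
#' and ARI plus DARI (sum of the two interval-end concentrations), and
#' returns the fraction attaining each criterion threshold.
#' Inter-individual variability only: residual (assay) error would
#' double-count variability in true exposure; set `residual_error = TRUE`
#' for a sensitivity analysis that includes it.
#'
#' @param model a [ppk_model()].
#' @param phenotype,weight,dose scenario definition.
#' @param criteria a [pta_criteria()] table.
#' @param n_sim virtual subjects per scenario (>= 100).
#' @param seed optional integer seed.
#' @param residual_error add proportional residual error to the troughs.
#' @return data.frame: one row per criterion with `analyte`, `threshold`,
#'   `type`, `prob`, `pta` and `pass`.
#' @export
simulate_pta <- function(model, phenotype, weight, dose,
                         criteria = pta_criteria(), n_sim = 1000,
                         seed = NULL, residual_error = FALSE) {
  stopifnot(n_sim >= 100)
  if (!is.null(seed)) set.seed(seed)
  tr <- scenario_troughs(model, phenotype, weight, dose, n_sim,
                         residual_error)
  pta <- vapply(seq_len(nrow(criteria)), function(i) {
    v <- if (criteria$analyte[i] == "ari") tr[, "ari"] else
      tr[, "ari"] + tr[, "dari"]
    mean(v >= criteria$threshold[i])
  }, numeric(1))
  out <- as.data.frame(criteria)
  out$pta <- pta
  out$pass <- ifelse(out$type == "floor", pta >= out$prob, pta <= out$prob)
  out
}

scenario_troughs <- function(model, phenotype, weight, dose, n_sim,
                             residual_error = FALSE) {
  etas <- sample_etas(model$omega2, n_sim)
  base <- individual_params(model, weight, phenotype)
  tr <- ss_trough_vec(cl = base$cl_f * exp(etas[, "cl"]),
                      vd = base$vd_f * exp(etas[, "vd"]),
                      clm = base$clm_fm * exp(etas[, "clm"]),
                      vdm = base$vdm_fm,
                      dose = dose, ka = base$ka, kn = base$kn)
  if (residual_error) {
    tr[, "ari"] <- apply_residual_error(tr[, "ari"], model$sigma, "ari")
    tr[, "dari"] <- apply_residual_error(tr[, "dari"], model$sigma, "dari")
  }
  tr
}

#' Optimize the dosing regimen over a weight x phenotype grid
#'
#' For each phenotype and weight, finds the lowest dose on the grid whose
#' Monte-Carlo PTA satisfies every criterion. Cells with no feasible dose
#' are reported as `NA` and flagged.
#'
#' @param model a [ppk_model()].
#' @param weights weight grid (kg); @param phenotypes phenotype grid.
#' @param dose_grid ascending candidate once-daily doses (mg).
#' @param criteria a [pta_criteria()] table.
#' @param n_sim virtual subjects per cell/dose.
#' @param seed optional integer seed.
#' @return An object of class `regimen_table`: data.frame `phenotype` x
#'   `weight` with the recommended dose (mg, NA if infeasible) and the
#'   attained PTAs at that dose.
#' @export
optimize_regimen <- function(model, weights = c(20, 40, 60, 80, 100),
                             phenotypes = c("IM", "NM", "UM"),
                             dose_grid = seq(2.5, 20, by = 2.5),
                             criteria = pta_criteria(), n_sim = 1000,
                             seed = NULL) {
  if (!length(dose_grid)) stop("dose grid is empty")
  stopifnot(!is.unsorted(dose_grid))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (ph in phenotypes) for (wt in weights) {
    chosen <- NA_real_
    ptas <- NULL
    for (d in dose_grid) {
      res <- simulate_pta(model, ph, wt, d, criteria, n_sim)
      if (all(res$pass)) {
        chosen <- d
        ptas <- res$pta
        break
      }
    }
    row <- data.frame(phenotype = ph, weight = wt, dose = chosen,
                      feasible = !is.na(chosen))
    if (!is.null(ptas))
      row <- cbind(row, setNames(as.data.frame(t(ptas)),
                                 paste0("pta_", criteria$analyte, "_",
                                        criteria$threshold)))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    if (length(miss)) r[miss] <- NA_real_
    r
  }))
  class(out) <- c("regimen_table", "data.frame")
  out
}

#' Published once-daily regimen recommendations
#'
#' The optimal once-daily aripiprazole doses (mg) per CYP2D6 phenotype and
#' body weight reported for the pediatric tic-disorder population, used as
#' the reference grid for PTA evaluation.
#'
#' @return data.frame: `phenotype`, `weight` (kg), `dose` (mg).
#' @export
reference_regimen_table <- function() {
  data.frame(
    phenotype = rep(c("NM", "IM", "UM"), each = 5),
    weight = rep(c(20, 40, 60, 80, 100), 3),
    dose = c(7.5, 10.0, 12.5, 15.0, 17.5,
             5.0, 7.5, 10.0, 12.5, 12.5,
             10.0, 12.5, 17.5, 20.0, 20.0))
}
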