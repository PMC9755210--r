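# Pharmacogenetic classification, YGTSS efficacy scoring, ROC analyses and
# pediatric covariate utilities.

#' Default CYP2D6 allele function table
#'
#' Function classes for the alleles observed in the study population:
#' normal function *1, *2, *34, *35, *39; decreased function *10, *33,
#' *41; no function *3, *4, *5, *6, *14. Two entries deserve a flag, as
#' classifications vary between sources: *14 is classed no-function (either
#' class yields the same IM assignment for the observed *10/*14 carriers),
#' and *33 is classed decreased-function to match the reference cohort's
#' phenotype counting, in which *1/*33 carriers are normal metabolizers
#' (one functional allele). Override entries via `overrides`.
#'
#' @param overrides optional named character vector, e.g.
#'   `c("*14" = "decreased")`.
#' @return Named character vector mapping allele to
#'   "normal"/"decreased"/"none".
#' @export
cyp2d6_allele_table <- function(overrides = NULL) {
  tab <- c("*1" = "normal", "*2" = "normal",
           "*34" = "normal", "*35" = "normal", "*39" = "normal",
           "*10" = "decreased", "*33" = "decreased", "*41" = "decreased",
           "*3" = "none", "*4" = "none", "*5" = "none", "*6" = "none",
           "*14" = "none")
  if (!is.null(overrides)) {
    bad <- setdiff(overrides, c("normal", "decreased", "none"))
    if (length(bad)) stop("invalid function class: ",
                          paste(bad, collapse = ", "))
    tab[names(overrides)] <- overrides
  }
  tab
}

#' Classify a CYP2D6 diplotype into a metabolizer phenotype
#'
#' Rule used for this population: UM if both alleles are normal-function
#' (e.g. *1/*1, *1/*2), NM if exactly one normal-function allele
#' (e.g. *1/*10), IM if decreased+none or two decreased-function alleles
#' (e.g. *10/*10), PM if two no-function alleles.
#'
#' @param diplotype two allele names, either a character vector of length 2
#'   or a single string like `"*1/*10"`.
#' @param table allele function table from [cyp2d6_allele_table()].
#' @return One of "UM", "NM", "IM", "PM". Symmetric in allele order.
#' @export
classify_cyp2d6 <- function(diplotype, table = cyp2d6_allele_table()) {
  if (length(diplotype) == 1)
    diplotype <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  stopifnot(length(diplotype) == 2)
  unknown <- setdiff(diplotype, names(table))
  if (length(unknown))
    stop("unknown CYP2D6 allele: ", paste(unknown, collapse = ", "))
  fn <- sort(unname(table[diplotype]))  # alphabetical: decreased, none, normal
  n_normal <- sum(fn == "normal")
  n_none <- sum(fn == "none")
  n_decr <- sum(fn == "decreased")
  if (n_normal == 2) "UM"
  else if (n_normal == 1) "NM"
  else if (n_none == 2) "PM"
  else if (n_decr == 2 || (n_decr == 1 && n_none == 1)) "IM"
  else stop("unclassifiable diplotype")  # unreachable
}

#' CYP2D6 genotype counts of the study cohort
#'
#' The twelve observed diplotypes and their counts among the 84 genotyped
#' patients, as reported for the pediatric tic-disorder cohort.
#'
#' @return Named integer vector of diplotype counts (sums to 84).
#' @export
td_genotype_counts <- function() {
  c("*1/*1" = 1L, "*1/*2" = 6L, "*39/*39" = 8L, "*1/*10" = 27L,
    "*1/*41" = 3L, "*1/*14" = 1L, "*10/*34" = 1L, "*10/*35" = 1L,
    "*1/*33" = 1L, "*10/*10" = 30L, "*10/*14" = 3L, "*10/*41" = 2L)
}

#' Phenotype census from genotype counts
#'
#' Applies [classify_cyp2d6()] to each genotype and aggregates counts and
#' percentages per phenotype. Percentages are rounded to one decimal, so
#' they can sum to slightly off 100.
#'
#' @param counts named vector of diplotype counts, e.g.
#'   [td_genotype_counts()].
#' @param table allele function table.
#' @return data.frame with `phenotype`, `n`, `pct` rows for UM/NM/IM/PM.
#' @export
phenotype_census <- function(counts, table = cyp2d6_allele_table()) {
  stopifnot(all(counts >= 0))
  levels <- c("UM", "NM", "IM", "PM")
  n <- setNames(integer(4), levels)
  for (g in names(counts)) {
    ph <- classify_cyp2d6(g, table)
    n[ph] <- n[ph] + counts[[g]]
  }
  total <- sum(n)
  pct <- if (total > 0) round(100 * n / total, 1) else n * 0
  data.frame(phenotype = levels, n = as.integer(n), pct = as.numeric(pct))
}

#' YGTSS reduction rate and responder status
#'
#' Reduction rate (%) = (baseline - week12) / baseline * 100; responder if
#' the reduction is strictly greater than 50% (exactly 50% counts as
#' non-responder).
#'
#' @param baseline,week12 YGTSS total scores (baseline > 0).
#' @return list with `ygtss_baseline`, `ygtss_week12`, `reduction_rate`
#'   (%), `responder` (logical).
#' @export
ygtss_reduction <- function(baseline, week12) {
  if (any(baseline <= 0)) stop("baseline YGTSS score must be positive")
  stopifnot(all(week12 >= 0))
  rate <- (baseline - week12) / baseline * 100
  list(ygtss_baseline = baseline, ygtss_week12 = week12,
       reduction_rate = rate, responder = rate > 50)
}

#' Empirical ROC analysis of an exposure metric against response
#'
#' Empirical ROC over all observed thresholds; AUC by the trapezoid rule
#' (equal to the Mann-Whitney probability of correct pairwise ordering,
#' ties counted 1/2); standard error by Hanley-McNeil; the reported cutoff
#' maximizes Youden's J (ties broken toward the lower threshold, i.e.
#' higher sensitivity).
#'
#' @param values exposure metric per patient.
#' @param labels logical (or 0/1) responder indicator.
#' @param direction `">="` if larger values call positives (default), or
#'   `"<="`.
#' @return An object of class `roc_report`: list with `auc`, `auc_se`,
#'   `ci` (95%), `cutoff`, `sensitivity`, `specificity`, `direction` and
#'   the full `curve` data.frame (threshold, sens, spec).
#' @export
roc_analysis <- function(values, labels, direction = ">=") {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels),
            direction %in% c(">=", "<="))
  if (!any(labels) || all(labels))
    stop("both responder classes must be present")
  x <- if (direction == ">=") values else -values
  pos <- x[labels]; neg <- x[!labels]
  n1 <- length(pos); n0 <- length(neg)
  # Mann-Whitney AUC (== trapezoid area under the empirical ROC)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  auc_se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                    (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * auc_se, 0), 1)
  thr <- sort(unique(x))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # lowest threshold among ties
  cutoff <- if (direction == ">=") thr[best] else -thr[best]
  curve <- data.frame(threshold = if (direction == ">=") thr else
    rev(-thr), sens = if (direction == ">=") sens else rev(sens),
    spec = if (direction == ">=") spec else rev(spec))
  structure(list(auc = auc, auc_se = auc_se, ci = ci, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 direction = direction, curve = curve),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f +/- %.3f (95%% CI %.3f-%.3f)\ncutoff %s%.4g: sens %.3f, spec %.3f\n",
    x$auc, x$auc_se, x$ci[1], x$ci[2], x$direction, x$cutoff,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Phenotype discrimination from metabolic ratios
#'
#' One-vs-rest ROC of a steady-state DARI/ARI metabolic ratio for picking
#' out UMs (reported as >= cutoffs, high MR) or IMs (reported as <=
#' cutoffs, low MR) from the rest of the population.
#'
#' @param mr metabolic-ratio values.
#' @param phenotype phenotype labels aligned with `mr`.
#' @param target "UM" or "IM".
#' @return A `roc_report` (see [roc_analysis()]).
#' @export
mr_phenotype_discrimination <- function(mr, phenotype, target = c("UM", "IM")) {
  target <- match.arg(target)
  if (!any(phenotype == target))
    stop("target phenotype ", target, " not present")
  roc_analysis(mr, phenotype == target,
               direction = if (target == "UM") ">=" else "<=")
}

#' Mosteller body surface area
#'
#' BSA (m^2) = sqrt(height_cm * weight_kg / 3600).
#'
#' @param height_cm height in cm; @param weight_kg weight in kg.
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive")
  sqrt(height_cm * weight_kg / 3600)
}

#' Modified Schwartz estimated glomerular filtration rate
#'
#' eGFR (ml/min/1.73 m^2) = 0.413 * height_cm / Scr with serum creatinine
#' in mg/dl; micromol/L input is converted by dividing by 88.4.
#'
#' @param height_cm height in cm.
#' @param scr serum creatinine.
#' @param scr_unit `"umol/L"` (default) or `"mg/dL"`.
#' @export
egfr_schwartz <- function(height_cm, scr, scr_unit = c("umol/L", "mg/dL")) {
  scr_unit <- match.arg(scr_unit)
  if (any(height_cm <= 0) || any(scr <= 0))
    stop("height and serum creatinine must be positive")
  scr_mgdl <- if (scr_unit == "umol/L") scr / 88.4 else scr
  0.413 * height_cm / scr_mgdl
}
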