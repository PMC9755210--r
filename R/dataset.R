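# NONMEM-style event dataset reading/writing.
#
# Dialect: columns ID, TIME (h), EVID (1 = dose, 0 = observation), AMT (mg,
# dose rows), DV (ng/ml, observation rows), DVID (1 = ARI, 2 = DARI), plus
# covariate columns (WT, AGE, SEX, PHEN, DIPLO, ...). Missing values are
# written as ".".

EVENT_COLS <- c("ID", "TIME", "EVID", "AMT", "DV", "DVID")

#' Write a study dataset to NONMEM-style CSV
#'
#' @param data a `ppk_data` object or a plain events data.frame.
#' @param path output CSV path; missing values encoded as ".".
#' @param efficacy_path optional path for the per-subject efficacy table.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, efficacy_path = NULL) {
  events <- if (inherits(data, "ppk_data")) data$events else data
  out <- events
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v)) v <- formatC(v, digits = 10, format = "g")
    v[is.na(out[[j]])] <- "."
    out[[j]] <- v
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(efficacy_path) && inherits(data, "ppk_data") &&
      !is.null(data$efficacy))
    write.csv(data$efficacy, efficacy_path, row.names = FALSE)
  invisible(path)
}

#' Read a NONMEM-style study dataset
#'
#' Parses and validates the event CSV dialect written by [write_dataset()].
#' Validation failures (non-monotone times within subject, observations
#' before the first dose, non-positive DV, unknown DVID codes) are reported
#' as errors naming the offending subjects or line numbers.
#'
#' @param path CSV path.
#' @param efficacy_path optional efficacy CSV.
#' @return A `ppk_data` object.
#' @export
read_dataset <- function(path, efficacy_path = NULL) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(EVENT_COLS, names(raw))
  if (length(missing_cols))
    stop("dataset is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  ev <- raw
  num_cols <- intersect(c("ID", "TIME", "EVID", "AMT", "DV", "DVID",
                          "WT", "AGE", "SEX"), names(ev))
  for (cn in num_cols) {
    v <- ev[[cn]]
    v[v == "."] <- NA
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(vn))
    if (length(bad))
      stop("malformed numeric value in column ", cn, " at data line(s) ",
           paste(head(bad + 1, 5), collapse = ", "))
    ev[[cn]] <- vn
  }
  ev$EVID <- as.integer(ev$EVID)
  ev$DVID <- as.integer(ev$DVID)
  data <- structure(list(events = ev, efficacy = NULL, subjects = NULL),
                    class = "ppk_data")
  if (!is.null(efficacy_path))
    data$efficacy <- read.csv(efficacy_path)
  validate_dataset(data)
  data
}

#' Validate a study dataset
#'
#' @param data a `ppk_data` object.
#' @return `data` invisibly; stops with an informative message on the first
#'   class of validation failure found.
#' @export
validate_dataset <- function(data) {
  ev <- if (inherits(data, "ppk_data")) data$events else data
  obs <- ev[ev$EVID == 0, ]
  bad_dvid <- setdiff(unique(obs$DVID), c(1L, 2L))
  if (length(bad_dvid))
    stop("unknown analyte code (DVID): ", paste(bad_dvid, collapse = ", "))
  if (any(is.na(obs$DV)) || any(obs$DV <= 0))
    stop("observation rows must carry positive DV values")
  doses <- ev[ev$EVID == 1, ]
  if (any(is.na(doses$AMT)) || any(doses$AMT < 0))
    stop("dose rows must carry non-negative AMT")
  for (id in unique(ev$ID)) {
    sub_obs <- obs[obs$ID == id, ]
    sub_dose <- doses[doses$ID == id, ]
    if (nrow(sub_obs) && !nrow(sub_dose))
      stop("subject ", id, " has observations but no dose records")
    if (nrow(sub_obs) && min(sub_obs$TIME) < min(sub_dose$TIME))
      stop("subject ", id, " has an observation before the first dose")
  }
  invisible(data)
}

# Parse a ppk_data object into per-subject structures for estimation.
# Regular once-daily equal-amount regimens get the O(1) accumulation
# evaluator; anything else falls back to explicit superposition over
# individual dose events.
as_events <- function(data) {
  if (inherits(data, "ppk_data")) data$events
  else if (is.data.frame(data)) data
  else if (is.list(data) && !is.null(data$events)) data$events
  else stop("expected a ppk_data object or an events data.frame")
}

parse_subjects <- function(data) {
  ev <- as_events(data)
  cov_cols <- setdiff(names(ev), EVENT_COLS)
  ids <- unique(ev$ID)
  subjects <- list()
  for (id in ids) {
    sub <- ev[ev$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    if (!nrow(obs)) next
    doses <- sub[sub$EVID == 1, ]
    dt <- doses$TIME - min(doses$TIME)
    regular <- nrow(doses) == 1 ||
      (length(unique(doses$AMT)) == 1 &&
         max(abs(dt - (seq_len(nrow(doses)) - 1) * 24)) < 1e-6)
    covs <- as.list(sub[1, cov_cols, drop = FALSE])
    subjects[[as.character(id)]] <- list(
      id = id,
      times = obs$TIME - min(doses$TIME),
      analyte = ifelse(obs$DVID == 1, "ari", "dari"),
      dv = obs$DV,
      covs = covs,
      regular = regular,
      dose = doses$AMT[1], tau = 24, n_doses = nrow(doses),
      dose_times = doses$TIME - min(doses$TIME), dose_amts = doses$AMT)
  }
  subjects
}

# model-predicted concentrations for one parsed subject at given etas
subject_pred <- function(subj, model, eta) {
  pars <- individual_params(model, subj$covs, eta = eta)
  if (subj$regular) {
    amt <- closed_amounts(pars, subj$dose, subj$tau, subj$n_doses,
                          subj$times)
  } else {
    amt <- matrix(0, length(subj$times), 2,
                  dimnames = list(NULL, c("parent", "metab")))
    for (k in seq_along(subj$dose_times)) {
      rel <- subj$times - subj$dose_times[k]
      act <- rel > 0
      if (any(act))
        amt[act, ] <- amt[act, ] +
          closed_amounts(pars, subj$dose_amts[k], 24, 1, rel[act])
    }
  }
  conc <- ifelse(subj$analyte == "ari",
                 MG_TO_NGML * amt[, "parent"] / pars$vd_f,
                 MG_TO_NGML * amt[, "metab"] / pars$vdm_fm)
  conc
}
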