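# Run configuration and reproducibility plumbing. All randomness in a
# pipeline run flows from one top-level seed split into named streams so
# each stage (cohort, etas, residual, bootstrap, sim) is independently
# reproducible.

#' Derive a named seed stream from a top-level seed
#'
#' @param seed top-level integer seed.
#' @param stream one of "cohort", "etas", "residual", "bootstrap", "sim",
#'   "efficacy".
#' @return A derived integer seed (< 2^31), deterministic in
#'   (seed, stream).
#' @export
seed_stream <- function(seed,
                        stream = c("cohort", "etas", "residual",
                                   "bootstrap", "sim", "efficacy")) {
  stream <- match.arg(stream)
  offset <- c(cohort = 1L, etas = 2L, residual = 3L, bootstrap = 4L,
              sim = 5L, efficacy = 6L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Assemble a run configuration
#'
#' A serializable list holding everything a pipeline run needs: seed,
#' model parameters (the published final-model estimates by default),
#' cohort design, simulation grids, PTA criteria and estimation settings.
#'
#' @param seed top-level seed.
#' @param model a [ppk_model()].
#' @param cohort a [cohort_spec()].
#' @param weights,phenotypes,dose_grid simulation grids.
#' @param criteria a [pta_criteria()] table.
#' @param n_sim Monte-Carlo replicates.
#' @param estimation list of optimizer settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, model = ppk_model(),
                       cohort = cohort_spec(),
                       weights = c(20, 40, 60, 80, 100),
                       phenotypes = c("IM", "NM", "UM"),
                       dose_grid = seq(2.5, 20, by = 2.5),
                       criteria = pta_criteria(), n_sim = 1000,
                       estimation = list(iter.max = 150, rel.tol = 1e-8)) {
  structure(list(seed = seed, model = model, cohort = cohort,
                 weights = weights, phenotypes = phenotypes,
                 dose_grid = dose_grid, criteria = as.data.frame(criteria),
                 n_sim = n_sim, estimation = estimation),
            class = "run_config")
}

config_to_list <- function(cfg) {
  m <- cfg$model
  list(seed = cfg$seed,
       model = list(theta = as.list(m$theta),
                    fixed_theta = as.list(m$fixed_theta),
                    terms = m$terms,
                    omega2 = as.list(m$omega2), sigma = as.list(m$sigma),
                    kn = m$kn, ref_weight = m$ref_weight),
       cohort = lapply(unclass(cfg$cohort), function(v)
         if (!is.null(names(v))) as.list(v) else v),
       weights = cfg$weights, phenotypes = cfg$phenotypes,
       dose_grid = cfg$dose_grid,
       criteria = cfg$criteria,
       n_sim = cfg$n_sim, estimation = cfg$estimation)
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [run_config()]; @param path file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 12)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  terms <- lapply(x$model$terms, function(tm) {
    if (tm$form == "cat") {
      tm$beta <- unlist(tm$beta)
      tm$fixed <- unlist(tm$fixed)
    }
    tm
  })
  model <- ppk_model(theta = unlist(x$model$theta),
                     fixed_theta = unlist(x$model$fixed_theta),
                     terms = terms,
                     omega2 = unlist(x$model$omega2),
                     sigma = unlist(x$model$sigma),
                     kn = x$model$kn, ref_weight = x$model$ref_weight)
  ch <- lapply(x$cohort, function(v) if (is.list(v)) unlist(v) else v)
  cohort <- do.call(cohort_spec, ch)
  run_config(seed = x$seed, model = model, cohort = cohort,
             weights = unlist(x$weights), phenotypes = unlist(x$phenotypes),
             dose_grid = unlist(x$dose_grid),
             criteria = pta_criteria(as.data.frame(
               lapply(x$criteria, unlist))),
             n_sim = x$n_sim, estimation = x$estimation)
}

#' Hash of a resolved configuration
#'
#' MD5 of the serialized YAML form; two runs with equal hashes and seeds
#' produce identical outputs.
#'
#' @param cfg a [run_config()].
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(cfg, tf)
  unname(tools::md5sum(tf))
}
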