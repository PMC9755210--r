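# Shared fixtures: small synthetic designs built in code.

typical_params <- function(weight = 70, phenotype = "NM") {
  individual_params(ppk_model(), weight, phenotype)
}

# compact rich-sampling cohort for estimation tests
rich_spec <- function(n = 30, k = 3:4) {
  cohort_spec(n_subjects = n, samples_per_subject = k,
              sample_probs = rep(1 / length(k), length(k)))
}

# deterministic generating model without noise (for pipeline identities)
quiet_model <- function(sigma = 1e-6) {
  ppk_model(omega2 = c(vd = 0, cl = 0, clm = 0),
            fixed_omega = c(vd = TRUE, cl = TRUE, clm = TRUE),
            sigma = c(ari = sigma, dari = sigma),
            fixed_sigma = c(ari = TRUE, dari = TRUE))
}

# independent four-state ODE oracle including cumulative metabolite
# elimination, for mass-balance and profile cross-checks
oracle_ode <- function(params, dose, tau, n_doses, times) {
  rhs <- function(t, y, p) {
    with(as.list(p), list(c(
      -ka * y[1],
      ka * y[1] - ke * y[2],
      kn * ke * y[2] - kem * y[3],
      kem * y[3])))
  }
  p <- c(ka = params$ka, ke = params$cl_f / params$vd_f,
         kem = params$clm_fm / params$vdm_fm, kn = params$kn)
  dose_times <- (seq_len(n_doses) - 1) * tau
  ev <- data.frame(var = "depot", time = dose_times, value = dose,
                   method = "add")
  y0 <- c(depot = 0, parent = 0, metab = 0, elim = 0)
  grid <- sort(unique(c(0, dose_times, times)))
  sol <- deSolve::lsoda(y0, grid, rhs, p, events = list(data = ev),
                        rtol = 1e-11, atol = 1e-11)
  sol[match(times, sol[, "time"]), , drop = FALSE]
}
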