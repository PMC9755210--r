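# Vectorized FOCE evaluation engine.
#
# All subjects' conditional-mode searches advance simultaneously: the
# repeated-dose closed form is evaluated on stacked observation arrays, and
# a damped Newton iteration updates the whole eta matrix at once. This
# keeps a full objective evaluation at the millisecond scale, which the
# outer quasi-Newton fit needs. Only regular equal-dose once-daily
# regimens stack; datasets with irregular dose histories fall back to the
# per-subject path.

build_foce_stack <- function(subjects) {
  if (!all(vapply(subjects, function(s) isTRUE(s$regular), logical(1))))
    return(NULL)
  n <- length(subjects)
  nobs <- vapply(subjects, function(s) length(s$dv), integer(1))
  idx <- rep(seq_len(n), nobs)
  grab <- function(fld) unlist(lapply(subjects, `[[`, fld), use.names = FALSE)
  times <- grab("times")
  tau <- rep(vapply(subjects, `[[`, numeric(1), "tau"), nobs)
  m <- pmin(rep(vapply(subjects, `[[`, numeric(1), "n_doses"), nobs),
            floor(times / tau) + 1)
  covs <- do.call(rbind, lapply(subjects, function(s)
    data.frame(s$covs, stringsAsFactors = FALSE)))
  list(n_subj = n, n_obs = sum(nobs), idx = idx,
       y = grab("dv"),
       is_ari = grab("analyte") == "ari",
       s = times - (m - 1) * tau, m = m, tau = tau,
       D = rep(vapply(subjects, `[[`, numeric(1), "dose"), nobs),
       covs = covs, nobs = nobs)
}

# per-subject base structural parameters under the covariate model,
# vectorized over subjects (no random effects)
base_params_matrix <- function(model, covs) {
  n <- nrow(covs)
  p <- matrix(rep(unname(model$theta[c("vd", "cl", "vdm", "clm")]),
                  each = n), n, 4,
              dimnames = list(NULL, c("vd", "cl", "vdm", "clm")))
  for (tm in model$terms) {
    v <- covs[[tm$cov]]
    if (is.null(v))
      stop("covariate '", tm$cov, "' required by the model is missing")
    mult <- switch(tm$form,
      power  = (v / tm$ref)^tm$beta,
      linear = pmax(1 + tm$beta * (v - tm$ref) / tm$ref, 1e-6),
      cat    = {
        lev <- as.character(v)
        bad <- setdiff(unique(lev), names(tm$beta))
        if (length(bad))
          stop("no coefficient configured for ", tm$cov, " level '",
               bad[1], "'")
        exp(unname(tm$beta[lev]))
      },
      hill   = v^tm$gamma / (tm$beta^tm$gamma + v^tm$gamma))
    p[, tm$param] <- p[, tm$param] * mult
  }
  p
}

# stacked concentrations for eta matrix E (n_subj x 3: vd, cl, clm)
stack_pred <- function(st, B, ka, kn, E) {
  i <- st$idx
  vd <- B[i, 1] * exp(E[i, 1])
  cl <- B[i, 2] * exp(E[i, 2])
  vdm <- B[i, 3]
  clm <- B[i, 4] * exp(E[i, 3])
  ke <- cl / vd
  kem <- clm / vdm
  s <- st$s; m <- st$m; tau <- st$tau
  acc <- function(k) exp(-k * s) * (1 - exp(-k * m * tau)) /
    (1 - exp(-k * tau))
  e_ka <- acc(ka); e_ke <- acc(ke); e_km <- acc(kem)
  A <- ka / (ka - ke)
  K <- kn * ke * A * st$D
  metab <- K * ((e_ke - e_km) / (kem - ke) - (e_ka - e_km) / (kem - ka))
  f <- MG_TO_NGML * metab / vdm
  par_idx <- st$is_ari
  f[par_idx] <- (MG_TO_NGML * st$D * A * (e_ke - e_ka) / vd)[par_idx]
  f
}

# per-subject conditional objective for eta matrix E
stack_q <- function(st, B, ka, kn, sig_obs, w_inv, E) {
  f <- stack_pred(st, B, ka, kn, E)
  g2 <- (sig_obs * pmax(f, 1e-12))^2
  contrib <- log(g2) + (st$y - f)^2 / g2
  bad <- !is.finite(contrib)
  if (any(bad)) contrib[bad] <- BIG_OFV / st$n_obs
  drop(rowsum(contrib, st$idx, reorder = FALSE)) +
    drop(E^2 %*% w_inv)
}

# vectorized symmetric k x k solve (k <= 3) via the adjugate, one row per
# subject: Hd holds diagonals, Hoff off-diagonals ((1,2),(1,3),(2,3))
solve_sym_vec <- function(Hd, Hoff, G, k) {
  if (k == 1) return(G / Hd)
  if (k == 2) {
    a <- Hd[, 1]; c2 <- Hd[, 2]; b <- Hoff[, 1]
    det <- a * c2 - b^2
    return(cbind((c2 * G[, 1] - b * G[, 2]) / det,
                 (a * G[, 2] - b * G[, 1]) / det))
  }
  a <- Hd[, 1]; d <- Hd[, 2]; f <- Hd[, 3]
  b <- Hoff[, 1]; c3 <- Hoff[, 2]; e <- Hoff[, 3]
  i11 <- d * f - e^2
  i12 <- -(b * f - c3 * e)
  i13 <- b * e - c3 * d
  i22 <- a * f - c3^2
  i23 <- -(a * e - b * c3)
  i33 <- a * d - b^2
  det <- a * i11 + b * i12 + c3 * i13
  cbind((i11 * G[, 1] + i12 * G[, 2] + i13 * G[, 3]) / det,
        (i12 * G[, 1] + i22 * G[, 2] + i23 * G[, 3]) / det,
        (i13 * G[, 1] + i23 * G[, 2] + i33 * G[, 3]) / det)
}

# damped Newton for all subjects' conditional modes at once
stack_inner_modes <- function(st, B, ka, kn, sig_obs, w_inv, E0,
                              free = w_inv > 0, h = 1e-3, max_iter = 12,
                              gtol = 5e-4) {
  E <- E0
  E[, !free] <- 0
  nf <- which(free)
  qfun <- function(E) stack_q(st, B, ka, kn, sig_obs, w_inv, E)
  q0 <- qfun(E)
  gnorm <- rep(Inf, st$n_subj)
  for (it in seq_len(max_iter)) {
    k <- length(nf)
    G <- matrix(0, st$n_subj, k)
    Hd <- matrix(0, st$n_subj, k)
    qp <- qm <- vector("list", k)
    for (j in seq_len(k)) {
      Ep <- E; Ep[, nf[j]] <- Ep[, nf[j]] + h
      Em <- E; Em[, nf[j]] <- Em[, nf[j]] - h
      qp[[j]] <- qfun(Ep); qm[[j]] <- qfun(Em)
      G[, j] <- (qp[[j]] - qm[[j]]) / (2 * h)
      Hd[, j] <- (qp[[j]] - 2 * q0 + qm[[j]]) / h^2
    }
    gnorm <- apply(abs(G), 1, max)
    if (max(gnorm) < gtol) break
    Hoff <- matrix(0, st$n_subj, max(1, k * (k - 1) / 2))
    if (k > 1) {
      col <- 0
      for (j in seq_len(k - 1)) for (l in seq((j + 1), k)) {
        col <- col + 1
        Ep <- E
        Ep[, nf[j]] <- Ep[, nf[j]] + h
        Ep[, nf[l]] <- Ep[, nf[l]] + h
        Hoff[, col] <- (qfun(Ep) - qp[[j]] - qp[[l]] + q0) / h^2
      }
    }
    # Levenberg damping: ensure positive-definite curvature per subject
    lam <- pmax(0, -do.call(pmin, as.data.frame(Hd))) + 1e-6
    step <- solve_sym_vec(Hd + lam, Hoff, G, k)
    bad <- !is.finite(rowSums(step))
    if (any(bad))
      step[bad, ] <- G[bad, , drop = FALSE] / (abs(Hd[bad, , drop = FALSE]) + 1)
    # cap huge steps, then backtrack where the objective worsens
    stepn <- sqrt(rowSums(step^2))
    too_big <- stepn > 2
    step[too_big, ] <- step[too_big, , drop = FALSE] * (2 / stepn[too_big])
    alpha <- rep(1, st$n_subj)
    for (half in 1:12) {
      Et <- E
      Et[, nf] <- E[, nf] - alpha * step
      qt <- qfun(Et)
      worse <- qt > q0 + 1e-12
      if (!any(worse)) { E <- Et; q0 <- qt; break }
      keep <- !worse
      if (any(keep)) {
        E[keep, nf] <- Et[keep, nf, drop = FALSE]
        q0[keep] <- qt[keep]
        step[keep, ] <- 0
      }
      alpha[worse] <- alpha[worse] / 2
      if (half == 12) {
        # subjects that never improved keep their current eta
        break
      }
    }
  }
  attr(E, "gnorm") <- gnorm
  E
}

# full FOCE-ELS objective from the stacked representation; `subjects`
# enables a per-subject fallback search for the rare mode the vectorized
# Newton fails to reach
stack_foce_ofv <- function(st, model, E_start = NULL, subjects = NULL,
                           h_jac = 1e-4) {
  B <- base_params_matrix(model, st$covs)
  ka <- model$theta[["ka"]]
  kn <- model$kn
  sig_obs <- unname(model$sigma[ifelse(st$is_ari, "ari", "dari")])
  om <- unname(model$omega2[c("vd", "cl", "clm")])
  om[is.na(om)] <- 0
  w_inv <- ifelse(om > 0, 1 / om, 0)
  E0 <- if (is.null(E_start)) matrix(0, st$n_subj, 3) else E_start
  free <- om > 0
  if (any(free)) {
    E <- stack_inner_modes(st, B, ka, kn, sig_obs, w_inv, E0, free)
    stuck <- which(attr(E, "gnorm") > 0.02)
    if (length(stuck) && !is.null(subjects)) {
      qfun <- function(Em) stack_q(st, B, ka, kn, sig_obs, w_inv, Em)
      for (i in stuck) {
        parts <- subject_foce_parts(subjects[[i]], model)
        eta_i <- parts$eta[c("vd", "cl", "clm")]
        if (length(eta_i) != 3 || !all(is.finite(eta_i))) next
        Et <- E
        Et[i, ] <- eta_i
        if (qfun(Et)[i] < qfun(E)[i]) E <- Et
      }
    }
  } else {
    E <- matrix(0, st$n_subj, 3)
  }
  f_hat <- stack_pred(st, B, ka, kn, E)
  g_hat <- sig_obs * pmax(f_hat, 1e-12)
  if (any(!is.finite(f_hat)))
    return(list(ofv = BIG_OFV, etas = E))
  # jacobian in the free eta directions by central differences
  nf <- which(free)
  Fm <- matrix(0, st$n_obs, 3)
  for (j in nf) {
    Ep <- E; Ep[, j] <- Ep[, j] + h_jac
    Em <- E; Em[, j] <- Em[, j] - h_jac
    Fm[, j] <- (stack_pred(st, B, ka, kn, Ep) -
                  stack_pred(st, B, ka, kn, Em)) / (2 * h_jac)
  }
  r_all <- st$y - f_hat + rowSums(Fm * E[st$idx, , drop = FALSE])
  # matrix-determinant lemma: V = F Omega F' + diag(g^2) gives
  # log|V| = sum log g^2 + log|I + W| and a rank-3 quadratic-form
  # correction, with W and the projections accumulated by rowsum --
  # no per-subject linear algebra
  g2 <- g_hat^2
  M <- cbind(Fm[, 1]^2, Fm[, 2]^2, Fm[, 3]^2,
             Fm[, 1] * Fm[, 2], Fm[, 1] * Fm[, 3], Fm[, 2] * Fm[, 3],
             Fm[, 1] * r_all, Fm[, 2] * r_all, Fm[, 3] * r_all,
             r_all^2) / g2
  S <- rowsum(cbind(M, log(g2)), st$idx, reorder = FALSE)
  sq <- sqrt(om)
  Ad <- cbind(1 + om[1] * S[, 1], 1 + om[2] * S[, 2], 1 + om[3] * S[, 3])
  Ao <- cbind(sq[1] * sq[2] * S[, 4], sq[1] * sq[3] * S[, 5],
              sq[2] * sq[3] * S[, 6])
  u <- cbind(sq[1] * S[, 7], sq[2] * S[, 8], sq[3] * S[, 9])
  x <- solve_sym_vec(Ad, Ao, u, 3)
  detA <- Ad[, 1] * (Ad[, 2] * Ad[, 3] - Ao[, 3]^2) -
    Ao[, 1] * (Ao[, 1] * Ad[, 3] - Ao[, 2] * Ao[, 3]) +
    Ao[, 2] * (Ao[, 1] * Ao[, 3] - Ao[, 2] * Ad[, 2])
  total <- suppressWarnings(
    st$n_obs * log(2 * pi) +
      sum(S[, 11] + log(detA) + S[, 10] - rowSums(x * u)))
  if (!is.finite(total)) total <- BIG_OFV
  list(ofv = total, etas = E)
}
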