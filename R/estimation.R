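# Population-model estimation on NONMEM-style tables. The marginal
# likelihood of the nonlinear mixed-effects PK model is approximated FOCE
# style: per-subject conditional modes of the random effects are located by
# damped Gauss-Newton on the joint density (with interaction: the residual
# variance is evaluated at the conditional prediction), and the Laplace
# correction uses the Gauss-Newton curvature. The PD stage is sequential:
# individual PK parameters are frozen at their empirical-Bayes values and
# the IGF-1 and growth parameters are fit to their observations.

# ---- data plumbing ---------------------------------------------------------

split_subjects <- function(tab) {
  tab <- as.data.frame(tab)
  lapply(split(tab, tab$ID), function(d) {
    list(id = d$ID[1], wt = d$WT[1], age = d$AGE[1], sex = d$SEX[1],
         dose_time = d$TIME[d$EVID == 1], dose_amt = d$AMT[d$EVID == 1],
         dose_wt = d$WT[d$EVID == 1],
         pk_time = d$TIME[d$EVID == 0 & d$CMT == CMT_PK & d$MDV == 0],
         pk_dv = d$DV[d$EVID == 0 & d$CMT == CMT_PK & d$MDV == 0],
         igf_time = d$TIME[d$EVID == 0 & d$CMT == CMT_IGF1 & d$MDV == 0],
         igf_dv = d$DV[d$EVID == 0 & d$CMT == CMT_IGF1 & d$MDV == 0],
         gv_time = d$TIME[d$EVID == 0 & d$CMT == CMT_GV & d$MDV == 0],
         gv_dv = d$DV[d$EVID == 0 & d$CMT == CMT_GV & d$MDV == 0])
  })
}

# Superposed analytic concentration at arbitrary times for one subject.
pk_pred_fn <- function(sub, pop) {
  dt <- outer(sub$pk_time, sub$dose_time, "-")
  pos <- dt > 0
  amt <- sub$dose_amt
  wt_scale_cl <- (sub$wt / pop$wt_ref)^pop$exp_cl
  wt_scale_v <- (sub$wt / pop$wt_ref)^pop$exp_v
  function(theta, etas = c(0, 0, 0)) {
    # theta = c(cl_pop, v_pop, ka_pop)
    cl <- theta[1] * wt_scale_cl * exp(etas[1])
    v <- theta[2] * wt_scale_v * exp(etas[2])
    ka <- theta[3] * exp(etas[3])
    ke <- cl / v
    m <- matrix(0, nrow(dt), ncol(dt))
    m[pos] <- exp(-ke * dt[pos]) - exp(-ka * dt[pos])
    as.vector(m %*% amt) * pop$f_bio * ka / (v * (ka - ke))
  }
}

# Extended-least-squares residual term with interaction.
els_term <- function(y, f, sp, sa) {
  g2 <- sa^2 + (sp * f)^2
  sum((y - f)^2 / g2 + log(2 * pi * g2))
}

# ---- conditional (empirical-Bayes) step ------------------------------------

# Damped Gauss-Newton minimisation of the per-subject joint -2 log density
# over etas. Returns the mode, the GN curvature and the residual term.
eb_solve <- function(pred, y, theta, omega_inv, sp, sa, eta0 = c(0, 0, 0),
                     maxit = 25L, tol = 1e-8) {
  eta <- eta0
  obj <- function(e) {
    f <- pred(theta, e)
    els_term(y, f, sp, sa) + drop(e %*% omega_inv %*% e)
  }
  o0 <- obj(eta)
  hfd <- 1e-4
  H <- NULL
  for (it in seq_len(maxit)) {
    f0 <- pred(theta, eta)
    g2 <- sa^2 + (sp * f0)^2
    r <- y - f0
    J <- vapply(1:3, function(k) {
      ep <- eta; ep[k] <- ep[k] + hfd
      (pred(theta, ep) - f0) / hfd
    }, numeric(length(y)))
    J <- matrix(J, ncol = 3)
    dg2_df <- 2 * sp^2 * f0
    gf <- -2 * r / g2 - (r^2 / g2^2) * dg2_df + dg2_df / g2
    grad <- drop(crossprod(J, gf)) + 2 * drop(omega_inv %*% eta)
    H <- 2 * crossprod(J, J / g2) + 2 * omega_inv
    step <- tryCatch(-solve(H, grad), error = function(e) -grad / max(diag(H)))
    lambda <- 1
    improved <- FALSE
    for (ls in 1:6) {
      cand <- eta + lambda * step
      oc <- obj(cand)
      if (is.finite(oc) && oc < o0) {
        eta <- cand; o0 <- oc; improved <- TRUE; break
      }
      lambda <- lambda / 2
    }
    if (!improved || sum(abs(lambda * step)) < tol) break
  }
  f0 <- pred(theta, eta)
  list(eta = eta, objective = o0, hessian = H,
       els = els_term(y, f0, sp, sa))
}

#' Empirical-Bayes random effects for one subject
#'
#' Conditional mode of the PK random effects `(eta_cl, eta_v, eta_ka)`
#' given a subject's observations under fixed population parameters. With
#' no usable observations the prior mode 0 is returned with a shrinkage
#' warning attribute.
#'
#' @param params A [pk_params()] with non-zero omegas and residual SDs.
#' @param subject_obs Rows of a NONMEM-style table for one subject (dose
#'   and PK observation rows).
#' @return Numeric eta vector of length 3; attribute `shrunk` is `TRUE`
#'   when no data informed the mode.
#' @export
empirical_bayes <- function(params, subject_obs) {
  sub <- split_subjects(subject_obs)[[1]]
  if (length(sub$pk_dv) == 0) {
    out <- c(eta_cl = 0, eta_v = 0, eta_ka = 0)
    attr(out, "shrunk") <- TRUE
    return(out)
  }
  omegas <- c(params$omega_cl, params$omega_v, params$omega_ka)
  omega_inv <- diag(1 / pmax(omegas, 1e-8)^2)
  pred <- pk_pred_fn(sub, params)
  sol <- eb_solve(pred, sub$pk_dv, c(params$cl_pop, params$v_pop, params$ka_pop),
                  omega_inv, params$sigma_prop, max(params$sigma_add, 1e-9))
  out <- sol$eta
  names(out) <- c("eta_cl", "eta_v", "eta_ka")
  attr(out, "shrunk") <- FALSE
  out
}

# ---- population PK fit -----------------------------------------------------

#' Fit the population PK model
#'
#' `method = "naive_pooled"` maximises the extended-least-squares likelihood
#' with all random effects at zero (no between-subject variability), over
#' the fixed effects and optionally the proportional error SD.
#' `method = "foce"` maximises the Laplace-approximated marginal likelihood
#' with interaction; when all omegas in `init` are zero it reduces exactly
#' to the pooled objective.
#'
#' @param obs A NONMEM-style `obs_table` (e.g. from [phase1_design()]).
#' @param init A [pk_params()] holding starting values; its `wt_ref`,
#'   allometric exponents, `f_bio` and `sigma_add` are treated as known
#'   constants.
#' @param method Estimation method.
#' @param estimate_sigma Estimate `sigma_prop` (default) or keep it fixed
#'   at its `init` value.
#' @param control Passed to [stats::nlminb()].
#' @return A `pegsim_fit`: list with `estimates` (named vector), `params`
#'   (updated `pk_params`), `objective` (approximate -2 log-likelihood),
#'   `convergence`, `etas` (per-subject conditional modes, foce only).
#' @export
fit_pk <- function(obs, init, method = c("foce", "naive_pooled"),
                   estimate_sigma = TRUE,
                   control = list(iter.max = 200, rel.tol = 1e-6)) {
  method <- match.arg(method)
  subs <- split_subjects(obs)
  subs <- Filter(function(s) length(s$pk_dv) > 0, subs)
  if (length(subs) == 0) stop("no PK observations")
  preds <- lapply(subs, pk_pred_fn, pop = init)
  sa <- max(init$sigma_add, 1e-9)
  omegas0 <- c(init$omega_cl, init$omega_v, init$omega_ka)
  use_iiv <- method == "foce" && any(omegas0 > 0)

  p0 <- log(c(init$cl_pop, init$v_pop, init$ka_pop))
  if (use_iiv) p0 <- c(p0, log(pmax(omegas0, 1e-3)))
  if (estimate_sigma) p0 <- c(p0, log(max(init$sigma_prop, 1e-3)))

  eta_cache <- lapply(subs, function(s) c(0, 0, 0))
  nobs <- vapply(subs, function(s) length(s$pk_dv), numeric(1))

  objective <- function(p) {
    theta <- exp(p[1:3])
    k <- 3
    if (use_iiv) { omegas <- exp(p[4:6]); k <- 6 } else omegas <- c(0, 0, 0)
    sp <- if (estimate_sigma) exp(p[k + 1]) else init$sigma_prop
    total <- 0
    if (!use_iiv) {
      for (i in seq_along(subs)) {
        f <- preds[[i]](theta)
        total <- total + els_term(subs[[i]]$pk_dv, f, sp, sa)
      }
      return(total)
    }
    omega_inv <- diag(1 / omegas^2)
    log_det_omega <- 2 * sum(log(omegas))
    for (i in seq_along(subs)) {
      sol <- eb_solve(preds[[i]], subs[[i]]$pk_dv, theta, omega_inv, sp, sa,
                      eta0 = eta_cache[[i]])
      eta_cache[[i]] <<- sol$eta
      total <- total + sol$els + log_det_omega +
        drop(sol$eta %*% omega_inv %*% sol$eta) +
        determinant(sol$hessian / 2, logarithm = TRUE)$modulus -
        3 * log(2 * pi)
    }
    total
  }

  # Central-difference gradient with a step well above the numerical noise
  # of the warm-started inner optimisation; nlminb's own finite differences
  # are too fine-grained for the conditional-mode objective.
  gradient <- function(p) {
    h <- 1e-4
    vapply(seq_along(p), function(k) {
      pp <- p; pp[k] <- pp[k] + h
      pm <- p; pm[k] <- pm[k] - h
      (objective(pp) - objective(pm)) / (2 * h)
    }, numeric(1))
  }
  opt <- stats::nlminb(p0, objective, gradient = gradient, control = control)
  # declared convergence policy: optimizer success, or a stationary point
  # (small scaled gradient at the returned optimum)
  grad_norm <- max(abs(gradient(opt$par)))
  converged <- opt$convergence == 0 ||
    grad_norm < 1e-3 * max(1, abs(opt$objective))
  theta <- exp(opt$par[1:3])
  k <- 3
  est <- c(cl_pop = theta[1], v_pop = theta[2], ka_pop = theta[3])
  omegas <- omegas0
  if (use_iiv) {
    omegas <- exp(opt$par[4:6]); k <- 6
    est <- c(est, omega_cl = omegas[1], omega_v = omegas[2], omega_ka = omegas[3])
  }
  sp <- if (estimate_sigma) exp(opt$par[k + 1]) else init$sigma_prop
  if (estimate_sigma) est <- c(est, sigma_prop = sp)
  params <- pk_params(cl_pop = theta[1], v_pop = theta[2], ka_pop = theta[3],
                      f_bio = init$f_bio, wt_ref = init$wt_ref,
                      exp_cl = init$exp_cl, exp_v = init$exp_v,
                      omega_cl = omegas[1], omega_v = omegas[2],
                      omega_ka = omegas[3], sigma_prop = sp,
                      sigma_add = init$sigma_add)
  etas <- NULL
  if (use_iiv) {
    etas <- do.call(rbind, eta_cache)
    rownames(etas) <- vapply(subs, function(s) as.character(s$id), character(1))
    colnames(etas) <- c("eta_cl", "eta_v", "eta_ka")
  }
  structure(list(estimates = est, params = params, objective = opt$objective,
                 convergence = converged, grad_norm = grad_norm, method = method,
                 n_subjects = length(subs), n_obs = sum(nobs), etas = etas),
            class = "pegsim_fit")
}

# ---- sequential PD fit -----------------------------------------------------

# Exact-propagation concentration grids for many subjects sharing weekly
# dose times; clearance and volume may vary quarterly (time-varying body
# weight). Returns concentration at all sub-step points, weekly AUC and the
# step grid (which contains the 167.9 h trough points by construction).
conc_grids <- function(cl_mat, v_mat, ka, dose_mat, n_weeks, step_h = 6) {
  n <- nrow(dose_mat)
  ss <- week_substeps(step_h)
  hs <- ss$hs
  uh <- unique(hs); hmap <- match(hs, uh)
  npt <- n_weeks * length(hs) + 1
  conc <- matrix(0, n, npt)
  times <- numeric(npt)
  auc_weekly <- matrix(0, n, n_weeks)
  A <- C <- cum <- numeric(n)
  pos <- 1L
  hs_cum <- cumsum(hs)
  eka <- eke <- aee <- aea <- NULL
  for (w in seq_len(n_weeks) - 1L) {
    if (w %% 13 == 0) {
      q <- w %/% 13 + 1
      cl <- cl_mat[, min(q, ncol(cl_mat))]
      v <- v_mat[, min(q, ncol(v_mat))]
      ke <- cl / v
      b <- ka / (v * (ka - ke))
      eka <- lapply(uh, function(h) exp(-ka * h))
      eke <- lapply(uh, function(h) exp(-ke * h))
      aee <- lapply(seq_along(uh), function(j) (1 - eke[[j]]) / ke)
      aea <- lapply(seq_along(uh), function(j) (1 - eka[[j]]) / ka)
    }
    A <- A + dose_mat[, w + 1]
    a0 <- cum
    for (j in seq_along(hs)) {
      u <- hmap[j]
      cum <- cum + C * aee[[u]] + A * b * (aee[[u]] - aea[[u]])
      C <- C * eke[[u]] + A * b * (eke[[u]] - eka[[u]])
      A <- A * eka[[u]]
      pos <- pos + 1L
      conc[, pos] <- C
      times[pos] <- w * WEEK_H + hs_cum[j]
    }
    auc_weekly[, w + 1] <- cum - a0
  }
  list(times = times, conc = conc, auc_weekly = auc_weekly)
}

# Integrate the IDR model over precomputed concentration grids (vectorised
# across subjects) and return IGF-1 at requested time indices.
igf1_at <- function(grids, idr_kout, smax, sc50, r0, idx) {
  stim <- 1 + smax * grids$conc / (sc50 + grids$conc)
  h <- diff(grids$times)
  ek <- exp(-idr_kout * h)
  R <- r0
  out <- matrix(NA_real_, length(r0), length(idx))
  hit <- match(seq_along(grids$times), idx)
  if (!is.na(hit[1])) out[, hit[1]] <- R
  for (i in seq_along(h)) {
    sbar <- (stim[, i] + stim[, i + 1]) / 2
    R <- R * ek[i] + (idr_kout * r0 * sbar / idr_kout) * (1 - ek[i])
    if (!is.na(hit[i + 1])) out[, hit[i + 1]] <- R
  }
  out
}

#' Sequential PD fit conditioned on individual PK
#'
#' Implements the individual-PK-parameters sequential strategy: per-subject
#' PK random effects are frozen at their empirical-Bayes modes under the
#' supplied PK fit, individual concentration and interval-AUC grids are
#' precomputed, and then (1) the IGF-1 stimulation parameters `smax`,
#' `sc50` are fit to the IGF-1 observations by log-scale least squares
#' (log-normal residual), and (2) the growth parameters `e0`, `emax_gv`,
#' `auc50`, `lam` are fit to the GV observations by least squares.
#' The IGF-1 loss rate `kout` is a known constant: quarterly trough
#' sampling carries no information on it (the turnover settles within
#' days).
#'
#' @param pk_fit A converged [fit_pk()] result.
#' @param obs NONMEM-style table with dose, (optional) PK, IGF-1 and GV
#'   rows (e.g. from [sparse_pediatric_design()]).
#' @param init Parameter set (`list(idr, gv)`) of starting values; `kout`
#'   is taken from `init$idr` as a constant.
#' @param igf1_baseline `"individual"` anchors each subject's baseline to
#'   the pre-dose IGF-1 observation; `"pooled"` estimates one common
#'   baseline (used e.g. for reduced-model checks).
#' @param fix_smax Optionally fix `smax` (e.g. 0 for the no-drug-effect
#'   reduced model).
#' @param step_h Concentration/IDR integration step (h).
#' @return A `pegsim_fit` with `estimates` covering the IDR and GV
#'   parameters, per-stage objectives, `se` (GV stage), and the per-subject
#'   etas used.
#' @export
fit_pd_sequential <- function(pk_fit, obs, init, igf1_baseline = "individual",
                              fix_smax = NULL, step_h = 6) {
  if (!isTRUE(pk_fit$convergence))
    stop("PK fit did not converge; refusing sequential PD fit")
  pop <- pk_fit$params
  subs <- split_subjects(obs)
  keep <- vapply(subs, function(s)
    length(s$igf_dv) + length(s$gv_dv) > 0, logical(1))
  excluded <- names(subs)[!keep]
  subs <- subs[keep]
  n <- length(subs)
  # empirical-Bayes etas (prior mode when a subject has no PK rows)
  etas <- t(vapply(subs, function(s) {
    if (length(s$pk_dv) == 0) return(c(0, 0, 0))
    omega_inv <- diag(1 / pmax(c(pop$omega_cl, pop$omega_v, pop$omega_ka), 1e-8)^2)
    sol <- eb_solve(pk_pred_fn(s, pop), s$pk_dv,
                    c(pop$cl_pop, pop$v_pop, pop$ka_pop), omega_inv,
                    pop$sigma_prop, max(pop$sigma_add, 1e-9))
    sol$eta
  }, numeric(3)))
  n_weeks <- max(vapply(subs, function(s) length(s$dose_time), numeric(1)))
  n_quarters <- ceiling(n_weeks / 13)
  dose_mat <- matrix(0, n, n_weeks)
  wt_mat <- matrix(NA_real_, n, n_quarters)
  for (i in seq_len(n)) {
    wk <- round(subs[[i]]$dose_time / WEEK_H) + 1
    dose_mat[i, wk] <- subs[[i]]$dose_amt * pop$f_bio
    qw <- subs[[i]]$dose_wt[match((seq_len(n_quarters) - 1) * 13 + 1, wk)]
    if (anyNA(qw)) qw <- rep(subs[[i]]$wt, n_quarters)  # constant-weight table
    wt_mat[i, ] <- qw
  }
  cl_mat <- pop$cl_pop * (wt_mat / pop$wt_ref)^pop$exp_cl * exp(etas[, 1])
  v_mat <- pop$v_pop * (wt_mat / pop$wt_ref)^pop$exp_v * exp(etas[, 2])
  ka <- pop$ka_pop * exp(etas[, 3])
  grids <- conc_grids(cl_mat, v_mat, ka, dose_mat, n_weeks, step_h)

  # --- IGF-1 stage ---
  igf_t <- sort(unique(unlist(lapply(subs, `[[`, "igf_time"))))
  idx <- match(round(igf_t, 6), round(grids$times, 6))
  if (any(is.na(idx)))
    stop("IGF-1 observation times not on the integration grid")
  y_igf <- t(vapply(subs, function(s)
    s$igf_dv[match(igf_t, s$igf_time)], numeric(length(igf_t))))
  kout <- init$idr$kout
  if (igf1_baseline == "individual") {
    base_idx <- which(igf_t == 0)
    if (length(base_idx) == 0) stop("individual baselines need a time-0 IGF-1 row")
    r0_i <- y_igf[, base_idx]
  }
  igf_obj <- function(p) {
    smax <- if (is.null(fix_smax)) exp(p[1]) else fix_smax
    sc50 <- exp(p[length(p) - (igf1_baseline == "pooled")])
    r0 <- if (igf1_baseline == "pooled") rep(exp(p[length(p)]), n) else r0_i
    pred <- igf1_at(grids, kout, smax, sc50, r0, idx)
    sum((log(y_igf) - log(pred))^2, na.rm = TRUE)
  }
  p0 <- c(if (is.null(fix_smax)) log(max(init$idr$smax, 1e-3)),
          log(init$idr$sc50),
          if (igf1_baseline == "pooled") log(init$idr$r0_pop))
  igf_opt <- stats::nlminb(p0, igf_obj)
  smax_hat <- if (is.null(fix_smax)) exp(igf_opt$par[1]) else fix_smax
  sc50_hat <- exp(igf_opt$par[length(igf_opt$par) - (igf1_baseline == "pooled")])
  r0_hat <- if (igf1_baseline == "pooled") exp(igf_opt$par[length(igf_opt$par)]) else NA

  # --- GV stage ---
  gv_t <- sort(unique(unlist(lapply(subs, `[[`, "gv_time"))))
  y_gv <- t(vapply(subs, function(s)
    s$gv_dv[match(gv_t, s$gv_time)], numeric(length(gv_t))))
  gv_month <- gv_t / WEEK_H / 13 * 3
  qweeks <- lapply(gv_month, function(m) {
    if (m == 0) return(integer(0))
    ((m - 3) / 3 * 13 + 1):(m / 3 * 13)
  })
  t_mid <- lapply(qweeks, function(wk) (wk - 0.5) / 52)
  gv_pred <- function(par) {
    # par = c(e0, emax, auc50, lam) on natural scale (auc50, emax logged)
    e0 <- par[1]; emax <- exp(par[2]); auc50 <- exp(par[3]); lam <- par[4]
    vapply(seq_along(qweeks), function(k) {
      if (length(qweeks[[k]]) == 0) return(rep(e0, n))
      auc <- grids$auc_weekly[, qweeks[[k]], drop = FALSE]
      eff <- e0 + emax * auc / (auc50 + auc)
      rowMeans(sweep(eff, 2, exp(-lam * t_mid[[k]]), `*`))
    }, numeric(n))
  }
  gv_obj <- function(par) sum((y_gv - gv_pred(par))^2, na.rm = TRUE)
  gv0 <- c(init$gv$e0, log(init$gv$emax_gv), log(init$gv$auc50), init$gv$lam)
  gv_opt <- stats::nlminb(gv0, gv_obj)
  # NLS covariance from numerical curvature of half the SSR
  se <- rep(NA_real_, 4)
  npar_obs <- sum(!is.na(y_gv))
  sig2 <- gv_opt$objective / max(npar_obs - 4, 1)
  Hn <- num_hessian(function(p) gv_obj(p) / 2, gv_opt$par)
  cov <- tryCatch(solve(Hn) * sig2, error = function(e) NULL)
  if (!is.null(cov) && all(diag(cov) > 0)) se <- sqrt(diag(cov))
  # delta method back to natural scale for the logged parameters
  est_gv <- c(e0 = gv_opt$par[1], emax_gv = exp(gv_opt$par[2]),
              auc50 = exp(gv_opt$par[3]), lam = gv_opt$par[4])
  se_gv <- c(se[1], se[2] * est_gv[2], se[3] * est_gv[3], se[4])
  names(se_gv) <- names(est_gv)

  est <- c(smax = smax_hat, sc50 = sc50_hat, est_gv)
  if (igf1_baseline == "pooled") est <- c(r0_pop = r0_hat, est)
  structure(list(estimates = est, se = se_gv,
                 objective = c(igf1 = igf_opt$objective, gv = gv_opt$objective),
                 convergence = igf_opt$convergence == 0 && gv_opt$convergence == 0,
                 etas = etas, excluded = excluded,
                 method = "sequential-IPP"),
            class = "pegsim_fit")
}

num_hessian <- function(fn, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  f0 <- fn(x)
  for (i in 1:p) for (j in i:p) {
    xi <- x; xi[i] <- xi[i] + h
    xj <- x; xj[j] <- xj[j] + h
    xij <- xi; xij[j] <- xij[j] + h
    H[i, j] <- H[j, i] <- (fn(xij) - fn(xi) - fn(xj) + f0) / h^2
  }
  H
}

#' Parameter-recovery report
#'
#' @param truth Named vector (or coercible list) of true parameter values.
#' @param fit A `pegsim_fit` (or named vector of estimates).
#' @return Data.frame with `parameter`, `true`, `estimate`, `bias_pct`
#'   (`100 * (est - true) / true`) and `abs_err`.
#' @export
recovery_report <- function(truth, fit) {
  est <- if (inherits(fit, "pegsim_fit")) fit$estimates else fit
  truth <- unlist(truth)
  common <- intersect(names(truth), names(est))
  if (length(common) == 0) stop("no matching parameter names")
  data.frame(parameter = common, true = unname(truth[common]),
             estimate = unname(est[common]),
             bias_pct = unname(100 * (est[common] - truth[common]) / truth[common]),
             abs_err = unname(abs(est[common] - truth[common])))
}
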