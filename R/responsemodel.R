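# Response model: dive metric ~ linear foraging-success effect (dDR) +
# penalized smooth of drift rate (buoyancy) + per-seal random intercept and
# dDR slope, with continuous-time AR1 residuals within seal. Fitted by REML
# through the mixed-model representation of penalized splines, so one REML
# criterion governs the smoothing parameter, the random-effect variances and
# the AR1 parameter.

#' Build the model design for a dive-metric response model
#'
#' Fixed effects: intercept, the foraging-success proxy `ddr` (linear, to
#' keep coefficients comparable across strata) and the linear part of the
#' drift-rate smooth. The smooth of drift rate is a penalized cubic B-spline
#' basis (default rank 10, second-difference penalty) in its Demmler-Reinsch
#' mixed-model form: the penalty range space becomes 8 i.i.d. random-effect
#' columns, the null space (constant + linear) is absorbed by the intercept
#' and the linear `dr` column, and the basis columns are centered
#' (sum-to-zero identifiability). Random effects: per-seal intercept and
#' `ddr` slope with an estimated correlation. The AR1 kernel runs on `mid_day`
#' (days since departure).
#'
#' @param records Window-record tibble from [window_aggregate()] (needs
#'   `seal_id`, `mid_day`, `ddr`, `dr_window` and the response column); rows
#'   with missing `ddr` are dropped.
#' @param metric Response column name: one of `"descent_rate"`,
#'   `"ascent_rate"`, `"dive_residual"`, `"surface_residual"` (any numeric
#'   column works).
#' @param basis_dim Spline basis rank (default 10).
#' @param include_smooth Include the drift-rate smooth (default TRUE).
#' @param random_effects Include per-seal random intercept + slope (default
#'   TRUE).
#' @param meta Optional named list (e.g. sex/habitat/window labels) carried
#'   into the fit for reporting.
#' @return A `pamm_design` list (design matrices, indexing, metadata).
#' @export
build_design <- function(records, metric, basis_dim = 10,
                         include_smooth = TRUE, random_effects = TRUE,
                         meta = list()) {
  assert_cols(records, c("seal_id", "mid_day", "ddr", "dr_window", metric))
  df <- records[stats::complete.cases(records[c("seal_id", "mid_day", "ddr",
                                                "dr_window", metric)]), ]
  df <- dplyr::arrange(df, .data$seal_id, .data$mid_day)
  n <- nrow(df)
  if (n < 10) abort("too few complete records to build a design")
  seal <- factor(df$seal_id)
  m <- nlevels(seal)
  if (random_effects && m < 2) abort("random effects need at least 2 seals")
  if (random_effects && m < 10) {
    inform(sprintf("build_design: only %d seals; random-effect estimates are unstable below ~10", m))
  }

  y <- df[[metric]]
  ddr <- df$ddr
  dr <- df$dr_window

  X <- cbind(`(Intercept)` = 1, ddr = ddr)
  smooth <- NULL
  if (include_smooth) {
    if (sd(dr) < 1e-8) {
      abort("drift-rate covariate is (nearly) constant; the smooth is degenerate")
    }
    bs <- pspline_mm(dr, basis_dim)
    X <- cbind(X, dr = dr - mean(dr))
    smooth <- bs
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("rank-deficient fixed-effect design; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }

  # known averaging weights for the white-noise (nugget) component: a window
  # mean of k dives has white variance proportional to 1/k
  nugget_w <- if ("n_dives" %in% names(df)) {
    w0 <- 1 / pmax(df$n_dives, 1)
    w0 / mean(w0)
  } else {
    rep(1, n)
  }

  structure(list(
    y = y, X = X, smooth = smooth,
    Xs = if (include_smooth) smooth$Z else NULL,
    nugget_w = nugget_w,
    seal = seal, ddr = ddr, dr = dr, t_day = df$mid_day,
    random_effects = random_effects,
    include_smooth = include_smooth,
    n = n, n_seals = m,
    metric = metric, meta = meta,
    records = df
  ), class = "pamm_design")
}

# P-spline in mixed-model (Demmler-Reinsch) form: equally spaced cubic
# B-splines, second-difference penalty; returns the centered random-part
# basis Z (n x (nb - 2)) and an evaluator for new covariate values.
pspline_mm <- function(x, nb) {
  rng <- range(x)
  nseg <- nb - 3
  h <- diff(rng) / nseg
  knots <- seq(rng[1] - 3 * h, rng[2] + 3 * h, by = h)
  B <- splines::splineDesign(knots, x, ord = 4, outer.ok = TRUE)
  S <- crossprod(diff(diag(nb), differences = 2))
  eg <- eigen(S, symmetric = TRUE)
  pos <- seq_len(nb - 2)
  U <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  Tm <- U %*% diag(1 / sqrt(lam))
  Z <- B %*% Tm
  cm <- colMeans(Z)
  list(
    Z = sweep(Z, 2, cm),
    knots = knots, transform = Tm, center = cm, nb = nb, x_mean = mean(x),
    rng = rng
  )
}

pspline_eval <- function(smooth, x) {
  B <- splines::splineDesign(smooth$knots, x, ord = 4, outer.ok = TRUE)
  sweep(B %*% smooth$transform, 2, smooth$center)
}

# ---- REML machinery ---------------------------------------------------------

# AR1 whitening weights: r_i = phi^dt within seal (0 at each seal's first
# row); returns r and the whitening scale 1/sqrt(1 - r^2).
ar1_weights <- function(seal, t_day, phi) {
  n <- length(t_day)
  r <- numeric(n)
  if (phi > 0 && n > 1) {
    same <- c(FALSE, seal[-1] == seal[-n])
    dt <- c(0, pmax(diff(t_day), 1e-8))
    r[same] <- phi^dt[same]
  }
  list(r = r, scale = 1 / sqrt(1 - r^2), logdet = sum(log(1 - r^2)))
}

whiten_ar1 <- function(M, w) {
  M <- as.matrix(M)
  lag <- rbind(0, M[-nrow(M), , drop = FALSE])
  (M - w$r * lag) * w$scale
}

# Random-effect design columns and the Cholesky of their relative covariance
# D (variances relative to sigma^2).
pamm_random <- function(design, lam_s, lam0, lam1, rho) {
  U <- NULL; Ld_blocks <- list()
  if (design$include_smooth) {
    U <- design$Xs
    Ld_blocks$smooth <- sqrt(lam_s) * diag(ncol(design$Xs))
  }
  if (design$random_effects) {
    seal <- design$seal
    m <- nlevels(seal)
    n <- design$n
    Zre <- matrix(0, n, 2 * m)
    ix <- as.integer(seal)
    Zre[cbind(seq_len(n), 2 * ix - 1L)] <- 1
    Zre[cbind(seq_len(n), 2 * ix)] <- design$ddr
    U <- if (is.null(U)) Zre else cbind(U, Zre)
    S2 <- matrix(c(lam0, rho * sqrt(lam0 * lam1),
                   rho * sqrt(lam0 * lam1), lam1), 2, 2)
    L2 <- tryCatch(t(chol(S2 + diag(1e-12, 2))), error = function(e) {
      d <- sqrt(diag(S2)); matrix(c(d[1], 0, 0, d[2]), 2, 2)
    })
    Ld_blocks$re <- L2
  }
  list(U = U, Ld_blocks = Ld_blocks)
}

apply_Ld <- function(A, design, Ld_blocks) {
  # design transform A = U %*% Ld; columns ordered smooth block then
  # per-seal (intercept, slope) pairs
  off <- 0
  if (!is.null(Ld_blocks$smooth)) {
    k <- ncol(Ld_blocks$smooth)
    A[, seq_len(k)] <- A[, seq_len(k), drop = FALSE] %*% Ld_blocks$smooth
    off <- k
  }
  if (!is.null(Ld_blocks$re)) {
    m <- nlevels(design$seal)
    L2 <- Ld_blocks$re  # lower Cholesky, L2 %*% t(L2) == Sigma_re / sigma^2
    for (j in seq_len(m)) {
      cols <- off + c(2 * j - 1, 2 * j)
      A[, cols] <- A[, cols, drop = FALSE] %*% L2
    }
  }
  A
}

# coefficient back-transform c = Ld %*% b_std (same block structure)
Ld_mult <- function(b, design, Ld_blocks) {
  out <- b
  off <- 0
  if (!is.null(Ld_blocks$smooth)) {
    k <- ncol(Ld_blocks$smooth)
    out[seq_len(k)] <- drop(Ld_blocks$smooth %*% b[seq_len(k)])
    off <- k
  }
  if (!is.null(Ld_blocks$re)) {
    m <- nlevels(design$seal)
    L2 <- Ld_blocks$re
    for (j in seq_len(m)) {
      ix <- off + c(2 * j - 1, 2 * j)
      out[ix] <- drop(L2 %*% b[ix])
    }
  }
  out
}

# Profiled REML criterion and fitted quantities for one variance-parameter
# setting. `lam_n` is the white-noise nugget variance relative to the AR1
# residual variance: V = sigma2 (R_ar1 + lam_n I + U D U'). After AR1
# whitening the nugget becomes a tridiagonal perturbation, handled by a
# banded factorisation. Returns -2 * restricted log-likelihood (up to a
# constant) plus the ingredients needed at the optimum.
pamm_eval <- function(design, lam_s, lam0, lam1, rho, phi, lam_n = 0,
                      keep = FALSE) {
  n <- design$n
  w <- ar1_weights(as.integer(design$seal), design$t_day, phi)
  yw <- whiten_ar1(design$y, w)
  Xw <- whiten_ar1(design$X, w)
  p <- ncol(Xw)

  if (lam_n > 0) {
    s <- w$scale; r <- w$r
    g <- design$nugget_w %||% rep(1, n)
    glag <- c(1, g[-n])
    dvec <- 1 + lam_n * s^2 * (g + r^2 * glag)
    evec <- if (n > 1) (-lam_n * r * s * c(1, s[-n]) * glag)[-1] else numeric(0)
    fac <- .tridiag_factor_cpp(dvec, evec)
    if (any(fac$d <= 0)) return(list(obj = 1e12))
    v0solve <- function(z) .tridiag_solve_cpp(fac$l, fac$d, as.matrix(z))
    logdetV0 <- sum(log(fac$d))
  } else {
    v0solve <- function(z) as.matrix(z)
    logdetV0 <- 0
  }

  rnd <- pamm_random(design, lam_s, lam0, lam1, rho)
  if (!is.null(rnd$U)) {
    A <- whiten_ar1(rnd$U, w)
    A <- apply_Ld(A, design, rnd$Ld_blocks)
    q <- ncol(A)
    V0iA <- v0solve(A)
    M <- diag(q) + crossprod(A, V0iA)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(list(obj = 1e12))
    logdetM <- 2 * sum(log(diag(cM)))
    vinv <- function(z) {
      z0 <- v0solve(z)
      z0 - V0iA %*% backsolve(cM, forwardsolve(t(cM), crossprod(A, z0)))
    }
  } else {
    A <- NULL
    logdetM <- 0
    vinv <- v0solve
  }

  ViX <- vinv(Xw)
  Viy <- vinv(yw)
  XtViX <- crossprod(Xw, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(list(obj = 1e12))
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(Xw, Viy)))
  r <- yw - Xw %*% beta
  quad <- drop(crossprod(r, vinv(r)))
  if (quad <= 0) return(list(obj = 1e12))
  sigma2 <- quad / (n - p)
  # profiled REML deviance (up to a constant): (n-p) log sigma2
  # + log|V0 + A A'| + log|R_ar1| + log|X' V*^-1 X|
  obj <- (n - p) * log(sigma2) + logdetV0 + logdetM + w$logdet +
    2 * sum(log(diag(cX)))
  out <- list(obj = obj, sigma2 = sigma2, beta = drop(beta))
  if (keep) {
    bstd <- if (!is.null(A)) drop(crossprod(A, vinv(r))) else numeric(0)
    out$coef_random <- if (!is.null(A)) {
      Ld_mult(bstd, design, rnd$Ld_blocks)
    } else numeric(0)
    out$XtViX_inv <- chol2inv(cX)
    out$w <- w
    out$rnd <- rnd
    out$A <- A
    out$Xw <- Xw
    out$yw <- yw
  }
  out
}

#' Fit the penalized additive mixed model by REML
#'
#' Estimates the smoothing parameter, the per-seal random-effect variances
#' (intercept, dDR slope, their correlation), the continuous-time AR1
#' parameter `phi` (correlation per unit day; within-seal residual
#' correlation is `phi^dt` for a gap of `dt` days) and the residual variance
#' by profiled REML, with quasi-Newton optimisation on transformed
#' parameters. The foraging-success coefficient `beta1` is reported with its
#' standard error from the penalized mixed-model information matrix and a
#' Wald p-value.
#'
#' When the design has no smooth and no random effects and `phi` is fixed at
#' zero there is nothing to optimise and the fit reduces exactly to ordinary
#' least squares.
#'
#' @param design A `pamm_design` from [build_design()].
#' @param phi `NULL` to estimate the AR1 parameter, or a fixed value in
#'   `[0, 1)`.
#' @param nugget Include an estimated white-noise (nugget) variance alongside
#'   the AR1 residual process; defaults to `TRUE` when `phi` is estimated.
#'   With a fixed `phi` the nugget defaults off (at `phi = 0` it is not
#'   identifiable, and the no-smooth no-random-effect fit then reduces
#'   exactly to ordinary least squares).
#' @return A `pamm_fit` object; see [tidy.pamm_fit()], [glance.pamm_fit()],
#'   [autoplot.pamm_fit()], [smooth_estimate()].
#' @export
fit_pamm <- function(design, phi = NULL, nugget = is.null(phi)) {
  stopifnot(inherits(design, "pamm_design"))
  estimate_phi <- is.null(phi)
  phi_fixed <- if (estimate_phi) NA_real_ else phi
  if (!estimate_phi && (phi < 0 || phi >= 1)) abort("fixed `phi` must be in [0, 1)")

  # active transformed parameters
  par_names <- c(
    if (design$include_smooth) "log_lam_s",
    if (design$random_effects) c("log_lam0", "log_lam1", "atanh_rho"),
    if (estimate_phi) "logit_phi",
    if (nugget) "log_lam_n"
  )

  unpack <- function(par) {
    names(par) <- par_names
    list(
      lam_s = if (design$include_smooth) exp(par[["log_lam_s"]]) else 0,
      lam0 = if (design$random_effects) exp(par[["log_lam0"]]) else 0,
      lam1 = if (design$random_effects) exp(par[["log_lam1"]]) else 0,
      rho = if (design$random_effects) tanh(par[["atanh_rho"]]) else 0,
      phi = if (estimate_phi) stats::plogis(par[["logit_phi"]]) else phi_fixed,
      lam_n = if (nugget) exp(par[["log_lam_n"]]) else 0
    )
  }

  trace_first <- NULL
  objfun <- function(par) {
    th <- unpack(par)
    v <- pamm_eval(design, th$lam_s, th$lam0, th$lam1, th$rho, th$phi,
                   th$lam_n)$obj
    if (is.null(trace_first)) trace_first <<- v
    if (!is.finite(v)) 1e12 else v
  }

  if (length(par_names) == 0) {
    opt <- list(par = numeric(0), objective = pamm_eval(design, 0, 0, 0, 0,
                                                        phi_fixed)$obj,
                convergence = 0L, iterations = 0L, message = "closed form")
  } else {
    # heuristics: start random-effect variances at modest fractions of the
    # response variance relative to residual scale
    start <- c(
      if (design$include_smooth) 0,
      if (design$random_effects) c(log(0.5), log(0.5), 0),
      if (estimate_phi) stats::qlogis(0.3),
      if (nugget) 0
    )
    opt <- nlminb(start, objfun,
                  control = list(rel.tol = 1e-9, eval.max = 500, iter.max = 250))
    if (!is.finite(opt$objective)) {
      abort("REML optimisation failed (non-finite objective); see design for data issues")
    }
  }
  th <- unpack(opt$par)
  fit <- pamm_eval(design, th$lam_s, th$lam0, th$lam1, th$rho, th$phi,
                   th$lam_n, keep = TRUE)

  beta <- fit$beta
  names(beta) <- colnames(design$X)
  cov_beta <- fit$sigma2 * fit$XtViX_inv
  rownames(cov_beta) <- colnames(cov_beta) <- colnames(design$X)

  se <- sqrt(diag(cov_beta))
  z <- beta / se
  # reference distribution: with a per-seal random slope the dDR coefficient
  # is effectively a mean of seal-level slopes, so use t with n_seals - 1
  # degrees of freedom; without random effects, the residual df
  df_inference <- if (design$random_effects) design$n_seals - 1L else
    design$n - ncol(design$X)
  pvals <- 2 * stats::pt(-abs(z), df = df_inference)

  # fitted values (conditional on BLUPs), original scale
  fitted <- drop(design$X %*% beta)
  nsmooth <- if (design$include_smooth) ncol(design$Xs) else 0
  coef_smooth <- if (nsmooth > 0) fit$coef_random[seq_len(nsmooth)] else numeric(0)
  coef_re <- if (design$random_effects) {
    fit$coef_random[(nsmooth + 1):length(fit$coef_random)]
  } else numeric(0)
  if (nsmooth > 0) fitted <- fitted + drop(design$Xs %*% coef_smooth)
  if (design$random_effects) {
    ix <- as.integer(design$seal)
    fitted <- fitted + coef_re[2 * ix - 1] + coef_re[2 * ix] * design$ddr
  }
  r2 <- suppressWarnings(cor(fitted, design$y)^2)

  structure(list(
    design = design,
    beta = beta, se = se, p_value = pvals, cov_beta = cov_beta,
    beta1 = unname(beta["ddr"]), beta1_se = unname(se["ddr"]),
    beta1_p = unname(pvals["ddr"]), df = df_inference,
    significance = signif_flag(unname(pvals["ddr"])),
    sigma2 = fit$sigma2,
    var_intercept = fit$sigma2 * th$lam0,
    var_slope = fit$sigma2 * th$lam1,
    cor_re = th$rho,
    var_smooth = fit$sigma2 * th$lam_s,
    var_nugget = fit$sigma2 * th$lam_n, nugget = nugget,
    phi = th$phi, phi_estimated = estimate_phi,
    coef_smooth = coef_smooth, coef_re = coef_re,
    fitted = fitted, residuals = design$y - fitted,
    r2_fitted_obs = r2,
    reml = -0.5 * opt$objective,
    objective_start = trace_first, objective_final = opt$objective,
    convergence = opt$convergence, iterations = opt$iterations %||% NA_integer_,
    message = opt$message %||% "",
    n = design$n, n_seals = design$n_seals,
    metric = design$metric, meta = design$meta
  ), class = "pamm_fit")
}

signif_flag <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.05) "sig" else if (p < 0.10) "~" else "ns"
}

#' @export
print.pamm_fit <- function(x, ...) {
  cat(sprintf("<pamm_fit> %s, n = %d (%d seals)\n", x$metric, x$n, x$n_seals))
  cat(sprintf("  dDR effect: %.4g (SE %.3g, p = %.3g) [%s]\n",
              x$beta1, x$beta1_se, x$beta1_p, x$significance))
  cat(sprintf("  phi = %.3f/day, nugget var = %.3g, var(int) = %.3g, var(slope) = %.3g, rho = %.2f\n",
              x$phi, x$var_nugget, x$var_intercept, x$var_slope, x$cor_re))
  cat(sprintf("  sigma2 = %.4g, R2(fitted, obs) = %.3f, REML = %.2f\n",
              x$sigma2, x$r2_fitted_obs, x$reml))
  invisible(x)
}

#' Evaluate the fitted drift-rate smooth with pointwise intervals
#'
#' Returns the estimated smooth buoyancy effect (centered, i.e. the linear
#' drift-rate fixed effect plus the penalized deviation) on a grid, with
#' approximate 95% pointwise intervals from the conditional covariance of the
#' penalized system.
#'
#' @param fit A `pamm_fit` with a smooth.
#' @param at Optional drift-rate values (default: 100-point grid over the
#'   observed range).
#' @return Tibble `dr, estimate, lower, upper`.
#' @export
smooth_estimate <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "pamm_fit"))
  design <- fit$design
  if (!design$include_smooth) abort("fit has no smooth term")
  if (is.null(at)) at <- seq(min(design$dr), max(design$dr), length.out = 100)
  Znew <- pspline_eval(design$smooth, at)
  xc <- at - mean(design$dr)
  est <- xc * fit$beta[["dr"]] + drop(Znew %*% fit$coef_smooth)

  # conditional covariance of (beta, b) from the whitened penalized system
  th_w <- ar1_weights(as.integer(design$seal), design$t_day, fit$phi)
  Xw <- whiten_ar1(design$X, th_w)
  rnd <- pamm_random(design,
                     lam_s = fit$var_smooth / fit$sigma2,
                     lam0 = fit$var_intercept / fit$sigma2,
                     lam1 = fit$var_slope / fit$sigma2,
                     rho = fit$cor_re)
  A <- apply_Ld(whiten_ar1(rnd$U, th_w), design, rnd$Ld_blocks)
  C <- cbind(Xw, A)
  lam_n <- fit$var_nugget / fit$sigma2
  CtV0iC <- if (lam_n > 0) {
    s <- th_w$scale; r <- th_w$r; n <- nrow(C)
    g <- design$nugget_w %||% rep(1, n)
    glag <- c(1, g[-n])
    dvec <- 1 + lam_n * s^2 * (g + r^2 * glag)
    evec <- if (n > 1) (-lam_n * r * s * c(1, s[-n]) * glag)[-1] else numeric(0)
    fac <- .tridiag_factor_cpp(dvec, evec)
    crossprod(C, .tridiag_solve_cpp(fac$l, fac$d, C))
  } else {
    crossprod(C)
  }
  pen <- diag(c(rep(0, ncol(Xw)), rep(1, ncol(A))))
  H <- CtV0iC + pen
  Hinv <- chol2inv(chol(H + diag(1e-10, ncol(H))))
  # map: estimate = [0, 0(ddr), xc, Znew %*% Ld_s, 0...] on (beta, b_std)
  nsm <- ncol(design$Xs)
  Ld_s <- rnd$Ld_blocks$smooth
  G <- cbind(0, 0, xc, Znew %*% Ld_s,
             matrix(0, length(at), ncol(A) - nsm))
  vr <- fit$sigma2 * rowSums((G %*% Hinv) * G)
  tibble::tibble(dr = at, estimate = est,
                 lower = est - 1.96 * sqrt(pmax(vr, 0)),
                 upper = est + 1.96 * sqrt(pmax(vr, 0)))
}

#' @export
tidy.pamm_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se),
    statistic = unname(x$beta / x$se),
    p.value = unname(x$p_value)
  )
}

#' @export
glance.pamm_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, n_seals = x$n_seals,
    beta1 = x$beta1, beta1_se = x$beta1_se, beta1_p = x$beta1_p,
    significance = x$significance,
    phi = x$phi, sigma2 = x$sigma2,
    var_intercept = x$var_intercept, var_slope = x$var_slope,
    cor_re = x$cor_re, var_smooth = x$var_smooth, var_nugget = x$var_nugget,
    r2_fitted_obs = x$r2_fitted_obs, reml = x$reml,
    convergence = x$convergence
  )
}
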