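#' @useDynLib mnlfaAnchor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- data validation ---------------------------------------------------

.validate_data <- function(y, X, require_full_categories = FALSE) {
  y <- as.matrix(y)
  X <- as.matrix(X)
  if (any(is.na(y)) || any(is.na(X)))
    stop("missing values are not supported")
  if (!all(y == round(y)))
    stop("responses must be integer category codes")
  if (nrow(y) != nrow(X))
    stop("responses and covariates have different numbers of rows (",
         nrow(y), " vs ", nrow(X), ")")
  if (nrow(y) < 1 || ncol(y) < 2)
    stop("need n >= 1 persons and J >= 2 items")
  if (min(y) < 0) stop("category codes must start at 0")
  m <- max(y) + 1L
  nobs <- apply(y, 2, function(col) length(unique(col)))
  if (any(nobs < 2))
    stop("item(s) ", paste(which(nobs < 2), collapse = ", "),
         " have fewer than 2 observed categories")
  if (require_full_categories) {
    miss <- apply(y, 2, function(col) length(setdiff(0:(m - 1L), col)) > 0)
    if (any(miss))
      stop("empty response categories for item(s) ",
           paste(which(miss), collapse = ", "))
  }
  storage.mode(y) <- "integer"
  storage.mode(X) <- "double"
  list(y = y, X = X, m = m)
}

# ---- marginal likelihood ----------------------------------------------

#' Marginal log-likelihood of the moderated graded response model
#'
#' Integrates each person's response-pattern probability over the latent
#' trait with a standard-normal quadrature rule, after the per-person
#' location-scale change of variable `eta = mu_i + sigma_i * u` implied by
#' the impact model (the latent mean and variance vary with covariates, so
#' the rule is re-centred per person).
#'
#' @param y n x J integer matrix of category codes `0..m-1`.
#' @param X n x p covariate matrix.
#' @param params an [mnlfa_params()] object.
#' @param quad quadrature rule from [gauss_hermite_normal()].
#' @param adaptive recentre the rule per person at the posterior mode with a
#'   curvature-matched scale (density-ratio corrected). The default; the
#'   prior-located rule (`FALSE`) needs a much larger `K` for steep items.
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(y, X, params, quad = gauss_hermite_normal(21),
                            adaptive = TRUE) {
  d <- .validate_data(y, X)
  if (ncol(params$tau0) != d$m - 1L)
    stop("parameter set has ", ncol(params$tau0) + 1L,
         " categories but data have ", d$m)
  if (ncol(params$B) != ncol(d$X))
    stop("parameter set has ", ncol(params$B), " covariates but data have ",
         ncol(d$X))
  .mnlfa_ll_cpp(d$y, d$X, params$tau0, params$lambda0, params$B,
                params$Gamma, params$Omega, params$Kappa,
                quad$nodes, quad$weights, FALSE, adaptive)$loglik
}

# ---- packing between parameter objects and optimizer vectors -----------
#
# Optimizer scale per item: first threshold free, positive log-gaps for the
# remaining thresholds (guarantees strict ordering during optimization),
# loading unconstrained but box-bounded away from zero. DIF and impact
# coefficients enter untransformed. "Natural" scale keeps raw thresholds and
# is used for the observed-information standard errors.

.pack <- function(params, spec, natural = FALSE) {
  mm1 <- ncol(params$tau0)
  J <- nrow(params$tau0)
  item <- unlist(lapply(seq_len(J), function(j) {
    tj <- params$tau0[j, ]
    th <- if (natural || mm1 == 1L) tj else c(tj[1], log(diff(tj)))
    c(th, params$lambda0[j])
  }))
  c(item,
    params$B[spec$free_uniform],
    params$Gamma[spec$free_nonuniform],
    params$Omega[spec$impact_mean],
    params$Kappa[spec$impact_var])
}

.unpack <- function(theta, spec, J, mm1, p, natural = FALSE) {
  nb <- J * (mm1 + 1L)
  ih <- matrix(theta[seq_len(nb)], nrow = mm1 + 1L)
  tauraw <- t(ih[seq_len(mm1), , drop = FALSE])
  tau0 <- if (natural || mm1 == 1L) tauraw else
    t(apply(tauraw, 1, function(r) cumsum(c(r[1], exp(r[-1])))))
  lambda0 <- ih[mm1 + 1L, ]
  B <- matrix(0, J, p); Gamma <- matrix(0, J, p)
  Omega <- numeric(p); Kappa <- numeric(p)
  i <- nb
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  B[spec$free_uniform] <- take(sum(spec$free_uniform))
  Gamma[spec$free_nonuniform] <- take(sum(spec$free_nonuniform))
  Omega[spec$impact_mean] <- take(sum(spec$impact_mean))
  Kappa[spec$impact_var] <- take(sum(spec$impact_var))
  new_mnlfa_params(tau0, lambda0, B, Gamma, Omega, Kappa)
}

# map the full analytic gradient onto the packed vector
.pack_grad <- function(gr, spec, theta, J, mm1, natural = FALSE) {
  item <- unlist(lapply(seq_len(J), function(j) {
    gt <- gr$g_tau[j, ]
    th <- if (natural || mm1 == 1L) gt else {
      # d tau_c / d t1 = 1 for all c; d tau_c / d d_k = exp(d_k) for c >= k
      tails <- rev(cumsum(rev(gt)))
      d <- theta[(j - 1L) * (mm1 + 1L) + 2:mm1]
      c(tails[1], exp(d) * tails[-1])
    }
    c(th, gr$g_lambda[j])
  }))
  c(item,
    gr$g_B[spec$free_uniform],
    gr$g_Gamma[spec$free_nonuniform],
    gr$g_Omega[spec$impact_mean],
    gr$g_Kappa[spec$impact_var])
}

.param_labels <- function(spec, mm1, item_names = NULL, cov_names = NULL) {
  J <- nrow(spec$free_uniform); p <- ncol(spec$free_uniform)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(J))
  if (is.null(cov_names)) cov_names <- paste0("x", seq_len(p))
  item <- unlist(lapply(seq_len(J), function(j)
    c(paste0("tau[", item_names[j], ",", seq_len(mm1), "]"),
      paste0("lambda[", item_names[j], "]"))))
  bg <- function(free, sym) {
    idx <- which(free)  # column-major, matches matrix logical subsetting
    if (!length(idx)) return(character(0))
    rc <- arrayInd(idx, dim(free))
    paste0(sym, "[", item_names[rc[, 1]], ",", cov_names[rc[, 2]], "]")
  }
  c(item, bg(spec$free_uniform, "beta"), bg(spec$free_nonuniform, "gamma"),
    paste0("omega[", cov_names[spec$impact_mean], "]"),
    paste0("kappa[", cov_names[spec$impact_var], "]"))
}

# ---- fitting -----------------------------------------------------------

#' Control settings for MNLFA fitting
#'
#' @param quad_points number of Gauss-Hermite nodes (default 21).
#' @param iter_max optimizer iteration budget.
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param gtol gradient tolerance for declaring convergence; the criterion
#'   is `max|grad| < gtol * max(1, |logLik|)` since the score scales with
#'   the log-likelihood magnitude.
#' @param z_threshold robust-Z flagging threshold for anchor screening.
#' @param alpha Wald significance level for final DIF flagging.
#' @param wic_grid ladder of WIC weights tried when BIC flags nothing.
#' @return a list of class `mnlfa_control`.
#' @export
mnlfa_control <- function(quad_points = 21, iter_max = 1000,
                          rel_tol = 1e-8, gtol = 1e-4,
                          z_threshold = 1.65, alpha = 0.05,
                          wic_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(quad_points >= 15, z_threshold > 0, alpha > 0, alpha < 1,
            all(wic_grid > 0), all(wic_grid < 1),
            !is.unsorted(wic_grid, strictly = TRUE))
  structure(list(quad_points = quad_points, iter_max = iter_max,
                 rel_tol = rel_tol, gtol = gtol, z_threshold = z_threshold,
                 alpha = alpha, wic_grid = wic_grid),
            class = "mnlfa_control")
}

.start_values <- function(y, X, m, spec) {
  J <- ncol(y); p <- ncol(X); mm1 <- m - 1L
  tau0 <- t(vapply(seq_len(J), function(j) {
    ph <- vapply(seq_len(mm1), function(c) mean(y[, j] >= c), 0)
    ph <- pmin(pmax(ph, 1e-3), 1 - 1e-3)
    # marginal cumulative logit, de-attenuated for a unit-normal trait with
    # loading ~2 (logistic-normal approximation)
    tj <- -1.55 * stats::qlogis(ph)
    tj[1] <- min(tj[1], 24)
    if (mm1 > 1) for (c in 2:mm1) tj[c] <- max(tj[c], tj[c - 1] + 0.1)
    tj
  }, numeric(mm1)))
  if (mm1 == 1L) tau0 <- matrix(tau0, ncol = 1L)
  new_mnlfa_params(tau0, rep(2, J), matrix(0, J, p), matrix(0, J, p),
                   numeric(p), numeric(p))
}

#' Fit a moderated graded response model by marginal maximum likelihood
#'
#' Maximizes the quadrature marginal likelihood over all baseline item
#' parameters plus the DIF and impact coefficients freed by `spec`, using a
#' quasi-Newton optimizer with analytic gradients. Thresholds are
#' reparameterized internally (first threshold plus positive log-gaps) so
#' ordering is preserved throughout; estimates are reported on the natural
#' scale. The baseline latent mean and log-variance are fixed at zero for
#' identification.
#'
#' @param y n x J integer response matrix, categories `0..m-1`.
#' @param X n x p covariate matrix (no missing values).
#' @param spec a [dif_spec()]; default frees no DIF and all impact terms.
#' @param start optional [mnlfa_params()] warm start (e.g. a previous fit's
#'   estimates); coefficients fixed by `spec` are ignored.
#' @param se compute standard errors from the observed information
#'   (numerically differentiated analytic gradient) at the optimum.
#' @param control an [mnlfa_control()] list.
#' @return object of class `mnlfa_fit`: `params`, `se` (same shapes as the
#'   parameter set, `NA` for fixed entries; only when `se = TRUE`),
#'   `loglik`, `k`, `n`, `converged`, `AIC`, `BIC`, and `diagnostics`.
#' @export
mnlfa_fit <- function(y, X, spec = NULL, start = NULL, se = FALSE,
                      control = mnlfa_control()) {
  d <- .validate_data(y, X, require_full_categories = TRUE)
  y <- d$y; X <- d$X; m <- d$m
  J <- ncol(y); p <- ncol(X); mm1 <- m - 1L; n <- nrow(y)
  if (is.null(spec)) spec <- dif_spec(J, p)
  quad <- gauss_hermite_normal(control$quad_points)

  if (is.null(start)) start <- .start_values(y, X, m, spec)
  theta0 <- .pack(start, spec, natural = FALSE)
  nfree <- length(theta0)

  evalg <- function(theta, gradient) {
    par <- .unpack(theta, spec, J, mm1, p)
    .mnlfa_ll_cpp(y, X, par$tau0, par$lambda0, par$B, par$Gamma,
                  par$Omega, par$Kappa, quad$nodes, quad$weights, gradient)
  }
  # L-BFGS-B evaluates fn and gr at the same point, so one likelihood pass
  # (which returns both) is cached and serves both callbacks
  cache <- new.env(parent = emptyenv())
  both <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta))
      return(cache$val)
    v <- evalg(theta, TRUE)
    cache$theta <- theta
    cache$val <- v
    v
  }
  fn <- function(theta) -both(theta)$loglik
  gr <- function(theta) -.pack_grad(both(theta), spec, theta, J, mm1)
  item_lo <- rep(c(-25, rep(-8, max(mm1 - 1L, 0)), 0.01), J)
  item_hi <- rep(c(25, rep(4, max(mm1 - 1L, 0)), 50), J)
  nrest <- nfree - length(item_lo)
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      lower = c(item_lo, rep(-10, nrest)),
                      upper = c(item_hi, rep(10, nrest)),
                      control = list(maxit = control$iter_max,
                                     factr = control$rel_tol /
                                       .Machine$double.eps,
                                     pgtol = 0, lmm = 15))
  theta <- opt$par
  v <- both(theta)
  ll <- v$loglik
  gmax <- max(abs(.pack_grad(v, spec, theta, J, mm1)))
  # convergence is judged by the score (scaled by |LL|, which sets the
  # score's magnitude) rather than the optimizer return code alone
  converged <- opt$convergence %in% c(0L, 52L) &&
    gmax < control$gtol * max(1, abs(ll))
  params <- .unpack(theta, spec, J, mm1, p)
  validate_mnlfa_params(params, warn_only = TRUE)

  k <- n_free_params(spec, m)
  fit <- structure(list(
    params = params, se = NULL, loglik = ll, k = k, n = n, m = m,
    spec = spec, converged = converged,
    AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n),
    labels = .param_labels(spec, mm1, colnames(y), colnames(X)),
    diagnostics = list(evaluations = opt$counts,
                       grad_max = gmax, optimizer_message = opt$message,
                       optimizer_code = opt$convergence,
                       nonpos_lambda = isTRUE(v$nonpos_lambda))),
    class = "mnlfa_fit")
  if (se) fit <- .add_se(fit, y, X, quad)
  fit
}

# observed information: numeric Jacobian (central differences) of the
# analytic score on the natural parameter scale
.add_se <- function(fit, y, X, quad) {
  spec <- fit$spec; params <- fit$params
  J <- nrow(params$tau0); mm1 <- ncol(params$tau0); p <- ncol(params$B)
  theta <- .pack(params, spec, natural = TRUE)
  score <- function(th) {
    par <- .unpack(th, spec, J, mm1, p, natural = TRUE)
    v <- .mnlfa_ll_cpp(y, X, par$tau0, par$lambda0, par$B, par$Gamma,
                       par$Omega, par$Kappa, quad$nodes, quad$weights, TRUE)
    .pack_grad(v, spec, th, J, mm1, natural = TRUE)
  }
  nf <- length(theta)
  H <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    h <- 1e-4 * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- theta[i] + h
    tm <- theta; tm[i] <- theta[i] - h
    H[, i] <- (score(tp) - score(tm)) / (2 * h)
  }
  info <- -(H + t(H)) / 2
  se_vec <- rep(NA_real_, nf)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov)) {
    warning("observed information is singular; standard errors unavailable")
  } else {
    dg <- diag(cov)
    if (any(dg <= 0))
      warning("observed information is not positive definite for some ",
              "parameters; their standard errors are reported as missing")
    se_vec[dg > 0] <- sqrt(dg[dg > 0])
  }
  names(se_vec) <- fit$labels
  # reshape into parameter-set geometry
  nb <- J * (mm1 + 1L)
  ih <- matrix(se_vec[seq_len(nb)], nrow = mm1 + 1L)
  seB <- matrix(NA_real_, J, p); seG <- matrix(NA_real_, J, p)
  seO <- rep(NA_real_, p); seK <- rep(NA_real_, p)
  i <- nb
  take <- function(k) { v <- se_vec[i + seq_len(k)]; i <<- i + k; v }
  seB[spec$free_uniform] <- take(sum(spec$free_uniform))
  seG[spec$free_nonuniform] <- take(sum(spec$free_nonuniform))
  seO[spec$impact_mean] <- take(sum(spec$impact_mean))
  seK[spec$impact_var] <- take(sum(spec$impact_var))
  fit$se <- list(tau0 = t(ih[seq_len(mm1), , drop = FALSE]),
                 lambda0 = ih[mm1 + 1L, ], B = seB, Gamma = seG,
                 Omega = seO, Kappa = seK, vector = se_vec)
  fit
}

#' @export
print.mnlfa_fit <- function(x, ...) {
  cat("MNLFA graded-response fit:", nrow(x$params$tau0), "items, n =", x$n,
      "\n  logLik =", format(x$loglik), " k =", x$k,
      " AIC =", format(x$AIC), " BIC =", format(x$BIC),
      "\n  converged:", x$converged,
      "(max|grad| =", format(x$diagnostics$grad_max, digits = 3), ")\n")
  invisible(x)
}

#' @export
logLik.mnlfa_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Information criteria for a fitted model
#'
#' `AIC = -2LL + 2k`, `BIC = -2LL + k log(N)`, and the weighted criterion
#' `WIC(lambda) = lambda * AIC + (1 - lambda) * BIC`, which interpolates
#' between BIC's conservatism (`lambda = 0`) and AIC's sensitivity
#' (`lambda = 1`).
#'
#' @param fit an `mnlfa_fit` (or any list with `loglik`, `k`, `n`).
#' @param criterion one of `"AIC"`, `"BIC"`, `"WIC"`.
#' @param lambda WIC weight in `[0, 1]`; required for `"WIC"`.
#' @return scalar criterion value.
#' @export
information_criterion <- function(fit, criterion = c("AIC", "BIC", "WIC"),
                                  lambda = NULL) {
  criterion <- match.arg(criterion)
  aic <- -2 * fit$loglik + 2 * fit$k
  bic <- -2 * fit$loglik + fit$k * log(fit$n)
  switch(criterion,
         AIC = aic,
         BIC = bic,
         WIC = {
           if (is.null(lambda) || length(lambda) != 1 || is.na(lambda) ||
               lambda < 0 || lambda > 1)
             stop("WIC weight lambda must be a single value in [0, 1]")
           lambda * aic + (1 - lambda) * bic
         })
}

#' Wald tests for every free DIF coefficient
#'
#' Two-sided normal-approximation tests `z = estimate / SE` for each freely
#' estimated uniform (`beta`) and non-uniform (`gamma`) DIF coefficient.
#'
#' @param fit an `mnlfa_fit` fitted with `se = TRUE`.
#' @return data frame with columns `item`, `covariate`, `type`
#'   (`"uniform"`/`"nonuniform"`), `estimate`, `se`, `z`, `p`.
#' @export
wald_tests <- function(fit) {
  if (is.null(fit$se))
    stop("fit was run without standard errors; refit with se = TRUE")
  spec <- fit$spec
  one <- function(free, est, sem, type) {
    idx <- which(free)
    if (!length(idx))
      return(data.frame(item = integer(0), covariate = integer(0),
                        type = character(0), estimate = numeric(0),
                        se = numeric(0), z = numeric(0), p = numeric(0)))
    rc <- arrayInd(idx, dim(free))
    e <- est[idx]; s <- sem[idx]
    z <- e / s
    data.frame(item = rc[, 1], covariate = rc[, 2], type = type,
               estimate = e, se = s, z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  out <- rbind(one(spec$free_uniform, fit$params$B, fit$se$B, "uniform"),
               one(spec$free_nonuniform, fit$params$Gamma, fit$se$Gamma,
                   "nonuniform"))
  if (any(is.na(out$p)) && nrow(out))
    warning("singular information: some p-values reported as missing")
  out[order(out$item, out$covariate, out$type), , drop = FALSE]
}
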