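#' Parameter set for a moderated graded response model
#'
#' Container for every parameter of the moderated nonlinear factor analysis
#' (MNLFA) graded response model: baseline thresholds and loadings, uniform
#' and non-uniform DIF coefficients, and impact coefficients on the
#' latent-trait mean and log-variance. The baseline latent mean and
#' log-variance are fixed at zero for identification and are not stored.
#'
#' The moderated model for item \eqn{j}, person \eqn{i} with covariates
#' \eqn{x_i} is
#' \deqn{logit P(y_{ij} \ge c \mid \eta_i) = \lambda_j(x_i)\,\eta_i - \tau_{jc}(x_i)}
#' with \eqn{\tau_{jc}(x_i) = \tau_{jc0} + B_{j\cdot} x_i} (one uniform shift
#' per item applied to all thresholds), \eqn{\lambda_j(x_i) = \lambda_{j0} +
#' \Gamma_{j\cdot} x_i}, \eqn{E(\eta_i) = \Omega x_i} and
#' \eqn{V(\eta_i) = \exp(K x_i)}.
#'
#' @param tau0 J x (m-1) matrix of baseline thresholds; each row strictly
#'   increasing.
#' @param lambda0 length-J vector of baseline loadings, all positive.
#' @param B J x p matrix of uniform-DIF coefficients (logits).
#' @param Gamma J x p matrix of non-uniform-DIF coefficients.
#' @param Omega length-p impact coefficients on the latent mean.
#' @param Kappa length-p impact coefficients on the latent log-variance.
#' @return An object of class `mnlfa_params`.
#' @export
mnlfa_params <- function(tau0, lambda0, B = NULL, Gamma = NULL,
                         Omega = NULL, Kappa = NULL) {
  tau0 <- as.matrix(tau0)
  J <- nrow(tau0)
  if (is.null(B)) B <- matrix(0, J, 0)
  if (is.null(Gamma)) Gamma <- matrix(0, J, 0)
  p <- ncol(as.matrix(B))
  if (is.null(Omega)) Omega <- numeric(p)
  if (is.null(Kappa)) Kappa <- numeric(p)
  obj <- new_mnlfa_params(tau0, as.numeric(lambda0), as.matrix(B),
                          as.matrix(Gamma), as.numeric(Omega),
                          as.numeric(Kappa))
  validate_mnlfa_params(obj)
  obj
}

new_mnlfa_params <- function(tau0, lambda0, B, Gamma, Omega, Kappa) {
  structure(list(tau0 = tau0, lambda0 = lambda0, B = B, Gamma = Gamma,
                 Omega = Omega, Kappa = Kappa),
            class = "mnlfa_params")
}

validate_mnlfa_params <- function(x, warn_only = FALSE) {
  J <- nrow(x$tau0)
  p <- ncol(x$B)
  complain <- if (warn_only) warning else stop
  if (length(x$lambda0) != J || nrow(x$B) != J || nrow(x$Gamma) != J ||
      ncol(x$Gamma) != p || length(x$Omega) != p || length(x$Kappa) != p)
    stop("inconsistent parameter dimensions")
  if (ncol(x$tau0) >= 2 && any(apply(x$tau0, 1, function(r) any(diff(r) <= 0))))
    complain("thresholds must be strictly increasing within each item")
  if (any(x$lambda0 <= 0))
    complain("baseline loadings must be positive")
  invisible(x)
}

#' @export
print.mnlfa_params <- function(x, ...) {
  cat("MNLFA parameter set:", nrow(x$tau0), "items,",
      ncol(x$tau0) + 1, "categories,", ncol(x$B), "covariates\n")
  cat("  non-zero uniform DIF entries:   ", sum(x$B != 0), "\n")
  cat("  non-zero non-uniform DIF entries:", sum(x$Gamma != 0), "\n")
  invisible(x)
}

#' DIF specification: which effects are freely estimated
#'
#' Boolean map of which uniform/non-uniform DIF coefficients and which impact
#' coefficients are freely estimated; everything not freed is fixed at zero.
#' An item is an *anchor* under a specification iff its entire rows of
#' `free_uniform` and `free_nonuniform` are `FALSE`.
#'
#' @param J number of items.
#' @param p number of covariates.
#' @param dif_items items whose full rows of uniform and non-uniform DIF are
#'   freed (convenience shortcut; default none).
#' @param free_uniform,free_nonuniform optional J x p logical matrices
#'   overriding `dif_items`.
#' @param impact_mean,impact_var length-p logicals (recycled); default all
#'   `TRUE`.
#' @return An object of class `dif_spec`.
#' @export
dif_spec <- function(J, p, dif_items = integer(0),
                     free_uniform = NULL, free_nonuniform = NULL,
                     impact_mean = TRUE, impact_var = TRUE) {
  mk <- function(m) {
    if (is.null(m)) {
      m <- matrix(FALSE, J, p)
      m[dif_items, ] <- TRUE
    }
    m <- as.matrix(m)
    stopifnot(nrow(m) == J, ncol(m) == p, is.logical(m))
    m
  }
  structure(list(free_uniform = mk(free_uniform),
                 free_nonuniform = mk(free_nonuniform),
                 impact_mean = rep_len(as.logical(impact_mean), p),
                 impact_var = rep_len(as.logical(impact_var), p)),
            class = "dif_spec")
}

#' Anchor status implied by a DIF specification
#'
#' @param spec a [dif_spec()].
#' @return logical vector, `TRUE` for items with no free DIF coefficient.
#' @export
anchor_items <- function(spec) {
  !(rowSums(spec$free_uniform) + rowSums(spec$free_nonuniform) > 0)
}

# free a set of items' full DIF rows on top of an existing specification
free_items <- function(spec, items) {
  spec$free_uniform[items, ] <- TRUE
  spec$free_nonuniform[items, ] <- TRUE
  spec
}

#' Number of free parameters implied by a DIF specification
#'
#' Counts baseline item parameters (all thresholds and loadings are always
#' free), the freed DIF coefficients, and the freed impact coefficients.
#'
#' @param spec a [dif_spec()].
#' @param m number of response categories.
#' @return integer count `k` used by the information criteria.
#' @export
n_free_params <- function(spec, m) {
  J <- nrow(spec$free_uniform)
  J * (m - 1) + J + sum(spec$free_uniform) + sum(spec$free_nonuniform) +
    sum(spec$impact_mean) + sum(spec$impact_var)
}

#' Cumulative response probability of the graded response model
#'
#' Probability of responding in category `c` or higher:
#' `plogis(lambda * eta - tau)`.
#'
#' @param eta latent trait value(s).
#' @param lambda item loading.
#' @param tau threshold for the category boundary.
#' @return probability in (0, 1), vectorized over `eta`.
#' @export
cumulative_prob <- function(eta, lambda, tau) {
  stats::plogis(lambda * eta - tau)
}

#' Category probabilities of the graded response model
#'
#' Adjacent differences of the cumulative curve: for `m` categories coded
#' `0..m-1` with thresholds `tau[1..m-1]`, `P(y = 0) = 1 - P+(1)`,
#' `P(y = c) = P+(c) - P+(c+1)` and `P(y = m-1) = P+(m-1)`.
#'
#' @param eta latent trait value(s).
#' @param lambda item loading.
#' @param tau strictly increasing vector of m-1 thresholds.
#' @return if `eta` is scalar, a length-m probability vector; otherwise a
#'   `length(eta)` x m matrix with rows summing to one.
#' @export
category_probs <- function(eta, lambda, tau) {
  if (length(tau) >= 2 && any(diff(tau) <= 0))
    stop("invalid parameterization: thresholds must be strictly increasing")
  cp <- cbind(1, stats::plogis(outer(eta, tau, function(e, t) lambda * e - t)), 0)
  out <- cp[, -ncol(cp), drop = FALSE] - cp[, -1, drop = FALSE]
  if (length(eta) == 1L) drop(out) else out
}

#' Per-person moderated item parameters
#'
#' Applies the covariate moderation to one person's item parameters: every
#' threshold of item `j` is shifted by the uniform-DIF inner product
#' `B[j, ] %*% x` and the loading becomes `lambda0[j] + Gamma[j, ] %*% x`.
#'
#' @param params an [mnlfa_params()] object.
#' @param x covariate vector of length p.
#' @return list with `tau` (J x (m-1)) and `lambda` (length J). A warning is
#'   issued if any moderated loading is non-positive; the likelihood remains
#'   evaluable but fits flag this in their diagnostics.
#' @export
moderate_item <- function(params, x) {
  x <- as.numeric(x)
  shift <- drop(params$B %*% x)
  lambda <- params$lambda0 + drop(params$Gamma %*% x)
  if (any(lambda <= 0))
    warning("moderated loading is non-positive for item(s) ",
            paste(which(lambda <= 0), collapse = ", "))
  list(tau = params$tau0 + shift, lambda = lambda)
}

#' Per-person latent-trait moments
#'
#' Mean and variance of the latent trait implied by the impact model:
#' `mu = Omega . x` and `sigma2 = exp(Kappa . x)` (baseline mean and
#' log-variance fixed at zero).
#'
#' @param params an [mnlfa_params()] object.
#' @param x covariate vector of length p.
#' @return list with `mean` and `var` (always positive).
#' @export
latent_moments <- function(params, x) {
  x <- as.numeric(x)
  list(mean = sum(params$Omega * x), var = exp(sum(params$Kappa * x)))
}
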