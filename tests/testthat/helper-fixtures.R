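# Shared fixtures, generated in code and cached for the session so expensive
# fits run once. All seeds fixed.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fix[[name]])) .fix[[name]] <- make()
  .fix[[name]]
}

# small two_dif world: J = 10, 70% anchors (DIF items 1-3)
fix_world <- function() fixture("world", function() {
  gen_true_params(10, 0.7, "two_dif", seed = 7)
})

# N = 500 dataset from the small world
fix_data500 <- function() fixture("data500", function() {
  gp <- fix_world()
  X <- gen_covariates(500, seed = 11)
  y <- gen_responses(X, gp$params, seed = 12)
  list(y = y, X = X, gp = gp)
})

# null-spec baseline fit on the N = 500 dataset
fix_fit500 <- function() fixture("fit500", function() {
  d <- fix_data500()
  mnlfa_fit(d$y, d$X)
})

# tiny mild instance for likelihood-oracle comparisons: J = 5, moderate
# loadings, n = 50
fix_mild <- function() fixture("mild", function() {
  set.seed(42)
  J <- 5; p <- 2
  tau0 <- t(sapply(1:J, function(j) sort(rnorm(3, c(-1, 0, 1.2), 0.3))))
  # DIF coefficients only on items 1-2, matching the dif_spec used in the
  # gradient tests (unpacking zeroes whatever the spec does not free)
  B <- matrix(0, J, p); B[1:2, ] <- rnorm(2 * p, 0, 0.2)
  G <- matrix(0, J, p); G[1:2, ] <- rnorm(2 * p, 0, 0.1)
  params <- mnlfa_params(tau0, runif(J, 1, 2), B = B, Gamma = G,
                         Omega = c(0.2, -0.1), Kappa = c(0.1, -0.2))
  X <- cbind(rbinom(50, 1, 0.5), rnorm(50))
  y <- gen_responses(X, params, seed = 43)
  list(y = y, X = X, params = params)
})

# stratified Monte-Carlo oracle for the marginal log-likelihood: M draws per
# person from the person's latent normal via randomized quantile strata
# (Monte Carlo in expectation, with near-deterministic error << 1e-3)
mc_loglik <- function(y, X, params, M = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(y); J <- ncol(y)
  mm1 <- ncol(params$tau0)
  ll <- 0
  u_strata <- (seq_len(M) - 1) / M
  for (i in seq_len(n)) {
    mom <- latent_moments(params, X[i, ])
    mi <- moderate_item(params, X[i, ])
    eta <- mom$mean + sqrt(mom$var) *
      qnorm(u_strata + runif(M) / M)
    f <- rep(1, M)
    for (j in seq_len(J)) {
      cp <- cbind(1, plogis(outer(eta, mi$tau[j, ], function(e, t)
        mi$lambda[j] * e - t)), 0)
      pc <- cp[, y[i, j] + 1] - cp[, y[i, j] + 2]
      f <- f * pc
    }
    ll <- ll + log(mean(f))
  }
  ll
}
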