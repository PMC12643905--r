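# probability layer, moderation, marginal likelihood, fitting, criteria

test_that("cumulative_prob matches hand-computed logistic values", {
  expect_equal(cumulative_prob(0, 1, 0), 0.5)
  expect_equal(cumulative_prob(0.5, 2, 1), 0.5)
  expect_equal(cumulative_prob(0, 2, -1), plogis(1), tolerance = 1e-10)
  expect_equal(round(cumulative_prob(0, 2, -1), 5), 0.73106)
})

test_that("category_probs follows the adjacent-difference casework", {
  p <- category_probs(0, 2, c(-1, 0, 1))
  expect_equal(round(p, 5), c(0.26894, 0.23106, 0.23106, 0.26894))
  expect_equal(sum(p), 1)
  # binary case collapses to (1 - P+, P+)
  p2 <- category_probs(0.3, 1.5, 0.2)
  expect_equal(p2, c(1 - plogis(1.5 * 0.3 - 0.2), plogis(1.5 * 0.3 - 0.2)))
  # probability simplex over randomized parameter draws
  set.seed(1)
  for (r in 1:25) {
    tau <- sort(rnorm(3, c(-1, 0.5, 2)))
    pr <- category_probs(rnorm(7), runif(1, 0.5, 4), tau)
    expect_true(all(pr >= 0))
    expect_equal(rowSums(pr), rep(1, 7))
  }
  expect_error(category_probs(0, 2, c(1, 0, 2)), "increasing")
})

test_that("moderate_item applies uniform shifts and loading moderation", {
  gp <- fix_world()
  # x = 0 leaves the baseline untouched
  m0 <- moderate_item(gp$params, c(0, 0, 0))
  expect_equal(m0$tau, gp$params$tau0)
  expect_equal(m0$lambda, gp$params$lambda0)
  # a 0.5 uniform coefficient shifts every threshold of that item by 0.5
  pr <- mnlfa_params(gp$params$tau0, gp$params$lambda0,
                     B = matrix(c(0.5, rep(0, 29)), 10, 3),
                     Gamma = matrix(0, 10, 3))
  m1 <- moderate_item(pr, c(1, 0, 0))
  expect_equal(m1$tau[1, ], gp$params$tau0[1, ] + 0.5)
  expect_equal(m1$tau[-1, ], gp$params$tau0[-1, ])
  # loading moderation is the inner product Gamma[j, ] . x
  pg <- mnlfa_params(gp$params$tau0, gp$params$lambda0,
                     B = matrix(0, 10, 3),
                     Gamma = matrix(c(rep(0, 20), 0.3, rep(0, 9)), 10, 3))
  m2 <- moderate_item(pg, c(0, 0, 1.2))
  expect_equal(m2$lambda[1], gp$params$lambda0[1] + 0.36)
  # non-positive moderated loading warns but still evaluates
  expect_warning(moderate_item(pg, c(0, 0, -20)), "non-positive")
})

test_that("latent_moments implements the impact model", {
  gp <- fix_world()
  expect_equal(latent_moments(gp$params, c(0, 0, 0)), list(mean = 0, var = 1))
  pr <- mnlfa_params(gp$params$tau0, gp$params$lambda0,
                     B = matrix(0, 10, 3), Gamma = matrix(0, 10, 3),
                     Omega = c(-0.25, -0.10, 0.25), Kappa = c(0.1, 0.3, -0.3))
  expect_equal(latent_moments(pr, c(1, 1, 0))$mean, -0.35)
  expect_equal(latent_moments(pr, c(0, 0, 1))$var, exp(-0.3))
  expect_equal(round(latent_moments(pr, c(0, 0, 1))$var, 5), 0.74082)
})

test_that("marginal likelihood: flat items are quadrature-independent", {
  # loadings ~ 0 make the integrand constant in eta, so the log-likelihood
  # is the sum of threshold-only category log-probabilities for any K
  tau <- rbind(c(-1, 0, 1), c(-0.5, 0.5, 1.5))
  par <- mnlfa_params(tau, c(1e-9, 1e-9), B = matrix(0, 2, 0))
  y <- rbind(c(0L, 2L), c(1L, 3L), c(3L, 0L))
  X <- matrix(numeric(0), 3, 0)
  expected <- sum(log(category_probs(0, 0, tau[1, ])[y[, 1] + 1]),
                  log(category_probs(0, 0, tau[2, ])[y[, 2] + 1]))
  for (K in c(15, 21, 51))
    expect_equal(marginal_loglik(y, X, par, gauss_hermite_normal(K)),
                 expected, tolerance = 1e-8)
})

test_that("marginal likelihood matches a Monte-Carlo integration oracle", {
  m <- fix_mild()
  ll <- marginal_loglik(m$y, m$X, m$params)
  ll_mc <- mc_loglik(m$y, m$X, m$params, M = 1e5, seed = 5)
  expect_equal(ll, ll_mc, tolerance = 1e-3)
})

test_that("quadrature refinement leaves the adaptive likelihood unchanged", {
  m <- fix_mild()
  l21 <- marginal_loglik(m$y, m$X, m$params, gauss_hermite_normal(21))
  l41 <- marginal_loglik(m$y, m$X, m$params, gauss_hermite_normal(41))
  expect_lt(abs(l41 - l21), 1e-6)
})

test_that("analytic gradient matches numeric differentiation", {
  m <- fix_mild()
  sp <- dif_spec(5, 2, dif_items = 1:2)
  th <- mnlfaAnchor:::.pack(m$params, sp)
  check <- function(adaptive, tol) {
    q <- gauss_hermite_normal(21)
    fn <- function(t) {
      par <- mnlfaAnchor:::.unpack(t, sp, 5, 3, 2)
      mnlfaAnchor:::.mnlfa_ll_cpp(m$y, m$X, par$tau0, par$lambda0, par$B,
                                  par$Gamma, par$Omega, par$Kappa,
                                  q$nodes, q$weights, FALSE, adaptive)$loglik
    }
    v <- mnlfaAnchor:::.mnlfa_ll_cpp(m$y, m$X, m$params$tau0,
                                     m$params$lambda0, m$params$B,
                                     m$params$Gamma, m$params$Omega,
                                     m$params$Kappa, q$nodes, q$weights,
                                     TRUE, adaptive)
    ga <- mnlfaAnchor:::.pack_grad(v, sp, th, 5, 3)
    gn <- vapply(seq_along(th), function(i) {
      h <- 1e-5
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      (fn(tp) - fn(tm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga - gn)), tol)
  }
  # fixed rule: the analytic score is exact
  check(adaptive = FALSE, tol = 1e-4)
  # adaptive rule: the score treats the adaptation point as fixed, so it may
  # differ from the numeric gradient by the (small) adaptation sensitivity
  check(adaptive = TRUE, tol = 0.05)
})

test_that("fit errors on invalid data", {
  d <- fix_data500()
  expect_error(mnlfa_fit(d$y[1:100, ], d$X), "different numbers of rows")
  ym <- d$y; ym[1, 1] <- NA
  expect_error(mnlfa_fit(ym, d$X), "missing")
  yc <- d$y; yc[, 2] <- 1L
  expect_error(mnlfa_fit(yc, d$X), "fewer than 2 observed categories")
  ye <- d$y; ye[ye[, 3] == 3L, 3] <- 2L   # wipe out top category of item 3
  expect_error(mnlfa_fit(ye, d$X), "empty response categories")
})

test_that("nested specifications never decrease the fitted log-likelihood", {
  d <- fix_data500()
  f0 <- fix_fit500()
  f1 <- mnlfa_fit(d$y, d$X, dif_spec(10, 3, dif_items = 1),
                  start = f0$params)
  f2 <- mnlfa_fit(d$y, d$X, dif_spec(10, 3, dif_items = c(1, 3)),
                  start = f1$params)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  # k bookkeeping follows the specification
  expect_equal(f0$k, 10 * 3 + 10 + 6)
  expect_equal(f1$k, f0$k + 6)
  expect_equal(f2$k, f0$k + 12)
})

test_that("refitting from the optimum is a fixed point", {
  d <- fix_data500()
  f0 <- fix_fit500()
  f0b <- mnlfa_fit(d$y, d$X, start = f0$params)
  expect_equal(f0b$loglik, f0$loglik, tolerance = 1e-6)
})

test_that("information criteria follow the exact formulas", {
  fake <- list(loglik = -100, k = 5, n = 100)
  expect_equal(information_criterion(fake, "AIC"), 210)
  expect_equal(information_criterion(fake, "BIC"), 200 + 5 * log(100))
  expect_equal(round(information_criterion(fake, "BIC"), 4), 223.0259)
  expect_equal(round(information_criterion(fake, "WIC", lambda = 0.5), 4),
               216.5129)
  expect_equal(information_criterion(fake, "WIC", lambda = 0),
               information_criterion(fake, "BIC"))
  expect_equal(information_criterion(fake, "WIC", lambda = 1),
               information_criterion(fake, "AIC"))
  expect_error(information_criterion(fake, "WIC", lambda = 1.2), "lambda")
  expect_error(information_criterion(fake, "WIC", lambda = -0.1), "lambda")
})

test_that("delta-AIC and delta-BIC obey the exact k identity", {
  d <- fix_data500()
  f0 <- fix_fit500()
  f1 <- mnlfa_fit(d$y, d$X, dif_spec(10, 3, dif_items = 2),
                  start = f0$params)
  dk <- f1$k - f0$k
  dAIC <- f0$AIC - f1$AIC
  dBIC <- f0$BIC - f1$BIC
  expect_equal(dAIC - dBIC, dk * (log(f0$n) - 2), tolerance = 1e-10)
})

test_that("wald_tests reports two-sided normal p-values for free effects", {
  d <- fix_data500()
  ft <- fixture("fit500_dif_se", function()
    mnlfa_fit(d$y, d$X, dif_spec(10, 3, dif_items = 1), se = TRUE,
              start = fix_fit500()$params))
  w <- wald_tests(ft)
  expect_equal(nrow(w), 6)   # one item x 3 covariates x 2 effect types
  expect_true(all(w$se > 0))
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_error(wald_tests(fix_fit500()), "se = TRUE")
})
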