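# Stage-2 sampler: clique enumeration, conditional updates against closed
# forms, the SSVS special case, selection post-processing, the Bayesian
# FDR threshold, and posterior prediction.

test_that("maximal cliques match exhaustive enumeration", {
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  expect_equal(unclass(enumerate_cliques(path3))[], list(c(1L, 2L), c(2L, 3L)),
               ignore_attr = TRUE)
  empty3 <- matrix(0L, 3, 3)
  cl <- enumerate_cliques(empty3)
  expect_equal(length(cl), 3)  # q = p: the SSVS special case
  expect_equal(unclass(cl)[], list(1L, 2L, 3L), ignore_attr = TRUE)
  tri <- matrix(0L, 4, 4)
  tri[1:3, 1:3] <- 1L
  diag(tri) <- 0L
  expect_equal(unclass(enumerate_cliques(tri))[], list(c(1L, 2L, 3L), 4L),
               ignore_attr = TRUE)
  # all graphs on 4 nodes, random graphs on 5 and 6 nodes
  for (m in 0:63) {
    adj <- matrix(0L, 4, 4)
    adj[upper.tri(adj)] <- as.integer(intToBits(m))[1:6]
    adj <- adj + t(adj)
    got <- unclass(enumerate_cliques(adj))
    attributes(got) <- NULL
    expect_equal(got, brute_force_cliques(adj))
  }
  set.seed(1)
  for (p in c(5, 6)) {
    for (r in 1:10) {
      adj <- matrix(0L, p, p)
      adj[upper.tri(adj)] <- rbinom(p * (p - 1) / 2, 1, 0.5)
      adj <- adj + t(adj)
      got <- unclass(enumerate_cliques(adj))
      attributes(got) <- NULL
      expect_equal(got, brute_force_cliques(adj))
      expect_setequal(unlist(got), 1:p)  # coverage
    }
  }
})

make_state <- function(p, q, gamma = rep(0L, q), beta = rep(0, p),
                       tau2 = rep(1, p), alpha = 0, eta = 1,
                       eta1_sq = 1, pi = 0.5) {
  list(gamma = gamma, beta = beta, tau2 = tau2, alpha = alpha,
       eta = eta, eta1_sq = eta1_sq, pi = pi)
}
hyp <- function(...) unclass(varsel_control(...))

test_that("clique indicators obey the prior mass at pi = 0 and pi = 1", {
  set.seed(2)
  n <- 40; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  cl <- lapply(1:p, identity)
  upd <- c(TRUE, rep(FALSE, 6))  # gamma only
  st0 <- make_state(p, p, pi = 0)
  st1 <- make_state(p, p, pi = 1)
  for (r in 1:20) {
    o0 <- bvssl:::varsel_sweep_cpp(st0, y, X, cl, hyp(), upd)
    expect_equal(sum(o0$gamma), 0)
    o1 <- bvssl:::varsel_sweep_cpp(st1, y, X, cl, hyp(), upd)
    expect_equal(sum(o1$gamma), p)
  }
})

test_that("singleton-clique inclusion matches the two-model Bayes factor", {
  # p = 2 orthonormal design: closed-form marginal likelihood ratio
  set.seed(3)
  n <- 60
  X <- qr.Q(qr(matrix(rnorm(n * 2), n, 2))) * sqrt(n)
  beta_t <- c(0.4, 0)
  y <- drop(X %*% beta_t) + rnorm(n)
  tau2 <- c(0.8, 0.8); eta <- 1; piv <- 0.3
  cl <- list(1L, 2L)
  # oracle: integrate the clique-1 coefficient out exactly
  logbf <- function(j) {
    r <- y            # other clique inactive in the state below
    b <- sum(X[, j] * r)
    M <- sum(X[, j]^2) + tau2[j]
    0.5 * (log(tau2[j]) - log(M)) + 0.5 * eta * b^2 / M
  }
  pr_oracle <- function(j) {
    lo <- log(piv / (1 - piv)) + logbf(j)
    1 / (1 + exp(-lo))
  }
  upd <- c(TRUE, rep(FALSE, 6))
  set.seed(4)
  draws <- replicate(6000, {
    st <- make_state(2, 2, gamma = c(0L, 0L), tau2 = tau2, pi = piv)
    as.vector(bvssl:::varsel_sweep_cpp(st, y, X, cl, hyp(), upd)$gamma)
  })
  expect_lt(abs(mean(draws[1, ]) - pr_oracle(1)), 0.02)
  expect_lt(abs(mean(draws[2, ]) - pr_oracle(2)), 0.02)
})

test_that("regression conditionals match the printed forms", {
  # eta | - ~ Ga(n/2 + a_eta, RSS/2 + b_eta): n = 100, RSS = 50 -> Ga(50.1, 26)
  n <- 100
  y <- rnorm(n)
  y <- y * sqrt(50 / sum(y^2))   # forces RSS = 50 with beta = 0, alpha = 0
  X <- matrix(0, n, 1)
  cl <- list(1L)
  upd <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)  # eta only
  set.seed(5)
  ed <- replicate(20000, bvssl:::varsel_sweep_cpp(
    make_state(1, 1), y, X, cl, hyp(), upd)$eta)
  expect_lt(abs(mean(ed) - 50.1 / 26), 3 * sqrt(50.1 / 26^2 / 20000))
  expect_lt(abs(var(ed) - 50.1 / 26^2), 4 * (50.1 / 26^2) * sqrt(2 / 20000))

  # pi | - ~ Beta(q* + a_pi, q - q* + b_pi): q = 10, q* = 2 -> Beta(2.1, 9)
  p <- 10
  X10 <- matrix(rnorm(40 * p), 40, p)
  y10 <- rnorm(40)
  cl10 <- lapply(1:p, identity)
  updp <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)  # pi only
  gam <- c(1L, 1L, rep(0L, 8))
  set.seed(6)
  pd <- replicate(20000, bvssl:::varsel_sweep_cpp(
    make_state(p, p, gamma = gam), y10, X10, cl10, hyp(), updp)$pi)
  expect_lt(abs(mean(pd) - 2.1 / 11.1), 3 * sqrt(0.18 * 0.82 / 12.1 / 20000))
  # q* = q -> Beta(q + 0.1, 1): mean 10.1/11.1
  set.seed(7)
  pd1 <- replicate(5000, bvssl:::varsel_sweep_cpp(
    make_state(p, p, gamma = rep(1L, p)), y10, X10, cl10, hyp(), updp)$pi)
  expect_lt(abs(mean(pd1) - 10.1 / 11.1), 0.005)

  # vanishing diagonal loadings: beta posterior mean -> OLS
  set.seed(8)
  Xo <- matrix(rnorm(80 * 3), 80, 3)
  yo <- drop(Xo %*% c(1, -0.5, 0.2)) + rnorm(80)
  ols <- drop(solve(crossprod(Xo), crossprod(Xo, yo)))
  updb <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)  # beta only
  st <- make_state(3, 3, gamma = rep(1L, 3), tau2 = rep(1e-10, 3), eta = 1)
  set.seed(9)
  bd <- replicate(4000, bvssl:::varsel_sweep_cpp(
    st, yo, Xo, list(1L, 2L, 3L), hyp(), updb)$beta)
  expect_lt(max(abs(rowMeans(bd) - ols)), 0.02)
})

test_that("single-covariate chain matches the Bayesian-lasso quadrature", {
  set.seed(10)
  n <- 60
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  y <- y - mean(y)           # intercept pinned at zero
  eta1 <- 1.5
  ctl <- varsel_control(a_pi = 1e8, b_pi = 1e-4,       # pi ~ 1, gamma = 1
                        eta1_sq_shape = 1e8, eta1_sq_rate = 1e8 / eta1^2,
                        sigma2_alpha = 1e-12)           # alpha ~ 0
  fit <- bvssl(y, matrix(x), control = ctl, n_iter = 24000, burn_in = 4000,
               seed = 10, standardize = FALSE)
  qd <- quad_bayes_lasso(y, x, a_eta = 0.1, b_eta = 1, eta1 = eta1)
  bd <- fit$draws$beta[, 1]
  expect_lt(abs(mean(bd) - qd$mean), 0.02 * max(abs(qd$mean), 0.1))
  expect_lt(abs(sd(bd) - qd$sd), 0.05 * qd$sd)
})

test_that("empty graph reproduces SSVS draws exactly under the same seed", {
  set.seed(11)
  n <- 50; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, -1, rep(0, 4))) + rnorm(n)
  f_graph <- bvssl(y, X, graph = matrix(0L, p, p), n_iter = 800,
                   burn_in = 200, seed = 11)
  f_ssvs <- bvssl(y, X, n_iter = 800, burn_in = 200, seed = 11)
  expect_identical(f_graph$draws$gamma, f_ssvs$draws$gamma)
  expect_identical(f_graph$draws$beta, f_ssvs$draws$beta)
  expect_equal(length(f_ssvs$cliques), p)
})

test_that("variable MIP equals clique MIP for disjoint cliques", {
  set.seed(12)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, 1, 0, 0, 0, 0)) + rnorm(n)
  adj <- matrix(0L, p, p)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[3, 4] <- adj[4, 3] <- 1L
  fit <- bvssl(y, X, graph = adj, n_iter = 800, burn_in = 200, seed = 12)
  for (k in seq_along(fit$cliques)) {
    for (j in fit$cliques[[k]]) {
      expect_equal(fit$variable_mip[j], fit$clique_mip[k])
    }
  }
  expect_true(all(fit$variable_mip >= 0 & fit$variable_mip <= 1))
  # selected variables always lie inside selected cliques
  expect_true(all(fit$selected_variables %in%
                  unlist(fit$cliques[fit$selected_cliques])))
})

test_that("selection applies the median-probability and CI rules", {
  fake <- structure(list(
    clique_mip = c(0.6, 0.4, 0.9),
    cliques = structure(list(c(1L, 2L), 3L, 4L), class = "clique_set", p = 4),
    ci_lower = c(0.1, -0.2, 0, 0.05),
    ci_upper = c(0.5, 0.3, 0, 0.6)
  ), class = "bvssl")
  sel <- select_variables(fake, 0.5)
  expect_equal(sel$selected_cliques, c(1L, 3L))
  expect_equal(sel$candidates, c(1L, 2L, 4L))
  # candidate 2 has CI (-0.2, 0.3) spanning zero -> dropped
  expect_equal(sel$selected_variables, c(1L, 4L))
})

test_that("Bayesian FDR threshold matches prefix enumeration", {
  expect_equal(bayesian_fdr_threshold(c(0.95, 0.9, 0.8, 0.4, 0.1), 0.2), 0.8)
  expect_equal(bayesian_fdr_threshold(rep(1, 5), 0.01), 1)
  expect_equal(bayesian_fdr_threshold(0.5, 0.2), Inf)
  expect_error(bayesian_fdr_threshold(numeric(0), 0.1), "empty")
  expect_error(bayesian_fdr_threshold(0.5, 1.2), "theta")
  set.seed(13)
  for (r in 1:50) {
    m <- runif(sample(1:12, 1))
    th <- runif(1, 0.05, 0.5)
    expect_equal(bayesian_fdr_threshold(m, th), naive_fdr_threshold(m, th))
  }
  # monotone: larger theta never selects fewer markers
  for (r in 1:20) {
    m <- runif(10)
    t1 <- bayesian_fdr_threshold(m, 0.1)
    t2 <- bayesian_fdr_threshold(m, 0.3)
    expect_gte(sum(m >= t1), 0)
    expect_gte(sum(m >= t2), sum(m >= t1))
  }
})

test_that("posterior prediction is calibrated and degenerates correctly", {
  # zero coefficient draws with constant intercept -> predictive mean = c
  nd <- 5
  obj <- structure(list(
    draws = list(beta = matrix(0, 100, 3), alpha = rep(2.5, 100),
                 eta = rep(1e8, 100)),
    center = rep(0, 3), scale = rep(1, 3), p = 3
  ), class = "bvssl")
  set.seed(14)
  pr <- predict(obj, matrix(rnorm(nd * 3), nd, 3))
  expect_equal(pr$fit, rep(2.5, nd))
  expect_lt(max(pr$upr - pr$lwr), 0.01)
  # self-consistency: coverage of 95% intervals near nominal
  set.seed(15)
  n <- 80; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  beta_t <- c(1.5, -1, 0, 0, 0)
  y <- drop(X %*% beta_t) + rnorm(n)
  fit <- bvssl(y, X, n_iter = 2500, burn_in = 500, seed = 15)
  Xn <- matrix(rnorm(400 * p), 400, p)
  yn <- drop(Xn %*% beta_t) + rnorm(400)
  pr <- predict(fit, Xn)
  cov <- mean(yn >= pr$lwr & yn <= pr$upr)
  expect_gt(cov, 0.86)
  expect_lt(cov, 1)
})

test_that("collinear designs do not break the sampler (A stays PD)", {
  set.seed(16)
  n <- 40
  x <- rnorm(n)
  X <- cbind(x, x, rnorm(n))   # exactly duplicated column
  y <- x + rnorm(n)
  expect_no_error(bvssl(y, X, n_iter = 500, burn_in = 100, seed = 16))
})
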