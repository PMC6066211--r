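# Conditional samplers of the stage-1 graphical model checked against
# closed forms and quadrature oracles.

test_that("prior edge-inclusion mean matches the closed form", {
  expect_equal(prior_edge_mean(1, 50, 0.1, 1), 50.1 / 51.1)
  expect_equal(prior_edge_mean(0, 0, 0.1, 1), 0.1 / 1.1)
  expect_equal(prior_edge_mean(1, 0, 0.1, 1), 0.1 / 1.1)
  expect_lt(prior_edge_mean(0, 1e8, 0.1, 1), 1e-6)
  expect_gt(prior_edge_mean(1, 1e8, 0.1, 1), 1 - 1e-6)
  # vectorised
  expect_equal(prior_edge_mean(c(0, 1), c(10, 10)),
               c(0.1, 10.1) / 11.1)
})

test_that("chain initialisation follows the stated conventions", {
  X <- matrix(rnorm(30), 10, 3)
  st <- init_graph_chain(mixed_data(X), seed = 1)
  expect_equal(st$Omega, diag(3))
  expect_length(st$ord_cols, 0)
  Xb <- cbind(rbinom(20, 1, 0.5), rnorm(20))
  stb <- init_graph_chain(mixed_data(Xb, c("ordinal", "continuous"),
                                     c(2L, NA)), seed = 1)
  expect_equal(stb$cutpoints[[1]], c(-Inf, 0, Inf))
  expect_false(stb$free_cut[1])
  s1 <- init_graph_chain(mixed_data(Xb, c("ordinal", "continuous"), c(2L, NA)),
                         seed = 5)
  s2 <- init_graph_chain(mixed_data(Xb, c("ordinal", "continuous"), c(2L, NA)),
                         seed = 5)
  expect_identical(s1, s2)
  expect_error(mixed_data(cbind(c(0, 3), c(1, 0)), c("ordinal", "ordinal"),
                          c(2L, 2L)), "codes 0")
})

test_that("latent draws follow the truncated Gaussian full conditional", {
  # independence case: Omega = I, binary code 1, cutpoint 0 -> N(0,1) on (0, Inf)
  n <- 20000
  W <- matrix(0, n, 2)
  codes <- matrix(1L, n, 1)
  set.seed(1)
  W2 <- bvssl:::sample_latent_cpp(W, diag(2), codes, 0L,
                                  list(c(-Inf, 0, Inf)))
  z <- W2[, 1]
  expect_true(all(z > 0))
  mo <- tnorm_moments(0, 1, 0, Inf)
  expect_lt(abs(mean(z) - mo$mean), 3 * sqrt(mo$var / n))
  expect_lt(abs(var(z) - mo$var), 3 * mo$var * sqrt(2 / n))
  # dependent case: conditional mean/variance read off Omega, cross-checked
  # against the dense-covariance bivariate conditional
  om12 <- 0.6
  Om <- matrix(c(1.3, om12, om12, 1.1), 2)
  x2 <- 1.7
  W <- matrix(rep(c(0, x2), each = n), n, 2)
  cond_mean <- -om12 * x2 / Om[1, 1]
  cond_sd <- sqrt(1 / Om[1, 1])
  Sig <- solve(Om)
  expect_equal(cond_mean, Sig[1, 2] / Sig[2, 2] * x2)
  expect_equal(cond_sd^2, Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2])
  set.seed(2)
  W2 <- bvssl:::sample_latent_cpp(W, Om, matrix(0L, n, 1), 0L,
                                  list(c(-Inf, 0, Inf)))
  z <- W2[, 1]
  mo <- tnorm_moments(cond_mean, cond_sd, -Inf, 0)
  expect_true(all(z <= 0))
  expect_lt(abs(mean(z) - mo$mean), 3 * sqrt(mo$var / n))
  expect_lt(abs(var(z) - mo$var), 3 * mo$var * sqrt(2 / n))
})

test_that("cutpoint draws are uniform between adjacent latent extremes", {
  # three-level column engineered so the free cutpoint interval is (0.4, 0.9)
  z <- c(0.1, 0.4, 0.9, 1.5, 2.5, 3.0)
  codes <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L), ncol = 1)
  W <- matrix(z, ncol = 1)
  cuts <- list(c(-Inf, 0.42, 2, Inf))
  set.seed(3)
  draws <- replicate(4000, {
    out <- bvssl:::sample_cutpoints_cpp(W, codes, 0L, cuts, TRUE)
    out[[1]][2]
  })
  expect_true(all(draws > 0.4 & draws < 0.9))
  ks <- suppressWarnings(ks.test(draws, punif, 0.4, 0.9))
  expect_gt(ks$p.value, 0.01)
  # binary columns have no free cutpoint
  outb <- bvssl:::sample_cutpoints_cpp(W, matrix(0L, 6, 1), 0L,
                                       list(c(-Inf, 0, Inf)), FALSE)
  expect_equal(outb[[1]], c(-Inf, 0, Inf))
  # empty level: falls back to the adjacent cutpoints, ordering preserved
  codes2 <- matrix(c(0L, 0L, 2L, 2L, 2L, 2L), ncol = 1)
  set.seed(4)
  out2 <- bvssl:::sample_cutpoints_cpp(W, codes2, 0L,
                                       list(c(-Inf, 0.42, 2, Inf)), TRUE)
  expect_true(all(diff(out2[[1]]) > 0))
})

test_that("precision sampler matches conjugate and quadrature oracles", {
  # p = 1: omega ~ Gamma(n/2 + 1, sum(x^2)/2 + lambda)
  set.seed(5)
  n <- 50
  x <- rnorm(n)
  S <- matrix(sum(x^2), 1, 1)
  lam <- 0.8
  draws <- replicate(20000, bvssl:::sample_precision_cpp(
    matrix(1), S, matrix(1), lam, n)[1, 1])
  sh <- n / 2 + 1
  rt <- S[1, 1] / 2 + lam
  expect_lt(abs(mean(draws) - sh / rt), 3 * sqrt(sh / rt^2 / 20000))
  expect_lt(abs(var(draws) - sh / rt^2), 4 * (sh / rt^2) * sqrt(2 / 20000))

  # p = 2: marginal of omega_12 against dense grid quadrature
  set.seed(6)
  n <- 30
  Om0 <- matrix(c(1, 0.3, 0.3, 1), 2)
  X <- matrix(rnorm(n * 2), n) %*% chol(solve(Om0))
  S <- crossprod(X)
  lam12 <- 1
  ld <- c(0.5, 0.5)
  Lam <- matrix(lam12, 2, 2)
  Omega <- diag(2)
  Tlat <- matrix(1, 2, 2)
  set.seed(7)
  keep <- matrix(NA_real_, 12000, 1)
  for (it in 1:14000) {
    Tlat <- bvssl:::sample_latent_scales_cpp(Tlat, Omega, Lam)
    Omega <- bvssl:::sample_precision_cpp(Omega, S, Tlat, ld, n)
    if (it > 2000) keep[it - 2000, 1] <- Omega[1, 2]
    expect_gt(Omega[1, 1] * Omega[2, 2] - Omega[1, 2]^2, 0)
  }
  qd <- quad_p2_omega12(S, n, lam12, ld)
  expect_lt(abs(mean(keep) - qd$mean), 0.02 + 3 * qd$sd / sqrt(1000))
  expect_lt(abs(sd(keep) - qd$sd), 0.15 * qd$sd)
  # KS distance between kept draws and the quadrature marginal
  emp <- ecdf(keep)
  ks <- max(abs(emp(qd$grid) - qd$cdf))
  expect_lt(ks, 0.05)
})

test_that("shrinkage conditionals match printed substitutions", {
  # delta = 1 branch: lambda ~ Ga(1 + a_lam, |omega| + b_lam)
  p <- 2
  Om <- matrix(c(1, 0.5, 0.5, 1), 2)
  A1 <- matrix(c(0L, 1L, 1L, 0L), 2)
  K <- matrix(1e6, 2, 2); diag(K) <- 0   # pins p_ij ~ 1, delta = 1
  set.seed(8)
  d1 <- replicate(20000, bvssl:::sample_shrinkage_cpp(
    matrix(1, 2, 2), rep(1, 2), matrix(0.999, 2, 2), A1, Om, A1, K,
    1, 10, 0.1, 1, 1e-2, 1e-6)$lam_offdiag[1, 2])
  expect_lt(abs(mean(d1) - 2 / 10.5), 3 * sqrt(2 / 10.5^2 / 20000))
  # delta = 0 branch with kappa = 50: lambda ~ Ga(52, 10.5)
  A0 <- matrix(0L, 2, 2)
  K50 <- matrix(50, 2, 2); diag(K50) <- 0
  set.seed(9)
  d0 <- replicate(20000, bvssl:::sample_shrinkage_cpp(
    matrix(1, 2, 2), rep(1, 2), matrix(0.001, 2, 2), A0, Om, A0, K50,
    1, 10, 0.1, 1, 1e-2, 1e-6)$lam_offdiag[1, 2])
  # draws are a mixture; condition on the delta = 0 component via the
  # closed form weight
  cf <- mixture_closed_form(0.5, 50, 0, 1, 10, 0.1, 1)
  expect_lt(abs(mean(d0) - cf$e_lambda), 4 * sd(d0) / sqrt(20000))
  # diagonal: lambda_ii ~ Ga(1 + a, omega_ii + b)
  set.seed(10)
  dd <- replicate(20000, bvssl:::sample_shrinkage_cpp(
    matrix(1, 2, 2), rep(1, 2), matrix(0.5, 2, 2), A0, Om, A0,
    matrix(0, 2, 2), 1, 10, 0.1, 1, 2, 3)$lam_diag[1])
  expect_lt(abs(mean(dd) - 3 / 4), 3 * sqrt(3 / 16 / 20000))
})

test_that("chained (lambda, delta, p) updates match the closed-form joint", {
  Om <- matrix(c(1, 0.25, 0.25, 1), 2)
  a_lam <- 0.5; b_lam <- 2; a_p <- 0.3; b_p <- 0.7; kap <- 6
  for (a0 in c(0L, 1L)) {
    A0 <- matrix(a0, 2, 2); diag(A0) <- 0L
    K <- matrix(kap, 2, 2); diag(K) <- 0
    Lam <- matrix(1, 2, 2); Pm <- matrix(0.5, 2, 2)
    Del <- matrix(0L, 2, 2); ldg <- rep(1, 2)
    set.seed(11 + a0)
    nit <- 30000
    lam_d <- del_d <- p_d <- numeric(nit)
    for (it in seq_len(nit)) {
      out <- bvssl:::sample_shrinkage_cpp(Lam, ldg, Pm, Del, Om, A0, K,
                                          a_lam, b_lam, a_p, b_p, 1e-2, 1e-6)
      Lam <- out$lam_offdiag; Pm <- out$pmix; Del <- out$delta
      ldg <- out$lam_diag
      lam_d[it] <- Lam[1, 2]; del_d[it] <- Del[1, 2]; p_d[it] <- Pm[1, 2]
    }
    cf <- mixture_closed_form(0.25, kap, a0, a_lam, b_lam, a_p, b_p)
    expect_lt(abs(mean(del_d) - cf$p_delta1), 0.015)
    expect_lt(abs(mean(lam_d) - cf$e_lambda), 4 * sd(lam_d) / sqrt(nit / 5))
    expect_lt(abs(mean(p_d) - cf$e_p), 0.015)
  }
})

test_that("large belief on a present edge yields stochastically smaller lambda", {
  # |omega| small enough that the two mixture components compete
  Om <- matrix(c(1, 0.05, 0.05, 1), 2)
  K <- matrix(30, 2, 2); diag(K) <- 0
  draw_lam <- function(a0val, seed) {
    A0 <- matrix(a0val, 2, 2); diag(A0) <- 0L
    Lam <- matrix(1, 2, 2); Pm <- matrix(0.5, 2, 2); Del <- A0
    ldg <- rep(1, 2)
    set.seed(seed)
    out <- numeric(4000)
    for (it in 1:4000) {
      s <- bvssl:::sample_shrinkage_cpp(Lam, ldg, Pm, Del, Om, A0, K,
                                        0.01, 0.1, 0.1, 1, 1e-2, 1e-6)
      Lam <- s$lam_offdiag; Pm <- s$pmix; Del <- s$delta; ldg <- s$lam_diag
      out[it] <- Lam[1, 2]
    }
    out
  }
  l1 <- draw_lam(1L, 21)
  l0 <- draw_lam(0L, 22)
  w <- wilcox.test(l1, l0, alternative = "less")
  expect_lt(w$p.value, 1e-6)
})
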