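# Independent oracles used across the test files: brute-force clique
# enumeration, closed-form truncated-normal moments, grid quadrature for
# the small-dimension posteriors, and naive metric recomputations.

# all maximal cliques by exhaustive subset enumeration (p <= ~12)
brute_force_cliques <- function(adj) {
  p <- nrow(adj)
  subsets <- lapply(seq_len(2^p) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  is_complete <- vapply(subsets, function(s) {
    if (length(s) <= 1) return(TRUE)
    all(adj[t(combn(s, 2))] == 1)
  }, logical(1))
  comp <- subsets[is_complete & lengths(subsets) > 0]
  keep <- vapply(seq_along(comp), function(i) {
    !any(vapply(seq_along(comp), function(j) {
      j != i && length(comp[[j]]) > length(comp[[i]]) &&
        all(comp[[i]] %in% comp[[j]])
    }, logical(1)))
  }, logical(1))
  out <- comp[keep]
  out[order(vapply(out, `[`, integer(1), 1),
            lengths(out),
            vapply(out, paste, character(1), collapse = ","))]
}

# mean and variance of N(mu, sd^2) truncated to (lo, hi)
tnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mu + sd * (da - db) / Z
  v <- sd^2 * (1 + (ifelse(is.finite(a), a * da, 0) -
                    ifelse(is.finite(b), b * db, 0)) / Z -
               ((da - db) / Z)^2)
  list(mean = m, var = v)
}

# closed-form conditional moments of (delta, p, lambda) given |omega|
# under the shrinkage mixture prior (lambda and p marginalised exactly)
mixture_closed_form <- function(abs_omega, kappa, a0, a_lam, b_lam, a_p, b_p) {
  A <- a0 * kappa + a_p
  B <- (1 - a0) * kappa + b_p
  logC1 <- log(a_lam) + a_lam * log(b_lam) -
    (a_lam + 1) * log(b_lam + abs_omega)
  logC0 <- log(kappa + a_lam) + (kappa + a_lam) * log(b_lam) -
    (kappa + a_lam + 1) * log(b_lam + abs_omega)
  l1 <- log(A / (A + B)) + logC1
  l0 <- log(B / (A + B)) + logC0
  p1 <- 1 / (1 + exp(l0 - l1))
  list(
    p_delta1 = p1,
    e_lambda = p1 * (1 + a_lam) / (b_lam + abs_omega) +
      (1 - p1) * (1 + kappa + a_lam) / (b_lam + abs_omega),
    e_p = p1 * (A + 1) / (A + B + 1) + (1 - p1) * A / (A + B + 1)
  )
}

# grid quadrature for the p = 2 precision posterior under fixed Laplace /
# exponential shrinkage: returns the marginal distribution of omega_12
quad_p2_omega12 <- function(S, n, lam12, lam_diag,
                            w_max = 5, n_diag = 100, n_off = 161) {
  w11 <- seq(1e-3, w_max, length.out = n_diag)
  w22 <- seq(1e-3, w_max, length.out = n_diag)
  w12 <- seq(-w_max / 2, w_max / 2, length.out = n_off)
  gd <- expand.grid(w11 = w11, w22 = w22)
  lp_all <- matrix(-Inf, nrow(gd), length(w12))
  for (k in seq_along(w12)) {
    o <- w12[k]
    det <- gd$w11 * gd$w22 - o^2
    ok <- det > 0
    lp_all[ok, k] <- (n / 2) * log(det[ok]) -
      0.5 * (S[1, 1] * gd$w11[ok] + S[2, 2] * gd$w22[ok] + 2 * S[1, 2] * o) -
      lam_diag[1] * gd$w11[ok] - lam_diag[2] * gd$w22[ok] - lam12 * abs(o)
  }
  dens <- colSums(exp(lp_all - max(lp_all)))
  dens <- dens / sum(dens)
  list(grid = w12, pmf = dens,
       mean = sum(w12 * dens),
       sd = sqrt(sum(w12^2 * dens) - sum(w12 * dens)^2),
       cdf = cumsum(dens))
}

# 2-D grid quadrature of the single-covariate Bayesian lasso posterior
# (intercept pinned at 0, Laplace rate eta1 fixed): p(beta, eta | y, x)
quad_bayes_lasso <- function(y, x, a_eta, b_eta, eta1,
                             n_beta = 401, n_eta = 301) {
  bhat <- sum(x * y) / sum(x^2)
  se <- sqrt(1 / sum(x^2)) * 3
  beta <- seq(bhat - 8 * se, bhat + 8 * se, length.out = n_beta)
  eta <- seq(1e-3, 4, length.out = n_eta)
  n <- length(y)
  lp <- outer(beta, eta, function(b, e) {
    rss <- vapply(b, function(bb) sum((y - x * bb)^2), numeric(1))
    (n / 2 + a_eta - 1 + 0.5) * log(e) - e * (rss / 2 + b_eta) -
      eta1 * sqrt(e) * abs(b)
  })
  w <- exp(lp - max(lp))
  pb <- rowSums(w)
  pb <- pb / sum(pb)
  list(mean = sum(beta * pb),
       sd = sqrt(sum(beta^2 * pb) - sum(beta * pb)^2))
}

# naive ROC AUC: pairwise comparison probability with 0.5 for ties
naive_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# naive sensitivity at a specificity floor via explicit cutoff loop
naive_power_at_spec <- function(scores, truth, level = 0.9) {
  cuts <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  best <- 0
  for (ct in cuts) {
    sel <- scores >= ct
    tn <- sum(!sel & truth == 0)
    fp <- sum(sel & truth == 0)
    spec <- tn / (tn + fp)
    sens <- sum(sel & truth == 1) / sum(truth == 1)
    if (spec >= level) best <- max(best, sens)
  }
  best
}

# prefix-enumeration oracle for the Bayesian FDR cutoff
naive_fdr_threshold <- function(mips, theta) {
  s <- sort(mips, decreasing = TRUE)
  best <- Inf
  for (k in seq_along(s)) {
    if (mean(1 - s[seq_len(k)]) <= theta) best <- s[k]
  }
  best
}

# short-hand: run a stage-1 chain on plain continuous data
fit_graph_quick <- function(X, ..., n_iter = 1500, burn_in = 500, seed = 1) {
  bvssl_graph(X, n_iter = n_iter, burn_in = burn_in, seed = seed, ...)
}
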