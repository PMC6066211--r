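# Stage 2: clique-structured spike-and-slab regression.  Maximal cliques
# of the estimated graph define the selectable groups; a Gibbs sampler
# alternates clique indicators, Laplace-prior coefficients, residual
# precision, clique sparsity, the Laplace rate and the intercept.

#' Hyperparameters of the structured variable-selection model
#'
#' @param a_pi,b_pi Beta hyperparameters of the clique inclusion
#'   probability; the default 0.1/1 favours few included cliques
#'   (multiplicity control).
#' @param a_eta,b_eta Gamma prior on the residual precision (default
#'   Ga(0.1, 1), thick-tailed residuals).
#' @param eta1_sq_shape,eta1_sq_rate Gamma prior on the squared Laplace
#'   rate of the coefficient prior (default Ga(1, 2)).
#' @param mu_alpha,sigma2_alpha Gaussian prior on the intercept.
#' @return list of class \code{varsel_control}.
#' @export
varsel_control <- function(a_pi = 0.1, b_pi = 1, a_eta = 0.1, b_eta = 1,
                           eta1_sq_shape = 1, eta1_sq_rate = 2,
                           mu_alpha = 0, sigma2_alpha = 100) {
  stopifnot(a_pi > 0, b_pi > 0, a_eta > 0, b_eta > 0,
            eta1_sq_shape > 0, eta1_sq_rate > 0, sigma2_alpha > 0)
  structure(list(a_pi = a_pi, b_pi = b_pi, a_eta = a_eta, b_eta = b_eta,
                 eta1_sq_shape = eta1_sq_shape, eta1_sq_rate = eta1_sq_rate,
                 mu_alpha = mu_alpha, sigma2_alpha = sigma2_alpha),
            class = "varsel_control")
}

#' Maximal cliques of an undirected graph
#'
#' Returns every maximal clique of the adjacency (isolated nodes appear
#' as singletons), so the union of cliques covers all nodes.  With an
#' empty graph this gives q = p singleton cliques, the stochastic search
#' variable selection (SSVS) special case.
#'
#' @param graph a symmetric 0/1 adjacency matrix or a
#'   \code{graph_estimate} / \code{bvssl_graph} object.
#' @return list of integer vectors (sorted, deterministic order), class
#'   \code{clique_set}.
#' @export
enumerate_cliques <- function(graph) {
  adj <- if (is.matrix(graph)) graph else graph$adjacency
  if (is.null(adj)) stop("no adjacency found in 'graph'")
  if (!isTRUE(all.equal(unname(adj * 1), unname(t(adj) * 1))))
    stop("adjacency must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  ord <- order(vapply(cl, `[`, integer(1), 1),
               vapply(cl, length, integer(1)),
               vapply(cl, function(v) paste(v, collapse = ","), character(1)))
  structure(cl[ord], class = "clique_set", p = nrow(adj))
}

#' @export
print.clique_set <- function(x, ...) {
  cat("Clique set: q =", length(x), "maximal cliques covering",
      attr(x, "p"), "nodes\n")
  sizes <- vapply(x, length, integer(1))
  cat("  size distribution:",
      paste(names(table(sizes)), table(sizes), sep = "x", collapse = ", "),
      "\n")
  invisible(x)
}

singleton_cliques <- function(p) {
  structure(lapply(seq_len(p), identity), class = "clique_set", p = p)
}

#' Fit the clique-structured spike-and-slab regression
#'
#' Gibbs sampler for the linear model \eqn{y = \alpha + X_\gamma
#' \beta_\gamma + \epsilon}, \eqn{\epsilon \sim N(0, \eta^{-1})}, with
#' Laplace (double-exponential) priors on coefficients and a
#' clique-inclusion prior on the model space: each maximal clique of the
#' supplied graph enters or leaves the model as a block with prior
#' probability \eqn{\pi \sim Be(a_\pi, b_\pi)}.  With no graph (or an
#' empty one) every variable is its own clique and the sampler is
#' ordinary SSVS with Laplace priors.
#'
#' Marginal inclusion probabilities (MIPs) are the fraction of kept
#' iterations in which a clique (or a variable, via any containing
#' clique) is in the model.  Pointwise 95\% credible intervals for each
#' coefficient are computed over the iterations in which the variable was
#' active, and the default selection applies the median-probability rule
#' to clique MIPs followed by exclusion of candidates whose interval
#' spans zero.
#'
#' @param y numeric response vector.
#' @param X numeric covariate matrix (ordinal covariates entered as
#'   numeric codes).
#' @param graph optional adjacency matrix, \code{graph_estimate} or
#'   \code{bvssl_graph} defining the cliques; NULL gives SSVS.
#' @param cliques optionally, a precomputed \code{clique_set} (overrides
#'   \code{graph}).
#' @param control hyperparameters, see \code{\link{varsel_control}}.
#' @param n_iter,burn_in chain length and burn-in.
#' @param seed integer seed.
#' @param standardize centre and scale the columns of X before fitting
#'   (coefficients are reported on the standardised scale).
#' @param mip_threshold clique MIP cutoff for the default selection.
#' @return An object of class \code{bvssl}; see
#'   \code{\link{select_variables}}, \code{\link{predict.bvssl}}.
#' @export
bvssl <- function(y, X, graph = NULL, cliques = NULL,
                  control = varsel_control(), n_iter = 10000,
                  burn_in = 3000, seed = 1, standardize = TRUE,
                  mip_threshold = 0.5) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(length(y) == n, n_iter > burn_in, burn_in >= 0)
  if (is.null(cliques)) {
    cliques <- if (is.null(graph)) singleton_cliques(p)
               else enumerate_cliques(graph)
  }
  stopifnot(inherits(cliques, "clique_set"))
  covered <- sort(unique(unlist(cliques)))
  if (!identical(covered, seq_len(p)))
    stop("cliques must cover all ", p, " variables")
  ctr <- if (standardize) colMeans(X) else rep(0, p)
  Xc <- sweep(X, 2, ctr)
  scl <- if (standardize) apply(Xc, 2, sd) else rep(1, p)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(Xc, 2, scl, "/")
  set.seed(seed)
  res <- varsel_mcmc_cpp(y, Xs, unclass(cliques), unclass(control),
                         as.integer(n_iter), as.integer(burn_in))
  q <- length(cliques)
  membership <- matrix(0L, q, p)
  for (k in seq_len(q)) membership[k, cliques[[k]]] <- 1L
  gamma_draws <- res$gamma_draws
  active <- (gamma_draws %*% membership) > 0
  clique_mip <- colMeans(gamma_draws)
  variable_mip <- colMeans(active)
  beta_draws <- res$beta_draws
  beta_hat <- colMeans(beta_draws)
  ci <- matrix(NA_real_, p, 2)
  for (j in seq_len(p)) {
    act <- active[, j]
    if (any(act))
      ci[j, ] <- quantile(beta_draws[act, j], c(0.025, 0.975), names = FALSE)
  }
  fit <- structure(list(
    clique_mip = clique_mip, variable_mip = variable_mip,
    beta_hat = beta_hat, ci_lower = ci[, 1], ci_upper = ci[, 2],
    cliques = cliques, membership = membership,
    draws = list(gamma = gamma_draws, beta = beta_draws,
                 alpha = res$alpha_draws, eta = res$eta_draws,
                 active = active),
    center = ctr, scale = scl, X = X, y = y, n = n, p = p,
    control = control, n_iter = n_iter, burn_in = burn_in, seed = seed,
    mip_threshold = mip_threshold
  ), class = "bvssl")
  sel <- select_variables(fit, mip_threshold)
  fit$selected_cliques <- sel$selected_cliques
  fit$selected_variables <- sel$selected_variables
  fit
}

#' Median-probability selection with credible-interval thresholding
#'
#' Selects the cliques with marginal inclusion probability strictly above
#' \code{mip_threshold}; candidate variables are the union of selected
#' cliques, and candidates whose pointwise 95\% credible interval spans
#' zero are dropped.
#'
#' @param fit a \code{bvssl} fit.
#' @param mip_threshold clique MIP cutoff (default 0.5, the median
#'   probability rule).
#' @return list with \code{selected_cliques}, \code{candidates} and
#'   \code{selected_variables} (integer index vectors).
#' @export
select_variables <- function(fit, mip_threshold = 0.5) {
  stopifnot(inherits(fit, "bvssl"))
  sel_k <- which(fit$clique_mip > mip_threshold)
  cand <- sort(unique(unlist(fit$cliques[sel_k])))
  keep <- cand[!is.na(fit$ci_lower[cand]) &
               (fit$ci_lower[cand] > 0 | fit$ci_upper[cand] < 0)]
  list(selected_cliques = sel_k, candidates = cand,
       selected_variables = keep)
}

#' Bayesian FDR threshold for marginal inclusion probabilities
#'
#' Returns the cutoff \eqn{\phi_\theta} such that the selected set
#' \eqn{\{j : MIP_j \ge \phi_\theta\}} is the largest whose average
#' posterior false-inclusion probability (mean of 1 - MIP over the
#' selected set) is at most \eqn{\theta}; about \eqn{100\theta}\% of the
#' markers called significant are then expected to be false positives.
#' Returns \code{Inf} when even the top-ranked marker fails.
#'
#' @param mips vector of marginal inclusion probabilities in [0, 1].
#' @param theta target average Bayesian FDR, in (0, 1).
#' @return the MIP cutoff (scalar; \code{Inf} when nothing is selected).
#' @export
bayesian_fdr_threshold <- function(mips, theta) {
  if (length(mips) == 0) stop("empty MIP vector")
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta >= 1)
    stop("theta must be a scalar in (0, 1)")
  s <- sort(mips, decreasing = TRUE)
  run_mean <- cumsum(1 - s) / seq_along(s)
  ok <- which(run_mean <= theta)
  if (length(ok) == 0) return(Inf)
  s[max(ok)]
}

#' @export
print.bvssl <- function(x, ...) {
  cat("Clique-structured Bayesian variable selection fit\n")
  cat("  n =", x$n, ", p =", x$p, ", q =", length(x$cliques), "cliques\n")
  cat("  kept draws:", nrow(x$draws$beta), "\n")
  cat("  selected cliques:", length(x$selected_cliques),
      "; selected variables:",
      paste(x$selected_variables, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.bvssl <- function(object, ...) {
  tab <- data.frame(
    variable = seq_len(object$p),
    mip = object$variable_mip,
    beta = object$beta_hat,
    ci_lower = object$ci_lower,
    ci_upper = object$ci_upper,
    selected = seq_len(object$p) %in% object$selected_variables
  )
  out <- list(variables = tab,
              cliques = data.frame(
                clique = seq_along(object$cliques),
                members = vapply(object$cliques, paste, character(1),
                                 collapse = ","),
                mip = object$clique_mip,
                selected = seq_along(object$cliques) %in%
                  object$selected_cliques))
  class(out) <- "summary.bvssl"
  out
}

#' @export
print.summary.bvssl <- function(x, ...) {
  cat("Cliques (by inclusion probability):\n")
  ck <- x$cliques[order(-x$cliques$mip), ]
  print(utils::head(ck, 10), row.names = FALSE)
  cat("\nVariables with MIP > 0.5:\n")
  vt <- x$variables[x$variables$mip > 0.5, ]
  print(vt[order(-vt$mip), ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.bvssl <- function(object, rescale = TRUE, ...) {
  b <- object$beta_hat
  if (rescale) b <- b / object$scale
  names(b) <- paste0("x", seq_along(b))
  b
}

#' @export
plot.bvssl <- function(x, ...) {
  graphics::plot(seq_len(x$p), x$variable_mip, type = "h", lwd = 2,
                 xlab = "variable", ylab = "marginal inclusion probability",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' @export
residuals.bvssl <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
fitted.bvssl <- function(object, ...) {
  mean(object$draws$alpha) +
    drop(scale_design(object, object$X) %*% object$beta_hat)
}

scale_design <- function(object, newdata) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != object$p) stop("newdata has wrong number of columns")
  sweep(sweep(Xn, 2, object$center), 2, object$scale, "/")
}

#' Posterior predictive distribution for new samples
#'
#' For every kept draw \eqn{(\alpha, \beta, \eta)} computes \eqn{\hat y =
#' \alpha + x_{new}\beta + e}, \eqn{e \sim N(0, \eta^{-1})}; reports the
#' posterior predictive mean (computed without the noise term) and the
#' central credible interval across draws.
#'
#' @param object a \code{bvssl} fit.
#' @param newdata matrix of new covariate rows (original scale).
#' @param level credible level of the predictive interval.
#' @param ... unused.
#' @return data frame with columns \code{fit}, \code{lwr}, \code{upr}.
#' @export
predict.bvssl <- function(object, newdata, level = 0.95, ...) {
  Xs <- scale_design(object, newdata)
  B <- object$draws$beta            # kept x p
  nk <- nrow(B)
  lin <- Xs %*% t(B)                # n_new x kept
  lin <- sweep(lin, 2, object$draws$alpha, "+")
  fitm <- rowMeans(lin)
  noise <- matrix(rnorm(length(lin), sd = rep(1 / sqrt(object$draws$eta),
                                              each = nrow(lin))),
                  nrow(lin), nk)
  pred <- lin + noise
  a <- (1 - level) / 2
  qs <- t(apply(pred, 1, quantile, probs = c(a, 1 - a), names = FALSE))
  data.frame(fit = fitm, lwr = qs[, 1], upr = qs[, 2])
}
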