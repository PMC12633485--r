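# 2-component full-covariance Gaussian mixture, fitted by EM with a
# fixed ridge added to every covariance diagonal. The ridge keeps the
# E-step well-posed when features carry near-degenerate dimensions
# (e.g. high-frequency filter responses after Gaussian smoothing),
# which rules out off-the-shelf unregularized fitters.

# Per-component Gaussian log-densities plus log-weights.
# Returns an n x G matrix.
gmm_log_dens <- function(X, pro, mean_mat, sigma, ridge = 0) {
  n <- nrow(X); d <- ncol(X); G <- length(pro)
  ld <- matrix(0, n, G)
  for (g in seq_len(G)) {
    S <- sigma[, , g]
    if (ridge > 0) S <- S + diag(ridge, d)
    R <- chol(S)
    Xc <- sweep(X, 2, mean_mat[, g])
    Y <- Xc %*% backsolve(R, diag(d))
    ld[, g] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                         rowSums(Y^2)) + log(pro[g])
  }
  ld
}

# Responsibilities and log-likelihood from log-densities (log-sum-exp).
gmm_estep <- function(ld) {
  mx <- pmax(ld[, 1], ld[, 2])
  e <- exp(ld - mx)
  s <- rowSums(e)
  list(z = e / s, loglik = sum(log(s) + mx))
}

# EM for a 2-component full-covariance mixture with ridge
# regularization, from initial responsibilities z0. Converges when the
# relative log-likelihood change drops below `tol`.
gmm_fit_em <- function(X, z0, ridge = 1e-6, itmax = 200L, tol = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  z <- z0
  ll_old <- -Inf
  pro <- NULL; mean_mat <- NULL; sigma <- NULL
  for (it in seq_len(itmax)) {
    w <- colSums(z)
    if (any(w < d + 1))
      stop("a mixture component collapsed (", round(min(w), 1),
           " effective observations)")
    pro <- w / n
    mean_mat <- t(crossprod(z, X) / w)          # d x 2
    sigma <- array(0, c(d, d, 2))
    for (g in 1:2) {
      Xc <- sweep(X, 2, mean_mat[, g])
      sigma[, , g] <- crossprod(Xc * z[, g], Xc) / w[g] + diag(ridge, d)
    }
    es <- gmm_estep(gmm_log_dens(X, pro, mean_mat, sigma))
    z <- es$z
    if (is.finite(ll_old) &&
        abs(es$loglik - ll_old) <= tol * abs(es$loglik)) {
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  list(pro = pro, mean = mean_mat, sigma = sigma, loglik = ll_old,
       iterations = it)
}
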