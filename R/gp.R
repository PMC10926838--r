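# Gaussian-process internals shared by the landscape surrogate.
#
# Both outputs (activity classifier, thermostability regressor) use the same
# linear Hamming kernel k(x, x') = sigma0^2 + x . x' on the one-hot encoding,
# under which the dot product equals (number of variable columns) - Hamming
# distance, so kernel similarity is exactly sequence similarity. The
# regressor additionally carries an additive white-noise term on the
# diagonal. All heavy computation is expressed in terms of kernel matrices so
# that a precomputed design-by-design Gram matrix can stand in for repeated
# feature products during simulations.

linear_kernel <- function(X1, X2 = X1, sigma0 = 1) {
  sigma0^2 + tcrossprod(X1, X2)
}

JITTER <- 1e-8

# --- exact GP regression -------------------------------------------------

# K: train kernel (no noise); y: targets; returns chol factor and weights
gp_reg_fit <- function(K, y, noise_level) {
  n <- length(y)
  Ky <- K + diag(noise_level + JITTER, n)
  L <- chol(Ky)                       # upper triangular, Ky = L'L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  list(L = L, alpha = alpha, y = y, noise_level = noise_level, lml = lml)
}

# Ks: m x n cross kernel; kss: length-m prior diagonal (no noise)
gp_reg_predict <- function(fit, Ks, kss, include_noise = TRUE) {
  mu <- drop(Ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(Ks))
  var_f <- pmax(kss - colSums(v^2), 0)
  if (include_noise) var_f <- var_f + fit$noise_level
  list(mu = mu, sigma = sqrt(var_f))
}

# marginal-likelihood optimization of (sigma0, noise) on the log scale,
# single deterministic L-BFGS-B start from the configured values
gp_reg_optimize <- function(G, y, sigma0, noise_level) {
  obj <- function(par) {
    K <- exp(2 * par[1]) + G
    f <- tryCatch(gp_reg_fit(K, y, exp(par[2])), error = function(e) NULL)
    if (is.null(f) || !is.finite(f$lml)) return(1e10)
    -f$lml
  }
  start <- log(c(max(sigma0, 1e-3), max(noise_level, 1e-6)))
  opt <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = log(c(1e-4, 1e-6)), upper = log(c(1e3, 1e4)))
  list(sigma0 = exp(opt$par[1]), noise_level = exp(opt$par[2]))
}

# --- GP classification, Laplace approximation ----------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Newton iteration for the mode of the latent posterior (logistic link);
# t is the 0/1 label vector, K the train kernel
gp_cls_fit <- function(K, t, max_iter = 50, tol = 1e-8) {
  n <- length(t)
  f <- numeric(n)
  obj_old <- -Inf
  for (it in seq_len(max_iter)) {
    p <- sigmoid(f)
    W <- pmax(p * (1 - p), 1e-10)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B)
    b <- W * f + (t - p)
    a <- b - sW * backsolve(L, forwardsolve(t(L), sW * drop(K %*% b)))
    f <- drop(K %*% a)
    p <- sigmoid(f)
    obj <- -0.5 * sum(a * f) + sum(t * log(p) + (1 - t) * log1p(-p))
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  p <- sigmoid(f)
  W <- pmax(p * (1 - p), 1e-10)
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * K)
  list(f_hat = f, grad = t - p, sW = sW, L = L, t = t)
}

# predictive activity probability; latent Gaussian squashed through the
# logistic using the standard probit-style approximation
gp_cls_predict <- function(fit, Ks, kss) {
  f_mu <- drop(Ks %*% fit$grad)
  v <- forwardsolve(t(fit$L), fit$sW * t(Ks))
  f_var <- pmax(kss - colSums(v^2), 0)
  sigmoid(f_mu / sqrt(1 + pi * f_var / 8))
}
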