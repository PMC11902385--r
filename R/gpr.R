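# Exact Gaussian-process regression with the five stationary kernels used for
# the kernel-robustness study: squared-exponential, exponential, Matern 3/2,
# Matern 5/2, rational quadratic (shape fixed at 1).  Hyperparameters
# (length-scale, signal SD, noise SD) are fitted by maximizing the log
# marginal likelihood with analytic gradients; predictive intervals come from
# the Gaussian predictive distribution (latent variance + noise variance).

gpr_kernels <- c("squaredexponential", "exponential", "matern32", "matern52",
                 "rationalquadratic")

# kernel correlation and its derivative wrt log length-scale, as functions of
# the Euclidean distance matrix r
gpr_kfun <- function(kernel, r, ell) {
  switch(kernel,
    squaredexponential = exp(-r^2 / (2 * ell^2)),
    exponential = exp(-r / ell),
    matern32 = {
      a <- sqrt(3) / ell
      (1 + a * r) * exp(-a * r)
    },
    matern52 = {
      a <- sqrt(5) / ell
      (1 + a * r + (a * r)^2 / 3) * exp(-a * r)
    },
    rationalquadratic = 1 / (1 + r^2 / (2 * ell^2)),
    abort(sprintf("Unknown GPR kernel '%s'.", kernel))
  )
}

gpr_kgrad_logell <- function(kernel, r, ell, k) {
  switch(kernel,
    squaredexponential = k * (r^2 / ell^2),
    exponential = k * (r / ell),
    matern32 = {
      a <- sqrt(3) / ell
      a^2 * r^2 * exp(-a * r)
    },
    matern52 = {
      a <- sqrt(5) / ell
      (a^2 * r^2 / 3) * (1 + a * r) * exp(-a * r)
    },
    rationalquadratic = {
      u <- r^2 / (2 * ell^2)
      2 * u / (1 + u)^2
    }
  )
}

gpr_dist <- function(X, Y = NULL) {
  if (is.null(Y)) Y <- X
  sx <- rowSums(X^2)
  sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, "+") - 2 * tcrossprod(X, Y)
  sqrt(pmax(d2, 0))
}

# negative log marginal likelihood and gradient in theta = (log ell, log sf,
# log sn)
gpr_nll <- function(theta, kernel, r, yc, grad = FALSE) {
  ell <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
  n <- length(yc)
  k0 <- gpr_kfun(kernel, r, ell)
  K <- sf^2 * k0
  diag(K) <- diag(K) + sn^2 + 1e-8 * sf^2
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(if (grad) list(value = 1e10, grad = c(0, 0, 0)) else 1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  nll <- 0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  if (!grad) return(nll)
  Kinv <- chol2inv(ch)
  W <- Kinv - tcrossprod(alpha)           # dNLL/dtheta = 0.5 tr(W dK/dtheta)
  dK_ell <- sf^2 * gpr_kgrad_logell(kernel, r, ell, k0)
  g <- c(0.5 * sum(W * dK_ell),
         0.5 * sum(W * (2 * (sf^2 * k0 + diag(1e-8 * sf^2, n)))),
         0.5 * sum(diag(W)) * 2 * sn^2)
  list(value = nll, grad = g)
}

gpr_fit <- function(X, y, kernel = "squaredexponential", optimize = TRUE,
                    maxit = 50) {
  kernel <- match.arg(kernel, gpr_kernels)
  n <- nrow(X)
  ybar <- mean(y)
  yc <- y - ybar
  r <- gpr_dist(X)
  # median-distance heuristic initialization
  med <- median(r[upper.tri(r)])
  if (!is.finite(med) || med <= 0) med <- 1
  sy <- sd(y)
  if (!is.finite(sy) || sy <= 0) sy <- 1
  theta <- log(c(med, sy, 0.1 * sy))
  if (optimize && n >= 5 && sd(y) > 0) {
    fn <- function(th) gpr_nll(th, kernel, r, yc, grad = FALSE)
    gr <- function(th) gpr_nll(th, kernel, r, yc, grad = TRUE)$grad
    opt <- tryCatch(
      optim(theta, fn, gr, method = "L-BFGS-B",
            lower = theta - 8, upper = theta + 8,
            control = list(maxit = maxit)),
      error = function(e) NULL)
    if (!is.null(opt)) theta <- opt$par
  }
  ell <- exp(theta[1]); sf <- exp(theta[2]); sn <- exp(theta[3])
  K <- sf^2 * gpr_kfun(kernel, r, ell)
  diag(K) <- diag(K) + sn^2 + 1e-8 * sf^2
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(kernel = kernel, X = X, ybar = ybar, alpha = alpha, chol = ch,
       ell = ell, sf = sf, sn = sn)
}

gpr_predict <- function(fit, Xnew, se = FALSE) {
  r <- gpr_dist(Xnew, fit$X)
  Ks <- fit$sf^2 * gpr_kfun(fit$kernel, r, fit$ell)
  mu <- as.numeric(Ks %*% fit$alpha) + fit$ybar
  if (!se) return(list(mean = mu))
  V <- forwardsolve(t(fit$chol), t(Ks))
  var_lat <- pmax(fit$sf^2 * (1 + 1e-8) - colSums(V^2), 0)
  list(mean = mu, sd = sqrt(var_lat + fit$sn^2))
}
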