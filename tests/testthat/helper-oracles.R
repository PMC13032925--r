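# Independent numerical oracle for the ridge closed form: BFGS (with analytic
# gradient and restarts) on the penalized least-squares loss.
ridge_loss_min <- function(F_rate, X, lambda) {
  Z <- scale(as.matrix(X))
  p <- ncol(Z)
  loss <- function(b) sum((F_rate - b[1] - Z %*% b[-1])^2) +
    lambda * sum(b[-1]^2)
  grad <- function(b) {
    r <- as.numeric(F_rate - b[1] - Z %*% b[-1])
    c(-2 * sum(r), -2 * as.numeric(crossprod(Z, r)) + 2 * lambda * b[-1])
  }
  par <- rep(0, p + 1)
  for (k in 1:3)  # restarts sharpen the tail convergence
    par <- optim(par, loss, grad, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 2000))$par
  # BFGS stalls once loss differences fall under double precision; polish by
  # solving grad = 0 with a central-finite-difference Newton step
  h <- 1e-5
  for (k in 1:3) {
    g <- grad(par)
    J <- vapply(seq_along(par), function(j) {
      e <- numeric(length(par)); e[j] <- h
      (grad(par + e) - grad(par - e)) / (2 * h)
    }, numeric(length(par)))
    par <- par - solve(J, g)
  }
  par
}
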