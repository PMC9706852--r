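# Independent oracles used to cross-check the package's estimators.
# Deliberately brute-force and free of the code paths they verify.

# AUC by exhaustive enumeration of case-control pairs (ties count 1/2)
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# logistic ML by a hand-rolled Newton-Raphson on the score equations
oracle_logistic_newton <- function(X, y, tol = 1e-12, max_iter = 100) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(t(Xd) %*% (y - p))
    W <- p * (1 - p)
    H <- t(Xd) %*% (Xd * W)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = beta,
       loglik = sum(y * log(p) + (1 - y) * log(1 - p)))
}

# Cox partial likelihood by direct risk-set enumeration (tie-free data)
oracle_cox_partial_loglik <- function(time, status, x, beta) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small complete beta matrix with fixed values
toy_meth <- function(values, cpgs = NULL, samples = NULL,
                     scale = "beta") {
  if (is.null(cpgs)) cpgs <- sprintf("cg%08d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(cpgs, samples)
  meth_matrix(values, scale = scale)
}
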