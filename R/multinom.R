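## Weighted multinomial (polychotomous) logistic regression by Newton-
## Raphson on the multinomial log-likelihood; class 1 is the reference.
## Small, dense problems only (ABC rejection samples), so the full
## Hessian is built explicitly.  Returns NULL on failure/separation so
## callers can fall back to the categorical frequency estimator.
.multinom_fit <- function(y, X, w, max_iter = 100L, tol = 1e-8,
                          ridge = 1e-8) {
  K <- max(y)
  n <- nrow(X)
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  npar <- (K - 1L) * p
  beta <- rep(0, npar)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  loglik <- function(beta) {
    B <- matrix(beta, nrow = p)
    eta <- cbind(0, Xd %*% B)
    m <- apply(eta, 1L, max)
    sum(w * (rowSums(Y * eta) - (m + log(rowSums(exp(eta - m))))))
  }
  ll_old <- loglik(beta)
  for (it in seq_len(max_iter)) {
    B <- matrix(beta, nrow = p)
    eta <- cbind(0, Xd %*% B)
    eta <- eta - apply(eta, 1L, max)
    P <- exp(eta); P <- P / rowSums(P)
    grad <- numeric(npar)
    H <- matrix(0, npar, npar)
    for (k in 2:K) {
      idx <- ((k - 2L) * p + 1L):((k - 1L) * p)
      grad[idx] <- crossprod(Xd, w * (Y[, k] - P[, k]))
      for (l in 2:K) {
        jdx <- ((l - 2L) * p + 1L):((l - 1L) * p)
        wkl <- w * (P[, k] * ((k == l) - P[, l]))
        H[idx, jdx] <- crossprod(Xd, Xd * wkl)
      }
    }
    H <- H + diag(ridge, npar)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) return(NULL)
    ## step halving
    alpha <- 1
    repeat {
      beta_new <- beta + alpha * step
      ll_new <- loglik(beta_new)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { beta_new <- beta; ll_new <- ll_old; break }
    }
    conv <- abs(ll_new - ll_old) < tol * (abs(ll_old) + 1)
    beta <- beta_new; ll_old <- ll_new
    if (conv) break
  }
  if (any(abs(beta) > 50)) return(NULL)  # separation guard
  B <- matrix(beta, nrow = p)
  ## observed information for the delta-method CIs
  eta <- cbind(0, Xd %*% B)
  eta <- eta - apply(eta, 1L, max)
  P <- exp(eta); P <- P / rowSums(P)
  H <- matrix(0, npar, npar)
  for (k in 2:K) {
    idx <- ((k - 2L) * p + 1L):((k - 1L) * p)
    for (l in 2:K) {
      jdx <- ((l - 2L) * p + 1L):((l - 1L) * p)
      wkl <- w * (P[, k] * ((k == l) - P[, l]))
      H[idx, jdx] <- crossprod(Xd, Xd * wkl)
    }
  }
  vcov <- tryCatch(solve(H + diag(ridge, npar)), error = function(e) NULL)
  list(B = B, K = K, p = p, vcov = vcov, loglik = ll_old)
}

## fitted probabilities at covariates = 0, with delta-method 95% CIs
.multinom_probs_at_zero <- function(fit) {
  K <- fit$K; p <- fit$p
  eta0 <- c(0, fit$B[1, ])
  eta0 <- eta0 - max(eta0)
  pr <- exp(eta0) / sum(exp(eta0))
  se <- rep(NA_real_, K)
  if (!is.null(fit$vcov)) {
    ## intercept positions in the flattened parameter vector
    int_idx <- ((2:K) - 2L) * p + 1L
    V <- fit$vcov[int_idx, int_idx, drop = FALSE]
    for (k in seq_len(K)) {
      ## dp_k / d eta_l (l = 2..K): p_k (delta_kl - p_l)
      g <- vapply(2:K, function(l) pr[k] * ((k == l) - pr[l]), numeric(1))
      se[k] <- sqrt(max(0, drop(t(g) %*% V %*% g)))
    }
  }
  list(prob = pr, se = se)
}
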