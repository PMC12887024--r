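# Independent reference implementations used as oracles.  These never call
# into the package's own engines.

# NIPALS PLS1 in plain R (mean-centered), returning the coefficient vector
# for `ncomp` components.
nipals_pls_coef <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  E <- Xc
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, yc)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    q <- sum(yc * t) / tt
    E <- E - t %*% t(p)
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  B <- W %*% solve(t(P) %*% W, Q)
  list(coef = as.numeric(B), x_means = xm, y_mean = ym)
}

# Epsilon-SVR dual solved by exact pairwise coordinate descent on
# beta = alpha - alpha*:
#   min 1/2 b'Kb - y'b + eps * sum|b|   s.t.  sum b = 0,  |b_i| <= C
# Updates move along e_i - e_j, preserving the equality constraint; each
# 1-D piecewise-quadratic subproblem is solved exactly by candidate
# enumeration.  Converges to the global optimum of this convex QP.
svr_dual_oracle <- function(K, y, C, eps, sweeps = 2000, tol = 1e-12) {
  n <- length(y)
  b <- numeric(n)
  obj <- function(b) 0.5 * sum(b * (K %*% b)) - sum(y * b) + eps * sum(abs(b))
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    Kb <- as.numeric(K %*% b)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      q <- K[i, i] + K[j, j] - 2 * K[i, j]
      if (q <= 0) next
      g <- Kb[i] - Kb[j] - y[i] + y[j]
      lo <- max(-C - b[i], b[j] - C)
      hi <- min(C - b[i], b[j] + C)
      cand <- c(-b[i], b[j])
      for (a in c(-1, 1)) for (bb in c(-1, 1)) {
        cand <- c(cand, (-g - eps * a + eps * bb) / q)
      }
      cand <- unique(pmin(pmax(cand, lo), hi))
      f <- function(d) 0.5 * q * d^2 + g * d +
        eps * (abs(b[i] + d) + abs(b[j] - d) - abs(b[i]) - abs(b[j]))
      vals <- vapply(cand, f, numeric(1))
      d <- cand[which.min(vals)]
      if (min(vals) < -tol) {
        b[i] <- b[i] + d
        b[j] <- b[j] - d
        Kb <- Kb + d * (K[, i] - K[, j])
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # intercept from free support vectors (KKT): f(x_i) = y_i - sign(b_i)*eps
  Kb <- as.numeric(K %*% b)
  free <- which(abs(b) > 1e-8 & abs(b) < C - 1e-8)
  bias <- if (length(free)) {
    mean(y[free] - sign(b[free]) * eps - Kb[free])
  } else {
    mean(y - Kb)
  }
  list(beta = b, bias = bias, objective = obj(b))
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}
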