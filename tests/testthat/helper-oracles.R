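# Independent oracles used to validate the package implementations.

# Brute-force COW: exhaustive enumeration over all feasible boundary
# combinations, scoring with the same objective as the dynamic program
# (sum of segment Pearson correlations, degenerate-segment floor, tiny
# displacement penalty). Only usable on toy signals.
cow_bruteforce <- function(x, ref, seg, slack) {
  Lx <- length(x)
  Lr <- length(ref)
  N <- max(1, floor((Lr - 1) / seg + 0.5))
  v <- floor((0:N) * (Lr - 1) / N + 0.5)
  u <- floor((0:N) * (Lx - 1) / N + 0.5)
  pvar <- function(z) mean(z^2) - mean(z)^2
  xfloor <- 1e-10 * pvar(x)
  rfloor <- 1e-10 * pvar(ref)
  disp_pen <- 1e-6 / (slack + 1)^2

  segcor <- function(q, p, i) {
    len <- v[i + 1] - v[i] + 1
    refseg <- ref[(v[i] + 1):(v[i + 1] + 1)]
    refc <- refseg - mean(refseg)
    nrm2 <- sum(refc^2)
    if (nrm2 <= rfloor * len) return(0)
    pos <- q + (0:(len - 1)) * (p - q) / (len - 1)
    i0 <- pmin(floor(pos), p - 1)
    fr <- pos - i0
    vv <- x[i0 + 1] * (1 - fr) + x[i0 + 2] * fr
    ss <- sum(vv^2) - len * mean(vv)^2
    if (ss <= xfloor * len) return(0)
    sum(vv * refc) / sqrt(ss * nrm2)
  }

  best <- list(score = -Inf, bounds = NULL)
  recurse <- function(bounds, score) {
    i <- length(bounds)  # boundaries fixed so far: 0 .. i-1
    if (i == N) {
      p <- Lx - 1
      d <- u[N + 1] - u[N]
      step <- p - bounds[i]
      if (step < max(2, d - slack) || step > d + slack) return()
      sc <- score + segcor(bounds[i], p, N) -
        disp_pen * (p - u[N + 1])^2
      if (sc > best$score) best <<- list(score = sc,
                                         bounds = c(bounds, p))
      return()
    }
    d <- u[i + 1] - u[i]
    for (p in (bounds[i] + max(2, d - slack)):(bounds[i] + d + slack)) {
      if (p > Lx - 1) next
      sc <- score + segcor(bounds[i], p, i) - disp_pen * (p - u[i + 1])^2
      recurse(c(bounds, p), sc)
    }
  }
  recurse(0, 0)
  best
}

# Eigendecomposition-based PLS2: the dominant eigenvector of X'YY'X gives
# each component's weight vector; deflation as in NIPALS.
pls2_eigen_oracle <- function(X, Y, A) {
  p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(X), 0)
  C <- matrix(0, ncol(Y), 0)
  for (a in seq_len(A)) {
    M <- crossprod(X, Y)          # p x m
    e <- eigen(M %*% t(M), symmetric = TRUE)
    w <- e$vectors[, 1]
    t <- X %*% w
    tt <- sum(t^2)
    cv <- crossprod(Y, t) / tt
    pv <- crossprod(X, t) / tt
    X <- X - t %*% t(pv)
    Y <- Y - t %*% t(cv)
    W <- cbind(W, w)
    P <- cbind(P, pv)
    C <- cbind(C, cv)
    Tm <- cbind(Tm, t)
  }
  list(W = W, P = P, C = C, T = Tm)
}

# Sign-insensitive column-wise comparison of two matrices.
expect_equal_up_to_sign <- function(A, B, tol = 1e-8) {
  expect_equal(dim(A), dim(B))
  for (j in seq_len(ncol(A))) {
    d <- min(max(abs(A[, j] - B[, j])), max(abs(A[, j] + B[, j])))
    expect_lt(d, tol)
  }
}

# Small smooth toy signal with structure everywhere (no degenerate
# segments), for warping tests.
toy_signal <- function(n, seed) {
  set.seed(seed)
  t <- seq(0, 1, length.out = n)
  rowSums(sapply(1:4, function(k) {
    runif(1, 0.5, 1.5) * sin(2 * pi * k * t + runif(1, 0, 2 * pi))
  }))
}
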