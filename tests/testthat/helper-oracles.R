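# Independent oracles, deliberately built on different algorithms than the
# implementation: the SBM fractional programs are minimized by exhaustive
# vertex enumeration of their polyhedra (no LP, no Charnes-Cooper), and
# betweenness path counts come from adjacency-power walk counting.

# minimize a linear-fractional objective over {v : G v <= h} by enumerating
# basic feasible points; valid because a linear-fractional program with
# positive denominator on the (pointed, optimum-attaining) feasible set takes
# its minimum at a vertex
enumerate_min_ratio <- function(G, h, num_fun, den_fun) {
  d <- ncol(G)
  best <- Inf
  combs <- utils::combn(nrow(G), d)
  for (ci in seq_len(ncol(combs))) {
    idx <- combs[, ci]
    Gs <- G[idx, , drop = FALSE]
    v <- tryCatch(solve(Gs, h[idx]), error = function(e) NULL)
    if (is.null(v)) next
    if (any(G %*% v > h + 1e-8 * (1 + abs(h)))) next
    den <- den_fun(v)
    if (den <= 1e-12) next
    val <- num_fun(v) / den
    if (val < best) best <- val
  }
  best
}

# SBM efficiency of DMU k by direct minimization of the ratio over lambda
oracle_sbm <- function(X, Yg, Yb, k) {
  m <- nrow(X); n <- ncol(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  x0 <- X[, k]; yg0 <- Yg[, k]; yb0 <- Yb[, k]
  G <- rbind(-diag(n), X, -Yg, Yb)
  h <- c(rep(0, n), x0, -yg0, yb0)
  enumerate_min_ratio(G, h,
    num_fun = function(l) 1 - mean((x0 - as.numeric(X %*% l)) / x0),
    den_fun = function(l) 1 + (sum((as.numeric(Yg %*% l) - yg0) / yg0) +
                               sum((yb0 - as.numeric(Yb %*% l)) / yb0)) /
                              (s1 + s2))
}

# super-SBM of an efficient DMU k by direct minimization over
# (lambda_-k, xbar, ygbar, ybbar)
oracle_super_sbm <- function(X, Yg, Yb, k) {
  m <- nrow(X); n <- ncol(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  x0 <- X[, k]; yg0 <- Yg[, k]; yb0 <- Yb[, k]
  Xr <- X[, -k, drop = FALSE]; Ygr <- Yg[, -k, drop = FALSE]
  Ybr <- Yb[, -k, drop = FALSE]
  np <- n - 1L
  d <- np + m + s1 + s2
  iL <- seq_len(np); iX <- np + seq_len(m); iG <- np + m + seq_len(s1)
  iB <- np + m + s1 + seq_len(s2)
  row_of <- function(cols, vals) { r <- numeric(d); r[cols] <- vals; r }
  G <- rbind(
    -diag(d)[iL, , drop = FALSE],                              # lambda >= 0
    t(vapply(seq_len(m), function(i)
      row_of(c(iL, iX[i]), c(Xr[i, ], -1)), numeric(d))),      # Xr l <= xbar
    -diag(d)[iX, , drop = FALSE],                              # xbar >= x0
    t(vapply(seq_len(s1), function(r)
      row_of(c(iL, iG[r]), c(-Ygr[r, ], 1)), numeric(d))),     # ygbar <= Ygr l
    diag(d)[iG, , drop = FALSE],                               # ygbar <= yg0
    -diag(d)[iG, , drop = FALSE],                              # ygbar >= 0
    t(vapply(seq_len(s2), function(t2)
      row_of(c(iL, iB[t2]), c(Ybr[t2, ], -1)), numeric(d))),   # ybbar >= Ybr l
    -diag(d)[iB, , drop = FALSE])                              # ybbar >= yb0
  h <- c(rep(0, np), rep(0, m), -x0, rep(0, s1), yg0, rep(0, s1),
         rep(0, s2), -yb0)
  enumerate_min_ratio(G, h,
    num_fun = function(v) (sum(v[iX] / x0) + sum(v[iB] / yb0)) / (m + s2),
    den_fun = function(v) sum(v[iG] / yg0) / s1)
}

# walk-counting betweenness for tiny graphs: with M binary symmetric, the
# number of geodesics j->k equals (M^d)[j,k] at the geodesic length d, and the
# number through i is the product of the two leg counts when lengths add up
brute_betweenness <- function(M, normalized = TRUE) {
  n <- nrow(M)
  pw <- list(diag(n))
  for (L in seq_len(n)) pw[[L + 1L]] <- pw[[L]] %*% M
  dist <- matrix(Inf, n, n)
  for (L in 0:n) {
    hit <- pw[[L + 1L]] > 0 & is.infinite(dist)
    dist[hit] <- L
  }
  counts <- function(j, k) {
    if (is.infinite(dist[j, k])) return(0)
    pw[[dist[j, k] + 1L]][j, k]
  }
  bc <- numeric(n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    if (is.infinite(dist[j, k])) next
    tot <- counts(j, k)
    for (i in seq_len(n)) {
      if (i == j || i == k) next
      if (is.finite(dist[j, i]) && is.finite(dist[i, k]) &&
          dist[j, i] + dist[i, k] == dist[j, k])
        bc[i] <- bc[i] + counts(j, i) * counts(i, k) / tot
    }
  }
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}
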