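# SBM and super-SBM scoring: analytic cases, invariances, monotonicity and
# equivalence with the vertex-enumeration oracle for the fractional programs.

test_that("analytic SBM cases solve exactly", {
  # single DMU against itself sits on the frontier with zero slacks
  d1 <- dea_dataset(matrix(2, 1), matrix(3, 1), matrix(1, 1))
  s <- solve_sbm(d1, 1)
  expect_equal(s$rho, 1, tolerance = 1e-9)
  expect_true(all(abs(unlist(s$slacks)) < 1e-9))

  # A=(1,1,1) dominates B=(2,1,1): rho(B) = (1 - 1/2) / 1 = 0.5
  d <- dea_dataset(matrix(c(1, 2), 1), matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  sB <- solve_sbm(d, 2)
  expect_equal(sB$rho, 0.5, tolerance = 1e-9)
  expect_equal(sB$slacks$s_in, 1, tolerance = 1e-8)
  expect_equal(solve_sbm(d, 1)$rho, 1, tolerance = 1e-9)

  # a DMU dominated in one input with equal outputs scores below 1
  d2 <- dea_dataset(matrix(c(1, 1, 2, 1), 2), matrix(c(3, 3), 1),
                    matrix(c(1, 1), 1))
  expect_lt(solve_sbm(d2, 2)$rho, 1)
})

test_that("analytic super-SBM cases solve exactly", {
  # identical peers: the excluded point is reproduced exactly, delta = 1
  d2 <- dea_dataset(matrix(c(1, 1), 1), matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_equal(solve_super_sbm(d2, 1)$delta, 1, tolerance = 1e-9)
  # dominating DMU vs its only peer (x 1 vs 2, outputs equal): the minimal
  # worsening is xbar = 2 while the bad stays put, so
  # delta = ((2/1 + 1/1) / 2) / 1 = 1.5 (value frozen from oracle_super_sbm)
  d <- dea_dataset(matrix(c(1, 2), 1), matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_equal(solve_super_sbm(d, 1)$delta, 1.5, tolerance = 1e-8)
  expect_equal(oracle_super_sbm(d$X, d$Yg, d$Yb, 1), 1.5, tolerance = 1e-10)
  # single DMU in scope has no residual frontier
  d1 <- dea_dataset(matrix(1, 1), matrix(1, 1), matrix(1, 1))
  expect_error(solve_super_sbm(d1, 1), "peer")
})

test_that("removing a non-referenced DMU leaves super-efficiency unchanged", {
  set.seed(21)
  d <- rand_dea(n = 6)
  rho <- vapply(1:6, function(k) solve_sbm(d, k)$rho, numeric(1))
  eff <- which(rho >= 1 - 1e-7)
  ineff <- which(rho < 1 - 1e-4)
  expect_gte(length(eff), 1)   # this seed yields both frontier and dominated
  expect_gte(length(ineff), 1)
  k <- eff[1]
  s_full <- solve_super_sbm(d, k)
  unref <- ineff[!ineff %in% which(s_full$lambda > 1e-9) & ineff != k]
  expect_gte(length(unref), 1)
  drop <- unref[1]
  d_red <- dea_dataset(d$X[, -drop, drop = FALSE], d$Yg[, -drop, drop = FALSE],
                       d$Yb[, -drop, drop = FALSE])
  k_red <- k - (drop < k)
  expect_equal(solve_super_sbm(d_red, k_red)$delta, s_full$delta,
               tolerance = 1e-8)
})

test_that("LP optimum matches the fractional-program oracle on random instances", {
  set.seed(31)
  for (i in 1:25) {
    d <- rand_dea(n = 5, m = 2, s1 = 1, s2 = 1)
    for (k in 1:5) {
      rho <- solve_sbm(d, k)$rho
      expect_equal(rho, oracle_sbm(d$X, d$Yg, d$Yb, k), tolerance = 1e-6)
    }
  }
})

test_that("super-SBM matches the oracle on random frontier DMUs", {
  set.seed(41)
  found <- 0
  while (found < 12) {
    d <- rand_dea(n = 5, m = 2, s1 = 1, s2 = 1)
    rho <- vapply(1:5, function(k) solve_sbm(d, k)$rho, numeric(1))
    for (k in which(rho >= 1 - 1e-7)) {
      delta <- solve_super_sbm(d, k)$delta
      expect_equal(delta, oracle_super_sbm(d$X, d$Yg, d$Yb, k),
                   tolerance = 1e-6)
      expect_gte(delta, 1 - 1e-8)
      found <- found + 1
    }
  }
})

test_that("scores are units-invariant under column rescaling", {
  set.seed(51)
  d <- rand_dea(n = 8, m = 3, s1 = 2, s2 = 1)
  base <- vapply(1:8, function(k) solve_sbm(d, k)$rho, numeric(1))
  for (scale_what in c("input", "good", "bad")) {
    X <- d$X; Yg <- d$Yg; Yb <- d$Yb
    if (scale_what == "input") X[2, ] <- X[2, ] * 1000
    if (scale_what == "good") Yg[1, ] <- Yg[1, ] * 0.001
    if (scale_what == "bad") Yb[1, ] <- Yb[1, ] * 250
    d2 <- dea_dataset(X, Yg, Yb)
    r2 <- vapply(1:8, function(k) solve_sbm(d2, k)$rho, numeric(1))
    expect_equal(r2, base, tolerance = 1e-9)
  }
})

test_that("increasing one input of a dominated DMU never raises its score", {
  set.seed(61)
  for (i in 1:10) {
    d <- rand_dea(n = 6, m = 2, s1 = 1, s2 = 1)
    rho <- vapply(1:6, function(k) solve_sbm(d, k)$rho, numeric(1))
    k <- which(rho < 1 - 1e-4)[1]
    if (is.na(k)) next
    X2 <- d$X
    X2[1, k] <- X2[1, k] * (1 + runif(1, 0.05, 0.5))
    d2 <- dea_dataset(X2, d$Yg, d$Yb)
    expect_lte(solve_sbm(d2, k)$rho, rho[k] + 1e-8)
  }
})

test_that("score_panel: frontier membership, determinism and grade columns", {
  cfg <- synthetic_config(n_cities = 8, years = 2010:2011, seed = 9,
                          n_provinces = 2, efficiency_gradient = c(1, 0.6),
                          noise_cv = 0.1)
  ws <- generate_panel(cfg)
  sc <- score_panel(ws$panel)
  expect_equal(nrow(sc), 16L)
  expect_true(all(sc$P > 0))
  expect_true(all(sc$rho <= 1 + 1e-9))
  expect_true(all(is.na(sc$delta) | sc$delta >= 1 - 1e-8))
  expect_equal(sc$grade, classify_grade(sc$P))
  # frontier units and only frontier units carry a super score
  expect_identical(!is.na(sc$delta), sc$rho >= 1 - 1e-7)
  sc2 <- score_panel(ws$panel)
  expect_identical(sc, sc2)
})

test_that("with noiseless data the province productivity gradient orders scores", {
  cfg <- synthetic_config(n_cities = 8, years = 2010:2010, seed = 13,
                          n_provinces = 2, efficiency_gradient = c(1, 0.5),
                          noise_cv = 0)
  ws <- generate_panel(cfg)
  sc <- score_panel(ws$panel)
  hi <- sc$P[sc$province == "P1"]
  lo <- sc$P[sc$province == "P2"]
  expect_true(min(hi) >= max(lo) - 1e-8)
})

test_that("pooled scope scores across all years at once", {
  cfg <- synthetic_config(n_cities = 5, years = 2010:2012, seed = 15)
  ws <- generate_panel(cfg)
  sc <- score_panel(ws$panel, scope = "pooled")
  # pooled frontier has at most as many efficient units as the union of
  # per-year frontiers
  scy <- score_panel(ws$panel, scope = "per-year")
  expect_lte(sum(sc$rho >= 1 - 1e-7), sum(scy$rho >= 1 - 1e-7))
  expect_true(all(sc$P > 0))
})
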