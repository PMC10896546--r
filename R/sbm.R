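# Slacks-based measure (SBM) of efficiency with an undesirable output, and
# super-efficiency SBM for frontier units, via Charnes-Cooper linearization of
# the fractional programs.

#' Assemble a DEA dataset
#'
#' @param X inputs matrix, m rows (inputs) x n columns (DMUs), all > 0.
#' @param Yg desirable-output matrix, s1 x n, all > 0.
#' @param Yb undesirable-output matrix, s2 x n, all > 0.
#' @param dmu_ids DMU identifiers (default column names or indices).
#' @return list of class `dea_dataset`.
#' @export
dea_dataset <- function(X, Yg, Yb, dmu_ids = NULL) {
  X <- as.matrix(X); Yg <- as.matrix(Yg); Yb <- as.matrix(Yb)
  n <- ncol(X)
  if (ncol(Yg) != n || ncol(Yb) != n)
    stop("X, Yg, Yb must have one column per DMU")
  if (any(X <= 0) || any(Yg <= 0) || any(Yb <= 0))
    stop("all DEA entries must be strictly positive")
  if (is.null(dmu_ids)) dmu_ids <- colnames(X)
  if (is.null(dmu_ids)) dmu_ids <- as.character(seq_len(n))
  structure(list(X = X, Yg = Yg, Yb = Yb, dmu_ids = as.character(dmu_ids)),
            class = "dea_dataset")
}

#' @export
print.dea_dataset <- function(x, ...) {
  cat("DEA dataset: ", ncol(x$X), " DMUs, ", nrow(x$X), " inputs, ",
      nrow(x$Yg), " desirable and ", nrow(x$Yb), " undesirable outputs\n",
      sep = "")
  invisible(x)
}

# shared LP scaffolding ------------------------------------------------------

# Linearized SBM for DMU k (reference set includes k).
# rho* = min [1 - (1/m) sum s-_i/x_i0] / [1 + 1/(s1+s2) (sum sg_r/yg_r0 + sum sb_t/yb_t0)]
# s.t. x0 = X lam + s-, yg0 = Yg lam - sg, yb0 = Yb lam + sb, all vars >= 0.
# Charnes-Cooper: scale every variable by t, pin the denominator to 1.
sbm_lp <- function(data, k, rts) {
  X <- data$X; Yg <- data$Yg; Yb <- data$Yb
  m <- nrow(X); n <- ncol(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  x0 <- X[, k]; yg0 <- Yg[, k]; yb0 <- Yb[, k]
  nv <- 1 + n + m + s1 + s2
  iT <- 1L; iL <- 1L + seq_len(n); iSm <- 1L + n + seq_len(m)
  iSg <- 1L + n + m + seq_len(s1); iSb <- 1L + n + m + s1 + seq_len(s2)
  obj <- numeric(nv); obj[iT] <- 1; obj[iSm] <- -1 / (m * x0)
  nr <- 1 + m + s1 + s2 + (rts == "vrs")
  A <- matrix(0, nr, nv); b <- numeric(nr)
  A[1, iT] <- 1
  A[1, iSg] <- 1 / ((s1 + s2) * yg0)
  A[1, iSb] <- 1 / ((s1 + s2) * yb0)
  b[1] <- 1
  for (i in seq_len(m)) {
    r <- 1L + i
    A[r, iT] <- x0[i]; A[r, iL] <- -X[i, ]; A[r, iSm[i]] <- -1
  }
  for (rr in seq_len(s1)) {
    r <- 1L + m + rr
    A[r, iT] <- yg0[rr]; A[r, iL] <- -Yg[rr, ]; A[r, iSg[rr]] <- 1
  }
  for (tt in seq_len(s2)) {
    r <- 1L + m + s1 + tt
    A[r, iT] <- yb0[tt]; A[r, iL] <- -Yb[tt, ]; A[r, iSb[tt]] <- -1
  }
  if (rts == "vrs") {
    r <- nr
    A[r, iL] <- 1; A[r, iT] <- -1
  }
  list(obj = obj, A = A, b = b, dir = rep("=", nr),
       idx = list(t = iT, lambda = iL, s_in = iSm, s_good = iSg, s_bad = iSb))
}

#' Solve the SBM program for one DMU
#'
#' Computes the slacks-based efficiency score rho in (0, 1] under the chosen
#' returns-to-scale assumption, with the DMU's carbon-type undesirable outputs
#' entering the constraints in the input direction. rho = 1 exactly when all
#' optimal slacks are zero (the DMU lies on the frontier).
#'
#' @param data a [dea_dataset()].
#' @param dmu DMU index or id.
#' @param rts `"crs"` (constant returns, default) or `"vrs"` (adds
#'   `sum(lambda) = 1` in de-scaled terms).
#' @return list of class `sbm_score`: `rho`, de-scaled `slacks` (`s_in`,
#'   `s_good`, `s_bad`), `lambda`, `lp_status`.
#' @export
solve_sbm <- function(data, dmu, rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  k <- resolve_dmu(data, dmu)
  lp <- sbm_lp(data, k, rts)
  sol <- solve_lp(lp$obj, lp$A, lp$b, lp$dir)
  if (sol$status != "optimal")
    stop("SBM LP did not solve for DMU ", data$dmu_ids[k],
         " (lp_status: ", sol$status, ")")
  t <- sol$x[lp$idx$t]
  if (t <= 1e-12)
    stop("SBM LP degenerate scale factor for DMU ", data$dmu_ids[k],
         " (lp_status: t=0)")
  structure(list(
    dmu_id = data$dmu_ids[k],
    rho = sol$value,
    slacks = list(s_in = sol$x[lp$idx$s_in] / t,
                  s_good = sol$x[lp$idx$s_good] / t,
                  s_bad = sol$x[lp$idx$s_bad] / t),
    lambda = sol$x[lp$idx$lambda] / t,
    lp_status = sol$status), class = "sbm_score")
}

# Linearized super-efficiency SBM for an efficient DMU k (reference set
# excludes k). The evaluated point may be worsened to reach the residual
# frontier; the undesirable output is treated direction-wise like an input:
# delta* = min [1/(m+s2) (sum xbar_i/x_i0 + sum ybbar_t/yb_t0)] /
#              [(1/s1) sum ygbar_r/yg_r0]
# s.t. xbar >= X_-k lam, ygbar <= Yg_-k lam, ybbar >= Yb_-k lam,
#      xbar >= x0, 0 <= ygbar <= yg0, ybbar >= yb0, lam >= 0.
super_sbm_lp <- function(data, k, rts) {
  X <- data$X; Yg <- data$Yg; Yb <- data$Yb
  m <- nrow(X); n <- ncol(X); s1 <- nrow(Yg); s2 <- nrow(Yb)
  x0 <- X[, k]; yg0 <- Yg[, k]; yb0 <- Yb[, k]
  Xr <- X[, -k, drop = FALSE]; Ygr <- Yg[, -k, drop = FALSE]
  Ybr <- Yb[, -k, drop = FALSE]
  np <- n - 1L
  nv <- 1L + np + m + s1 + s2
  iT <- 1L; iL <- 1L + seq_len(np); iX <- 1L + np + seq_len(m)
  iG <- 1L + np + m + seq_len(s1); iB <- 1L + np + m + s1 + seq_len(s2)
  obj <- numeric(nv)
  obj[iX] <- 1 / ((m + s2) * x0)
  obj[iB] <- 1 / ((m + s2) * yb0)
  rows <- list(); dirs <- c(); bs <- c()
  add <- function(v, d, rhs) {
    rows[[length(rows) + 1L]] <<- v; dirs <<- c(dirs, d); bs <<- c(bs, rhs)
  }
  # denominator normalization
  v <- numeric(nv); v[iG] <- 1 / (s1 * yg0); add(v, "=", 1)
  for (i in seq_len(m)) {
    v <- numeric(nv); v[iX[i]] <- 1; v[iL] <- -Xr[i, ]; add(v, ">=", 0)
    v <- numeric(nv); v[iX[i]] <- 1; v[iT] <- -x0[i];   add(v, ">=", 0)
  }
  for (r in seq_len(s1)) {
    v <- numeric(nv); v[iL] <- Ygr[r, ]; v[iG[r]] <- -1; add(v, ">=", 0)
    v <- numeric(nv); v[iT] <- yg0[r];  v[iG[r]] <- -1; add(v, ">=", 0)
  }
  for (t2 in seq_len(s2)) {
    v <- numeric(nv); v[iB[t2]] <- 1; v[iL] <- -Ybr[t2, ]; add(v, ">=", 0)
    v <- numeric(nv); v[iB[t2]] <- 1; v[iT] <- -yb0[t2];   add(v, ">=", 0)
  }
  if (rts == "vrs") { v <- numeric(nv); v[iL] <- 1; v[iT] <- -1; add(v, "=", 0) }
  A <- do.call(rbind, rows)
  list(obj = obj, A = A, b = bs, dir = dirs,
       idx = list(t = iT, lambda = iL, xbar = iX, ygbar = iG, ybbar = iB))
}

#' Solve the super-efficiency SBM program for a frontier DMU
#'
#' Re-evaluates an SBM-efficient DMU against the frontier formed without it,
#' allowing the point to be worsened (inputs and undesirable outputs expanded,
#' desirable outputs retained) to reach the residual frontier; the score
#' delta >= 1 ranks efficient units. Undesirable outputs are treated
#' direction-wise like inputs (one of several published variants; see the
#' methods vignette).
#'
#' @inheritParams solve_sbm
#' @return list of class `super_sbm_score`: `delta`, `lambda`, `lp_status`.
#' @export
solve_super_sbm <- function(data, dmu, rts = c("crs", "vrs")) {
  rts <- match.arg(rts)
  k <- resolve_dmu(data, dmu)
  if (ncol(data$X) < 2)
    stop("super-efficiency needs at least one peer DMU in scope")
  lp <- super_sbm_lp(data, k, rts)
  sol <- solve_lp(lp$obj, lp$A, lp$b, lp$dir)
  if (sol$status != "optimal")
    stop("super-SBM LP did not solve for DMU ", data$dmu_ids[k],
         " (lp_status: ", sol$status, ")")
  t <- sol$x[lp$idx$t]
  if (t <= 1e-12)
    stop("super-SBM LP degenerate scale factor for DMU ", data$dmu_ids[k])
  structure(list(dmu_id = data$dmu_ids[k],
                 delta = sol$value,
                 lambda = sol$x[lp$idx$lambda] / t,
                 lp_status = sol$status), class = "super_sbm_score")
}

resolve_dmu <- function(data, dmu) {
  if (is.character(dmu)) {
    k <- match(dmu, data$dmu_ids)
    if (is.na(k)) stop("unknown DMU id: ", dmu)
    return(k)
  }
  k <- as.integer(dmu)
  if (k < 1 || k > ncol(data$X)) stop("DMU index out of range")
  k
}

# rho within this distance of 1 counts as efficient (triggers super-SBM)
EFFICIENT_TOL <- 1e-7

#' Score a whole panel by (super-)SBM efficiency
#'
#' For each frontier scope group (each year separately by default, matching
#' annual cross-section reporting; or all city-years pooled), computes rho for
#' every city and, for cities with rho = 1, the super-efficiency delta against
#' the residual frontier. The final score is P = rho if rho < 1 else delta;
#' P is the mass term the gravity network uses. Carbon emissions computed from
#' the panel's carbon sources are the sole undesirable output.
#'
#' @param panel an `eep_panel`.
#' @param coef carbon-coefficient table (see [read_carbon_coefficients()]).
#' @param scope `"per-year"` (default) or `"pooled"`.
#' @param rts `"crs"` (default) or `"vrs"`.
#' @return data.frame of class `efficiency_table`: `city_id`, `province`,
#'   `year`, `rho`, `delta` (NA for non-frontier units), `P`, `grade`,
#'   `lp_status`. Deterministic given inputs and options.
#' @export
score_panel <- function(panel, coef = read_carbon_coefficients(),
                        scope = c("per-year", "pooled"),
                        rts = c("crs", "vrs")) {
  scope <- match.arg(scope)
  rts <- match.arg(rts)
  emis <- carbon_emissions(panel, coef)
  if (any(emis <= 0))
    stop("carbon emissions must be strictly positive to enter the SBM; ",
         "zero-emission record at row ", which(emis <= 0)[1L])
  df <- as.data.frame(panel)
  df$.emis <- emis
  groups <- if (scope == "per-year") split(df, df$year) else list(pooled = df)
  out <- lapply(groups, function(g) {
    ids <- if (scope == "per-year") g$city_id else paste(g$city_id, g$year)
    data <- dea_dataset(t(as.matrix(g[, DEA_INPUTS])),
                        t(as.matrix(g[, DEA_GOODS])),
                        matrix(g$.emis, nrow = 1), dmu_ids = ids)
    n <- nrow(g)
    rho <- delta <- rep(NA_real_, n)
    status <- character(n)
    for (k in seq_len(n)) {
      s <- tryCatch(solve_sbm(data, k, rts), error = function(e)
        stop("SBM failed for (", g$city_id[k], ", ", g$year[k], "): ",
             conditionMessage(e)))
      rho[k] <- s$rho
      status[k] <- s$lp_status
    }
    eff <- rho >= 1 - EFFICIENT_TOL
    for (k in which(eff)) {
      s <- tryCatch(solve_super_sbm(data, k, rts), error = function(e)
        stop("super-SBM failed for (", g$city_id[k], ", ", g$year[k], "): ",
             conditionMessage(e)))
      delta[k] <- s$delta
    }
    P <- ifelse(eff, delta, rho)
    data.frame(city_id = g$city_id, province = g$province, year = g$year,
               rho = rho, delta = delta, P = P, grade = classify_grade(P),
               lp_status = status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  cities <- attr(panel, "cities")
  res <- res[order(res$year, match(res$city_id, cities)), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("efficiency_table", "data.frame")
  res
}

#' @export
print.efficiency_table <- function(x, ...) {
  cat("Efficiency scores: ", length(unique(x$city_id)), " cities x ",
      length(unique(x$year)), " years; mean P = ",
      format(mean(x$P), digits = 4), "; ",
      sum(x$rho >= 1 - EFFICIENT_TOL), " frontier city-years\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
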