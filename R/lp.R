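# Dense two-phase simplex for the small, heavily degenerate linear programs
# arising from SBM/super-SBM linearizations (tens of variables, <20 rows).
# Row and column equilibration keep the tableau well-scaled; pivots prefer
# large elements (Dantzig entering, largest-pivot ratio ties) and fall back to
# Bland's least-index rule on degenerate stalls so termination is guaranteed.

#' Solve a small linear program
#'
#' Minimizes `obj %*% x` subject to `A %*% x (dir) b` and `x >= 0`, where `dir`
#' is one of `"="`, `"<="`, `">="` per row. Intended for the small degenerate
#' programs of DEA linearizations, not for large-scale use; the returned
#' solution is verified against the original constraints.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param dir character vector of row directions, `"="`, `"<="` or `">="`.
#' @param tol reduced-cost/feasibility tolerance on the equilibrated tableau.
#' @param maxit maximum number of pivots per phase.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"maxit"`, `"numerical"`), `x` (primal solution on the original
#'   variables) and `value` (objective at `x`).
#' @keywords internal
solve_lp <- function(obj, A, b, dir = rep("=", length(b)),
                     tol = 1e-9, maxit = 20000L) {
  stopifnot(is.matrix(A), length(obj) == ncol(A), length(b) == nrow(A),
            length(dir) == nrow(A), all(dir %in% c("=", "<=", ">=")))
  m <- nrow(A)
  n <- ncol(A)

  # standard form: slack (+1) for "<=", surplus (-1) for ">="
  n_slack <- sum(dir != "=")
  As <- cbind(A, matrix(0, m, n_slack))
  sj <- n
  for (i in seq_len(m)) {
    if (dir[i] == "<=") { sj <- sj + 1L; As[i, sj] <- 1 }
    if (dir[i] == ">=") { sj <- sj + 1L; As[i, sj] <- -1 }
  }
  ns <- n + n_slack

  # equilibrate: rows then columns (powers kept implicit; solution de-scaled)
  rsc <- apply(abs(As), 1, max); rsc[rsc == 0] <- 1
  As <- As / rsc
  bs <- b / rsc
  csc <- apply(abs(As), 2, max); csc[csc == 0] <- 1
  As <- sweep(As, 2, csc, "/")          # x = x_scaled / csc
  neg <- bs < 0
  if (any(neg)) { As[neg, ] <- -As[neg, , drop = FALSE]; bs[neg] <- -bs[neg] }

  Tb <- cbind(As, diag(m), bs)
  rhs_col <- ncol(Tb)
  basis <- ns + seq_len(m)

  simplex_phase <- function(Tb, basis, cost, ncols) {
    # cost: length ncols (+ zeros for any artificials still in the tableau)
    z <- cost - as.numeric(cost[basis] %*% Tb[, seq_len(length(cost)), drop = FALSE])
    it <- 0L
    stall <- 0L
    bland <- FALSE
    last_obj <- Inf
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "maxit", Tb = Tb, basis = basis))
      negc <- which(z[seq_len(ncols)] < -tol)
      if (!length(negc)) return(list(status = "optimal", Tb = Tb, basis = basis))
      pc <- if (bland) negc[1L] else negc[which.min(z[negc])]
      col <- Tb[, pc]
      cand <- which(col > 1e-9)
      if (!length(cand)) return(list(status = "unbounded", Tb = Tb, basis = basis))
      ratio <- Tb[cand, rhs_col] / col[cand]
      rmin <- min(ratio)
      tie <- cand[ratio <= rmin + tol * (1 + abs(rmin))]
      pr <- if (bland) tie[which.min(basis[tie])] else tie[which.max(col[tie])]
      piv <- Tb[pr, pc]
      Tb[pr, ] <- Tb[pr, ] / piv
      other <- setdiff(seq_len(nrow(Tb)), pr)
      if (length(other))
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, pc], Tb[pr, ])
      z <- z - z[pc] * Tb[pr, seq_along(z)]
      basis[pr] <- pc
      # anti-cycling: switch to Bland after a long degenerate stall
      cur_obj <- sum(cost[basis] * Tb[, rhs_col])
      if (cur_obj < last_obj - 1e-12) { stall <- 0L; last_obj <- cur_obj }
      else stall <- stall + 1L
      if (stall > 200L) bland <- TRUE
    }
  }

  # phase 1: minimize sum of artificials
  cost1 <- c(rep(0, ns), rep(1, m))
  r1 <- simplex_phase(Tb, basis, cost1, ns + m)
  if (r1$status != "optimal")
    return(list(status = r1$status, x = NULL, value = NA_real_))
  Tb <- r1$Tb; basis <- r1$basis
  art_rows <- which(basis > ns)
  p1 <- if (length(art_rows)) sum(Tb[art_rows, rhs_col]) else 0
  if (p1 > 1e-7)
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  # drive residual (degenerate) artificials out where a pivot exists
  for (pr in which(basis > ns)) {
    pc <- which(abs(Tb[pr, seq_len(ns)]) > 1e-7)
    if (length(pc)) {
      pc <- pc[which.max(abs(Tb[pr, pc]))]
      piv <- Tb[pr, pc]
      Tb[pr, ] <- Tb[pr, ] / piv
      other <- setdiff(seq_len(nrow(Tb)), pr)
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, pc], Tb[pr, ])
      basis[pr] <- pc
    }
  }
  keep <- basis <= ns
  if (!all(keep)) {   # redundant rows: artificial basic at zero level
    Tb <- Tb[keep, , drop = FALSE]
    basis <- basis[keep]
  }

  # phase 2 on the original objective (column-scaled)
  cost2 <- c(obj, rep(0, n_slack)) / csc
  Tb2 <- Tb[, c(seq_len(ns), rhs_col), drop = FALSE]
  rhs_col2 <- ncol(Tb2)
  simplex_phase2 <- function(Tb, basis, cost) {
    z <- cost - as.numeric(cost[basis] %*% Tb[, seq_len(length(cost)), drop = FALSE])
    it <- 0L; stall <- 0L; bland <- FALSE; last_obj <- Inf
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "maxit", Tb = Tb, basis = basis))
      negc <- which(z < -tol)
      if (!length(negc)) return(list(status = "optimal", Tb = Tb, basis = basis))
      pc <- if (bland) negc[1L] else negc[which.min(z[negc])]
      col <- Tb[, pc]
      cand <- which(col > 1e-9)
      if (!length(cand)) return(list(status = "unbounded", Tb = Tb, basis = basis))
      ratio <- Tb[cand, rhs_col2] / col[cand]
      rmin <- min(ratio)
      tie <- cand[ratio <= rmin + tol * (1 + abs(rmin))]
      pr <- if (bland) tie[which.min(basis[tie])] else tie[which.max(col[tie])]
      piv <- Tb[pr, pc]
      Tb[pr, ] <- Tb[pr, ] / piv
      other <- setdiff(seq_len(nrow(Tb)), pr)
      if (length(other))
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(Tb[other, pc], Tb[pr, ])
      z <- z - z[pc] * Tb[pr, seq_along(z)]
      basis[pr] <- pc
      cur_obj <- sum(cost[basis] * Tb[, rhs_col2])
      if (cur_obj < last_obj - 1e-12) { stall <- 0L; last_obj <- cur_obj }
      else stall <- stall + 1L
      if (stall > 200L) bland <- TRUE
    }
  }
  r2 <- simplex_phase2(Tb2, basis, cost2[seq_len(ns)])
  if (r2$status != "optimal")
    return(list(status = r2$status, x = NULL, value = NA_real_))
  xs <- numeric(ns)
  xs[r2$basis] <- r2$Tb[, rhs_col2]
  x <- (xs / csc)[seq_len(n)]
  # verify against the original constraints
  lhs <- as.numeric(A %*% x)
  resid <- max(c(0,
                 abs(lhs - b)[dir == "="],
                 (lhs - b)[dir == "<="],
                 (b - lhs)[dir == ">="]))
  scale_ref <- max(1, max(abs(b)))
  if (resid > 1e-6 * scale_ref || min(x) < -1e-8)
    return(list(status = "numerical", x = NULL, value = NA_real_))
  list(status = "optimal", x = pmax(x, 0), value = sum(obj * x))
}
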