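# QAP correlation and MRQAP permutation regression of the tie network on
# predictor matrices (attribute-difference matrices and spatial adjacency).
# Permutation inference preserves dyadic dependence by permuting node labels
# (rows and columns jointly).

offdiag <- function(M) M[row(M) != col(M)]

#' Absolute-difference predictor matrix from a per-city scalar
#'
#' cell (i, j) = |v_i - v_j|; symmetric, zero diagonal.
#'
#' @param values named numeric vector, one value per city.
#' @param cities canonical city order (default `names(values)`).
#' @return n x n matrix with city dimnames.
#' @export
difference_matrix <- function(values, cities = names(values)) {
  if (is.null(cities)) stop("city ids required (names or `cities`)")
  v <- values[cities]
  if (anyNA(v))
    stop("missing value for city: ",
         paste(cities[is.na(v)], collapse = ", "))
  M <- abs(outer(as.numeric(v), as.numeric(v), "-"))
  dimnames(M) <- list(cities, cities)
  M
}

#' Binary spatial adjacency matrix from a contiguity list
#'
#' Symmetric closure of the listed pairs, zero diagonal; listing a pair twice
#' (or in both orders) is idempotent.
#'
#' @param contiguity data.frame with columns `from`, `to` of city ids.
#' @param cities canonical city order.
#' @return binary n x n matrix with city dimnames.
#' @export
adjacency_matrix <- function(contiguity, cities) {
  n <- length(cities)
  S <- matrix(0L, n, n, dimnames = list(cities, cities))
  if (nrow(contiguity)) {
    i <- match(contiguity$from, cities)
    j <- match(contiguity$to, cities)
    if (anyNA(i) || anyNA(j))
      stop("unknown city id in contiguity list: ",
           paste(unique(c(contiguity$from[is.na(i)],
                          contiguity$to[is.na(j)])), collapse = ", "))
    S[cbind(i, j)] <- 1L
    S[cbind(j, i)] <- 1L
  }
  diag(S) <- 0L
  S
}

#' QAP correlation between two city matrices
#'
#' Pearson correlation of the vectorized off-diagonal entries, with a
#' permutation null built from simultaneous identical row-and-column
#' permutations of `X`. P-values use the add-one convention
#' p = (1 + #{extreme}) / (1 + n_perm), so they are never exactly zero; both
#' the two-tailed p (on |r|) and the one-tailed p in the direction of the
#' observed r are reported.
#'
#' @param R dependent matrix (tie network or numeric matrix).
#' @param X predictor matrix, same cities.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed (set for reproducibility).
#' @return list: `r`, `p_two`, `p_one`, `n_perm`, `seed`.
#' @export
qap_correlation <- function(R, X, n_perm = 5000L, seed = NULL) {
  R <- if (inherits(R, "tie_network")) R$A else as.matrix(R)
  X <- as.matrix(X)
  stopifnot(all(dim(R) == dim(X)))
  y <- offdiag(R)
  x <- offdiag(X)
  if (stats::sd(y) == 0 || stats::sd(x) == 0)
    stop("zero variance: QAP correlation undefined")
  r_obs <- stats::cor(y, x)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(R)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm[b] <- stats::cor(y, offdiag(X[p, p]))
  }
  eps <- 1e-12
  p_two <- (1 + sum(abs(r_perm) >= abs(r_obs) - eps)) / (1 + n_perm)
  p_one <- if (r_obs >= 0)
    (1 + sum(r_perm >= r_obs - eps)) / (1 + n_perm)
  else
    (1 + sum(r_perm <= r_obs + eps)) / (1 + n_perm)
  list(r = r_obs, p_two = p_two, p_one = p_one, n_perm = n_perm, seed = seed)
}

#' MRQAP: multiple regression of a tie matrix on predictor matrices
#'
#' OLS on the vectorized off-diagonal entries (a linear probability model for
#' a binary dependent network), with permutation-based coefficient tests.
#' `y-permutation` (default) permutes the dependent matrix's rows and columns
#' jointly and compares |beta|; `double-semi-partialing` (Dekker) permutes,
#' for each predictor, the matrix of its residuals on the other predictors.
#'
#' @param R dependent matrix (tie network or numeric matrix).
#' @param predictors named list of predictor matrices.
#' @param n_perm permutations (default 5000).
#' @param seed RNG seed.
#' @param method `"y-permutation"` or `"double-semi-partialing"`.
#' @return list of class `qap_result`: `coefficients` data.frame (`predictor`,
#'   `beta`, `p_two`, `p_one`, significance stars at 0.01/0.05/0.1),
#'   `r_squared`, `adj_r_squared`, `intercept`, `n_perm`, `seed`, `method`.
#' @export
mrqap_regression <- function(R, predictors, n_perm = 5000L, seed = NULL,
                             method = c("y-permutation",
                                        "double-semi-partialing")) {
  method <- match.arg(method)
  R <- if (inherits(R, "tie_network")) R$A else as.matrix(R)
  if (!length(predictors)) stop("at least one predictor is required")
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- paste0("X", seq_along(predictors))
  y <- offdiag(R)
  if (stats::sd(y) == 0) stop("zero-variance dependent matrix")
  Xcols <- vapply(predictors, function(M) offdiag(as.matrix(M)),
                  numeric(length(y)))
  p <- ncol(Xcols)
  # exact collinearity check, naming the offending pair where there is one
  if (p > 1) {
    cc <- suppressWarnings(stats::cor(Xcols))
    hit <- which(abs(cc) > 1 - 1e-12 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(hit))
      stop("exactly collinear predictors: ",
           colnames(Xcols)[hit[1, 1]], " and ", colnames(Xcols)[hit[1, 2]])
  }
  Xd <- cbind(`(Intercept)` = 1, Xcols)
  qr_X <- qr(Xd)
  if (qr_X$rank < ncol(Xd)) stop("rank-deficient predictor set")
  N <- length(y)
  beta <- qr.coef(qr_X, y)
  fit <- qr.fitted(qr_X, y)
  ss_res <- sum((y - fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (1 - r2) * (N - 1) / (N - p - 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(R)
  eps <- 1e-12
  exceed_two <- exceed_one <- numeric(p)
  if (method == "y-permutation") {
    # hat matrix rows for the predictors; X fixed, y permuted
    H <- solve(crossprod(Xd), t(Xd))
    for (b in seq_len(n_perm)) {
      pp <- sample.int(n)
      bp <- H %*% offdiag(R[pp, pp])
      bp <- bp[-1L]
      exceed_two <- exceed_two + (abs(bp) >= abs(beta[-1L]) - eps)
      exceed_one <- exceed_one +
        ifelse(beta[-1L] >= 0, bp >= beta[-1L] - eps, bp <= beta[-1L] + eps)
    }
  } else {
    # Dekker double semi-partialing: permute each predictor's residual matrix
    for (k in seq_len(p)) {
      Xk <- Xd[, -(k + 1L), drop = FALSE]
      qk <- qr(Xk)
      ek <- qr.resid(qk, Xcols[, k])
      # rebuild the residuals as a matrix to permute rows/columns jointly
      Ek <- matrix(0, n, n)
      Ek[row(Ek) != col(Ek)] <- ek
      My <- qr.resid(qk, y)
      # FWL: beta_k = <e, My> / <e, Me> for the column e orthogonalized on Xk
      for (b in seq_len(n_perm)) {
        pp <- sample.int(n)
        e <- offdiag(Ek[pp, pp])
        Me <- e - Xk %*% qr.coef(qk, e)
        bk <- sum(Me * My) / sum(Me * Me)
        exceed_two[k] <- exceed_two[k] + (abs(bk) >= abs(beta[k + 1L]) - eps)
        exceed_one[k] <- exceed_one[k] +
          if (beta[k + 1L] >= 0) (bk >= beta[k + 1L] - eps)
          else (bk <= beta[k + 1L] + eps)
      }
    }
  }
  p_two <- (1 + exceed_two) / (1 + n_perm)
  p_one <- (1 + exceed_one) / (1 + n_perm)
  stars <- ifelse(p_two < 0.01, "***",
                  ifelse(p_two < 0.05, "**", ifelse(p_two < 0.1, "*", "")))
  coefs <- data.frame(predictor = colnames(Xcols), beta = beta[-1L],
                      p_two = p_two, p_one = p_one, sig = stars,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, intercept = beta[[1L]],
                 r_squared = r2, adj_r_squared = adj_r2,
                 n_perm = n_perm, seed = seed, method = method),
            class = "qap_result")
}

#' @export
print.qap_result <- function(x, ...) {
  cat("MRQAP (", x$method, ", ", x$n_perm, " permutations)\n",
      "R-squared = ", format(x$r_squared, digits = 3),
      ", adjusted = ", format(x$adj_r_squared, digits = 3), "\n", sep = "")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Build the full QAP design from attributes and contiguity
#'
#' Predictors mirror the driver set of the spatial association analysis: six
#' absolute-difference matrices (agricultural-economy level = agri output
#' value / GDP share, urbanization rate, rural per-capita income, fertilizer
#' intensity, mechanization intensity, population) plus the binary spatial
#' adjacency matrix.
#'
#' @param attrs attribute table (see [read_attributes()]).
#' @param contiguity contiguity pair list (see [read_contiguity()]).
#' @param cities canonical city order (default the attribute table order).
#' @return named list of n x n predictor matrices.
#' @export
qap_design <- function(attrs, contiguity, cities = attrs$city_id) {
  attrs <- validate_attributes(attrs, cities)
  vals <- function(col) stats::setNames(attrs[[col]], attrs$city_id)
  list(
    agri_gdp_share          = difference_matrix(vals("agri_gdp_share")),
    urbanization_rate       = difference_matrix(vals("urbanization_rate")),
    rural_income            = difference_matrix(vals("rural_income")),
    fertilizer_intensity    = difference_matrix(vals("fertilizer_intensity")),
    mechanization_intensity = difference_matrix(vals("mechanization_intensity")),
    population              = difference_matrix(vals("population")),
    adjacency               = adjacency_matrix(contiguity, cities))
}
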