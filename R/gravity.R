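# Modified gravity model: directed association strengths from efficiency
# "masses" and great-circle distances, binarized at the matrix mean.

#' Great-circle distance matrix between cities
#'
#' Spherical (haversine) distances on radius 6371.0088 km from the attribute
#' table's lon/lat, in km. Symmetric, zero diagonal. Coincident coordinates for
#' distinct cities give a zero off-diagonal distance: warned here, and an error
#' at the gravity stage (division by zero).
#'
#' @param attrs attribute table with `city_id`, `lon`, `lat` (see
#'   [read_attributes()]).
#' @return n x n km matrix with city dimnames.
#' @export
distance_matrix <- function(attrs) {
  if (any(abs(attrs$lat) > 90) || any(abs(attrs$lon) > 180))
    stop("invalid coordinates")
  p <- cbind(attrs$lon, attrs$lat)
  D <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  dimnames(D) <- list(attrs$city_id, attrs$city_id)
  diag(D) <- 0
  off <- D[row(D) != col(D)]
  if (any(off == 0))
    warning("coincident coordinates: zero off-diagonal distance(s)")
  D
}

#' Directed gravity matrix of spatial association strengths
#'
#' S_ij = K_ij * M_i * M_j / D_ij^b with the asymmetric contribution rate
#' K_ij = M_i / (M_i + M_j), so that K_ij + K_ji = 1 and S_ij / S_ji =
#' M_i / M_j. Masses M are the cities' efficiency scores P; b is the distance
#' attenuation exponent (conventionally 2).
#'
#' @param M named numeric vector of positive per-city masses.
#' @param Dist n x n distance matrix (km), positive off-diagonal.
#' @param b attenuation exponent (default 2).
#' @return list of class `gravity_matrix`: `S` (strengths, zero diagonal),
#'   `K` (contribution rates), `M`, `Dist`, `b`.
#' @export
gravity_matrix <- function(M, Dist, b = 2) {
  n <- length(M)
  stopifnot(nrow(Dist) == n, ncol(Dist) == n)
  ids <- names(M)
  if (is.null(ids)) ids <- rownames(Dist)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (any(M <= 0)) {
    bad <- ids[which(M <= 0)[1L]]
    stop("non-positive mass for city ", bad)
  }
  off <- row(Dist) != col(Dist)
  if (any(Dist[off] <= 0)) {
    w <- which(off & Dist <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive distance for pair (", ids[w[1L]], ", ", ids[w[2L]], ")")
  }
  K <- outer(M, M, function(mi, mj) mi / (mi + mj))
  S <- K * outer(M, M) / ifelse(off, Dist^b, 1)
  diag(S) <- 0; diag(K) <- 0
  dimnames(S) <- dimnames(K) <- list(ids, ids)
  structure(list(S = S, K = K, M = stats::setNames(M, ids), Dist = Dist, b = b),
            class = "gravity_matrix")
}

#' @export
print.gravity_matrix <- function(x, ...) {
  cat("Gravity matrix: ", length(x$M), " cities, b = ", x$b,
      ", mean off-diagonal strength ",
      format(mean(x$S[row(x$S) != col(x$S)]), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Binarize a gravity matrix into the tie network
#'
#' Default rule: the threshold is the mean of all off-diagonal strengths, and
#' A_ij = 1 iff S_ij is strictly greater than it (ties at exactly the mean are
#' 0). The `row-mean` variant thresholds each row at its own off-diagonal
#' mean. A constant strength matrix yields the empty network with a warning.
#'
#' @param G a [gravity_matrix()] (or a bare numeric matrix of strengths).
#' @param rule `"global-mean"` (default) or `"row-mean"`.
#' @param year optional year tag carried on the result.
#' @return list of class `tie_network`: `A` (binary, zero diagonal),
#'   `threshold_used`, `rule`, `year`.
#' @export
binarize <- function(G, rule = c("global-mean", "row-mean"), year = NA) {
  rule <- match.arg(rule)
  S <- if (inherits(G, "gravity_matrix")) G$S else as.matrix(G)
  off <- row(S) != col(S)
  if (rule == "global-mean") {
    thr <- mean(S[off])
    A <- (S > thr) * 1L
  } else {
    n <- nrow(S)
    thr <- (rowSums(S) - diag(S)) / (n - 1)
    A <- (S > matrix(thr, n, n)) * 1L
  }
  diag(A) <- 0L
  if (all(A[off] == 0))
    warning("constant or sub-threshold strengths: empty tie network")
  dimnames(A) <- dimnames(S)
  structure(list(A = A, threshold_used = thr, rule = rule, year = year),
            class = "tie_network")
}

#' @export
print.tie_network <- function(x, ...) {
  n <- nrow(x$A)
  m <- sum(x$A)
  cat("Tie network: ", n, " nodes, ", m, " directed ties (density ",
      format(m / (n * (n - 1)), digits = 3), "), rule ", x$rule,
      if (!is.na(x$year)) paste0(", year ", x$year), "\n", sep = "")
  invisible(x)
}

# accept either a tie_network or a bare binary matrix
tie_matrix <- function(A) {
  M <- if (inherits(A, "tie_network")) A$A else as.matrix(A)
  if (nrow(M) != ncol(M)) stop("tie matrix must be square")
  if (any(M != 0 & M != 1)) stop("tie matrix must be binary")
  if (any(diag(M) != 0)) stop("tie matrix must have a zero diagonal")
  M
}
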