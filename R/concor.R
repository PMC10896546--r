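# CONCOR blockmodelling: iterated correlation convergence on node tie
# profiles, recursive bipartition to a fixed depth, subgroup density and
# image matrices.

# profile correlation matrix for a node subset: profiles are each node's full
# row and column of the tie matrix (structural equivalence is with respect to
# the whole network, also when a block is re-split), with the standard
# exclusions: when correlating nodes i and j, the positions referring to i
# and j themselves (diagonal and mutual-pair entries, in both the row and the
# column profile) are dropped, pairwise.
profile_correlations <- function(M, nodes) {
  k <- length(nodes)
  n <- nrow(M)
  C <- diag(1, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      i <- nodes[a]; j <- nodes[b]
      keep <- setdiff(seq_len(n), c(i, j))
      v1 <- c(M[i, keep], M[keep, i])
      v2 <- c(M[j, keep], M[keep, j])
      C[a, b] <- C[b, a] <-
        if (stats::sd(v1) == 0 || stats::sd(v2) == 0) NA_real_
        else stats::cor(v1, v2)
    }
  }
  C
}

#' One CONCOR bipartition of a node subset
#'
#' Builds each node's profile from its full row and column of the tie matrix
#' (structural equivalence with respect to the whole network, also when a
#' block is re-split; self and mutual-pair positions excluded), computes
#' the Pearson correlation matrix of profiles, then repeatedly replaces the
#' matrix by the correlation matrix of its own columns until every
#' off-diagonal entry is within `tol` of +1 or -1. The sign pattern of the
#' first row splits the set in two.
#'
#' Zero-variance profiles have no defined correlation with any neighbor; such
#' nodes are assigned, with a warning, to the block of their most-correlated
#' non-degenerate neighbor when any initial correlation is defined, else to
#' the larger block.
#'
#' @param A a `tie_network` or binary matrix.
#' @param nodes indices (or names) of the subset to split; at least 2.
#' @param tol convergence tolerance on |corr| - 1 (default 1e-6).
#' @param maxit iteration cap (default 200); non-convergence is an error.
#' @return list with `groups` (list of two integer vectors, indices into the
#'   full matrix), `iterations`, `degenerate` (indices assigned by fallback).
#' @export
concor_split <- function(A, nodes = NULL, tol = 1e-6, maxit = 200L) {
  M <- tie_matrix(A)
  if (is.null(nodes)) nodes <- seq_len(nrow(M))
  if (is.character(nodes)) nodes <- match(nodes, rownames(M))
  if (length(nodes) < 2) stop("need at least 2 nodes to split")
  if (length(nodes) == 2)
    return(list(groups = list(nodes[1], nodes[2]), iterations = 0L,
                degenerate = integer(0)))
  C0 <- profile_correlations(M, nodes)
  degen <- which(vapply(seq_len(nrow(C0)), function(i)
    all(is.na(C0[i, -i])), logical(1)))
  live <- setdiff(seq_along(nodes), degen)
  if (length(live) < 2)
    stop("all profiles degenerate; cannot split")
  C <- C0[live, live, drop = FALSE]
  # a pair can have an undefined correlation (profile constant after the
  # pairwise exclusions) even when both nodes correlate with others; treat
  # such pairs as uncorrelated so the iteration can proceed
  C[is.na(C)] <- 0
  it <- 0L
  repeat {
    off <- abs(C[row(C) != col(C)])
    if (!length(off) || max(abs(off - 1)) < tol) break
    it <- it + 1L
    if (it > maxit)
      stop("CONCOR did not converge in ", maxit, " iterations")
    C <- stats::cor(C)
    if (anyNA(C)) stop("zero-variance column during CONCOR iteration")
  }
  in_first <- C[1, ] > 0
  g1 <- live[in_first]
  g2 <- live[!in_first]
  if (length(degen)) {
    warning("zero-variance profile(s) assigned by fallback rule: ",
            paste(nodes[degen], collapse = ", "))
    for (d in degen) {
      r <- C0[d, live]
      if (any(is.finite(r))) {
        best <- live[which.max(r)]
        if (best %in% g1) g1 <- c(g1, d) else g2 <- c(g2, d)
      } else if (length(g1) >= length(g2)) g1 <- c(g1, d) else g2 <- c(g2, d)
    }
  }
  if (!length(g2)) { # degenerate: all signs equal; peel the least-similar node
    g2 <- g1[length(g1)]
    g1 <- g1[-length(g1)]
  }
  list(groups = list(nodes[sort(g1)], nodes[sort(g2)]),
       iterations = it, degenerate = nodes[degen])
}

#' Recursive CONCOR partition with subgroup density and image matrices
#'
#' Applies [concor_split()] recursively to `depth` levels (depth 2 yields four
#' cohesive subgroups, barring blocks too small to split). Leaves are ordered
#' canonically by their smallest member index. The subgroup density matrix and
#' the alpha-density image matrix (alpha defaulting to the overall network
#' density) are computed from the full directed tie matrix.
#'
#' @param A a `tie_network` or binary matrix.
#' @param depth recursion depth (default 2).
#' @param alpha image threshold; default the overall network density.
#' @param tol,maxit passed to [concor_split()].
#' @return list of class `concor_result`: `membership` (named integer vector),
#'   `split_tree` (nested list of index vectors), `density_matrix`,
#'   `image_matrix`, `alpha`, `sizes`.
#' @export
concor_tree <- function(A, depth = 2L, alpha = NULL, tol = 1e-6,
                        maxit = 200L) {
  M <- tie_matrix(A)
  n <- nrow(M)
  if (n < 2^depth)
    stop("need at least ", 2^depth, " nodes for depth ", depth)
  recurse <- function(nodes, d) {
    if (d == 0L || length(nodes) < 2L) return(list(nodes))
    sp <- concor_split(M, nodes, tol = tol, maxit = maxit)
    c(recurse(sp$groups[[1]], d - 1L), recurse(sp$groups[[2]], d - 1L))
  }
  leaves <- recurse(seq_len(n), as.integer(depth))
  leaves <- leaves[order(vapply(leaves, min, integer(1)))]
  membership <- integer(n)
  for (g in seq_along(leaves)) membership[leaves[[g]]] <- g
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  names(membership) <- ids
  dens <- subgroup_density(M, membership)
  if (is.null(alpha)) alpha <- network_density(M)$density
  img <- image_matrix(dens, alpha)
  structure(list(membership = membership, split_tree = leaves,
                 density_matrix = dens, image_matrix = img, alpha = alpha,
                 sizes = vapply(leaves, length, integer(1))),
            class = "concor_result")
}

#' @export
print.concor_result <- function(x, ...) {
  cat("CONCOR partition: ", length(x$sizes), " subgroups of sizes ",
      paste(x$sizes, collapse = ", "), " (alpha = ",
      format(x$alpha, digits = 3), ")\n", sep = "")
  cat("Density matrix:\n")
  print(round(x$density_matrix, 3))
  cat("Image matrix:\n")
  print(x$image_matrix)
  invisible(x)
}

#' Subgroup tie-density matrix
#'
#' Cell (g, h) is the number of ties from members of g to members of h divided
#' by the number of possible ties: n_g * n_h off the diagonal, n_g (n_g - 1)
#' on it. A singleton diagonal cell has no possible ties and is recorded as 0
#' (flagged in the `"singleton"` attribute).
#'
#' @param A a `tie_network` or binary matrix.
#' @param membership integer vector of subgroup ids, one per node.
#' @return k x k density matrix.
#' @export
subgroup_density <- function(A, membership) {
  M <- tie_matrix(A)
  if (length(membership) != nrow(M))
    stop("membership length must equal the node count")
  ids <- sort(unique(membership))
  k <- length(ids)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  singleton <- logical(k)
  for (a in seq_len(k)) {
    ga <- which(membership == ids[a])
    for (b in seq_len(k)) {
      gb <- which(membership == ids[b])
      ties <- sum(M[ga, gb])
      poss <- if (a == b) length(ga) * (length(ga) - 1) else length(ga) * length(gb)
      if (poss == 0) { D[a, b] <- 0; singleton[a] <- TRUE }
      else D[a, b] <- ties / poss
    }
  }
  attr(D, "singleton") <- ids[singleton]
  D
}

#' Alpha-density image matrix
#'
#' cell = 1 iff the subgroup density reaches the threshold alpha (the overall
#' network density, by convention).
#'
#' @param density_matrix k x k density matrix.
#' @param alpha threshold, >= 0.
#' @return binary k x k matrix.
#' @export
image_matrix <- function(density_matrix, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  (density_matrix >= alpha) * 1L
}
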