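# Social-network structure statistics: overall density, Freeman degree,
# closeness (with an explicit disconnection convention) and Brandes
# betweenness, plus the ranked report table.

#' Overall density of a directed tie network
#'
#' density = m / (n (n - 1)) where m counts off-diagonal ones.
#'
#' @param A a `tie_network` or binary matrix.
#' @return list of class `network_summary`: `n`, `m`, `density`.
#' @export
network_density <- function(A) {
  M <- tie_matrix(A)
  n <- nrow(M)
  if (n < 2) stop("density needs at least 2 nodes")
  m <- sum(M)
  structure(list(n = n, m = m, density = m / (n * (n - 1))),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("n = ", x$n, ", m = ", x$m, ", density = ",
      format(x$density, digits = 4), "\n", sep = "")
  invisible(x)
}

symmetrize <- function(M) (M + t(M) > 0) * 1L

#' Normalized degree centrality
#'
#' Freeman degree centrality degree_i / (n - 1). By default the directed
#' network is symmetrized first (a tie in either direction counts); `in` and
#' `out` modes use column and row sums of the directed matrix.
#'
#' @param A a `tie_network` or binary matrix.
#' @param mode `"symmetrized"` (default), `"in"` or `"out"`.
#' @return named numeric vector in `[0, 1]`.
#' @export
degree_centrality <- function(A, mode = c("symmetrized", "in", "out")) {
  mode <- match.arg(mode)
  M <- tie_matrix(A)
  n <- nrow(M)
  deg <- switch(mode,
                symmetrized = rowSums(symmetrize(M)),
                "in" = colSums(M),
                out = rowSums(M))
  stats::setNames(deg / (n - 1), rownames(M))
}

# BFS geodesic distances from every node on an undirected binary graph;
# unreachable pairs are Inf
bfs_distances <- function(M) {
  n <- nrow(M)
  nbr <- lapply(seq_len(n), function(i) which(M[i, ] == 1))
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  dimnames(D) <- dimnames(M)
  D
}

#' Closeness centrality with explicit disconnection convention
#'
#' On the symmetrized network, farness_i = sum_j d_ij with unreachable
#' distances set to `unreachable` (default n, the node count); closeness_i =
#' (n - 1) / farness_i. Both are returned.
#'
#' @param A a `tie_network` or binary matrix.
#' @param unreachable distance substituted for unreachable pairs (default n).
#' @return list with `closeness` and `farness` (named numeric vectors).
#' @export
closeness_centrality <- function(A, unreachable = NULL) {
  M <- symmetrize(tie_matrix(A))
  n <- nrow(M)
  if (is.null(unreachable)) unreachable <- n
  D <- bfs_distances(M)
  D[is.infinite(D)] <- unreachable
  farness <- rowSums(D)
  list(closeness = stats::setNames((n - 1) / farness, rownames(M)),
       farness = stats::setNames(farness, rownames(M)))
}

#' Betweenness centrality (Brandes) on the symmetrized network
#'
#' For each unordered pair (j, k), the fraction of shortest j-k paths passing
#' through i, summed; unreachable pairs contribute zero. Normalization divides
#' by (n - 1)(n - 2) / 2.
#'
#' @param A a `tie_network` or binary matrix.
#' @param normalized divide by (n-1)(n-2)/2 (default TRUE).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(A, normalized = TRUE) {
  M <- symmetrize(tie_matrix(A))
  n <- nrow(M)
  nbr <- lapply(seq_len(n), function(i) which(M[i, ] == 1))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    # Brandes single-source accumulation
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbr[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each unordered pair counted from both endpoints
  if (normalized && n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  stats::setNames(bc, rownames(M))
}

#' Ranked centrality report
#'
#' One row per city with the three centrality measures (fraction and percent
#' scales) and their ranks; the per-measure means are attached as the
#' `"means"` attribute and appended by [write_centrality()]. Ranking is
#' deterministic: value descending, city id ascending on ties.
#'
#' @param A a `tie_network` or binary matrix.
#' @return data.frame of class `centrality_report`.
#' @export
centrality_report <- function(A) {
  M <- tie_matrix(A)
  ids <- rownames(M)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(M)))
  deg <- degree_centrality(M)
  clo <- closeness_centrality(M)$closeness
  btw <- betweenness_centrality(M)
  rank_of <- function(v) {
    ord <- order(-v, ids)
    r <- integer(length(v)); r[ord] <- seq_along(v)
    r
  }
  out <- data.frame(city_id = ids,
                    degree = as.numeric(deg),
                    closeness = as.numeric(clo),
                    betweenness = as.numeric(btw),
                    degree_pct = 100 * as.numeric(deg),
                    closeness_pct = 100 * as.numeric(clo),
                    betweenness_pct = 100 * as.numeric(btw),
                    rank_degree = rank_of(deg),
                    rank_closeness = rank_of(clo),
                    rank_betweenness = rank_of(btw),
                    stringsAsFactors = FALSE)
  attr(out, "means") <- c(degree = mean(deg), closeness = mean(clo),
                          betweenness = mean(btw))
  class(out) <- c("centrality_report", "data.frame")
  out
}

#' Write a centrality report with its mean row
#' @param report a [centrality_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(report, path) {
  d <- as.data.frame(report)
  m <- attr(report, "means")
  mean_row <- data.frame(city_id = "Average",
                         degree = m[["degree"]], closeness = m[["closeness"]],
                         betweenness = m[["betweenness"]],
                         degree_pct = 100 * m[["degree"]],
                         closeness_pct = 100 * m[["closeness"]],
                         betweenness_pct = 100 * m[["betweenness"]],
                         rank_degree = NA, rank_closeness = NA,
                         rank_betweenness = NA)
  utils::write.csv(rbind(d, mean_row), path, row.names = FALSE)
  invisible(path)
}
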