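# Small in-code fixtures shared across test files.

# minimal valid panel data.frame: `cities` x `years`, all DEA fields positive
toy_panel_df <- function(cities = c("A", "B"), years = 2010:2011,
                         province = rep("P1", length(cities))) {
  g <- expand.grid(city_id = cities, year = years, stringsAsFactors = FALSE)
  i <- seq_len(nrow(g))
  data.frame(city_id = g$city_id,
             province = province[match(g$city_id, cities)],
             year = g$year,
             sown_area = 100 + i, labor = 10 + i, machinery_power = 20 + i,
             fertilizer = 5 + i, grain_output = 50 + i,
             agri_output_value = 80 + i,
             cs_fertilizer = 5 + i, cs_diesel = 2 + i,
             stringsAsFactors = FALSE)
}

# directed random binary tie matrix with zero diagonal
rand_tie <- function(n, p = 0.3) {
  A <- matrix(rbinom(n * n, 1L, p), n, n)
  diag(A) <- 0L
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  A
}

# undirected star with node 1 at the center, as a symmetric binary matrix
star_tie <- function(n) {
  A <- matrix(0L, n, n)
  A[1, -1] <- 1L
  A[-1, 1] <- 1L
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  A
}

# random positive DEA instance
rand_dea <- function(n = 5, m = 2, s1 = 1, s2 = 1, lo = 0.5, hi = 5) {
  dea_dataset(matrix(runif(m * n, lo, hi), m),
              matrix(runif(s1 * n, lo, hi), s1),
              matrix(runif(s2 * n, lo, hi), s2))
}

# directed planted k-block network: within-block ties with p_in, across p_out
planted_blocks <- function(block_sizes, p_in = 0.6, p_out = 0.05) {
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  P <- ifelse(outer(block, block, "=="), p_in, p_out)
  A <- matrix(rbinom(n * n, 1L, P), n, n)
  diag(A) <- 0L
  list(A = A, block = block)
}

# do two partitions agree up to label permutation?
same_partition <- function(a, b) {
  ta <- split(seq_along(a), a)
  tb <- split(seq_along(b), b)
  length(ta) == length(tb) &&
    setequal(lapply(ta, sort), lapply(tb, sort))
}
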