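# Internal helpers shared across modules.

#' Upper-triangle pair index for an R-node undirected graph
#'
#' Enumerates the strict upper triangle of an `R x R` matrix in R's
#' column-major extraction order, i.e. the order produced by
#' `m[upper.tri(m)]`. This is the canonical edge order used everywhere an
#' undirected edge needs a single index.
#'
#' @param R Number of nodes.
#' @return A tibble with columns `i`, `j` (`i < j`) and `idx` (1-based
#'   position in the flattened upper triangle).
#' @keywords internal
#' @noRd
upper_pairs <- function(R) {
  ind <- which(upper.tri(matrix(0L, R, R)), arr.ind = TRUE)
  tibble::tibble(i = ind[, 1L], j = ind[, 2L], idx = seq_len(nrow(ind)))
}

# Number of possible undirected edges among R nodes.
n_pairs <- function(R) R * (R - 1L) / 2L

# Rebuild a symmetric R x R matrix (zero diagonal) from its upper-triangle
# vector in canonical order.
unflatten_edges <- function(values, R) {
  m <- matrix(0, R, R)
  m[upper.tri(m)] <- values
  m + t(m)
}

# Flatten the strict upper triangle of a symmetric matrix in canonical order.
flatten_edges <- function(w) w[upper.tri(w)]

# Stop with a consistent error class so callers/tests can target failures.
abort_recallnet <- function(msg, class = "recallnet_error") {
  rlang::abort(msg, class = class)
}

# Derive a stream of distinct 32-bit-safe seeds from one master seed.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.integer(seed) + salt + 1000L * seq_len(n)) %% .Machine$integer.max
}
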