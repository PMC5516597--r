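# Independent brute-force oracles and small fixture builders. Every oracle
# here is deliberately naive (element loops, exhaustive path enumeration)
# so it cannot share a code path with the implementation it checks.

random_connectome <- function(R, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, R, R)
  ut <- which(upper.tri(w))
  on <- sample(ut, round(density * length(ut)))
  w[on] <- runif(length(on), 0.05, 1)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  diag(w) <- 0
  w
}

random_connected_connectome <- function(R, density = 0.6, seed = NULL) {
  repeat {
    w <- random_connectome(R, density, seed)
    seed <- if (is.null(seed)) NULL else seed + 1000
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}

oracle_symmetrize <- function(p) {
  R <- nrow(p)
  out <- matrix(0, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i != j) out[i, j] <- (p[i, j] + p[j, i]) / 2
  }
  out
}

oracle_cost <- function(w) {
  R <- nrow(w)
  s <- 0
  for (i in seq_len(R - 1)) for (j in (i + 1):R) s <- s + w[i, j]
  s / (R * (R - 1) / 2)
}

oracle_mask <- function(weight_rows, R, floor) {
  # weight_rows: subjects x edges matrix over the canonical order
  keep <- logical(ncol(weight_rows))
  for (e in seq_len(ncol(weight_rows))) {
    x <- weight_rows[, e]
    keep[e] <- (mean(x) + 2 * sd(x)) >= floor
  }
  keep
}

# All simple paths between a and b; returns list of node vectors.
all_simple_paths_rec <- function(w, a, b) {
  R <- nrow(w)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (nxt in which(w[last, ] > 0)) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(a)
  out
}

path_len <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1])])
}

oracle_distances <- function(w) {
  R <- nrow(w)
  d <- matrix(Inf, R, R)
  diag(d) <- 0
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) next
    paths <- all_simple_paths_rec(w, a, b)
    if (length(paths)) d[a, b] <- min(vapply(paths, path_len, numeric(1), w = w))
  }
  d
}

oracle_betweenness <- function(w, tol = 1e-9) {
  R <- nrow(w)
  b <- numeric(R)
  for (s in seq_len(R)) for (t in seq_len(R)) {
    if (s == t) next
    paths <- all_simple_paths_rec(w, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, path_len, numeric(1), w = w)
    best <- min(lens)
    short <- paths[lens <= best + tol]
    for (v in seq_len(R)) {
      if (v == s || v == t) next
      through <- sum(vapply(short, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + through / length(short)
    }
  }
  b / ((R - 1) * (R - 2))
}

oracle_clustering <- function(w) {
  R <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, R))
  ww <- w / mx
  cc <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a == b) next
      j <- nb[a]; h <- nb[b]
      if (w[j, h] > 0) s <- s + (ww[i, j] * ww[i, h] * ww[j, h])^(1 / 3)
    }
    cc[i] <- s / (k * (k - 1))
  }
  cc
}

oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kstar <- k
  if (kstar == 0) integer(0) else sort(ord[seq_len(kstar)])
}

# Small aligned phenotype table for association tests.
toy_cohort <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = rnorm(n, 23, 3), gender = rbinom(n, 1, 0.5),
    icv = rnorm(n, 1.5e6, 1e5)
  )
}

# Warm the calibration cache cheaply for a non-default test config.
warm_calibration <- function(cfg, n_sim = 2e4) {
  invisible(calibrate_generator(cfg, n_sim = n_sim))
  cfg
}
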