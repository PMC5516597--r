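# Weighted graph metrics at global, nodal and edge resolution.
#
# Conventions (documented in the methods vignette):
#   * zero weights are absent edges;
#   * path-based metrics map weight to length as 1/w (stronger connection =
#     shorter path), the standard convention for probabilistic connection
#     weights;
#   * characteristic path length averages finite distances only, reporting
#     the number of unreachable pairs as an attribute.

graph_from_connectome <- function(w, lengths = TRUE) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (lengths && igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  }
  g
}

#' Network cost (weighted density)
#'
#' The sum of all connection weights divided by the number of possible
#' undirected edges `R(R-1)/2`. Equals the mean of the nodal degrees, and
#' serves as a simple estimator of physical wiring cost.
#'
#' @param w Symmetric connectome matrix.
#' @return Scalar in `[0, 1]`.
#' @export
network_cost <- function(w) {
  R <- nrow(w)
  sum(flatten_edges(w)) / n_pairs(R)
}

#' Nodal degree (strength)
#'
#' The average connectivity of each node across its `R - 1` possible
#' connections: `k_i = sum_j w_ij / (R - 1)`.
#'
#' @param w Symmetric connectome matrix.
#' @return Numeric vector of length `R`, named by dimnames when present.
#' @export
nodal_degree <- function(w) {
  rowSums(w) / (nrow(w) - 1L)
}

#' Weighted clustering coefficient
#'
#' Per-node weighted clustering in the geometric-mean-of-triangles
#' (Onnela) form on weights scaled by the maximum weight:
#' `C_i = (sum of (w'_ij w'_ih w'_jh)^(1/3) over triangles) / (k_i (k_i - 1))`
#' with `w' = w / max(w)` and `k_i` the binary degree. Nodes with binary
#' degree below 2 get 0. For binary graphs this reduces to the fraction of
#' a node's neighbour pairs that are themselves connected.
#'
#' @param w Symmetric connectome matrix.
#' @return List with `node` (per-node vector) and `global` (mean over all
#'   nodes).
#' @export
weighted_clustering <- function(w) {
  R <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(list(node = rep(0, R), global = 0))
  s <- (w / mx)^(1 / 3)
  tri <- diag(s %*% s %*% s) / 2  # each triangle counted twice around a node
  kbin <- rowSums(w > 0)
  cc <- ifelse(kbin >= 2, 2 * tri / (kbin * (kbin - 1)), 0)
  list(node = unname(cc), global = mean(cc))
}

#' Pairwise shortest-path distances
#'
#' Edge length is `1/w` for positive weights; absent edges cannot be
#' traversed. Distances are computed with Dijkstra's algorithm; pairs in
#' different components get `Inf`.
#'
#' @param w Symmetric connectome matrix.
#' @return `R x R` matrix of distances (0 on the diagonal).
#' @export
shortest_paths <- function(w) {
  g <- graph_from_connectome(w)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all unordered node pairs with a finite
#' distance. Optionally normalized by the mean characteristic path length
#' of degree-preserving random reference networks (see
#' [random_reference()]).
#'
#' @param w Symmetric connectome matrix with at least one edge.
#' @param normalize Divide by the mean path length of `n_random` rewired
#'   surrogates.
#' @param n_random Number of random reference networks (default 100).
#' @param rewires_per_edge Rewiring intensity for the surrogates.
#' @param seed Optional seed for surrogate generation.
#' @return Scalar; attribute `n_unreachable` counts the (unordered) node
#'   pairs with infinite distance in the original graph.
#' @export
characteristic_path_length <- function(w, normalize = FALSE, n_random = 100,
                                       rewires_per_edge = 20, seed = NULL) {
  if (all(w == 0)) abort_recallnet("path length undefined for an edgeless graph")
  L <- raw_path_length(w)
  if (normalize) {
    ls <- vapply(seq_len(n_random), function(k) {
      wr <- random_reference(w, rewires_per_edge = rewires_per_edge,
                             seed = if (is.null(seed)) NULL else seed + k)
      raw_path_length(wr)
    }, numeric(1))
    out <- as.numeric(L) / mean(ls)
    attr(out, "n_unreachable") <- attr(L, "n_unreachable")
    return(out)
  }
  L
}

raw_path_length <- function(w) {
  d <- shortest_paths(w)
  dd <- d[upper.tri(d)]
  fin <- is.finite(dd)
  out <- mean(dd[fin])
  attr(out, "n_unreachable") <- sum(!fin)
  out
}

#' Global and nodal efficiency
#'
#' Global efficiency is the mean inverse shortest-path distance over all
#' ordered node pairs, with `1/Inf = 0`, making it robust to disconnected
#' pairs. The nodal efficiency of node `i` is the global efficiency of the
#' subgraph induced by `i`'s neighbours.
#'
#' @param w Symmetric connectome matrix.
#' @return `global_efficiency()`: scalar. `nodal_efficiency()`: per-node
#'   numeric vector.
#' @export
global_efficiency <- function(w) {
  R <- nrow(w)
  if (R < 2) return(0)
  d <- shortest_paths(w)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (R * (R - 1L))
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(w) {
  vapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

#' Betweenness centrality
#'
#' The fraction of shortest paths between all ordered pairs of other nodes
#' that pass through each node (endpoints excluded), on `1/w` edge lengths,
#' normalized by `(R-1)(R-2)`.
#'
#' @param w Symmetric connectome matrix.
#' @return Per-node numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(w) {
  R <- nrow(w)
  if (R < 3) return(rep(0, R))
  g <- graph_from_connectome(w)
  b <- igraph::betweenness(g, directed = FALSE)
  # igraph counts unordered pairs; the ordered-pair count is twice that
  unname(2 * b / ((R - 1) * (R - 2)))
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps on the binary topology: two edges
#' `(a,b)` and `(c,d)` are replaced by `(a,d)` and `(c,b)` when all four
#' nodes are distinct and neither new edge already exists. Each edge
#' carries its weight with it, so the binary degree sequence, the edge
#' count and the multiset of weights are all exactly preserved.
#'
#' @param w Symmetric connectome matrix with at least 2 edges.
#' @param rewires_per_edge Target number of successful swaps per edge
#'   (default 20).
#' @param seed Optional RNG seed.
#' @return A rewired connectome matrix. If no legal swap was achieved the
#'   input is returned unchanged with attribute `rewire_failed = TRUE`.
#' @export
random_reference <- function(w, rewires_per_edge = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- nrow(w)
  pr <- upper_pairs(R)
  keep <- flatten_edges(w) > 0
  ei <- pr$i[keep]; ej <- pr$j[keep]; ew <- flatten_edges(w)[keep]
  E <- length(ei)
  if (E < 2) abort_recallnet("rewiring needs at least 2 edges")
  adj <- w > 0
  target <- rewires_per_edge * E
  attempts_cap <- 100L * target
  done <- 0L; attempts <- 0L
  while (done < target && attempts < attempts_cap) {
    attempts <- attempts + 1L
    e <- sample.int(E, 2L)
    a <- ei[e[1L]]; b <- ej[e[1L]]; c <- ei[e[2L]]; d <- ej[e[2L]]
    if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
    if (length(unique(c(a, b, c, d))) < 4L) next
    if (adj[a, d] || adj[c, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c, b] <- adj[b, c] <- TRUE
    ei[e[1L]] <- min(a, d); ej[e[1L]] <- max(a, d)
    ei[e[2L]] <- min(c, b); ej[e[2L]] <- max(c, b)
    done <- done + 1L
  }
  out <- matrix(0, R, R)
  out[cbind(ei, ej)] <- ew
  out[cbind(ej, ei)] <- ew
  dimnames(out) <- dimnames(w)
  if (done == 0L) {
    warning("no legal swap found; returning input unchanged")
    attr(out, "rewire_failed") <- TRUE
  }
  attr(out, "n_swaps") <- done
  out
}

#' Binarize a connectome at a target cost
#'
#' Retains the `round(kappa * R(R-1)/2)` strongest edges by weight (never
#' more than the available nonzero edges; zero weight is an absent edge)
#' and sets their weight to 1. Ties are broken deterministically by
#' lexicographic `(i, j)` order.
#'
#' @param w Symmetric connectome matrix.
#' @param kappa Target cost in `(0, 1]`.
#' @return Binary symmetric matrix; attribute `k_requested` records the
#'   requested edge count, `k_realized` the number actually available.
#' @export
binarize_at_cost <- function(w, kappa) {
  if (!is.numeric(kappa) || kappa <= 0 || kappa > 1) {
    abort_recallnet("kappa must be in (0, 1]")
  }
  R <- nrow(w)
  pr <- upper_pairs(R)
  vals <- flatten_edges(w)
  k_req <- max(1L, round(kappa * n_pairs(R)))
  nz <- which(vals > 0)
  ord <- nz[order(-vals[nz], pr$i[nz], pr$j[nz])]
  take <- ord[seq_len(min(k_req, length(ord)))]
  out <- unflatten_edges(as.numeric(seq_along(vals) %in% take), R)
  dimnames(out) <- dimnames(w)
  attr(out, "k_requested") <- k_req
  attr(out, "k_realized") <- length(take)
  out
}

#' Cost grid for cost-integrated metrics
#'
#' Equispaced grid of cost (density) levels between the minimum meaningful
#' cost `1/(R(R-1)/2)` (a single edge) and an upper bound, by default the
#' smallest maximum cost common to all subjects (so every subject has
#' enough nonzero edges at every grid level).
#'
#' @param stack A `connectome_stack` (typically already masked) used to
#'   derive the common upper bound; or `NULL` if `kappa_max` is given.
#' @param n Number of grid points (default 50).
#' @param kappa_max Optional explicit upper bound in `(0, 1]`.
#' @param R Node count, required when `stack` is `NULL`.
#' @return Strictly increasing numeric vector of cost levels.
#' @export
cost_grid <- function(stack = NULL, n = 50, kappa_max = NULL, R = NULL) {
  if (is.null(kappa_max)) {
    stopifnot(inherits(stack, "connectome_stack"))
    R <- stack$R
    kappa_max <- min(rowSums(stack$weights > 0)) / n_pairs(R)
  }
  if (is.null(R)) abort_recallnet("R required when no stack is given")
  lo <- 1 / n_pairs(R)
  if (kappa_max <= lo || kappa_max > 1) abort_recallnet("invalid cost upper bound")
  seq(lo, kappa_max, length.out = n)
}

#' Cost-integrated global metric
#'
#' Evaluates a global metric on the binarized graph at each cost level of
#' the grid and averages over the grid (uniform weights). This removes the
#' cost-dependence that confounds topology comparisons across subjects.
#' Grid points where the metric is undefined (`NA`/`NaN`) are excluded
#' from the average and counted.
#'
#' @param w Symmetric connectome matrix.
#' @param metric Function mapping a binary connectome matrix to a scalar
#'   (e.g. [global_efficiency()]).
#' @param grid Cost grid from [cost_grid()].
#' @return Scalar; attribute `n_excluded` counts undefined grid points.
#' @export
cost_integrated_metric <- function(w, metric, grid) {
  if (any(grid <= 0 | grid > 1)) abort_recallnet("grid must lie in (0, 1]")
  vals <- vapply(grid, function(k) {
    v <- metric(binarize_at_cost(w, k))
    as.numeric(v)[1L]
  }, numeric(1))
  bad <- !is.finite(vals)
  out <- mean(vals[!bad])
  attr(out, "n_excluded") <- sum(bad)
  out
}

# Fast stack-level metric helpers ------------------------------------------

#' Per-subject network cost for a stack
#'
#' @param stack A `connectome_stack`.
#' @return Named numeric vector, one cost per subject.
#' @export
stack_costs <- function(stack) {
  stopifnot(inherits(stack, "connectome_stack"))
  stats::setNames(rowSums(stack$weights) / ncol(stack$weights),
                  stack$subject_id)
}

#' Per-subject nodal degrees for a stack
#'
#' @param stack A `connectome_stack`.
#' @return Numeric matrix, subjects x nodes, columns named by atlas label.
#' @export
stack_degrees <- function(stack) {
  stopifnot(inherits(stack, "connectome_stack"))
  R <- stack$R
  deg <- matrix(0, nrow(stack$weights), R,
                dimnames = list(stack$subject_id, stack$atlas$label))
  for (v in seq_len(R)) {
    inc <- stack$pairs$idx[stack$pairs$i == v | stack$pairs$j == v]
    deg[, v] <- rowSums(stack$weights[, inc, drop = FALSE]) / (R - 1L)
  }
  deg
}

#' Tidy per-subject metric table
#'
#' Computes a selection of global and nodal metrics for every subject in a
#' stack and returns them in long format, the package's on-disk metric
#' interface.
#'
#' @param stack A `connectome_stack`.
#' @param metrics Character subset of `c("cost", "degree", "clustering",
#'   "char_path_length", "global_efficiency", "nodal_efficiency",
#'   "betweenness")`.
#' @return Tibble with columns `subject_id`, `metric`, `node` (atlas label
#'   or `"global"`), `value`.
#' @export
compute_metrics <- function(stack, metrics = c("cost", "degree")) {
  stopifnot(inherits(stack, "connectome_stack"))
  choices <- c("cost", "degree", "clustering", "char_path_length",
               "global_efficiency", "nodal_efficiency", "betweenness")
  metrics <- match.arg(metrics, choices, several.ok = TRUE)
  labels <- stack$atlas$label
  rows <- purrr::map(stack$subject_id, function(id) {
    w <- connectome_matrix(stack, id)
    out <- list()
    if ("cost" %in% metrics) {
      out$cost <- tibble::tibble(metric = "cost", node = "global",
                                 value = network_cost(w))
    }
    if ("degree" %in% metrics) {
      out$degree <- tibble::tibble(metric = "degree", node = labels,
                                   value = nodal_degree(w))
    }
    if ("clustering" %in% metrics) {
      cl <- weighted_clustering(w)
      out$clustering <- tibble::tibble(metric = "clustering",
                                       node = c(labels, "global"),
                                       value = c(cl$node, cl$global))
    }
    if ("char_path_length" %in% metrics) {
      out$cpl <- tibble::tibble(metric = "char_path_length", node = "global",
                                value = as.numeric(characteristic_path_length(w)))
    }
    if ("global_efficiency" %in% metrics) {
      out$ge <- tibble::tibble(metric = "global_efficiency", node = "global",
                               value = global_efficiency(w))
    }
    if ("nodal_efficiency" %in% metrics) {
      out$ne <- tibble::tibble(metric = "nodal_efficiency", node = labels,
                               value = nodal_efficiency(w))
    }
    if ("betweenness" %in% metrics) {
      bt <- betweenness_centrality(w)
      out$bt <- tibble::tibble(metric = "betweenness",
                               node = c(labels, "global"),
                               value = c(bt, mean(bt)))
    }
    dplyr::bind_rows(out) |> dplyr::mutate(subject_id = id, .before = 1L)
  })
  dplyr::bind_rows(rows)
}
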