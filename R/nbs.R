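# Network-based statistic: per-edge association tests, suprathreshold
# component extraction, and permutation-based family-wise-error inference
# on component size (edge count).

#' One-sided tail probability of the t distribution
#'
#' Maps a cluster-forming threshold `T` to the nominal per-edge p-value it
#' corresponds to: the upper-tail probability of the central t
#' distribution at `T` (e.g. `T = 2.5` at `df = 660` gives 0.0063).
#'
#' @param T Statistic threshold.
#' @param df Degrees of freedom (`>= 1`).
#' @return Upper-tail probability.
#' @export
t_threshold_p <- function(T, df) {
  if (any(df < 1)) abort_recallnet("df must be >= 1")
  stats::pt(T, df = df, lower.tail = FALSE)
}

# Residualize y and the edge matrix on [intercept, covariates]; returns the
# pieces needed for vectorised slope t-statistics.
nbs_prepare <- function(recall, edges, covariates) {
  edges <- as.matrix(edges)
  n <- length(recall)
  if (nrow(edges) != n) abort_recallnet("recall and edges are not aligned")
  X0 <- cbind(rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    X0 <- cbind(X0, cm)
  }
  qx <- qr(X0)
  if (qx$rank < ncol(X0)) abort_recallnet("rank-deficient covariate design")
  list(ry = qr.resid(qx, recall), RE = qr.resid(qx, edges),
       df = n - ncol(X0) - 1L, n = n, k0 = ncol(X0))
}

# Vectorised per-edge slope t statistics for one response vector.
edge_t_from_prepared <- function(prep, y = NULL) {
  y <- if (is.null(y)) prep$ry else y
  sxx <- colSums(prep$RE^2)
  syy <- sum(y^2)
  b <- drop(crossprod(prep$RE, y))
  t <- rep(0, length(sxx))
  ok <- sxx > 1e-30
  b[ok] <- b[ok] / sxx[ok]
  rss <- pmax(syy - b^2 * sxx, 0)
  exact <- ok & rss < 1e-12 * syy
  reg <- ok & !exact
  t[reg] <- b[reg] * sqrt(sxx[reg] * prep$df / rss[reg])
  t[exact] <- sign(b[exact]) * Inf
  list(t = t, constant = !ok)
}

#' Per-edge association t-statistics
#'
#' For every edge, the t-statistic of the edge coefficient in an ordinary
#' least-squares regression of recall on `[intercept, edge, covariates]`,
#' with `df = n - (2 + number of covariates)` (df = n - 5 for the standard
#' age/gender/ICV adjustment). Edges constant across subjects get `t = 0`
#' with a flag; exact fits get an infinite sentinel.
#'
#' @param recall Per-subject recall counts (or any phenotype).
#' @param edges Subjects x edges matrix of connection weights (see
#'   [edge_values()]); column order defines the edge index.
#' @param covariates Data frame of covariates (default age/gender/ICV from
#'   a cohort: pass `cohort[, c("age", "gender", "icv")]`).
#' @param T Cluster-forming threshold on the statistic (default 2.5).
#' @param sided `"one"` (suprathreshold iff `t >= T`; positive
#'   associations, the default) or `"two"` (`|t| >= T`).
#' @param pairs Optional tibble with columns `i`, `j` giving node indices
#'   per edge column (enables component extraction).
#' @return Object of class `edge_stat_map`: tibble with `t`,
#'   `suprathreshold`, `constant` (plus `i`, `j` when given) and
#'   attributes `df`, `T`, `sided`.
#' @export
edge_t_stats <- function(recall, edges, covariates = NULL, T = 2.5,
                         sided = c("one", "two"), pairs = NULL) {
  sided <- match.arg(sided)
  prep <- nbs_prepare(recall, edges, covariates)
  et <- edge_t_from_prepared(prep)
  supra <- if (sided == "one") et$t >= T else abs(et$t) >= T
  out <- tibble::tibble(t = et$t, suprathreshold = supra, constant = et$constant)
  if (!is.null(pairs)) {
    out <- dplyr::bind_cols(tibble::as_tibble(pairs[, c("i", "j")]), out)
  }
  structure(out, df = prep$df, T = T, sided = sided,
            class = c("edge_stat_map", class(out)))
}

# Maximum component size (edge count) of an edge list, via union-find.
# Used in the permutation inner loop; igraph::components is the
# cross-checked reference on observed maps.
max_component_edges <- function(ei, ej) {
  if (length(ei) == 0L) return(0L)
  nodes <- unique(c(ei, ej))
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- match(ei, nodes); b <- match(ej, nodes)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(a, find, integer(1))
  max(tabulate(roots))
}

#' Connected components of the suprathreshold graph
#'
#' Builds the graph whose edges are the suprathreshold links of an edge
#' statistic map and identifies its connected components (breadth-first
#' search); component size is the number of edges it comprises.
#'
#' @param statmap An `edge_stat_map` carrying `i`/`j` node indices.
#' @param atlas Optional atlas tibble for node labels.
#' @return Tibble of components, one row each (`component`, `n_nodes`,
#'   `n_edges`, `nodes` and `edges` as list-columns), ordered by
#'   decreasing edge count. Empty tibble when nothing is suprathreshold.
#' @export
suprathreshold_components <- function(statmap, atlas = NULL) {
  stopifnot(inherits(statmap, "edge_stat_map"))
  if (!all(c("i", "j") %in% names(statmap))) {
    abort_recallnet("statmap lacks node indices; pass `pairs` to edge_t_stats()")
  }
  sub <- statmap[statmap$suprathreshold, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(component = integer(0), n_nodes = integer(0),
                          n_edges = integer(0), nodes = list(), edges = list()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = sub$i, to = sub$j), directed = FALSE)
  comp <- igraph::components(g)
  node_ids <- as.integer(igraph::V(g)$name)
  membership <- comp$membership
  edge_comp <- membership[match(as.character(sub$i), igraph::V(g)$name)]
  out <- purrr::map_dfr(seq_len(comp$no), function(cc) {
    nodes <- sort(node_ids[membership == cc])
    edges <- sub[edge_comp == cc, , drop = FALSE]
    tibble::tibble(component = cc, n_nodes = length(nodes),
                   n_edges = nrow(edges), nodes = list(nodes),
                   edges = list(edges))
  }) |> dplyr::arrange(dplyr::desc(n_edges))
  out$component <- seq_len(nrow(out))
  if (!is.null(atlas)) {
    out$labels <- purrr::map(out$nodes, ~ atlas$label[.x])
  }
  out
}

#' Network-based statistic with permutation FWE control
#'
#' The four NBS steps: (1) a per-edge t-statistic for the association
#' between each connection and recall, adjusted for covariates; (2)
#' thresholding at `T` to form the suprathreshold link set; (3) connected
#' components of that set, sized by edge count; (4) a family-wise-error
#' corrected p-value per component by indexing its size against the
#' permutation null distribution of the maximal component size.
#'
#' Permutation follows the Freedman-Lane idea on the covariate-adjusted
#' phenotype: recall and the edges are residualized on the covariates once,
#' the residualized recall vector is permuted, and the per-edge statistics
#' are recomputed against the fixed residualized edges. p-values use the
#' `+1` correction: `(1 + #{null max >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams edge_t_stats
#' @param pairs Tibble with `i`, `j` node indices per edge column (required
#'   for component extraction).
#' @param n_perm Number of permutations (default 10000; values below 100
#'   are rejected unless `allow_small = TRUE`).
#' @param alpha FWE significance level for flagging components (default
#'   0.005).
#' @param seed RNG seed for the permutations.
#' @param allow_small Permit `n_perm < 100` (for toy examples).
#' @return Object of class `nbs_result`: `components` tibble (with
#'   `p_fwe` and `significant`), `statmap`, `null_max_sizes`, `n_perm`,
#'   `T`, `alpha`, `df`, `seed`.
#' @export
nbs_fwe <- function(recall, edges, pairs, covariates = NULL, T = 2.5,
                    n_perm = 10000, alpha = 0.005, sided = c("one", "two"),
                    seed = NULL, allow_small = FALSE) {
  sided <- match.arg(sided)
  if (n_perm < 100 && !allow_small) {
    abort_recallnet("n_perm < 100 is statistically meaningless; set allow_small = TRUE to override")
  }
  prep <- nbs_prepare(recall, edges, covariates)
  statmap <- edge_t_stats(recall, edges, covariates, T = T, sided = sided,
                          pairs = pairs)
  comps <- suprathreshold_components(statmap)

  if (!is.null(seed)) set.seed(seed)
  null_max <- integer(n_perm)
  chunk <- 250L
  ei <- pairs$i; ej <- pairs$j
  sxx <- colSums(prep$RE^2)
  ok <- sxx > 1e-30
  REok <- prep$RE[, ok, drop = FALSE]
  sxx_ok <- sxx[ok]
  ei_ok <- ei[ok]; ej_ok <- ej[ok]
  syy <- sum(prep$ry^2)
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    YP <- vapply(seq_len(m), function(b) prep$ry[sample.int(prep$n)],
                 numeric(prep$n))
    B <- crossprod(REok, YP) / sxx_ok          # edges x m slopes
    RSS <- pmax(syy - B^2 * sxx_ok, 1e-300)
    TT <- B * sqrt(sxx_ok * prep$df) / sqrt(RSS)
    for (b in seq_len(m)) {
      supra <- if (sided == "one") TT[, b] >= T else abs(TT[, b]) >= T
      null_max[done + b] <- max_component_edges(ei_ok[supra], ej_ok[supra])
    }
    done <- done + m
  }

  if (nrow(comps)) {
    comps$p_fwe <- vapply(comps$n_edges, function(sz) {
      (1 + sum(null_max >= sz)) / (n_perm + 1)
    }, numeric(1))
    comps$significant <- comps$p_fwe < alpha
  } else {
    comps$p_fwe <- numeric(0)
    comps$significant <- logical(0)
  }

  structure(list(components = comps, statmap = statmap,
                 null_max_sizes = null_max, n_perm = n_perm, T = T,
                 alpha = alpha, sided = sided, df = prep$df, seed = seed),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> T = %g (%s-sided, df = %d), %d permutations\n",
              x$T, x$sided, x$df, x$n_perm))
  if (nrow(x$components)) {
    sig <- sum(x$components$significant)
    cat(sprintf("  %d component(s); %d significant at FWE p < %g\n",
                nrow(x$components), sig, x$alpha))
    top <- x$components[1, ]
    cat(sprintf("  largest: %d edges / %d nodes, p_fwe = %.4g\n",
                top$n_edges, top$n_nodes, top$p_fwe))
  } else cat("  no suprathreshold components\n")
  invisible(x)
}

#' Tidy NBS components
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return Tibble with one row per component: size, FWE p-value,
#'   significance flag.
#' @export
tidy.nbs_result <- function(x, ...) {
  dplyr::select(x$components, component, n_nodes, n_edges, p_fwe, significant)
}

#' NBS summary
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return One-row tibble: threshold, permutations, number of components
#'   and of significant components, smallest FWE p-value.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    T = x$T, df = x$df, n_perm = x$n_perm,
    n_components = nrow(x$components),
    n_significant = if (nrow(x$components)) sum(x$components$significant) else 0L,
    min_p_fwe = if (nrow(x$components)) min(x$components$p_fwe) else NA_real_,
    alpha = x$alpha
  )
}

#' Plot the NBS permutation null distribution
#'
#' Histogram of the null maximal component sizes with the observed
#' component sizes marked.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, ...) {
  df <- tibble::tibble(max_size = object$null_max_sizes)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = max_size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    ggplot2::labs(x = "Null maximal component size (edges)", y = "Permutations",
                  title = sprintf("NBS null distribution (T = %g, %d permutations)",
                                  object$T, object$n_perm)) +
    ggplot2::theme_minimal(base_size = 10)
  if (nrow(object$components)) {
    p <- p + ggplot2::geom_vline(
      data = object$components,
      ggplot2::aes(xintercept = n_edges, colour = significant),
      linetype = "dashed") +
      ggplot2::scale_colour_manual(
        values = c(`FALSE` = "steelblue", `TRUE` = "#B2182B"),
        name = sprintf("FWE p < %g", object$alpha))
  }
  p
}
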