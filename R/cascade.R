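# The hierarchical global -> nodal -> edge inference cascade.
#
# Hypotheses are arranged by spatial resolution: one global measure per
# subject (lowest level), 82 nodal degrees, then node-to-node connections
# (highest level). Each level is tested with a BH FDR procedure, but only
# if the level below rejected its null, which keeps the multiplicity burden
# proportionate to the resolution actually examined.

#' Hierarchical cost -> degree -> edge association cascade
#'
#' Level 1 tests the Spearman association between (residualized) recall
#' and (residualized) network cost; its p-value is BH-adjusted within the
#' global family, which by default comprises network cost and the four
#' cost-integrated global topological metrics (global efficiency,
#' clustering, characteristic path length, betweenness), i.e. m = 5.
#' Level 2 (entered only if the cost test is rejected) tests each node's
#' degree with BH over the `R` nodes. Level 3 (entered only if level 2
#' rejected at least one node) tests every mask-retained edge incident to
#' a rejected node, each undirected edge once, with BH over that edge set.
#'
#' Bootstrap confidence intervals are computed for the rejected units only
#' (they are what gets reported), keeping runtime proportional to the
#' findings.
#'
#' @param stack A `connectome_stack` (unmasked).
#' @param mask An `edge_mask` from [population_edge_mask()].
#' @param cohort Cohort tibble aligned with the stack's subjects
#'   (`subject_id`, `recall_total`, `age`, `gender`, `icv`).
#' @param q FDR level at every level (default 0.05).
#' @param global_family Include the four cost-integrated metrics in the
#'   level-1 family (default `TRUE`). With `FALSE` the family is cost
#'   alone (m = 1), which skips the expensive cost-grid computation.
#' @param grid_points Cost-grid resolution for the cost-integrated metrics.
#' @param n_random Random references for normalized path length inside the
#'   cost-integrated family; 0 (default) uses the unnormalized length.
#' @param B Bootstrap replicates for CIs of rejected units.
#' @param seed RNG seed (bootstrap).
#' @return Object of class `recall_cascade`; see [tidy.recall_cascade()].
#' @export
hierarchical_cascade <- function(stack, mask, cohort, q = 0.05,
                                 global_family = TRUE, grid_points = 10,
                                 n_random = 0, B = 2000, seed = NULL) {
  stopifnot(inherits(stack, "connectome_stack"), inherits(mask, "edge_mask"))
  if (!identical(cohort$subject_id, stack$subject_id)) {
    abort_recallnet("cohort and stack subjects are not aligned")
  }
  masked <- apply_edge_mask(stack, mask)
  n <- length(masked$subject_id)
  ry <- residualize(cohort$recall_total, recall_design(cohort))
  net_cov <- network_design(cohort)

  # ---- level 1: global family -------------------------------------------
  cost <- stack_costs(masked)
  glob <- tibble::tibble(metric = "cost", value = list(unname(cost)))
  if (global_family) {
    grid <- cost_grid(masked, n = grid_points)
    ci_metrics <- list(
      global_efficiency = global_efficiency,
      clustering = function(w) weighted_clustering(w)$global,
      char_path_length = function(w) {
        as.numeric(characteristic_path_length(
          w, normalize = n_random > 0, n_random = n_random, seed = seed))
      },
      betweenness = function(w) mean(betweenness_centrality(w))
    )
    for (nm in names(ci_metrics)) {
      vals <- vapply(masked$subject_id, function(id) {
        as.numeric(cost_integrated_metric(connectome_matrix(masked, id),
                                          ci_metrics[[nm]], grid))
      }, numeric(1))
      glob <- dplyr::bind_rows(glob,
        tibble::tibble(metric = nm, value = list(unname(vals))))
    }
  }
  level1 <- purrr::pmap_dfr(glob, function(metric, value) {
    rx <- residualize(value, net_cov)
    r <- spearman_r(rx, ry)
    tibble::tibble(metric = metric, r = r, p = spearman_p(r, n))
  })
  fdr1 <- bh_fdr(level1$p, q = q)
  level1$p_adj <- fdr1$adjusted
  level1$rejected <- seq_len(nrow(level1)) %in% fdr1$rejected
  cost_row <- which(level1$metric == "cost")
  ci1 <- spearman_assoc(residualize(unname(cost), net_cov), ry, B = B, seed = seed)
  level1$ci_low <- NA_real_; level1$ci_high <- NA_real_
  level1$ci_low[cost_row] <- ci1$ci_low
  level1$ci_high[cost_row] <- ci1$ci_high
  gate1 <- level1$rejected[cost_row]

  # ---- level 2: nodal degree --------------------------------------------
  level2 <- tibble::tibble()
  rejected_nodes <- integer(0)
  critical_p2 <- NA_real_
  if (gate1) {
    deg <- stack_degrees(masked)
    RD <- residualize_matrix(deg, net_cov)
    rvec <- drop(stats::cor(RD, ry, method = "spearman"))
    pvec <- vapply(rvec, spearman_p, numeric(1), n = n)
    fdr2 <- bh_fdr(pvec, q = q)
    rejected_nodes <- fdr2$rejected
    critical_p2 <- fdr2$critical_p
    level2 <- tibble::tibble(node = seq_len(masked$R),
                             label = masked$atlas$label,
                             r = rvec, p = pvec, p_adj = fdr2$adjusted,
                             rejected = seq_along(pvec) %in% fdr2$rejected,
                             ci_low = NA_real_, ci_high = NA_real_)
    for (v in rejected_nodes) {
      ci <- spearman_assoc(RD[, v], ry, B = B, seed = seed)
      level2$ci_low[v] <- ci$ci_low
      level2$ci_high[v] <- ci$ci_high
    }
  }

  # ---- level 3: edges incident to rejected nodes ------------------------
  level3 <- tibble::tibble()
  rejected_edges <- tibble::tibble()
  critical_p3 <- NA_real_
  n_profile_edges <- 0L
  if (length(rejected_nodes) > 0) {
    pr <- masked$pairs
    incident <- (pr$i %in% rejected_nodes) | (pr$j %in% rejected_nodes)
    n_profile_edges <- sum(incident)
    sel <- pr[incident & mask$retained_edges, ]
    if (nrow(sel) > 0) {
      EV <- masked$weights[, sel$idx, drop = FALSE]
      REV <- residualize_matrix(EV, net_cov)
      rvec <- drop(stats::cor(REV, ry, method = "spearman"))
      pvec <- vapply(rvec, spearman_p, numeric(1), n = n)
      fdr3 <- bh_fdr(pvec, q = q)
      critical_p3 <- fdr3$critical_p
      level3 <- tibble::tibble(i = sel$i, j = sel$j,
                               label_i = masked$atlas$label[sel$i],
                               label_j = masked$atlas$label[sel$j],
                               r = rvec, p = pvec, p_adj = fdr3$adjusted,
                               rejected = seq_along(pvec) %in% fdr3$rejected,
                               ci_low = NA_real_, ci_high = NA_real_)
      for (k in fdr3$rejected) {
        ci <- spearman_assoc(REV[, k], ry, B = B, seed = seed)
        level3$ci_low[k] <- ci$ci_low
        level3$ci_high[k] <- ci$ci_high
      }
      rejected_edges <- level3[level3$rejected, c("i", "j", "label_i", "label_j", "r", "p")]
    }
  }

  structure(list(
    level1 = level1, level2 = level2, level3 = level3,
    rejected_nodes = rejected_nodes, rejected_edges = rejected_edges,
    critical_p = c(level1 = fdr1$critical_p,
                   level2 = critical_p2, level3 = critical_p3),
    n_profile_edges = n_profile_edges,
    n_tested = c(level1 = nrow(level1), level2 = nrow(level2),
                 level3 = nrow(level3)),
    q = q, n = n
  ), class = "recall_cascade")
}

#' @export
print.recall_cascade <- function(x, ...) {
  cat(sprintf("<recall_cascade> n = %d, q = %g\n", x$n, x$q))
  l1 <- x$level1[x$level1$metric == "cost", ]
  cat(sprintf("  level 1 (cost): r = %.3f, p = %.2g, p_adj = %.2g (%s)\n",
              l1$r, l1$p, l1$p_adj,
              if (l1$rejected) "rejected" else "not rejected"))
  if (nrow(x$level2)) {
    cat(sprintf("  level 2: %d of %d nodes rejected\n",
                length(x$rejected_nodes), nrow(x$level2)))
  } else cat("  level 2: not entered\n")
  if (nrow(x$level3)) {
    cat(sprintf("  level 3: %d of %d edges rejected\n",
                nrow(x$rejected_edges), nrow(x$level3)))
  } else cat("  level 3: not entered\n")
  invisible(x)
}

#' Tidy a hierarchical cascade result
#'
#' @param x A `recall_cascade`.
#' @param ... Unused.
#' @return One tibble stacking all three levels, with a `level` column and
#'   a `unit` column (metric name, node label, or `label_i--label_j`).
#' @export
tidy.recall_cascade <- function(x, ...) {
  out <- list(
    dplyr::mutate(x$level1, level = 1L, unit = metric, .before = 1L)
  )
  if (nrow(x$level2)) {
    out <- c(out, list(dplyr::mutate(x$level2, level = 2L, unit = label,
                                     .before = 1L)))
  }
  if (nrow(x$level3)) {
    out <- c(out, list(dplyr::mutate(x$level3, level = 3L,
                                     unit = paste0(label_i, "--", label_j),
                                     .before = 1L)))
  }
  dplyr::bind_rows(out) |>
    dplyr::select(level, unit, r, p, p_adj, rejected, ci_low, ci_high,
                  dplyr::any_of(c("metric", "label", "label_i", "label_j", "i", "j")))
}

#' Cascade summary
#'
#' @param x A `recall_cascade`.
#' @param ... Unused.
#' @return One-row tibble: cost association, number of rejected nodes and
#'   edges, per-level critical p-values.
#' @export
glance.recall_cascade <- function(x, ...) {
  l1 <- x$level1[x$level1$metric == "cost", ]
  tibble::tibble(
    r_cost = l1$r, p_cost = l1$p, p_cost_adj = l1$p_adj,
    n_rejected_nodes = length(x$rejected_nodes),
    n_rejected_edges = nrow(x$rejected_edges),
    critical_p_nodes = unname(x$critical_p["level2"]),
    critical_p_edges = unname(x$critical_p["level3"]),
    q = x$q, n = x$n
  )
}

#' Plot the nodal level of a cascade
#'
#' Per-node association strength with the FDR decision highlighted.
#'
#' @param object A `recall_cascade` whose level 2 was entered.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recall_cascade <- function(object, ...) {
  if (!nrow(object$level2)) {
    abort_recallnet("level 2 was not entered; nothing to plot")
  }
  df <- object$level2
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(label, r), y = r,
                                   fill = rejected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#B2182B"),
                               name = sprintf("FDR q < %g", object$q)) +
    ggplot2::labs(x = NULL, y = "Spearman r (degree vs recall)",
                  title = "Nodal degree associations with free recall") +
    ggplot2::theme_minimal(base_size = 9)
}
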