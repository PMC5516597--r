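# Phenotype-network association machinery: residualization, Spearman
# associations with percentile-bootstrap CIs, BH FDR, robust regression,
# volumetry and control analyses.

#' Residualize a variable on covariates
#'
#' Ordinary least-squares residuals of `y` regressed on the covariate
#' design plus an intercept. Used to remove age/gender (and, for network
#' properties and volumes, intracranial volume) before rank-based
#' association testing; residualization precedes ranking.
#'
#' @param y Numeric response vector.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column; one is added). `NULL` or zero columns means demeaning only.
#' @return Residual vector (mean approximately 0, orthogonal to every
#'   covariate column).
#' @export
residualize <- function(y, covariates = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    X <- cbind(X, cm)
  }
  if (anyNA(y) || anyNA(X)) abort_recallnet("missing values in residualization")
  if (n <= ncol(X)) abort_recallnet("not enough observations for the design")
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort_recallnet("rank-deficient covariate design")
  unname(qr.resid(qx, y))
}

# Residualize every column of a matrix against one design (single QR).
residualize_matrix <- function(Y, covariates = NULL) {
  n <- nrow(Y)
  X <- cbind(rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    X <- cbind(X, cm)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort_recallnet("rank-deficient covariate design")
  qr.resid(qx, Y)
}

spearman_r <- function(x, y) stats::cor(x, y, method = "spearman")

spearman_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman association with percentile-bootstrap confidence interval
#'
#' Spearman rank correlation on average-ranked data (ties averaged), a
#' two-sided p-value from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom, and a 95%
#' percentile bootstrap CI over resampled subject pairs.
#'
#' @param x,y Numeric vectors of equal length (`n >= 10`).
#' @param B Bootstrap replicates (default 2000); `B = 0` skips the CI.
#' @param seed Optional RNG seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble of class `recallnet_assoc`: `r`, `p`,
#'   `ci_low`, `ci_high`, `n`, `B`.
#' @export
spearman_assoc <- function(x, y, B = 2000, seed = NULL, conf_level = 0.95) {
  n <- length(x)
  if (length(y) != n) abort_recallnet("x and y must have the same length")
  if (n < 10) abort_recallnet("need at least 10 observations")
  if (stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10) {
    abort_recallnet("constant input: Spearman correlation undefined")
  }
  r <- spearman_r(x, y)
  p <- spearman_p(r, n)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    rb <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      suppressWarnings(spearman_r(x[idx], y[idx]))
    }, numeric(1))
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(rb, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE))
  }
  out <- tibble::tibble(r = r, p = p, ci_low = ci[1], ci_high = ci[2],
                        n = n, B = B)
  class(out) <- c("recallnet_assoc", class(out))
  out
}

#' Benjamini-Hochberg FDR over a family of p-values
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, reject
#' the `k*` smallest where `k* = max{k : p_(k) <= k q / m}`. Also returns
#' the BH-adjusted p-values (monotone form, `stats::p.adjust`).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List of class `bh_fdr`: `rejected` (indices into `pvals`),
#'   `critical_p` (largest rejected p-value, `NA` if none), `adjusted`,
#'   `q`, `m`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) abort_recallnet("empty p-value vector")
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort_recallnet("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvals, method = "BH")
  rejected <- which(adjusted <= q)
  critical_p <- if (length(rejected)) max(pvals[rejected]) else NA_real_
  structure(list(rejected = rejected, critical_p = critical_p,
                 adjusted = adjusted, q = q, m = length(pvals)),
            class = "bh_fdr")
}

#' @export
print.bh_fdr <- function(x, ...) {
  cat(sprintf("<bh_fdr> %d of %d rejected at q = %g (critical p = %s)\n",
              length(x$rejected), x$m, x$q,
              if (is.na(x$critical_p)) "none" else format(x$critical_p)))
  invisible(x)
}

#' Robust multi-edge regression (Tukey bisquare IRLS)
#'
#' Iteratively reweighted least squares with the Tukey bisquare weight
#' function: residuals are scaled by `MAD / 0.6745`, weights are
#' `(1 - u^2)^2` for `|u| < 1` (zero beyond), with tuning constant
#' `c = 4.685` (95% Gaussian efficiency). Iterated until the largest
#' coefficient change falls below `tol` or `max_iter` is reached. The
#' variance explained is `1 - SSE/SST` using the unweighted residuals of
#' the converged fit.
#'
#' @param y Response (e.g. residualized recall).
#' @param X Predictor matrix or data frame (e.g. per-subject edge values);
#'   an intercept is added.
#' @param c Bisquare tuning constant (default 4.685).
#' @param tol Convergence tolerance on coefficients (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `robust_fit`: coefficients, fitted values,
#'   residuals, `r_squared`, `iterations`, `converged`, `c`.
#' @export
robust_r2 <- function(y, X, c = 4.685, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- length(y)
  if (n != nrow(X)) abort_recallnet("y and X sizes differ")
  if (n <= ncol(X) + 1L) abort_recallnet("need n > predictors + 1")
  Xi <- cbind(`(Intercept)` = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) abort_recallnet("singular design")
  beta <- qr.coef(qr(Xi), y)  # OLS start
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    res <- y - drop(Xi %*% beta)
    sigma <- stats::mad(res, center = stats::median(res))
    if (sigma < 1e-12) { converged <- TRUE; break }
    u <- res / (c * sigma)
    wts <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(wts == 0)) break
    fit <- stats::lm.wfit(Xi, y, w = wts)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) abort_recallnet("singular weighted design")
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  res <- y - drop(Xi %*% beta)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / sst
  structure(list(coefficients = beta, fitted = y - res, residuals = res,
                 r_squared = max(0, min(1, r2)), iterations = iter,
                 converged = converged, c = c, n = n, p = ncol(X)),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> %d predictors, n = %d, R^2 = %.4f (%s in %d iterations)\n",
              x$p, x$n, x$r_squared,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

# Standard covariate designs ------------------------------------------------

# recall is adjusted for age and gender; network properties and volumes
# additionally for intracranial volume.
recall_design <- function(cohort, extra = NULL) {
  d <- data.frame(age = cohort$age, gender = cohort$gender)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

network_design <- function(cohort, extra = NULL) {
  d <- data.frame(age = cohort$age, gender = cohort$gender, icv = cohort$icv)
  if (!is.null(extra)) d <- cbind(d, extra)
  d
}

#' Cost-recall association with covariate adjustment
#'
#' The level-1 global test: recall is residualized on age and gender, the
#' per-subject network cost on age, gender and intracranial volume, and
#' the two residual vectors are Spearman-correlated.
#'
#' @param cost Per-subject network cost (see [stack_costs()]).
#' @param cohort Cohort tibble with `recall_total`, `age`, `gender`, `icv`.
#' @param B,seed Bootstrap settings passed to [spearman_assoc()].
#' @return A `recallnet_assoc` tibble row.
#' @export
cost_recall_association <- function(cost, cohort, B = 2000, seed = NULL) {
  ry <- residualize(cohort$recall_total, recall_design(cohort))
  rc <- residualize(cost, network_design(cohort))
  spearman_assoc(rc, ry, B = B, seed = seed)
}

#' Attention / working-memory control analysis
#'
#' Re-runs the cost-recall association with a non-episodic cognitive
#' covariate (0-back attention accuracy, then 2-back minus 0-back working
#' memory) added to both residualization designs, to check that the global
#' association does not reflect those domains.
#'
#' @param cost Per-subject network cost.
#' @param cohort Cohort tibble with `attention` and `working_memory`.
#' @param B,seed Bootstrap settings.
#' @return Tibble with one row per control variable (`control`, `r`, `p`,
#'   CI bounds).
#' @export
control_analysis <- function(cost, cohort, B = 2000, seed = NULL) {
  if (!all(c("attention", "working_memory") %in% names(cohort))) {
    abort_recallnet("cohort lacks attention/working_memory columns")
  }
  purrr::map_dfr(c("attention", "working_memory"), function(ctrl) {
    extra <- stats::setNames(data.frame(cohort[[ctrl]]), ctrl)
    ry <- residualize(cohort$recall_total, recall_design(cohort, extra))
    rc <- residualize(cost, network_design(cohort, extra))
    spearman_assoc(rc, ry, B = B, seed = seed) |>
      dplyr::mutate(control = ctrl, .before = 1L)
  })
}

#' Grey-matter volumetry control analysis
#'
#' Per-node Spearman association between recall and regional grey-matter
#' volume: recall residualized on age and gender, each node's volume on
#' age, gender and intracranial volume, BH FDR over nodes; plus the
#' whole-brain mean-volume association.
#'
#' @param cohort Cohort tibble containing per-node volume columns named
#'   `vol_<label>` for every atlas label.
#' @param atlas Atlas tibble.
#' @param q FDR level.
#' @param B,seed Bootstrap settings for the whole-brain association.
#' @return List of class `volume_assoc`: `nodes` (tibble with per-node
#'   `r`, `p`, `p_adj`, `rejected`), `mean_volume` (assoc row), `fdr`.
#' @export
volume_association <- function(cohort, atlas = dk_atlas(), q = 0.05,
                               B = 2000, seed = NULL) {
  vcols <- paste0("vol_", atlas$label)
  if (!all(vcols %in% names(cohort))) abort_recallnet("missing per-node volume columns")
  V <- as.matrix(cohort[, vcols])
  ry <- residualize(cohort$recall_total, recall_design(cohort))
  RV <- residualize_matrix(V, network_design(cohort))
  rvec <- drop(stats::cor(RV, ry, method = "spearman"))
  n <- nrow(cohort)
  pvec <- vapply(rvec, spearman_p, numeric(1), n = n)
  fdr <- bh_fdr(pvec, q = q)
  nodes <- tibble::tibble(label = atlas$label, r = rvec, p = pvec,
                          p_adj = fdr$adjusted,
                          rejected = seq_along(pvec) %in% fdr$rejected)
  mean_assoc <- spearman_assoc(residualize(rowMeans(V), network_design(cohort)),
                               ry, B = B, seed = seed)
  structure(list(nodes = nodes, mean_volume = mean_assoc, fdr = fdr, q = q),
            class = "volume_assoc")
}

#' @export
print.volume_assoc <- function(x, ...) {
  cat(sprintf("<volume_assoc> %d of %d nodes FDR-rejected at q = %g; mean-volume r = %.3f (p = %.3g)\n",
              sum(x$nodes$rejected), nrow(x$nodes), x$q,
              x$mean_volume$r, x$mean_volume$p))
  invisible(x)
}
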