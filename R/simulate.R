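# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis pipeline assumes: a
# cohort of subjects sharing one sparse weighted template connectome, a
# global multiplicative subject factor that induces a monotone cost-recall
# association (Gaussian copula between the subject factor and a latent
# memory trait), a set of planted effect edges carrying additional
# memory-related deviations, valence-graded binomial recall counts,
# age/gender/ICV confounding on both sides, and null grey-matter volumes.
#
# The two effect-size dials (`rho_global`, `edge_r2_target`) are specified
# on the scale the pipeline MEASURES (Spearman of residualized cost vs
# residualized recall; in-sample R^2 of the planted edges at the cohort's
# n), and are reached by root-finding on the latent copula correlation and
# the edge loading over a reduced Monte-Carlo model of the measurement
# chain. Calibration results are cached per configuration.

#' Synthetic cohort configuration
#'
#' Defaults describe the emulated study: n = 664 subjects, 82 nodes, a
#' global cost-recall rank correlation of 0.102, 22 effect edges jointly
#' explaining 7.8% of recall variance, recall counts out of 24 pictures
#' per valence (72 in total) with emotional material remembered better
#' than neutral, age ~ N(22.85, 3.37^2) years, 59% female, and volumes
#' unrelated to memory.
#'
#' @param n Number of subjects.
#' @param R Number of nodes.
#' @param template_density Fraction of possible edges present in the
#'   template connectome.
#' @param weight_meanlog,weight_sdlog Lognormal parameters of template
#'   edge weights (clipped to `(0, 1]`).
#' @param template_seed Seed fixing the template (and effect-edge choice)
#'   across replicate cohorts.
#' @param subject_scale_sd SD of the log subject scale factor.
#' @param edge_noise_sdlog SD (log scale) of multiplicative per-edge noise.
#' @param rho_global Target Spearman correlation between residualized
#'   network cost and residualized recall (population value of the
#'   measured statistic).
#' @param n_effect_edges Number of planted effect edges (chosen among the
#'   strongest template edges of the highest-strength nodes when
#'   `effect_edges` is `NULL`).
#' @param effect_edges Optional tibble with columns `i`, `j` selecting the
#'   planted edges explicitly.
#' @param edge_r2_target Target in-sample variance fraction of recall
#'   explained by the planted edges at this `n` (0 disables edge effects).
#' @param valence_p Baseline recall probabilities per valence
#'   (negative/neutral/positive); emotional valences exceed neutral.
#' @param pictures_per_valence Pictures shown per valence category.
#' @param beta_memory Loading of the latent memory trait on the recall
#'   logit.
#' @param cov_cost Loadings of standardized age/gender/ICV on the log
#'   subject scale (confounding of cost).
#' @param cov_recall Loadings of standardized age/gender on the recall
#'   logit.
#' @param age_mean,age_sd,p_female,icv_mean,icv_sd Covariate distributions.
#' @param vol_sdlog Lognormal noise SD of per-node grey-matter volumes.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n = 664, R = 82,
                         template_density = 0.35,
                         weight_meanlog = -3.2, weight_sdlog = 1.1,
                         template_seed = 101,
                         subject_scale_sd = 0.2,
                         edge_noise_sdlog = 0.5,
                         rho_global = 0.102,
                         n_effect_edges = 22,
                         effect_edges = NULL,
                         edge_r2_target = 0.078,
                         valence_p = c(negative = 0.35, neutral = 0.22,
                                       positive = 0.30),
                         pictures_per_valence = 24,
                         beta_memory = 0.8,
                         cov_cost = c(age = -0.05, gender = 0, icv = 0.05),
                         cov_recall = c(age = -0.1, gender = 0.1),
                         age_mean = 22.85, age_sd = 3.37,
                         p_female = 0.59,
                         icv_mean = 1.5e6, icv_sd = 1.5e5,
                         vol_sdlog = 0.08) {
  cfg <- as.list(environment())
  if (cfg$template_density < 0 || cfg$template_density > 1) {
    abort_recallnet("template_density must be in [0, 1]")
  }
  if (abs(cfg$rho_global) >= 1) abort_recallnet("|rho_global| must be < 1")
  if (cfg$edge_r2_target < 0 || cfg$edge_r2_target >= 1) {
    abort_recallnet("edge_r2_target must be in [0, 1)")
  }
  if (n_pairs(cfg$R) * cfg$template_density < cfg$R - 1) {
    abort_recallnet("template_density below the spanning-tree minimum")
  }
  p_eff <- if (!is.null(cfg$effect_edges)) nrow(cfg$effect_edges) else cfg$n_effect_edges
  if (cfg$edge_r2_target > 0 && cfg$n <= p_eff + 2) {
    abort_recallnet("n must exceed the number of effect edges + 2 when edge_r2_target > 0")
  }
  structure(cfg, class = "synth_config")
}

#' Build a connected weighted template connectome
#'
#' A random spanning tree guarantees connectedness; the remaining edges
#' are sampled uniformly until the requested density is reached. Weights
#' are lognormal, clipped to `(0, 1]`.
#'
#' @param R Node count.
#' @param template_density Fraction of possible edges that are nonzero.
#' @param weight_meanlog,weight_sdlog Lognormal weight parameters.
#' @param seed RNG seed.
#' @return Symmetric `R x R` weighted matrix.
#' @export
make_template <- function(R, template_density, weight_meanlog = -3.2,
                          weight_sdlog = 1.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- n_pairs(R)
  n_edges <- round(template_density * np)
  if (n_edges < R - 1) abort_recallnet("density below the spanning-tree minimum")
  perm <- sample.int(R)
  tree_i <- integer(R - 1L); tree_j <- integer(R - 1L)
  for (k in 2:R) {
    a <- perm[k]; b <- perm[sample.int(k - 1L, 1L)]
    tree_i[k - 1L] <- min(a, b); tree_j[k - 1L] <- max(a, b)
  }
  pr <- upper_pairs(R)
  tree_idx <- pr$idx[match(paste(tree_i, tree_j), paste(pr$i, pr$j))]
  extra <- setdiff(seq_len(np), tree_idx)
  n_extra <- n_edges - (R - 1L)
  chosen <- c(tree_idx, sample(extra, n_extra))
  wvals <- numeric(np)
  wvals[chosen] <- pmin(stats::rlnorm(n_edges, weight_meanlog, weight_sdlog), 1)
  unflatten_edges(wvals, R)
}

# Default planted edges: among template edges incident to the 7 strongest
# nodes, the n_effect strongest by template weight.
default_effect_edges <- function(template, n_effect, n_seed_nodes = 7L) {
  R <- nrow(template)
  pr <- upper_pairs(R)
  tvals <- flatten_edges(template)
  strength <- rowSums(template)
  seed_nodes <- order(strength, decreasing = TRUE)[seq_len(n_seed_nodes)]
  cand <- which(tvals > 0 & (pr$i %in% seed_nodes | pr$j %in% seed_nodes))
  if (length(cand) < n_effect) abort_recallnet("template too sparse for effect edges")
  take <- cand[order(-tvals[cand], pr$i[cand], pr$j[cand])][seq_len(n_effect)]
  pr[pr$idx %in% take, ]
}

# The default 82-node configuration carries the real parcellation; other
# node counts (used in scaled-down experiments) get a generic atlas.
cohort_atlas <- function(R) {
  if (R == 82L) return(dk_atlas())
  tibble::tibble(label = sprintf("n%03d", seq_len(R)),
                 hemisphere = rep(c("left", "right"), length.out = R),
                 region = sprintf("region%03d", seq_len(R)),
                 tissue_class = "cortical")
}

# --- calibration ----------------------------------------------------------

.calib_cache <- new.env(parent = emptyenv())

calib_key <- function(cfg) {
  fields <- cfg[setdiff(names(cfg), c())]
  paste(vapply(fields, function(x) paste(format(x, digits = 15), collapse = ","),
               character(1)), collapse = "|")
}

# Preserve the caller's RNG state.
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Simulate the measured statistics on the reduced chain: the network cost
# is replaced by its exact conditional mean times one CLT-aggregated noise
# term (the mean of ~1100 independent clipped multiplicative noises has
# relative SD ~3%), so calibration is O(n) per evaluation instead of
# O(n x edges).
calib_draws <- function(cfg, template, eff, n_sim, seed = 20260921) {
  tvals <- flatten_edges(template)
  tnz <- tvals[tvals > 0]
  noise_var <- exp(cfg$edge_noise_sdlog^2) - 1
  varfac <- noise_var * sum(tnz^2) / sum(tnz)^2
  set.seed(seed %% .Machine$integer.max)
  list(
    z1 = stats::rnorm(n_sim), z2 = stats::rnorm(n_sim),
    age_z = stats::rnorm(n_sim),
    gender = stats::rbinom(n_sim, 1, cfg$p_female),
    icv_z = stats::rnorm(n_sim),
    epsbar = 1 + sqrt(varfac) * stats::rnorm(n_sim),
    u_val = matrix(stats::runif(n_sim * 3), n_sim, 3),
    eps_eff = matrix(stats::rlnorm(n_sim * nrow(eff),
                                   -cfg$edge_noise_sdlog^2 / 2,
                                   cfg$edge_noise_sdlog), n_sim, nrow(eff)),
    tbar = mean(tvals), t_eff = flatten_edges(template)[eff$idx],
    sum_t = sum(tvals), np = n_pairs(cfg$R), n_sim = n_sim
  )
}

calib_measure <- function(cfg, d, rho_lat, loading) {
  m <- rho_lat * d$z1 + sqrt(1 - rho_lat^2) * d$z2
  gender_c <- d$gender - cfg$p_female
  log_s <- cfg$subject_scale_sd * d$z1 +
    cfg$cov_cost["age"] * d$age_z + cfg$cov_cost["gender"] * gender_c +
    cfg$cov_cost["icv"] * d$icv_z
  s <- exp(log_s)
  cost <- s * d$tbar * d$epsbar +
    loading * m * sum(d$t_eff) / d$np
  logit_base <- cfg$beta_memory * m +
    cfg$cov_recall["age"] * d$age_z + cfg$cov_recall["gender"] * gender_c
  recall <- 0
  for (v in seq_along(cfg$valence_p)) {
    pv <- stats::plogis(stats::qlogis(cfg$valence_p[[v]]) + logit_base)
    recall <- recall + stats::qbinom(d$u_val[, v], cfg$pictures_per_valence, pv)
  }
  covs_r <- cbind(age = d$age_z, gender = gender_c)
  covs_n <- cbind(covs_r, icv = d$icv_z)
  ry <- residualize(recall, covs_r)
  rc <- residualize(cost, covs_n)
  rho_hat <- spearman_r(rc, ry)
  r2_hat <- NA_real_
  if (nrow(d$eps_eff) > 0 && length(d$t_eff) > 0) {
    X <- sweep(d$eps_eff, 2L, d$t_eff, "*") * s +
      outer(m, loading * d$t_eff)
    X <- pmin(pmax(X, 0), 1)
    RX <- residualize_matrix(X, covs_r)
    fit <- stats::lm.fit(cbind(1, RX), ry)
    r2_hat <- 1 - sum(fit$residuals^2) / sum((ry - mean(ry))^2)
  }
  list(rho = rho_hat, r2 = r2_hat)
}

#' Calibrate the generator's latent parameters
#'
#' Finds the Gaussian-copula correlation and the planted-edge loading such
#' that the measured cost-recall Spearman correlation and the in-sample
#' edge R^2 (at the configured `n` and number of effect edges) hit their
#' targets. The in-sample R^2 target is converted to a population target
#' by the standard inflation `E[R^2] ~ rho^2 + (1 - rho^2) p / (n - 1)`.
#' Results are cached per configuration; the caller's RNG state is left
#' untouched.
#'
#' @param config A `synth_config`.
#' @param n_sim Monte-Carlo sample size of the calibration chain.
#' @return List with `rho_lat`, `edge_loading`, and the achieved values.
#' @export
calibrate_generator <- function(config, n_sim = 2e5) {
  key <- calib_key(config)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  out <- with_preserved_rng({
    template <- make_template(config$R, config$template_density,
                              config$weight_meanlog, config$weight_sdlog,
                              seed = config$template_seed)
    eff <- resolve_effect_edges(config, template)
    d <- calib_draws(config, template, eff, n_sim)

    solve_rho <- function(loading) {
      if (config$rho_global == 0) return(0)
      f <- function(r) calib_measure(config, d, r, loading)$rho - config$rho_global
      hi <- f(0.95)
      if (hi < 0) {
        abort_recallnet(sprintf(
          "infeasible rho_global: achievable at most %.3f under these noise levels",
          hi + config$rho_global))
      }
      stats::uniroot(f, c(-0.95, 0.95), tol = 1e-4)$root
    }
    p_eff <- nrow(eff)
    r2_pop_target <- if (config$edge_r2_target > 0) {
      max(0, (config$edge_r2_target - p_eff / (config$n - 1)) /
               (1 - p_eff / (config$n - 1)))
    } else 0
    solve_loading <- function(rho_lat) {
      if (config$edge_r2_target == 0) return(0)
      g <- function(a) calib_measure(config, d, rho_lat, a)$r2 - r2_pop_target
      g0 <- g(0)
      if (g0 >= 0) return(0)  # baseline already reaches the target
      hi <- g(3)
      if (hi < 0) {
        abort_recallnet(sprintf(
          "infeasible edge_r2_target: achievable at most %.3f",
          hi + r2_pop_target))
      }
      stats::uniroot(g, c(0, 3), tol = 1e-5)$root
    }

    # The fitted quantity is the bisquare-IRLS R^2, slightly below the OLS
    # R^2 used inside the fast root-finder; one correction pass re-solves
    # with the OLS target shifted by the measured gap.
    robust_gap <- function(rho_lat, a) {
      if (a == 0) return(0)
      sub <- seq_len(min(5e4, d$n_sim))
      ds <- lapply(d, function(x) {
        if (is.matrix(x) && nrow(x) == d$n_sim) x[sub, , drop = FALSE]
        else if (length(x) == d$n_sim) x[sub] else x
      })
      ds$n_sim <- length(sub)
      mm <- calib_measure(config, ds, rho_lat, a)
      m_l <- rho_lat * ds$z1 + sqrt(1 - rho_lat^2) * ds$z2
      gender_c <- ds$gender - config$p_female
      s <- exp(config$subject_scale_sd * ds$z1 +
                 config$cov_cost["age"] * ds$age_z +
                 config$cov_cost["gender"] * gender_c +
                 config$cov_cost["icv"] * ds$icv_z)
      X <- sweep(ds$eps_eff, 2L, ds$t_eff, "*") * s + outer(m_l, a * ds$t_eff)
      X <- pmin(pmax(X, 0), 1)
      logit_base <- config$beta_memory * m_l +
        config$cov_recall["age"] * ds$age_z +
        config$cov_recall["gender"] * gender_c
      recall <- 0
      for (v in seq_along(config$valence_p)) {
        pv <- stats::plogis(stats::qlogis(config$valence_p[[v]]) + logit_base)
        recall <- recall + stats::qbinom(ds$u_val[, v],
                                         config$pictures_per_valence, pv)
      }
      covs_r <- cbind(age = ds$age_z, gender = gender_c)
      ry <- residualize(recall, covs_r)
      mm$r2 - robust_r2(ry, residualize_matrix(X, covs_r))$r_squared
    }

    rho_lat <- solve_rho(0)
    loading <- solve_loading(rho_lat)
    rho_lat <- solve_rho(loading)   # second pass: effect edges feed cost
    loading <- solve_loading(rho_lat)
    if (loading > 0) {
      gap <- robust_gap(rho_lat, loading)
      r2_pop_target <- r2_pop_target + max(0, gap)
      loading <- solve_loading(rho_lat)
    }
    ach <- calib_measure(config, d, rho_lat, loading)
    list(rho_lat = rho_lat, edge_loading = loading,
         achieved_rho = ach$rho, achieved_r2_pop = ach$r2,
         r2_pop_target = r2_pop_target, n_sim = n_sim)
  })
  .calib_cache[[key]] <- out
  out
}

resolve_effect_edges <- function(config, template) {
  pr <- upper_pairs(config$R)
  if (!is.null(config$effect_edges)) {
    eff <- dplyr::inner_join(tibble::as_tibble(config$effect_edges[, c("i", "j")]),
                             pr, by = c("i", "j"))
    if (nrow(eff) != nrow(config$effect_edges)) {
      abort_recallnet("effect_edges outside the upper triangle")
    }
    if (any(flatten_edges(template)[eff$idx] == 0)) {
      abort_recallnet("effect_edges must lie in the template's nonzero set")
    }
    eff
  } else if (config$n_effect_edges > 0 && config$edge_r2_target > 0) {
    default_effect_edges(template, config$n_effect_edges)
  } else {
    upper_pairs(config$R)[0, ]
  }
}

#' Simulate a synthetic cohort
#'
#' Draws one cohort (connectome stack, phenotype table, per-node volumes)
#' from a configuration. The template and planted-edge identities are
#' fixed by `config$template_seed`, so replicate cohorts differ only in
#' subjects. Latent calibration (see [calibrate_generator()]) runs once
#' per configuration and is cached.
#'
#' @param config A `synth_config`.
#' @param seed RNG seed for the subject-level draws.
#' @return Object of class `synthetic_cohort`: `stack`
#'   (`connectome_stack`), `cohort` (tibble with phenotypes, covariates
#'   and `vol_*` columns), `truth` (planted parameters), `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  calib <- calibrate_generator(config)
  template <- make_template(config$R, config$template_density,
                            config$weight_meanlog, config$weight_sdlog,
                            seed = config$template_seed)
  eff <- resolve_effect_edges(config, template)
  # per-node base volumes are part of the template draw
  vol_base <- with_preserved_rng({
    set.seed(config$template_seed + 1L)
    exp(stats::rnorm(config$R, log(8000), 0.4))
  })

  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  np <- n_pairs(config$R)
  tvals <- flatten_edges(template)
  tidx <- which(tvals > 0)

  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  g <- z1
  m <- calib$rho_lat * z1 + sqrt(1 - calib$rho_lat^2) * z2
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  gender <- stats::rbinom(n, 1, config$p_female)
  icv <- stats::rnorm(n, config$icv_mean, config$icv_sd)
  age_z <- (age - config$age_mean) / config$age_sd
  icv_z <- (icv - config$icv_mean) / config$icv_sd
  gender_c <- gender - config$p_female

  log_s <- config$subject_scale_sd * g +
    config$cov_cost["age"] * age_z + config$cov_cost["gender"] * gender_c +
    config$cov_cost["icv"] * icv_z
  s <- exp(log_s)

  eps <- matrix(stats::rlnorm(n * length(tidx), -config$edge_noise_sdlog^2 / 2,
                              config$edge_noise_sdlog), n, length(tidx))
  W <- matrix(0, n, np)
  W[, tidx] <- (s * eps) * rep(tvals[tidx], each = n)
  if (nrow(eff) > 0 && calib$edge_loading > 0) {
    W[, eff$idx] <- W[, eff$idx] +
      outer(m, calib$edge_loading * tvals[eff$idx])
  }
  W <- pmin(pmax(W, 0), 1)

  ids <- sprintf("S%04d", seq_len(n))
  rownames(W) <- ids
  atlas <- cohort_atlas(config$R)
  stack <- new_connectome_stack(W, ids, atlas)

  logit_base <- config$beta_memory * m +
    config$cov_recall["age"] * age_z + config$cov_recall["gender"] * gender_c
  recall_v <- vapply(names(config$valence_p), function(v) {
    pv <- stats::plogis(stats::qlogis(config$valence_p[[v]]) + logit_base)
    stats::rbinom(n, config$pictures_per_valence, pv)
  }, numeric(n))

  attention <- pmin(pmax(stats::rnorm(n, 0.95, 0.04), 0), 1)
  working_memory <- stats::rnorm(n, 0.12, 0.08)

  V <- (icv / config$icv_mean) *
    matrix(stats::rlnorm(n * config$R, -config$vol_sdlog^2 / 2,
                         config$vol_sdlog), n, config$R) *
    rep(vol_base, each = n)
  colnames(V) <- paste0("vol_", atlas$label)

  cohort <- tibble::tibble(
    subject_id = ids,
    recall_negative = recall_v[, "negative"],
    recall_neutral = recall_v[, "neutral"],
    recall_positive = recall_v[, "positive"],
    recall_total = rowSums(recall_v),
    attention = attention, working_memory = working_memory,
    age = age, gender = gender, icv = icv
  ) |> dplyr::bind_cols(tibble::as_tibble(V))

  truth <- list(
    m = m, g = g, s = s,
    rho_lat = calib$rho_lat, edge_loading = calib$edge_loading,
    effect_edges = dplyr::mutate(eff, template_w = tvals[eff$idx]),
    seed = seed
  )
  structure(list(stack = stack, cohort = cohort, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d subjects, R = %d nodes, %d planted edges\n",
              x$config$n, x$config$R, nrow(x$truth$effect_edges)))
  cat(sprintf("  targets: rho_global = %g, edge_r2 = %g (latent rho = %.3f, loading = %.3f)\n",
              x$config$rho_global, x$config$edge_r2_target,
              x$truth$rho_lat, x$truth$edge_loading))
  invisible(x)
}

# --- fixture I/O ----------------------------------------------------------

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(round(x))),
         sprintf("%.17g", x))
}

#' Write a synthetic cohort as an on-disk fixture
#'
#' Emits exactly the formats the pipeline reads: `matrices/<id>.tsv`
#' connectivity matrices, `cohort.tsv`, `atlas.tsv`, plus `truth.json`
#' and `config.json` so the planted parameters travel with the data.
#' Writing is full-precision and deterministic: the same cohort always
#' produces byte-identical files.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output directory (created).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_connectome_stack(cohort$stack, file.path(path, "matrices"))
  df <- cohort$cohort
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, file.path(path, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_atlas(cohort$stack$atlas, file.path(path, "atlas.tsv"))
  truth <- cohort$truth
  truth$effect_edges <- as.data.frame(truth$effect_edges)
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  cfg <- unclass(cohort$config)
  cfg$effect_edges <- if (is.null(cfg$effect_edges)) NULL else as.data.frame(cfg$effect_edges)
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a fixture directory back
#'
#' @param path Directory written by [write_fixture()].
#' @return List with `stack`, `cohort`, `truth`, `config`.
#' @export
read_fixture <- function(path) {
  atlas <- read_atlas(file.path(path, "atlas.tsv"))
  stack <- read_connectome_stack(file.path(path, "matrices"), atlas)
  cohort <- tibble::as_tibble(
    utils::read.delim(file.path(path, "cohort.tsv"), stringsAsFactors = FALSE))
  truth <- jsonlite::read_json(file.path(path, "truth.json"),
                               simplifyVector = TRUE)
  config <- jsonlite::read_json(file.path(path, "config.json"),
                                simplifyVector = TRUE)
  list(stack = stack, cohort = cohort, truth = truth, config = config)
}
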