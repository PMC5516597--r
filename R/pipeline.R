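# End-to-end pipeline orchestration: mask -> metrics -> hierarchical
# cascade -> NBS -> volumetry -> robust multi-edge regression, with TSV
# reports and a JSON run manifest.

#' Pipeline configuration
#'
#' Collects the tunable parameters of a full run. Defaults mirror the
#' reference analysis: edge-exclusion floor 0.01, FDR level q = 0.05,
#' NBS threshold T = 2.5 with 10000 permutations and FWE alpha = 0.005,
#' 2000 bootstrap replicates.
#'
#' @param matrices,atlas,cohort Input paths (directory of per-subject
#'   matrix TSVs; atlas TSV; cohort TSV). Leave `NULL` when calling
#'   [run_pipeline()] with in-memory objects.
#' @param out Output directory for reports.
#' @param floor Population edge-exclusion floor.
#' @param q FDR level for the cascade and volumetry.
#' @param nbs_T,nbs_n_perm,nbs_alpha,nbs_sided NBS settings.
#' @param B Bootstrap replicates for confidence intervals.
#' @param global_family,grid_points,n_random Level-1 family settings (see
#'   [hierarchical_cascade()]).
#' @param seed Master RNG seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(matrices = NULL, atlas = NULL, cohort = NULL,
                            out = "recallnet_report", floor = 0.01, q = 0.05,
                            nbs_T = 2.5, nbs_n_perm = 10000,
                            nbs_alpha = 0.005, nbs_sided = "one",
                            B = 2000, global_family = TRUE, grid_points = 10,
                            n_random = 0, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$floor >= 0, cfg$q > 0, cfg$q < 1, cfg$nbs_n_perm >= 1)
  structure(cfg, class = "pipeline_config")
}

write_tsv_report <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes population edge masking, the global/nodal/edge hierarchical
#' FDR cascade, the network-based statistic, the grey-matter volumetry
#' control, and (when the cascade reaches level 3) the robust bisquare
#' regression of recall on the FDR edge set. All result tables are
#' written as TSV under `config$out`, alongside a JSON manifest recording
#' parameters, seed and package version. Stages whose gating hypothesis
#' failed are skipped, and the log records why.
#'
#' @param config A `pipeline_config`.
#' @param stack Optional in-memory `connectome_stack` (otherwise read from
#'   `config$matrices`).
#' @param cohort Optional in-memory cohort tibble (otherwise read from
#'   `config$cohort`).
#' @return List of class `pipeline_result` with elements `mask`,
#'   `cascade`, `nbs`, `volumes` (when volume columns exist),
#'   `robust_fit` (when level 3 was reached), and `out`.
#' @export
run_pipeline <- function(config, stack = NULL, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  if (is.null(stack)) {
    atlas <- if (is.null(config$atlas)) dk_atlas() else read_atlas(config$atlas)
    stack <- read_connectome_stack(config$matrices, atlas)
  }
  if (is.null(cohort)) {
    cohort <- tibble::as_tibble(
      utils::read.delim(config$cohort, stringsAsFactors = FALSE))
  }
  cohort <- cohort[match(stack$subject_id, cohort$subject_id), ]
  if (anyNA(cohort$subject_id)) abort_recallnet("cohort/stack subject mismatch")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  log_stage("mask", "floor = %g over %d subjects", config$floor,
            length(stack$subject_id))
  mask <- population_edge_mask(stack, floor = config$floor)
  log_stage("mask", "%d of %d edges retained", mask$n_retained,
            ncol(stack$weights))
  masked <- apply_edge_mask(stack, mask)

  log_stage("cascade", "q = %g, global_family = %s, seed = %d", config$q,
            config$global_family, config$seed)
  cascade <- hierarchical_cascade(stack, mask, cohort, q = config$q,
                                  global_family = config$global_family,
                                  grid_points = config$grid_points,
                                  n_random = config$n_random,
                                  B = config$B, seed = config$seed)
  write_tsv_report(cascade$level1, file.path(config$out, "global_metrics.tsv"))
  if (nrow(cascade$level2)) {
    write_tsv_report(dplyr::select(cascade$level2, -node),
                     file.path(config$out, "nodal_degree.tsv"))
  } else log_stage("cascade", "stopped at level 1 (global null not rejected)")
  if (nrow(cascade$level3)) {
    write_tsv_report(dplyr::select(cascade$level3, -i, -j),
                     file.path(config$out, "edges.tsv"))
  }

  log_stage("nbs", "T = %g, %d permutations, alpha = %g", config$nbs_T,
            config$nbs_n_perm, config$nbs_alpha)
  keep <- mask$retained_edges
  pairs <- masked$pairs[keep, ]
  nbs <- nbs_fwe(cohort$recall_total, masked$weights[, pairs$idx, drop = FALSE],
                 pairs = pairs,
                 covariates = cohort[, c("age", "gender", "icv")],
                 T = config$nbs_T, n_perm = config$nbs_n_perm,
                 alpha = config$nbs_alpha, sided = config$nbs_sided,
                 seed = config$seed, allow_small = TRUE)
  write_tsv_report(tidy(nbs), file.path(config$out, "nbs_components.tsv"))
  if (nrow(nbs$components)) {
    comp_edges <- purrr::map_dfr(seq_len(nrow(nbs$components)), function(k) {
      ed <- nbs$components$edges[[k]]
      tibble::tibble(component = k,
                     label_i = stack$atlas$label[ed$i],
                     label_j = stack$atlas$label[ed$j], t = ed$t)
    })
    write_tsv_report(comp_edges, file.path(config$out, "nbs_edges.tsv"))
  }

  volumes <- NULL
  if (any(startsWith(names(cohort), "vol_"))) {
    log_stage("volumes", "per-node grey-matter control analysis")
    volumes <- volume_association(cohort, stack$atlas, q = config$q,
                                  B = config$B, seed = config$seed)
    write_tsv_report(volumes$nodes, file.path(config$out, "volumetry.tsv"))
  }

  rfit <- NULL
  n_sel <- nrow(cascade$rejected_edges)
  if (n_sel > 0 && n_sel + 2 <= length(stack$subject_id)) {
    log_stage("robust", "bisquare regression on %d FDR edges", n_sel)
    EV <- edge_values(masked, cascade$rejected_edges[, c("i", "j")])
    ry <- residualize(cohort$recall_total, recall_design(cohort))
    rfit <- robust_r2(ry, EV)
    write_tsv_report(glance(rfit), file.path(config$out, "robust_fit.tsv"))
  } else if (n_sel > 0) {
    log_stage("robust", "skipped: %d selected edges exceed what n = %d supports",
              n_sel, length(stack$subject_id))
  }

  manifest <- list(
    package = "recallnet",
    version = as.character(utils::packageVersion("recallnet")),
    r_version = R.version.string,
    config = unclass(config),
    n_subjects = length(stack$subject_id),
    n_retained_edges = mask$n_retained,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  structure(list(mask = mask, cascade = cascade, nbs = nbs,
                 volumes = volumes, robust_fit = rfit, out = config$out),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cascade)
  print(x$nbs)
  if (!is.null(x$robust_fit)) print(x$robust_fit)
  cat(sprintf("  reports: %s\n", x$out))
  invisible(x)
}
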