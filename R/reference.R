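# Published summary statistics from the reference free-recall connectome
# study that this package re-implements. These tables are inputs to worked
# examples and consistency checks; they are not computed by the package.

ref_path <- function(file) {
  system.file("extdata", file, package = "recallnet", mustWork = TRUE)
}

read_ref <- function(file) {
  tibble::as_tibble(utils::read.delim(ref_path(file), stringsAsFactors = FALSE))
}

#' Reference association tables from the study this package models
#'
#' Loads the published summary statistics of the reference analysis: the
#' Spearman associations between picture free-recall performance and (a)
#' the degree and grey-matter volume of each of the 82 atlas nodes, (b) the
#' seven nodes surviving node-level FDR correction, (c) the 22 edges
#' surviving edge-level FDR correction, and (d) the five global network
#' metrics (network cost plus four cost-integrated topological metrics).
#'
#' @param which One of `"nodes"` (82 per-node degree/volume associations),
#'   `"fdr_nodes"` (7 FDR-significant nodes), `"fdr_edges"` (22
#'   FDR-significant edges), or `"global"` (5 global metrics).
#' @return A tibble; columns include `r` (Spearman coefficient) and `p`
#'   (nominal two-sided p-value), plus 95% bootstrap CI bounds where the
#'   source reported them.
#' @examples
#' reference_associations("global")
#' @export
reference_associations <- function(which = c("nodes", "fdr_nodes",
                                             "fdr_edges", "global")) {
  which <- match.arg(which)
  switch(which,
    nodes = read_ref("reference_node_associations.tsv"),
    fdr_nodes = read_ref("reference_fdr_nodes.tsv"),
    fdr_edges = read_ref("reference_fdr_edges.tsv"),
    global = read_ref("reference_global_metrics.tsv")
  )
}
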