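# Node atlas: the 82-region parcellation used for all connectivity matrices.

dk_cortical_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

subcortical_regions <- c(
  "thalamus", "caudate", "putamen", "pallidum",
  "hippocampus", "amygdala", "accumbens"
)

#' Default 82-region brain parcellation atlas
#'
#' Builds the canonical node atlas used throughout the package: the 34
#' Desikan-Killiany gyral regions per hemisphere (68 cortical nodes) plus 7
#' subcortical grey-matter structures per hemisphere (14 subcortical nodes),
#' 82 nodes in total. The row order of this table is the canonical node
#' index: every connectivity matrix the package reads or simulates is
#' indexed by it.
#'
#' @return A tibble with one row per node and columns `label` (unique,
#'   e.g. `"lh_fusiform"`), `hemisphere` (`"left"`/`"right"`), `region`
#'   (atlas region name), and `tissue_class` (`"cortical"`/`"subcortical"`).
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas) # 82
#' table(atlas$tissue_class)
#' @export
dk_atlas <- function() {
  cortical <- tidyr::expand_grid(
    hemisphere = c("left", "right"),
    region = dk_cortical_regions
  ) |>
    dplyr::mutate(tissue_class = "cortical")
  subcort <- tidyr::expand_grid(
    hemisphere = c("left", "right"),
    region = subcortical_regions
  ) |>
    dplyr::mutate(tissue_class = "subcortical")
  dplyr::bind_rows(cortical, subcort) |>
    dplyr::mutate(
      label = paste0(ifelse(hemisphere == "left", "lh_", "rh_"), region),
      .before = 1L
    )
}

#' Read a node atlas from a TSV file
#'
#' @param path TSV file with header columns `label`, `hemisphere`,
#'   `tissue_class` and optionally `region`.
#' @return A validated atlas tibble (see [dk_atlas()]).
#' @export
read_atlas <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"region" %in% names(df)) df$region <- sub("^(lh|rh)_", "", df$label)
  atlas <- tibble::as_tibble(df[, c("label", "hemisphere", "region", "tissue_class")])
  validate_atlas(atlas)
  atlas
}

#' Write a node atlas to a TSV file
#'
#' @param atlas Atlas tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  needed <- c("label", "hemisphere", "tissue_class")
  if (!all(needed %in% names(atlas))) {
    abort_recallnet("atlas must have columns label, hemisphere, tissue_class")
  }
  if (anyDuplicated(atlas$label)) abort_recallnet("atlas labels must be unique")
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    abort_recallnet("hemisphere must be 'left' or 'right'")
  }
  if (!all(atlas$tissue_class %in% c("cortical", "subcortical"))) {
    abort_recallnet("tissue_class must be 'cortical' or 'subcortical'")
  }
  invisible(atlas)
}
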