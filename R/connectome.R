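# Connectome data model and I/O.
#
# A single subject's connectome is a plain symmetric R x R numeric matrix of
# connection probabilities in [0, 1] with a zero diagonal. A cohort of
# connectomes is held as a `connectome_stack`: internally one
# subjects x edges matrix over the canonical upper-triangle edge order
# (single source of truth per undirected edge), plus the atlas.

#' Validate a weighted connectome matrix
#'
#' Checks the invariants every connectivity matrix in the package must
#' satisfy: square, numeric, symmetric, zero diagonal, and all weights in
#' `[0, 1]`.
#'
#' @param w An `R x R` numeric matrix.
#' @param R Optional expected node count (e.g. `nrow(atlas)`).
#' @param tol Symmetry tolerance.
#' @return `w`, invisibly. Errors describe the first violated invariant.
#' @export
validate_connectome <- function(w, R = NULL, tol = 1e-12) {
  if (!is.matrix(w) || !is.numeric(w)) abort_recallnet("connectome must be a numeric matrix")
  if (nrow(w) != ncol(w)) abort_recallnet("connectome must be square")
  if (!is.null(R) && nrow(w) != R) {
    abort_recallnet(sprintf("connectome is %dx%d but atlas has %d nodes",
                            nrow(w), ncol(w), R))
  }
  if (anyNA(w)) abort_recallnet("connectome contains missing values")
  if (max(abs(w - t(w))) > tol) {
    abort_recallnet("connectome is not symmetric; use symmetrize() explicitly")
  }
  if (any(diag(w) != 0)) abort_recallnet("connectome diagonal must be zero")
  if (any(w < 0)) abort_recallnet("negative connection weight")
  if (any(w > 1)) abort_recallnet("connection weight exceeds 1")
  invisible(w)
}

#' Symmetrize a directed connectivity matrix
#'
#' Probabilistic tractography yields direction-dependent connection
#' probabilities; the undirected connectome averages the two directions:
#' `w_ij = (p_ij + p_ji) / 2`. The diagonal is forced to zero.
#'
#' @param p Square non-negative numeric matrix of directed connection
#'   probabilities.
#' @return A symmetric matrix of the same dimension with zero diagonal.
#' @examples
#' p <- matrix(c(0, 0.2, 0.4, 0), 2, 2, byrow = TRUE)
#' symmetrize(p) # off-diagonals both 0.3
#' @export
symmetrize <- function(p) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) abort_recallnet("input must be a square matrix")
  if (any(p < 0)) abort_recallnet("negative connection probability")
  w <- (p + t(p)) / 2
  diag(w) <- 0
  w
}

#' Construct a connectome stack from per-subject matrices
#'
#' @param matrices Named list of validated symmetric `R x R` matrices; names
#'   are subject IDs (unique).
#' @param atlas Atlas tibble (see [dk_atlas()]); `nrow(atlas)` must match
#'   the matrix dimension.
#' @return A `connectome_stack` object.
#' @export
connectome_stack <- function(matrices, atlas = dk_atlas()) {
  validate_atlas(atlas)
  R <- nrow(atlas)
  ids <- names(matrices)
  if (is.null(ids) || anyDuplicated(ids) || any(ids == "")) {
    abort_recallnet("matrices must be a named list with unique subject IDs")
  }
  for (m in matrices) validate_connectome(m, R = R)
  weights <- do.call(rbind, lapply(matrices, flatten_edges))
  rownames(weights) <- ids
  new_connectome_stack(weights, ids, atlas)
}

new_connectome_stack <- function(weights, subject_id, atlas) {
  structure(
    list(weights = weights, subject_id = subject_id, atlas = atlas,
         R = nrow(atlas), pairs = upper_pairs(nrow(atlas))),
    class = "connectome_stack"
  )
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat(sprintf("<connectome_stack> %d subjects, %d nodes, %d possible edges\n",
              length(x$subject_id), x$R, ncol(x$weights)))
  nz <- mean(x$weights > 0)
  cat(sprintf("  nonzero edge fraction: %.3f\n", nz))
  invisible(x)
}

#' @export
length.connectome_stack <- function(x) length(x$subject_id)

#' Extract one subject's connectome matrix from a stack
#'
#' @param stack A `connectome_stack`.
#' @param subject Subject ID (character) or positional index.
#' @return A symmetric `R x R` matrix with the atlas labels as dimnames.
#' @export
connectome_matrix <- function(stack, subject) {
  idx <- if (is.character(subject)) match(subject, stack$subject_id) else subject
  if (is.na(idx) || idx < 1L || idx > length(stack$subject_id)) {
    abort_recallnet("unknown subject")
  }
  w <- unflatten_edges(stack$weights[idx, ], stack$R)
  dimnames(w) <- list(stack$atlas$label, stack$atlas$label)
  w
}

#' Read a directory of per-subject connectivity matrices
#'
#' Each file is a whitespace/tab-delimited `R x R` numeric table with no
#' header; the file stem (name without extension) is the subject ID.
#' Matrices must already be symmetric: asymmetric inputs are rejected so
#' that symmetrization ([symmetrize()]) is always an explicit step.
#'
#' @param path Directory containing the matrix files (`.tsv` or `.txt`).
#' @param atlas Atlas tibble defining the expected dimension and node order.
#' @return A `connectome_stack`, subjects ordered by sorted file name.
#' @export
read_connectome_stack <- function(path, atlas = dk_atlas()) {
  files <- sort(list.files(path, pattern = "\\.(tsv|txt)$", full.names = TRUE))
  if (length(files) == 0L) abort_recallnet("no matrix files found")
  mats <- lapply(files, function(f) {
    m <- as.matrix(utils::read.table(f, header = FALSE))
    dimnames(m) <- NULL
    if (!is.numeric(m)) abort_recallnet(sprintf("non-numeric cell in %s", basename(f)))
    m
  })
  names(mats) <- sub("\\.[^.]*$", "", basename(files))
  connectome_stack(mats, atlas)
}

#' Write a connectome stack as per-subject TSV matrices
#'
#' Writes full-precision (`%.17g`) tab-separated `R x R` tables, one file
#' per subject named `<subject_id>.tsv`, so a read-back round-trip is
#' exact.
#'
#' @param stack A `connectome_stack`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_connectome_stack <- function(stack, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (id in stack$subject_id) {
    w <- connectome_matrix(stack, id)
    dimnames(w) <- NULL
    lines <- apply(w, 1L, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
    writeLines(lines, file.path(path, paste0(id, ".tsv")))
  }
  invisible(path)
}

#' Population-level exclusion of spurious connections
#'
#' Probabilistic tractography produces many weak, unreliable connections.
#' Following common practice for cohort studies, an edge is kept only when
#' it is consistently present across subjects: edge `(i, j)` is retained
#' iff `mean(w_ij) + 2 * sd(w_ij) >= floor`, where mean and standard
#' deviation (sample, `n - 1` denominator) are taken across subjects. The
#' resulting mask is applied identically to every subject.
#'
#' @param stack A `connectome_stack` with at least two subjects.
#' @param floor Connectivity floor below which an edge is deemed spurious
#'   (default 0.01).
#' @return An `edge_mask` object: list with `retained` (logical `R x R`
#'   symmetric matrix), `retained_edges` (logical vector over the canonical
#'   edge order), `n_retained`, and `floor`.
#' @export
population_edge_mask <- function(stack, floor = 0.01) {
  stopifnot(inherits(stack, "connectome_stack"))
  if (length(stack$subject_id) < 2L) {
    abort_recallnet("population mask needs at least 2 subjects (sd undefined)")
  }
  mu <- colMeans(stack$weights)
  sdv <- apply(stack$weights, 2L, stats::sd)
  keep <- (mu + 2 * sdv) >= floor
  retained <- unflatten_edges(as.numeric(keep), stack$R) > 0
  structure(
    list(retained = retained, retained_edges = keep,
         n_retained = sum(keep), floor = floor),
    class = "edge_mask"
  )
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d retained undirected edges (floor = %g)\n",
              x$n_retained, x$floor))
  invisible(x)
}

#' Apply an edge mask to a connectome stack
#'
#' Sets excluded edges to zero weight in every subject. Zero-weight edges
#' are treated as absent by all graph algorithms.
#'
#' @param stack A `connectome_stack`.
#' @param mask An `edge_mask` from [population_edge_mask()].
#' @return A masked `connectome_stack`.
#' @export
apply_edge_mask <- function(stack, mask) {
  stopifnot(inherits(stack, "connectome_stack"), inherits(mask, "edge_mask"))
  if (length(mask$retained_edges) != ncol(stack$weights)) {
    abort_recallnet("mask dimension does not match stack")
  }
  w <- stack$weights
  w[, !mask$retained_edges] <- 0
  new_connectome_stack(w, stack$subject_id, stack$atlas)
}

#' Per-subject edge values as a tidy table or matrix
#'
#' @param stack A `connectome_stack`.
#' @param edges Optional tibble/data frame with columns `i`, `j` (node
#'   indices, `i < j`) selecting a subset of edges; default all edges.
#' @param tidy If `TRUE` return a long tibble (`subject_id`, `i`, `j`,
#'   `weight`); otherwise a subjects x edges numeric matrix.
#' @return Tibble or matrix of edge weights.
#' @export
edge_values <- function(stack, edges = NULL, tidy = FALSE) {
  stopifnot(inherits(stack, "connectome_stack"))
  if (is.null(edges)) {
    sel <- stack$pairs
  } else {
    sel <- dplyr::inner_join(tibble::as_tibble(edges[, c("i", "j")]),
                             stack$pairs, by = c("i", "j"))
    if (nrow(sel) != nrow(edges)) abort_recallnet("edge selection outside upper triangle")
  }
  m <- stack$weights[, sel$idx, drop = FALSE]
  if (!tidy) return(m)
  tidyr::expand_grid(subject_id = stack$subject_id, edge = seq_len(nrow(sel))) |>
    dplyr::mutate(i = sel$i[edge], j = sel$j[edge],
                  weight = as.vector(t(m))) |>
    dplyr::select(subject_id, i, j, weight)
}
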