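# Core data containers: 3D volumes, 2D slice sets, feature matrices.

#' Construct a 3D volume
#'
#' A `volume3d` wraps a 3D voxel array together with per-axis spacing (mm),
#' an axis-order tag naming which array axis runs inferior-to-superior
#' (axial), and a subject identifier. It is the source object from which 2D
#' axial slices are extracted.
#'
#' @param voxels numeric 3D array of intensities.
#' @param spacing numeric length-3 vector of voxel sizes in mm, all > 0.
#' @param axis_order character length-3 permutation of `c("x","y","z")`;
#'   the position of `"z"` marks the axial (slicing) axis.
#' @param subject_id character scalar identifying the subject.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1),
                     axis_order = c("x", "y", "z"),
                     subject_id = "subject") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (any(dim(voxels) < 1L))
    stop("all three volume dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers", call. = FALSE)
  axis_order <- as.character(axis_order)
  if (length(axis_order) != 3L || anyDuplicated(axis_order) ||
      !setequal(axis_order, c("x", "y", "z")))
    stop("`axis_order` must name three distinct axes from x, y, z",
         call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, axis_order = axis_order,
         subject_id = as.character(subject_id)[1]),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> subject=%s dims=%s spacing=%s mm axial axis=%d\n",
              x$subject_id, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              axial_axis(x)))
  invisible(x)
}

# Index (1..3) of the axial array axis.
axial_axis <- function(vol) match("z", vol$axis_order)

#' Construct a slice set
#'
#' A `slice_set` holds an ordered collection of 2D gray images, one per
#' record, with aligned metadata: subject ID, 0-based slice index, optional
#' parent-class label, optional stratum tag (e.g. sex), and an optional
#' GLCM-entropy score. `(subject_id, slice_index)` pairs must be unique.
#'
#' @param images list of numeric matrices (one 2D image per record).
#' @param meta data.frame with columns `subject_id`, `slice_index` and
#'   optionally `label`, `stratum`, `entropy` (plus any extra columns,
#'   which are carried along).
#' @param provenance named list recording generation parameters.
#' @return An object of class `slice_set`.
#' @export
slice_set <- function(images, meta, provenance = list()) {
  if (!is.list(images)) stop("`images` must be a list of matrices", call. = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (length(images) != nrow(meta))
    stop("`images` and `meta` must have the same length", call. = FALSE)
  for (req in c("subject_id", "slice_index"))
    if (!req %in% names(meta)) stop("meta lacks column ", req, call. = FALSE)
  meta$subject_id <- as.character(meta$subject_id)
  meta$slice_index <- as.integer(meta$slice_index)
  if (!"label" %in% names(meta)) meta$label <- NA_character_
  if (!"stratum" %in% names(meta)) meta$stratum <- NA_character_
  if (!"entropy" %in% names(meta)) meta$entropy <- NA_real_
  meta$label <- as.character(meta$label)
  meta$stratum <- as.character(meta$stratum)
  key <- paste(meta$subject_id, meta$slice_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, slice_index) pairs in slice set",
         call. = FALSE)
  if (nrow(meta) > 0) {
    ok <- vapply(images, function(im) is.matrix(im) && all(dim(im) >= 1L),
                 logical(1))
    if (!all(ok)) stop("every image must be a matrix of dims >= 1x1",
                       call. = FALSE)
    if (any(meta$slice_index < 0L))
      stop("slice_index must be >= 0", call. = FALSE)
  }
  rownames(meta) <- NULL
  structure(list(images = images, meta = meta, provenance = provenance),
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<slice_set> %d slices, %d subjects, labels: %s\n",
    nrow(m), length(unique(m$subject_id)),
    if (all(is.na(m$label))) "<none>"
    else paste(names(table(m$label)), table(m$label), sep = "=",
               collapse = ", ")))
  invisible(x)
}

#' Number of slices in a slice set
#' @param x a `slice_set`.
#' @return integer count of records.
#' @export
n_slices <- function(x) nrow(x$meta)

#' Subset a slice set by record position
#' @param x a `slice_set`.
#' @param idx integer vector of record positions (1-based).
#' @return a `slice_set` with the selected records, order preserved.
#' @export
subset_slices <- function(x, idx) {
  slice_set(x$images[idx], x$meta[idx, , drop = FALSE], x$provenance)
}

# Canonical per-slice sample id used to key feature rows and decomposition
# assignments.
slice_ids <- function(x) paste(x$meta$subject_id, x$meta$slice_index, sep = ":")

#' Construct a feature matrix
#'
#' Rows are samples (typically slices), columns are features. Sample IDs,
#' parent-class labels, and subject IDs are carried alongside so that
#' decomposition and subject-grouped evaluation can refer back to them.
#'
#' @param X numeric matrix, `n_samples x n_features`, finite entries.
#' @param sample_ids character vector aligned with rows of `X`.
#' @param labels character vector of parent labels aligned with rows (may
#'   be `NA`).
#' @param subject_ids optional character vector of subject IDs per row.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, sample_ids, labels = NULL, subject_ids = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("feature matrix entries must be finite",
                               call. = FALSE)
  n <- nrow(X)
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n)
    stop("sample_ids length must equal nrow(X)", call. = FALSE)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("labels length must equal nrow(X)", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sample_ids
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != n)
    stop("subject_ids length must equal nrow(X)", call. = FALSE)
  rownames(X) <- sample_ids
  structure(list(X = X, sample_ids = sample_ids, labels = labels,
                 subject_ids = subject_ids),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
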