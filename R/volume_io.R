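# Volumetric I/O: NIfTI reading, axial slice extraction, slice-image
# datasets with CSV manifests.

#' Read a NIfTI volume
#'
#' Reads a 3D T1-weighted image (`.nii` / `.nii.gz`), already registered to
#' a standard space upstream. Intensities are taken as stored; spacing comes
#' from the header `pixdim`. The axial (inferior-superior) axis is located
#' from the header orientation; when the header carries no usable
#' orientation the last array axis is assumed axial and a warning is
#' emitted, which is correct for MNI-registered volumes.
#'
#' @param path path to a readable NIfTI file.
#' @param subject_id subject identifier to attach; defaults to the file
#'   name without extensions.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  # Trailing singleton dimensions (e.g. a 3D image stored as X x Y x Z x 1)
  # are dropped; any genuine 4th dimension is an error.
  while (length(d) > 3L && d[length(d)] == 1L) {
    dim(arr) <- d[-length(d)]
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions", call. = FALSE)
  pd <- tryCatch(RNifti::pixdim(img)[seq_len(3)], error = function(e) c(1, 1, 1))
  if (any(!is.finite(pd)) || any(pd <= 0)) pd <- c(1, 1, 1)
  ax <- 3L
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.character(orient) && !is.na(orient) && nchar(orient) == 3L) {
    codes <- strsplit(orient, "")[[1]]
    hit <- which(codes %in% c("S", "I"))
    if (length(hit) == 1L) ax <- hit else {
      warning("ambiguous NIfTI orientation; assuming last axis is axial")
    }
  } else {
    warning("NIfTI header lacks orientation; assuming last axis is axial")
  }
  axis_order <- rep(NA_character_, 3)
  axis_order[ax] <- "z"
  axis_order[is.na(axis_order)] <- c("x", "y")
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  volume3d(arr, spacing = pd, axis_order = axis_order,
           subject_id = subject_id)
}

#' Write a volume to NIfTI
#'
#' @param vol a [volume3d()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract all axial slices from a volume
#'
#' Re-slices a 3D volume into one 2D record per position along the axial
#' axis, slice index increasing inferior to superior (0-based). The number
#' of records equals the axial dimension, e.g. 189 for a standard
#' 197 x 233 x 189 MNI-registered scan.
#'
#' @param vol a [volume3d()].
#' @return A [slice_set()] with unlabeled records for one subject.
#' @export
extract_axial_slices <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  ax <- axial_axis(vol)
  depth <- dim(vol$voxels)[ax]
  images <- vector("list", depth)
  for (k in seq_len(depth)) {
    sl <- switch(ax,
                 vol$voxels[k, , , drop = TRUE],
                 vol$voxels[, k, , drop = TRUE],
                 vol$voxels[, , k, drop = TRUE])
    if (!is.matrix(sl)) sl <- matrix(sl, nrow = dim(vol$voxels)[-ax][1])
    images[[k]] <- sl
  }
  slice_set(
    images,
    data.frame(subject_id = vol$subject_id,
               slice_index = seq_len(depth) - 1L,
               stringsAsFactors = FALSE),
    provenance = list(source = "extract_axial_slices",
                      spacing = vol$spacing, axial_axis = ax)
  )
}

# Per-subject min-max rescale of a slice set to 8-bit integers [0, 255].
# Rescaling is per subject (per volume), not per slice, so that inter-slice
# intensity relations survive export.
rescale_8bit <- function(slices) {
  m <- slices$meta
  out <- slices$images
  for (sub in unique(m$subject_id)) {
    idx <- which(m$subject_id == sub)
    rng <- range(unlist(lapply(out[idx], range)))
    span <- rng[2] - rng[1]
    for (i in idx) {
      out[[i]] <- if (span <= 0) {
        matrix(0L, nrow(out[[i]]), ncol(out[[i]]))
      } else {
        v <- floor((out[[i]] - rng[1]) / span * 256)
        matrix(as.integer(pmin(v, 255)), nrow(out[[i]]))
      }
    }
  }
  out
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "-", x)

#' Write slice images and a manifest
#'
#' Rescales each subject's slices jointly to 8-bit, writes one image file
#' per record (PNG by default; JPEG supported for parity with legacy
#' exports, with a warning that JPEG is lossy), and writes a CSV manifest
#' with columns `subject_id`, `slice_index`, `label`, `stratum`, `path`
#' (path relative to the manifest's directory).
#'
#' @param slices a [slice_set()].
#' @param out_dir directory for the image files (created if needed).
#' @param format `"png"` (lossless, default) or `"jpeg"`.
#' @param manifest_path path of the CSV manifest to write.
#' @param quality JPEG quality in (0, 1], ignored for PNG.
#' @return Number of manifest rows written, invisibly.
#' @export
write_slice_images <- function(slices, out_dir,
                               format = c("png", "jpeg"),
                               manifest_path = file.path(out_dir, "manifest.csv"),
                               quality = 0.95) {
  format <- match.arg(format)
  if (format == "jpeg") {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG output requires the EBImage package", call. = FALSE)
    warning("JPEG is lossy; stored pixel values will deviate from the ",
            "8-bit rescaled slices. Use PNG for exact round-trips.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  imgs8 <- rescale_8bit(slices)
  m <- slices$meta
  ext <- if (format == "png") "png" else "jpg"
  fname <- sprintf("%s_slice%04d.%s", sanitize_id(m$subject_id),
                   m$slice_index, ext)
  for (i in seq_along(imgs8)) {
    fp <- file.path(out_dir, fname[i])
    if (format == "png") {
      png::writePNG(imgs8[[i]] / 255, fp)
    } else {
      EBImage::writeImage(EBImage::Image(t(imgs8[[i]] / 255)), fp,
                          quality = round(quality * 100))
    }
  }
  rel <- file.path(normalizePath(out_dir), fname)
  base <- dirname(normalizePath(manifest_path, mustWork = FALSE))
  rel <- relative_to(rel, base)
  man <- data.frame(subject_id = m$subject_id,
                    slice_index = m$slice_index,
                    label = m$label,
                    stratum = m$stratum,
                    path = rel,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(nrow(man))
}

relative_to <- function(paths, base) {
  base <- paste0(sub("/+$", "", base), "/")
  ifelse(startsWith(paths, base), substring(paths, nchar(base) + 1L), paths)
}

#' Read a slice dataset from a manifest
#'
#' Loads the images referenced by a CSV manifest (as written by
#' [write_slice_images()]) and reattaches labels and strata. Pixel values
#' are returned on the 8-bit scale `[0, 255]`. Rows with empty labels are
#' accepted as unlabeled records.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A [slice_set()].
#' @export
read_slice_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("no such manifest: ", manifest_path, call. = FALSE)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (req in c("subject_id", "slice_index", "path"))
    if (!req %in% names(man)) stop("manifest lacks column ", req, call. = FALSE)
  man$slice_index <- as.integer(man$slice_index)
  key <- paste(man$subject_id, man$slice_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("manifest has duplicate (subject_id, slice_index) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(manifest_path))
  images <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fp <- man$path[i]
    if (!startsWith(fp, "/")) fp <- file.path(base, fp)
    if (!file.exists(fp))
      stop("manifest row ", i, ": missing image file ", fp, call. = FALSE)
    im <- if (grepl("\\.png$", fp, ignore.case = TRUE)) {
      png::readPNG(fp)
    } else {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the EBImage package", call. = FALSE)
      t(as.matrix(EBImage::imageData(EBImage::readImage(fp))))
    }
    if (length(dim(im)) == 3L) im <- im[, , 1]
    images[[i]] <- round(im * 255)
  }
  lab <- if ("label" %in% names(man)) man$label else NA_character_
  lab[!is.na(lab) & lab == ""] <- NA_character_
  str <- if ("stratum" %in% names(man)) man$stratum else NA_character_
  str[!is.na(str) & str == ""] <- NA_character_
  slice_set(images,
            data.frame(subject_id = man$subject_id,
                       slice_index = man$slice_index,
                       label = lab, stratum = str,
                       stringsAsFactors = FALSE),
            provenance = list(source = manifest_path))
}
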