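# Gray-level co-occurrence matrices and their entropy.
#
# The GLCM at offset (distance D, direction theta) is the joint
# distribution p(i, j) of gray-level pairs observed at pixels separated by
# that offset; its Shannon entropy measures texture complexity and drives
# informative-slice selection.

#' GLCM configuration
#'
#' @param distance positive integer pixel offset D.
#' @param direction one of `0`, `45`, `90`, `135` (degrees) or the string
#'   `"mean4"`, which averages the four per-angle normalized matrices.
#'   Angles follow the usual image-analysis convention: 0 deg is
#'   horizontal, 90 deg vertical, 45 deg up-right, 135 deg up-left.
#' @param levels number of gray levels after quantization (>= 2).
#' @param symmetric count both orderings of each pair (default `TRUE`).
#' @param log_base `"e"` (entropy in nats) or `"2"` (bits).
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(distance = 1L, direction = 0, levels = 64L,
                        symmetric = TRUE, log_base = c("e", "2")) {
  log_base <- match.arg(as.character(log_base), c("e", "2"))
  distance <- as.integer(distance)
  levels <- as.integer(levels)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (!(identical(direction, "mean4") ||
        (is.numeric(direction) && direction %in% c(0, 45, 90, 135))))
    stop("direction must be 0, 45, 90, 135 or \"mean4\"", call. = FALSE)
  structure(list(distance = distance, direction = direction,
                 levels = levels, symmetric = isTRUE(symmetric),
                 log_base = log_base),
            class = "glcm_config")
}

#' Quantize an image to discrete gray levels
#'
#' Uniformly bins the image range `[min, max]` into `levels` bins, giving
#' integer codes in `[0, levels)`. A constant image maps entirely to bin 0
#' (and yields entropy 0 downstream), never an error.
#'
#' @param image numeric matrix.
#' @param levels integer >= 2.
#' @return Integer matrix of the same shape with values in `[0, levels)`.
#' @export
quantize <- function(image, levels) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  rng <- range(image)
  span <- rng[2] - rng[1]
  if (span <= 0) return(matrix(0L, nrow(image), ncol(image)))
  q <- floor((image - rng[1]) / span * levels)
  matrix(as.integer(pmin(q, levels - 1L)), nrow(image))
}

# Row/column offsets for one angle; row index increases downwards, so
# "up-right" (45 deg) means row - D, col + D.
glcm_offset <- function(direction, distance) {
  switch(as.character(direction),
         "0"   = c(0L, distance),
         "45"  = c(-distance, distance),
         "90"  = c(-distance, 0L),
         "135" = c(-distance, -distance),
         stop("bad direction"))
}

glcm_one_angle <- function(image, direction, distance, levels, symmetric) {
  off <- glcm_offset(direction, distance)
  dr <- off[1]; dc <- off[2]
  nr <- nrow(image); nc <- ncol(image)
  r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
  if (r0 > r1 || c0 > c1)
    stop("image smaller than the GLCM offset in the requested direction",
         call. = FALSE)
  rows <- r0:r1
  cols <- c0:c1
  a <- image[rows, cols, drop = FALSE]
  b <- image[rows + dr, cols + dc, drop = FALSE]
  counts <- tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                     nbins = levels * levels)
  M <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) M <- M + t(M)
  M / sum(M)
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts co-occurrences of gray levels `(i, j)` at pixels separated by the
#' configured offset and normalizes to a probability matrix summing to 1.
#' With `symmetric = TRUE` both orderings of each pair are counted, making
#' the matrix symmetric. With `direction = "mean4"` the four per-angle
#' normalized matrices are averaged entrywise.
#'
#' @param image integer matrix with values in `[0, config$levels)` (see
#'   [quantize()]).
#' @param config a [glcm_config()].
#' @return An object of class `glcm_matrix` with fields `p` (the
#'   `levels x levels` probability matrix) and `config`.
#' @export
compute_glcm <- function(image, config = glcm_config()) {
  stopifnot(inherits(config, "glcm_config"))
  storage.mode(image) <- "integer"
  if (min(image) < 0L || max(image) >= config$levels)
    stop("image values must lie in [0, levels)", call. = FALSE)
  p <- if (identical(config$direction, "mean4")) {
    mats <- lapply(c(0, 45, 90, 135), glcm_one_angle, image = image,
                   distance = config$distance, levels = config$levels,
                   symmetric = config$symmetric)
    Reduce(`+`, mats) / 4
  } else {
    glcm_one_angle(image, config$direction, config$distance,
                   config$levels, config$symmetric)
  }
  structure(list(p = p, config = config), class = "glcm_matrix")
}

#' GLCM entropy
#'
#' Shannon entropy of the co-occurrence distribution,
#' `-sum_ij p(i,j) log p(i,j)` with `0 log 0 := 0`, in nats
#' (`log_base = "e"`) or bits (`log_base = "2"`).
#'
#' @param glcm a `glcm_matrix` from [compute_glcm()].
#' @return Nonnegative scalar entropy.
#' @export
glcm_entropy <- function(glcm) {
  stopifnot(inherits(glcm, "glcm_matrix"))
  p <- glcm$p[glcm$p > 0]
  h <- -sum(p * log(p))
  if (glcm$config$log_base == "2") h <- h / log(2)
  # guard against -0 from rounding
  max(h, 0)
}
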