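# Synthetic data with the statistical structure the pipeline assumes:
# texture phantoms whose central axial band carries the highest GLCM
# entropy, and labeled 2D image tasks with planted within-class
# subclusters, class imbalance, strata, and base/target pairs sharing
# feature structure.
#
# Phantom construction: band slices are fine-grained white-noise texture
# (a near-uniform co-occurrence distribution, hence high entropy); outer
# slices are blocky smoothed noise whose equal-valued neighbors
# concentrate the co-occurrence mass near the diagonal (low entropy).
# Informativeness therefore *coincides with* GLCM entropy by
# construction, so a broken entropy ranking fails the recovery tests.

#' Phantom specification
#'
#' @param shape integer `(H, W, depth)` of the volume; depth >= 3.
#' @param center_band_fraction fraction of depth occupied by the
#'   high-texture central band, in (0, 1].
#' @param texture_scale amplitude of the in-band texture (> 0).
#' @param background_noise amplitude of the out-of-band smooth noise
#'   (>= 0, < `texture_scale`); 0 makes outer slices exactly constant.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 60L),
                         center_band_fraction = 1 / 3,
                         texture_scale = 1, background_noise = 0.1,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L) || shape[3] < 3L)
    stop("shape must be (H, W, depth) with depth >= 3", call. = FALSE)
  if (center_band_fraction <= 0 || center_band_fraction > 1)
    stop("center_band_fraction must be in (0, 1]", call. = FALSE)
  if (texture_scale <= background_noise)
    stop("texture_scale must exceed background_noise", call. = FALSE)
  if (background_noise < 0) stop("background_noise must be >= 0", call. = FALSE)
  structure(list(shape = shape,
                 center_band_fraction = center_band_fraction,
                 texture_scale = texture_scale,
                 background_noise = background_noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# blocky smoothed noise: white noise on a coarse grid, upsampled by
# constant blocks
smooth_field <- function(h, w, block = 8L) {
  z <- matrix(stats::rnorm(ceiling(h / block) * ceiling(w / block)),
              ceiling(h / block))
  resize_image(z, h, w)
}

#' Generate a texture phantom volume
#'
#' Central band slices (fractional width `center_band_fraction`, centered
#' in depth) carry high-variance fine texture; outer slices carry
#' low-amplitude smooth noise. Returns the volume together with the
#' 0-based ground-truth index set of the informative band.
#'
#' @param spec a [phantom_spec()].
#' @param subject_id subject tag for the volume.
#' @return List with `volume` (a [volume3d()]) and `band` (integer vector
#'   of 0-based informative slice indices).
#' @export
make_phantom <- function(spec = phantom_spec(), subject_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]; depth <- spec$shape[3]
  bw <- max(1L, min(depth, as.integer(round(depth * spec$center_band_fraction))))
  start <- floor((depth - bw) / 2)
  band <- seq(start, start + bw - 1L)
  set.seed(spec$seed)
  vox <- array(0, c(h, w, depth))
  for (k in seq_len(depth) - 1L) {
    vox[, , k + 1L] <- if (k %in% band) {
      spec$texture_scale *
        (matrix(stats::rnorm(h * w), h) + 0.5 * smooth_field(h, w, 4L))
    } else if (spec$background_noise > 0) {
      spec$background_noise * smooth_field(h, w, 8L)
    } else {
      matrix(0, h, w)
    }
  }
  list(volume = volume3d(vox, subject_id = subject_id),
       band = as.integer(band))
}

#' Classification task specification
#'
#' Each class is a mixture of `n_subclusters_per_class` subject templates.
#' Class identity shifts the amplitude of one fixed spatial pattern (the
#' "class statistic"); subcluster identity shifts the amplitude of an
#' orthogonal pattern, with subcluster centers `subcluster_separation`
#' within-cluster SDs apart. Subjects draw their amplitudes once and all
#' their slices share them plus independent pixel noise, emulating the
#' within-subject correlation that makes subject-grouped CV necessary.
#'
#' @param n_subjects_per_class named integer vector, subjects per class
#'   label (exact counts; imbalance is honored exactly).
#' @param slices_per_subject slices generated per subject.
#' @param n_subclusters_per_class planted subclusters per class.
#' @param subcluster_separation distance between subcluster centers in
#'   within-cluster SD units (>= 0).
#' @param class_overlap subject-level SD of the class statistic; 0 makes
#'   classes separable by a hard threshold.
#' @param class_axis_coupling in `[0, 1]`: how strongly a subject's
#'   class-statistic center depends on its subcluster, with the
#'   dependence mirrored across classes. 0 (default) keeps classes
#'   linearly separable along the class axis; 1 fully interleaves the
#'   subclusters of opposite classes (an XOR-like arrangement), making
#'   the class boundary irregular — the regime class decomposition is
#'   designed for.
#' @param stratum_ratios optional named proportions (e.g.
#'   `c(F = 0.5, M = 0.5)`) applied within each class by largest
#'   remainder, or `NULL` for no strata.
#' @param image_size integer `(H, W)` of each slice image.
#' @param seed integer seed.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(n_subjects_per_class = c(A = 12L, B = 12L),
                      slices_per_subject = 8L,
                      n_subclusters_per_class = 2L,
                      subcluster_separation = 8,
                      class_overlap = 0.25,
                      class_axis_coupling = 0,
                      stratum_ratios = NULL,
                      image_size = c(32L, 32L),
                      seed = 1L) {
  if (is.null(names(n_subjects_per_class)))
    stop("n_subjects_per_class must be named by class label", call. = FALSE)
  if (any(n_subjects_per_class < 1L))
    stop("need >= 1 subject per class", call. = FALSE)
  if (subcluster_separation < 0 || class_overlap < 0)
    stop("separation and overlap must be >= 0", call. = FALSE)
  if (class_axis_coupling < 0 || class_axis_coupling > 1)
    stop("class_axis_coupling must be in [0, 1]", call. = FALSE)
  if (!is.null(stratum_ratios)) {
    if (is.null(names(stratum_ratios)) || any(stratum_ratios < 0))
      stop("stratum_ratios must be named nonnegative proportions",
           call. = FALSE)
    stratum_ratios <- stratum_ratios / sum(stratum_ratios)
  }
  structure(list(n_subjects_per_class = n_subjects_per_class,
                 slices_per_subject = as.integer(slices_per_subject),
                 n_subclusters_per_class = as.integer(n_subclusters_per_class),
                 subcluster_separation = subcluster_separation,
                 class_overlap = class_overlap,
                 class_axis_coupling = class_axis_coupling,
                 stratum_ratios = stratum_ratios,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "task_spec")
}

# largest-remainder apportionment of n into proportions p
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# orthogonal unit-SD spatial patterns carrying class and subcluster signal
task_patterns <- function(h, w) {
  p1 <- matrix(rep(sin(2 * pi * seq_len(w) / w), each = h), h)
  p2 <- matrix(rep(sin(2 * pi * seq_len(h) / h), times = w), h)
  list(class = p1 / stats::sd(as.numeric(p1)),
       sub = p2 / stats::sd(as.numeric(p2)))
}

# Within-cluster SD of the subcluster statistic and slice pixel noise.
.SUBCLUSTER_SD <- 0.15
.SLICE_NOISE <- 0.05

# Core generator. class_centers: named amplitudes of the class statistic,
# one per class; the public wrappers derive them from the task_spec.
gen_task <- function(spec, class_centers, seed = spec$seed) {
  classes <- names(spec$n_subjects_per_class)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  pat <- task_patterns(h, w)
  set.seed(seed)
  images <- list(); rows <- list()
  subjects <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    n <- spec$n_subjects_per_class[[cls]]
    m <- spec$n_subclusters_per_class
    sub_centers <- (seq_len(m) - (m + 1) / 2) *
      spec$subcluster_separation * .SUBCLUSTER_SD
    sub_of <- rep(seq_len(m), length.out = n)
    strata <- if (is.null(spec$stratum_ratios)) rep(NA_character_, n)
    else rep(names(spec$stratum_ratios),
             times = apportion(n, spec$stratum_ratios))
    flip <- if (ci %% 2L == 1L) 1 else -1
    for (si in seq_len(n)) {
      sid <- sprintf("%s_s%04d", cls, si)
      cpl <- spec$class_axis_coupling %||% 0
      sub_sign <- sign(sub_centers[sub_of[si]])
      a_center <- class_centers[[cls]] * (1 - cpl) +
        cpl * abs(class_centers[[cls]]) * flip * sub_sign
      alpha <- stats::rnorm(1, a_center, spec$class_overlap)
      beta <- stats::rnorm(1, sub_centers[sub_of[si]], .SUBCLUSTER_SD)
      base_im <- alpha * pat$class + beta * pat$sub
      for (k in seq_len(spec$slices_per_subject) - 1L) {
        images[[length(images) + 1L]] <- base_im +
          .SLICE_NOISE * matrix(stats::rnorm(h * w), h)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, slice_index = k, label = cls,
          stratum = strata[si],
          subcluster = paste0(cls, "@", sub_of[si]),
          stringsAsFactors = FALSE)
      }
      subjects[[length(subjects) + 1L]] <- data.frame(
        subject_id = sid, label = cls, stratum = strata[si],
        subcluster = paste0(cls, "@", sub_of[si]),
        alpha = alpha, beta = beta, stringsAsFactors = FALSE)
    }
  }
  slice_set(images, do.call(rbind, rows),
            provenance = list(generator = "make_classification_task",
                              spec = spec, seed = seed,
                              class_centers = class_centers,
                              subjects = do.call(rbind, subjects)))
}

#' Generate a labeled classification task
#'
#' See [task_spec()] for the generative model. The returned slice set
#' carries hidden ground-truth subcluster labels in `meta$subcluster`
#' (for adjusted-Rand-index evaluation of the decomposition) and a
#' subject-level truth table in `provenance$subjects`.
#'
#' @param spec a [task_spec()].
#' @return A [slice_set()].
#' @export
make_classification_task <- function(spec = task_spec()) {
  stopifnot(inherits(spec, "task_spec"))
  classes <- names(spec$n_subjects_per_class)
  centers <- stats::setNames(
    2 * (seq_along(classes) - (length(classes) + 1) / 2), classes)
  gen_task(spec, centers)
}

#' Generate a base/target transfer pair
#'
#' The target task is drawn from the same template family as the base
#' task — identical patterns, subcluster structure and noise — but with
#' the class centers contracted toward each other by `target_shift`
#' (0 = statistically identical to base, values toward 1 make the target
#' progressively harder). Transfer from the base task is therefore
#' beneficial by construction. Target class labels get a `_t` suffix.
#'
#' @param base_spec a [task_spec()] for the base (easy) task.
#' @param target_shift contraction of the class separation, in `[0, 1)`.
#' @param seed seed for the pair (base and target draws differ).
#' @param target_n optional named subject counts for the target task
#'   (named like `base_spec`'s classes); defaults to the base counts.
#' @return List with `base` and `target`, both [slice_set()]s.
#' @export
make_transfer_pair <- function(base_spec = task_spec(), target_shift = 0.5,
                               seed = base_spec$seed, target_n = NULL) {
  stopifnot(inherits(base_spec, "task_spec"))
  if (target_shift < 0 || target_shift >= 1)
    stop("target_shift must be in [0, 1)", call. = FALSE)
  classes <- names(base_spec$n_subjects_per_class)
  centers <- stats::setNames(
    2 * (seq_along(classes) - (length(classes) + 1) / 2), classes)
  base <- gen_task(base_spec, centers, seed = seed)
  tgt_spec <- base_spec
  if (!is.null(target_n)) tgt_spec$n_subjects_per_class <- target_n
  names(tgt_spec$n_subjects_per_class) <-
    paste0(names(tgt_spec$n_subjects_per_class), "_t")
  tgt_centers <- stats::setNames(centers * (1 - target_shift),
                                 names(tgt_spec$n_subjects_per_class))
  target <- gen_task(tgt_spec, tgt_centers, seed = seed + 100003L)
  list(base = base, target = target)
}
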