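# Informative-slice selection: score every axial slice by GLCM entropy and
# keep either the top-N per subject or a centered window of N middle slices.

# Entropy of one raw-intensity slice under a GLCM config: per-slice min-max
# quantization to config$levels, then co-occurrence entropy.
slice_entropy <- function(image, config) {
  q <- quantize(image, config$levels)
  glcm_entropy(compute_glcm(q, config))
}

entropy_per_slice <- function(slices, config) {
  vapply(slices$images, slice_entropy, numeric(1), config = config)
}

#' Rank one subject's slices by GLCM entropy
#'
#' Scores every slice of a single subject and returns scores sorted by
#' entropy descending — the most informative (highest-entropy) slices
#' first — with ties broken by ascending slice index for determinism.
#'
#' @param slices a [slice_set()] containing exactly one subject.
#' @param config a [glcm_config()].
#' @return data.frame with columns `subject_id`, `slice_index`, `entropy`,
#'   `rank` (1 = highest entropy), sorted by rank.
#' @export
rank_slices_by_entropy <- function(slices, config = glcm_config()) {
  subs <- unique(slices$meta$subject_id)
  if (length(subs) != 1L)
    stop("rank_slices_by_entropy expects slices from a single subject; got ",
         length(subs), call. = FALSE)
  h <- entropy_per_slice(slices, config)
  ord <- order(-h, slices$meta$slice_index)
  data.frame(subject_id = slices$meta$subject_id[ord],
             slice_index = slices$meta$slice_index[ord],
             entropy = h[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Select the highest-entropy slices per subject
#'
#' For every subject independently, keeps the `min(n, available)` slices
#' with the highest GLCM entropy (ties broken by ascending slice index) and
#' populates the `entropy` column. The default of 20 slices per subject is
#' the base-task selection rule.
#'
#' @param slices a [slice_set()] (any number of subjects).
#' @param n slices to keep per subject (>= 1).
#' @param config a [glcm_config()].
#' @return A [slice_set()] with at most `n` records per subject.
#' @export
select_top_entropy <- function(slices, n = 20L, config = glcm_config()) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  h <- entropy_per_slice(slices, config)
  m <- slices$meta
  keep <- integer(0)
  for (sub in unique(m$subject_id)) {
    idx <- which(m$subject_id == sub)
    ord <- idx[order(-h[idx], m$slice_index[idx])]
    keep <- c(keep, sort(ord[seq_len(min(n, length(ord)))]))
  }
  out <- subset_slices(slices, keep)
  out$meta$entropy <- h[keep]
  out$provenance <- c(out$provenance,
                      list(selection = "top_entropy", n = n))
  out
}

#' Select a centered window of middle slices per subject
#'
#' For each subject with N slices (ordered by slice index), keeps a
#' contiguous window of `min(n, N)` slices starting at position
#' `floor((N - n) / 2)` (0 when N <= n). With N = 189 and n = 30 this keeps
#' slice indices 79..108 — the middle-slice rule used for the target task.
#'
#' @param slices a [slice_set()].
#' @param n window width (>= 1), default 30.
#' @return A [slice_set()].
#' @export
select_middle <- function(slices, n = 30L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  m <- slices$meta
  keep <- integer(0)
  for (sub in unique(m$subject_id)) {
    idx <- which(m$subject_id == sub)
    idx <- idx[order(m$slice_index[idx])]
    N <- length(idx)
    start <- max(0L, floor((N - n) / 2))
    keep <- c(keep, idx[seq(start + 1L, min(N, start + n))])
  }
  out <- subset_slices(slices, keep)
  out$provenance <- c(out$provenance, list(selection = "middle", n = n))
  out
}
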