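# Backbone adapters: the pluggable feature-extractor / classifier
# contract, with two desk-scale reference implementations.
#
#  * reference_cnn — fixed seeded random 3x3 convolution filters with
#    mean pooling in front of a trainable dense tail and softmax head;
#    trains on a CPU in seconds and is deterministic under its seed.
#  * deterministic_texture — a non-neural extractor (pooled grid
#    statistics plus GLCM entropies); no training at all, so every run is
#    bit-identical. Its classifier is a multinomial softmax head on the
#    standardized features.
#
# Large ImageNet-style backbones can be slotted in behind the same
# contract; the decomposition/transfer machinery never looks inside.

#' Training configuration
#'
#' Defaults mirror the published training regime (200 epochs, batch 50,
#' Adam at learning rate 1e-4); desk-scale runs and tests use far fewer
#' epochs.
#'
#' @param epochs integer >= 1.
#' @param batch_size integer >= 1.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate positive step size.
#' @param seed integer seed controlling initialization and batching.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 50L,
                         optimizer = "adam", learning_rate = 1e-4,
                         seed = 1L) {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Backbone specification
#'
#' @param name `"reference_cnn"` or `"deterministic_texture"`.
#' @param input_size length-2 integer `(H, W)`; images are resampled to
#'   this size before feature extraction.
#' @param n_trainable_tail_layers how many dense layers ahead of the head
#'   are trainable (the convolutional front of `reference_cnn` is always
#'   fixed; this knob plays the role of "adopting the top layers" of a
#'   large pretrained network).
#' @param head_classes output dimension of the softmax head (>= 2).
#' @param n_filters convolution filters for `reference_cnn`.
#' @param hidden width of the dense tail for `reference_cnn`.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("deterministic_texture", "reference_cnn"),
                          input_size = c(32L, 32L),
                          n_trainable_tail_layers = 1L,
                          head_classes = 2L,
                          n_filters = 8L, hidden = 32L) {
  name <- match.arg(name)
  head_classes <- as.integer(head_classes)
  if (head_classes < 2L) stop("head_classes must be >= 2", call. = FALSE)
  if (n_trainable_tail_layers < 0L)
    stop("n_trainable_tail_layers must be >= 0", call. = FALSE)
  structure(list(name = name, input_size = as.integer(input_size),
                 n_trainable_tail_layers = as.integer(n_trainable_tail_layers),
                 head_classes = head_classes,
                 n_filters = as.integer(n_filters),
                 hidden = as.integer(hidden)),
            class = "backbone_spec")
}

# ---- image resampling and raw features --------------------------------

# Average-pool resample to (th, tw); works for down- and up-sampling.
resize_image <- function(im, th, tw) {
  avg_mat <- function(nsrc, ntgt) {
    A <- matrix(0, ntgt, nsrc)
    for (t in seq_len(ntgt)) {
      lo <- floor((t - 1) * nsrc / ntgt) + 1L
      hi <- max(lo, floor(t * nsrc / ntgt))
      A[t, lo:hi] <- 1 / (hi - lo + 1L)
    }
    A
  }
  avg_mat(nrow(im), th) %*% im %*% t(avg_mat(ncol(im), tw))
}

# Pooled texture statistics: 4x4 grid of block means and SDs, global
# mean/SD, GLCM entropy at the four standard angles (16 levels, D=1), and
# mean absolute row/column gradients. 40 deterministic features.
texture_features_one <- function(im, input_size) {
  rs <- resize_image(im, input_size[1], input_size[2])
  g <- 4L
  rb <- floor(seq(0, nrow(rs), length.out = g + 1))
  cb <- floor(seq(0, ncol(rs), length.out = g + 1))
  means <- sds <- numeric(g * g)
  k <- 0L
  for (i in seq_len(g)) for (j in seq_len(g)) {
    k <- k + 1L
    blk <- rs[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
    means[k] <- mean(blk)
    sds[k] <- stats::sd(as.numeric(blk))
  }
  q <- quantize(rs, 16L)
  ent <- vapply(c(0, 45, 90, 135), function(th)
    glcm_entropy(compute_glcm(q, glcm_config(1L, th, 16L))), numeric(1))
  grad_r <- mean(abs(diff(rs)))
  grad_c <- mean(abs(t(diff(t(rs)))))
  c(means, sds, mean(rs), stats::sd(as.numeric(rs)), ent, grad_r, grad_c)
}

cnn_filters <- function(n_filters, seed) {
  set.seed(seed)
  lapply(seq_len(n_filters), function(i)
    matrix(stats::rnorm(9, sd = 1 / 3), 3, 3))
}

conv3x3_valid <- function(im, f) {
  nr <- nrow(im); nc <- ncol(im)
  out <- matrix(0, nr - 2L, nc - 2L)
  for (i in 1:3) for (j in 1:3)
    out <- out + f[i, j] * im[i:(nr - 3L + i), j:(nc - 3L + j)]
  out
}

cnn_features_one <- function(im, input_size, filters) {
  rs <- resize_image(im, input_size[1], input_size[2])
  rs <- (rs - mean(rs)) / max(stats::sd(as.numeric(rs)), 1e-8)
  unlist(lapply(filters, function(f)
    as.numeric(resize_image(pmax(conv3x3_valid(rs, f), 0), 8L, 8L))))
}

# Raw (pre-normalization) feature matrix for a slice set under a feature
# configuration (list: type, input_size, filters).
raw_features <- function(feat, slices) {
  fn <- switch(feat$type,
               deterministic_texture = function(im)
                 texture_features_one(im, feat$input_size),
               reference_cnn = function(im)
                 cnn_features_one(im, feat$input_size, feat$filters),
               stop("unknown feature type ", feat$type))
  X <- t(vapply(slices$images, fn, numeric(feat$dim)))
  X
}

feat_dim <- function(feat) {
  if (feat$type == "deterministic_texture") 40L
  else length(feat$filters) * 64L
}

fit_norm <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  list(mu = mu, sd = sdv)
}

apply_norm <- function(norm, X) {
  if (is.null(norm)) return(X)
  sweep(sweep(X, 2, norm$mu), 2, norm$sd, "/")
}

make_feat <- function(backbone, seed) {
  feat <- list(type = backbone$name, input_size = backbone$input_size)
  if (backbone$name == "reference_cnn")
    feat$filters <- cnn_filters(backbone$n_filters, seed + 101L)
  feat$dim <- if (backbone$name == "deterministic_texture") 40L
              else backbone$n_filters * 64L
  feat
}

# ---- extractor --------------------------------------------------------

#' Fit a feature extractor
#'
#' For `reference_cnn`, trains the dense tail and a temporary head on the
#' parent labels (fine-tuning) and exposes the penultimate representation
#' as the extracted features. For `deterministic_texture` there is nothing
#' to train: features are the standardized pooled texture statistics, and
#' the transform is identical across calls.
#'
#' @param backbone a [backbone_spec()].
#' @param images a [slice_set()] carrying >= 2 distinct labels.
#' @param cfg a [train_config()].
#' @return An object of class `cdtl_extractor`; use
#'   [transform_features()] to obtain a [feature_matrix()].
#' @export
fit_extractor <- function(backbone, images, cfg = train_config()) {
  stopifnot(inherits(backbone, "backbone_spec"), inherits(images, "slice_set"))
  labs <- images$meta$label
  classes <- sort(unique(labs[!is.na(labs)]))
  if (length(classes) < 2L)
    stop("extractor fine-tuning needs >= 2 classes", call. = FALSE)
  feat <- make_feat(backbone, cfg$seed)
  Xr <- raw_features(feat, images)
  # Texture statistics keep their natural units: standardization happens
  # after the PCA step, not before, and inflating near-constant
  # statistics to unit variance would drown the informative directions.
  # The network backbone standardizes its inputs for optimization.
  norm <- if (backbone$name == "reference_cnn") fit_norm(Xr) else NULL
  Xn <- apply_norm(norm, Xr)
  layers <- NULL; losses <- NULL
  if (backbone$name == "reference_cnn") {
    sizes <- c(ncol(Xn), backbone$hidden, length(classes))
    layers <- nn_init(sizes, cfg$seed)
    trainable <- c(backbone$n_trainable_tail_layers >= 1L, TRUE)
    tr <- nn_train(layers, Xn, one_hot(labs, classes), cfg$epochs,
                   cfg$batch_size, cfg$learning_rate, cfg$seed, trainable)
    layers <- tr$layers
    losses <- tr$losses
  }
  structure(list(backbone = backbone, feat = feat, norm = norm,
                 layers = layers, classes = classes,
                 loss_history = losses,
                 fitted_subjects = sort(unique(images$meta$subject_id))),
            class = "cdtl_extractor")
}

#' Extract features from slices
#'
#' @param extractor a `cdtl_extractor` from [fit_extractor()].
#' @param slices a [slice_set()].
#' @return A [feature_matrix()] (rows keyed by `subject:slice_index`),
#'   carrying the slices' labels and subject IDs.
#' @export
transform_features <- function(extractor, slices) {
  stopifnot(inherits(extractor, "cdtl_extractor"))
  Xn <- apply_norm(extractor$norm, raw_features(extractor$feat, slices))
  if (!is.null(extractor$layers)) {
    # penultimate representation of the fine-tuned network
    Xn <- nn_forward(extractor$layers, Xn)$penultimate
  }
  colnames(Xn) <- paste0("f", seq_len(ncol(Xn)))
  feature_matrix(Xn, slice_ids(slices), slices$meta$label,
                 slices$meta$subject_id)
}

# ---- classifier -------------------------------------------------------

#' Fit a classifier on labeled slices
#'
#' Trains the backbone's classification network on the slice labels
#' (typically subclass labels after decomposition). The softmax head's
#' width must equal the number of distinct labels. `predict_scores()`
#' returns per-class probabilities summing to 1.
#'
#' @param backbone a [backbone_spec()] whose `head_classes` matches the
#'   label count.
#' @param images a labeled [slice_set()].
#' @param cfg a [train_config()].
#' @return An object of class `cdtl_model`.
#' @export
fit_classifier <- function(backbone, images, cfg = train_config()) {
  stopifnot(inherits(backbone, "backbone_spec"), inherits(images, "slice_set"))
  labs <- images$meta$label
  if (any(is.na(labs))) stop("all slices must be labeled", call. = FALSE)
  classes <- sort(unique(labs))
  if (length(classes) != backbone$head_classes)
    stop("backbone head has ", backbone$head_classes,
         " classes but data has ", length(classes), call. = FALSE)
  feat <- make_feat(backbone, cfg$seed)
  Xr <- raw_features(feat, images)
  norm <- fit_norm(Xr)
  Xn <- apply_norm(norm, Xr)
  sizes <- if (backbone$name == "reference_cnn")
    c(ncol(Xn), backbone$hidden, length(classes))
  else c(ncol(Xn), length(classes))
  layers <- nn_init(sizes, cfg$seed)
  n_body_dense <- length(layers) - 1L
  trainable <- c(rep(TRUE, n_body_dense), TRUE)
  if (n_body_dense >= 1L && backbone$n_trainable_tail_layers < n_body_dense)
    trainable[seq_len(n_body_dense - backbone$n_trainable_tail_layers)] <- FALSE
  tr <- nn_train(layers, Xn, one_hot(labs, classes), cfg$epochs,
                 cfg$batch_size, cfg$learning_rate, cfg$seed, trainable)
  structure(list(backbone = backbone, feat = feat, norm = norm,
                 layers = tr$layers, classes = classes, frozen = FALSE,
                 loss_history = tr$losses, train_cfg = cfg,
                 fitted_subjects = sort(unique(images$meta$subject_id))),
            class = "cdtl_model")
}

#' @export
print.cdtl_model <- function(x, ...) {
  cat(sprintf("<cdtl_model> backbone=%s classes=[%s]%s\n", x$backbone$name,
              paste(x$classes, collapse = ", "),
              if (isTRUE(x$frozen)) " (body frozen)" else ""))
  invisible(x)
}

#' Predict class probabilities for slices
#'
#' @param model a `cdtl_model`.
#' @param slices a [slice_set()].
#' @return Numeric matrix, one row per slice, columns named by class,
#'   each row summing to 1.
#' @export
predict_scores <- function(model, slices) {
  stopifnot(inherits(model, "cdtl_model"))
  Xn <- apply_norm(model$norm, raw_features(model$feat, slices))
  P <- nn_forward(model$layers, Xn)$probs
  colnames(P) <- model$classes
  P
}

#' Digest of a model's body parameters
#'
#' Stable content hash of everything except the head: feature
#' configuration (including any convolution filters), normalization, and
#' all dense layers but the last. Changes iff a body parameter changes.
#'
#' @param model a `cdtl_model`.
#' @return Character hash.
#' @export
body_digest <- function(model) {
  body <- model$layers[-length(model$layers)]
  rlang::hash(list(model$feat, model$norm, body))
}

#' Freeze a model's body and replace its head
#'
#' The transfer protocol: every body parameter is frozen (its digest is
#' recorded and must be identical after any subsequent retraining) and the
#' softmax head is replaced by a freshly initialized one with
#' `n_new_classes` outputs. Replacing the head again simply discards the
#' previous new head; the body is untouched either way.
#'
#' @param model a trained `cdtl_model`.
#' @param n_new_classes output classes of the new head (>= 2).
#' @param seed seed for the new head's initialization.
#' @return A `cdtl_model` with `frozen = TRUE` and an untrained head; call
#'   [retrain_head()] before predicting.
#' @export
freeze_and_replace_head <- function(model, n_new_classes, seed = 1L) {
  stopifnot(inherits(model, "cdtl_model"))
  n_new_classes <- as.integer(n_new_classes)
  if (n_new_classes < 2L) stop("n_new_classes must be >= 2", call. = FALSE)
  L <- length(model$layers)
  d_in <- nrow(model$layers[[L]]$W)
  new_head <- nn_init(c(d_in, n_new_classes), seed + 577L)[[1]]
  out <- model
  out$layers[[L]] <- new_head
  out$classes <- NULL
  out$frozen <- TRUE
  out$frozen_body_digest <- body_digest(model)
  out
}

#' Retrain the head of a frozen model
#'
#' Trains only the (replaced) softmax head on new labels; body activations
#' are precomputed once since the body is frozen. Errors if the body
#' digest moved — which the freeze contract makes impossible.
#'
#' @param model a frozen `cdtl_model` from [freeze_and_replace_head()].
#' @param images a labeled [slice_set()] for the target task.
#' @param cfg a [train_config()].
#' @return The model with a trained head; body digest unchanged.
#' @export
retrain_head <- function(model, images, cfg = train_config()) {
  stopifnot(inherits(model, "cdtl_model"), isTRUE(model$frozen))
  labs <- images$meta$label
  if (any(is.na(labs))) stop("all slices must be labeled", call. = FALSE)
  classes <- sort(unique(labs))
  L <- length(model$layers)
  if (length(classes) != ncol(model$layers[[L]]$W))
    stop("head has ", ncol(model$layers[[L]]$W), " outputs but data has ",
         length(classes), " classes", call. = FALSE)
  digest_before <- body_digest(model)
  Xn <- apply_norm(model$norm, raw_features(model$feat, images))
  # body activations: forward through all but the last layer, with ReLU
  A <- Xn
  if (L > 1L) for (l in seq_len(L - 1L))
    A <- pmax(sweep(A %*% model$layers[[l]]$W, 2, model$layers[[l]]$b, "+"), 0)
  tr <- nn_train(model$layers[L], A, one_hot(labs, classes), cfg$epochs,
                 cfg$batch_size, cfg$learning_rate, cfg$seed, TRUE)
  out <- model
  out$layers[[L]] <- tr$layers[[1]]
  out$classes <- classes
  out$loss_history <- tr$losses
  out$train_cfg <- cfg
  out$fitted_subjects <- sort(unique(images$meta$subject_id))
  if (!identical(body_digest(out), digest_before))
    stop("internal consistency error: body digest changed during ",
         "head-only retraining", call. = FALSE)
  out
}
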