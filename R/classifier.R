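#' Build the model-input tensor for a set of records
#'
#' Embeds each record's maps into the 8 x 9 grid and stacks four raw
#' channels: ND (measured sensitivities, dB), NDP (pattern-deviation
#' values, dB), PDP (ordinal probability-category codes 0..4 scaled to
#' `[0, 1]`) and the occupancy mask. Off-grid and blind-spot cells carry 0
#' in every channel; the mask channel tells the network which cells are
#' real, so sentinel cells cannot imitate deep defects. The dB channels
#' are standardized later with training-set statistics (see
#' [train_vf_model()]).
#'
#' @param records list of `vf_record`s.
#' @param norm a `vf_normative`.
#' @param layout a `vf_layout`.
#' @return Array `[n, 8, 9, 4]` with channels ND, NDP, PDP, mask.
#' @export
vf_model_input <- function(records, norm, layout = vf_layout()) {
  n <- length(records)
  x <- array(0, c(n, 8, 9, 4))
  for (i in seq_len(n)) {
    maps <- deviation_maps(records[[i]], norm)
    nd <- vf_embed(layout, records[[i]]$sensitivities, sentinel = 0)
    ndp <- vf_embed(layout, maps$pd, sentinel = 0)
    pdp <- vf_embed(layout, maps$pd_cat / 4, sentinel = 0)
    x[i, , , 1] <- nd$grid
    x[i, , , 2] <- ndp$grid
    x[i, , , 3] <- pdp$grid
    x[i, , , 4] <- nd$mask
  }
  x
}

map_kind_channels <- function(map_kind) {
  switch(map_kind,
         ND = c(1L, 4L), NDP = c(2L, 4L), PDP = c(3L, 4L),
         fusion = 1:4,
         stop("unknown map kind: ", map_kind, call. = FALSE))
}

#' Build an untrained map classifier
#'
#' A compact residual CNN for the 8 x 9 embedded maps: a 3 x 3
#' convolutional stem, `n_blocks` identity residual blocks (each two 3 x 3
#' convolutions with batch normalization after the convolutions and ReLU
#' activations), global average pooling, dropout, and a 2-way
#' fully-connected layer with softmax. The depth is deliberately shallow
#' for a 72-cell input; `n_blocks` is configurable from 1 to 8 so deeper
#' variants can be requested.
#'
#' @param map_kind `"ND"`, `"NDP"`, `"PDP"` (single-map, 2 input channels:
#'   map + mask) or `"fusion"` (channel-stacked variant, 4 channels).
#' @param width channel width of the trunk (default 16).
#' @param n_blocks number of residual blocks (default 2).
#' @param dropout dropout probability before the dense layer.
#' @param seed integer; fixes the parameter initialization.
#' @return An object of class `vf_cnn` (untrained).
#' @export
build_vf_model <- function(map_kind = "PDP", width = 16, n_blocks = 2,
                           dropout = 0.25, seed = 1L) {
  channels <- map_kind_channels(map_kind)
  if (width < 2 || n_blocks < 1 || n_blocks > 8 ||
      dropout < 0 || dropout >= 1) {
    stop("invalid model configuration", call. = FALSE)
  }
  set.seed(seed)
  layers <- c(
    list(nn_init_conv(3, 3, length(channels), width),
         nn_init_bn(width), list(type = "relu")),
    lapply(seq_len(n_blocks), function(i) nn_init_resblock(width)),
    list(list(type = "gap"), list(type = "dropout", p = dropout),
         nn_init_dense(width, 2))
  )
  structure(
    list(layers = layers, map_kind = map_kind, channels = channels,
         width = width, n_blocks = n_blocks, dropout = dropout,
         seed = seed, trained = FALSE, norms = NULL,
         operating_threshold = NA_real_),
    class = "vf_cnn"
  )
}

#' @export
print.vf_cnn <- function(x, ...) {
  cat(sprintf(
    "vf_cnn (%s): width %d, %d residual block(s), dropout %.2f, %s\n",
    x$map_kind, x$width, x$n_blocks, x$dropout,
    if (x$trained) sprintf("trained (threshold %.3f)",
                           x$operating_threshold)
    else "untrained"))
  invisible(x)
}

standardize_input <- function(x, channels, norms) {
  xs <- x[, , , channels, drop = FALSE]
  for (j in seq_along(channels)) {
    ch <- channels[j]
    if (ch %in% c(1L, 2L)) {  # dB channels
      mask <- x[, , , 4] > 0.5
      v <- (xs[, , , j] - norms$mean[ch]) / norms$sd[ch]
      v[!mask] <- 0  # sentinel stays 0 after standardization
      xs[, , , j] <- v
    }
  }
  xs
}

rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train a map classifier
#'
#' Minimizes softmax cross-entropy with Adam, early-stopping on the
#' validation AUC, and fixes the operating threshold by the Youden index
#' on the validation scores — test data never influences the threshold.
#' The training/validation split must be disjoint at the patient level;
#' an overlap raises an error.
#'
#' @param model an untrained `vf_cnn` from [build_vf_model()].
#' @param records list of `vf_record`s.
#' @param labels optional logical vector (`TRUE` = glaucoma); defaults to
#'   the records' own labels.
#' @param patient_ids vector identifying the subject of each record (all
#'   records of one subject must land in the same split); defaults to the
#'   record ids.
#' @param val_patients patient ids forming the validation split; defaults
#'   to a random 20% of patients (drawn under `seed`).
#' @param val_mask optional explicit logical validation mask per record
#'   (overrides `val_patients`); a mask that separates records of the
#'   same patient into different splits is rejected.
#' @param norm a `vf_normative` used to derive the deviation maps.
#' @param layout a `vf_layout`.
#' @param epochs,batch,lr,weight_decay,patience optimizer settings
#'   (defaults: 60, 64, 1e-3, 1e-4, 10).
#' @param seed integer governing shuffling, dropout and the default split.
#' @return The trained `vf_cnn` with `operating_threshold`, input `norms`
#'   and a `history` data frame (epoch, train loss, validation AUC).
#' @export
train_vf_model <- function(model, records, labels = NULL,
                           patient_ids = NULL, val_patients = NULL,
                           val_mask = NULL,
                           norm, layout = vf_layout(),
                           epochs = 60, batch = 64, lr = 1e-3,
                           weight_decay = 1e-4, patience = 10, seed = 1L) {
  stopifnot(inherits(model, "vf_cnn"))
  if (is.null(labels)) {
    labels <- vapply(records, function(r) r$label == "glaucoma", logical(1))
  }
  if (is.null(patient_ids)) {
    patient_ids <- vapply(records, function(r) as.character(r$id),
                          character(1))
  }
  set.seed(seed)
  if (is.null(val_mask)) {
    if (is.null(val_patients)) {
      pats <- unique(patient_ids)
      val_patients <- sample(pats, max(1, round(0.2 * length(pats))))
    }
    is_val <- patient_ids %in% val_patients
  } else {
    stopifnot(length(val_mask) == length(records))
    is_val <- val_mask
  }
  if (any(patient_ids[is_val] %in% patient_ids[!is_val])) {
    stop("patient overlap between training and validation splits",
         call. = FALSE)
  }
  if (!any(is_val) || !any(!is_val)) {
    stop("both splits must be non-empty", call. = FALSE)
  }
  xall <- vf_model_input(records, norm, layout)
  mask <- xall[, , , 4] > 0.5
  norms <- list(mean = numeric(4), sd = rep(1, 4))
  for (ch in 1:2) {
    vals <- xall[!is_val, , , ch][mask[!is_val, , ]]
    norms$mean[ch] <- mean(vals)
    norms$sd[ch] <- max(stats::sd(vals), 1e-6)
  }
  model$norms <- norms
  xtr <- standardize_input(xall[!is_val, , , , drop = FALSE],
                           model$channels, norms)
  xva <- standardize_input(xall[is_val, , , , drop = FALSE],
                           model$channels, norms)
  ytr <- as.integer(labels[!is_val]) + 1L
  yva <- labels[is_val]
  st <- adam_state_new()
  best <- list(auc = -Inf, layers = model$layers, epoch = 0L)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_auc = numeric(0))
  t <- 0
  for (ep in seq_len(epochs)) {
    res <- nn_epoch(model, st, xtr, ytr, batch, lr, weight_decay, NULL, t)
    model <- res$model
    t <- res$t
    sva <- nn_predict(model, xva)[, 2]
    auc <- rank_auc(sva, yva)
    hist <- rbind(hist, data.frame(epoch = ep, loss = res$loss,
                                   val_auc = auc))
    if (auc > best$auc + 1e-6) {
      best <- list(auc = auc, layers = model$layers, epoch = ep)
    }
    if (ep - best$epoch >= patience) break
  }
  model$layers <- best$layers
  sva <- nn_predict(model, xva)[, 2]
  model$operating_threshold <- youden_threshold(sva, yva)$threshold
  model$trained <- TRUE
  model$history <- hist
  model$val_auc <- best$auc
  model$train_seed <- seed
  model
}

#' Scores from a trained map classifier
#'
#' @param model a trained `vf_cnn`.
#' @param records list of `vf_record`s.
#' @param norm a `vf_normative`.
#' @param layout a `vf_layout`.
#' @return Numeric vector of glaucoma probabilities in `[0, 1]`.
#' @export
predict_vf_model <- function(model, records, norm, layout = vf_layout()) {
  stopifnot(inherits(model, "vf_cnn"))
  if (!model$trained) stop("model is untrained", call. = FALSE)
  x <- standardize_input(vf_model_input(records, norm, layout),
                         model$channels, model$norms)
  nn_predict(model, x)[, 2]
}

#' Ensemble fusion of per-map scores
#'
#' The unweighted arithmetic mean of the available per-map glaucoma
#' probabilities (1 to 3 maps). With a single score the score is returned
#' unchanged.
#'
#' @param scores numeric vector (or single-row set) of per-map scores.
#' @return Scalar fused score.
#' @export
ensemble_score <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scores to fuse", call. = FALSE)
  mean(scores)
}

#' Grad-CAM heatmap on the embedded grid
#'
#' Standard gradient-weighted class-activation mapping on the last
#' residual stage: channel weights are the spatial means of the gradient
#' of the target-class logit, the weighted activation sum is
#' ReLU-rectified and max-normalized to 1. The trunk keeps the 8 x 9
#' resolution throughout, so no upsampling is needed.
#'
#' @param model a trained `vf_cnn`.
#' @param record a `vf_record`.
#' @param norm a `vf_normative`.
#' @param layout a `vf_layout`.
#' @param class target class index (2 = glaucoma, the default).
#' @param normalize if `TRUE` (default) the map is max-normalized to 1;
#'   with `FALSE` the raw rectified class-evidence weights are returned,
#'   whose overall magnitude distinguishes fields with a heated area from
#'   fields without one.
#' @return 8 x 9 non-negative matrix; with `normalize = TRUE` the maximum
#'   is 1 unless the map is identically zero.
#' @export
gradcam_heatmap <- function(model, record, norm, layout = vf_layout(),
                            class = 2L, normalize = TRUE) {
  stopifnot(inherits(model, "vf_cnn"))
  if (!model$trained) stop("model is untrained", call. = FALSE)
  x <- standardize_input(vf_model_input(list(record), norm, layout),
                         model$channels, model$norms)
  gradcam_from_input(model, x, class, normalize)
}

# Grad-CAM on an already-standardized input tensor [1, 8, 9, C]
gradcam_from_input <- function(model, x, class = 2L, normalize = TRUE) {
  fw <- nn_forward(model, x, train = FALSE)
  types <- vapply(model$layers, function(l) l$type, character(1))
  li_conv <- max(which(types %in% c("resblock", "conv")))
  li_gap <- which(types == "gap")[1]
  acts <- fw$outs[[li_conv]]          # 1 x 8 x 9 x width
  dout <- matrix(0, 1, ncol(fw$out))
  dout[1, class] <- 1
  bw <- nn_backward(fw$model, fw$caches, dout)
  dacts <- bw$dx_in[[li_gap]]         # gradient wrt gap input
  w <- apply(dacts[1, , , , drop = FALSE], 4, mean)
  cam <- matrix(0, 8, 9)
  for (ci in seq_along(w)) cam <- cam + w[ci] * acts[1, , , ci]
  cam <- pmax(cam, 0)
  if (normalize && max(cam) > 0) cam <- cam / max(cam)
  cam
}
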