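# bilinear resize of a single-channel matrix
resize_matrix <- function(m, h, w) {
  if (all(dim(m) == c(h, w))) return(m)
  EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w,
                                     filter = "bilinear"))
}

#' Grad-CAM saliency for the release prediction
#'
#' Gradient-weighted class-activation mapping adapted to scalar regression:
#' the predicted Q% is differentiated with respect to the final convolution
#' layer of the requested image branch, the gradients are globally
#' average-pooled into channel weights, and the rectified weighted activation
#' sum is min-max normalized and bilinearly upsampled to the input
#' resolution. A map whose rectified sum is identically zero (dead
#' gradients) is returned as all zeros rather than `NaN`.
#'
#' @param model A trained `qnet` containing image branches.
#' @param dataset A `q_dataset`.
#' @param index Record index.
#' @param branch `"280"` or `"520"`.
#' @return A list of class `saliency_map`: `heatmap` (input-resolution
#'   matrix in \[0, 1\]), `raw` (conv-resolution rectified map), `branch`,
#'   `record_id`, `conv_layer_id`.
#' @export
gradcam <- function(model, dataset, index, branch = c("280", "520")) {
  branch <- match.arg(as.character(branch[1]), c("280", "520"))
  if (model$variant == "toy_conv") {
    return(gradcam_toy(model, dataset, index))
  }
  if (!model$variant %in% c("img_only", "img_time", "full_multimodal")) {
    rlang::abort(sprintf("Variant '%s' has no image branches.", model$variant))
  }
  batch <- make_batch(dataset, index, model)
  fw <- forward_qnet(model, batch, keep_cache = TRUE)
  bw <- backward_qnet(model, 1, fw$cache)
  key <- paste0("b", branch)
  act <- fw$cache$branches[[key]]$a3[, , , 1, drop = FALSE]
  grad <- bw$act_grads[[key]][, , , 1, drop = FALSE]
  weights <- apply(grad, 3, mean)
  raw <- matrix(0, dim(act)[1], dim(act)[2])
  for (f in seq_along(weights)) raw <- raw + weights[f] * act[, , f, 1]
  raw <- pmax(raw, 0)
  finalize_saliency(raw, model$input_size, branch,
                    dataset$meta$record_id[index],
                    conv_layer_id = paste0(key, "_conv3"))
}

finalize_saliency <- function(raw, size, branch, record_id, conv_layer_id) {
  heat <- resize_matrix(raw, size, size)
  rng <- range(heat)
  heat <- if (diff(rng) <= 0) matrix(0, nrow(heat), ncol(heat)) else
    pmin(pmax((heat - rng[1]) / diff(rng), 0), 1)
  structure(list(heatmap = heat, raw = raw, branch = branch,
                 record_id = record_id, conv_layer_id = conv_layer_id),
            class = "saliency_map")
}

#' Single-filter linear toy network for saliency validation
#'
#' A minimal analytically tractable model: one 3x3 convolution filter with a
#' linear activation, followed by a global sum scaled by `coef`. Its
#' prediction is `coef * sum(conv(x, kernel))`, so the Grad-CAM map equals
#' the rectified product `relu(coef * conv(x, kernel))` up to min-max
#' normalization — an exact hand-computable reference.
#'
#' @param kernel 3 x 3 numeric kernel.
#' @param coef Scalar output weight.
#' @return A `qnet` of variant `"toy_conv"` operating on the first channel
#'   of the 280 nm frame.
#' @export
toy_conv_model <- function(kernel = matrix(1, 3, 3) / 9, coef = 1) {
  structure(list(variant = "toy_conv",
                 params = list(kernel = array(kernel, c(3, 3, 1, 1)),
                               coef = coef),
                 input_size = NA_integer_),
            class = "qnet")
}

toy_forward <- function(model, x_img) {
  x <- array(x_img[, , 1], c(dim(x_img)[1], dim(x_img)[2], 1, 1))
  act <- conv_fwd(x, model$params$kernel, 0)
  list(y = model$params$coef * sum(act), act = act[, , 1, 1])
}

gradcam_toy <- function(model, dataset, index) {
  x_img <- dataset$x280[, , , index]
  fw <- toy_forward(model, x_img)
  # d y / d act = coef everywhere; GAP weight = coef
  raw <- pmax(model$params$coef * fw$act, 0)
  finalize_saliency(raw, dim(x_img)[1], "280",
                    dataset$meta$record_id[index], "toy_conv1")
}

toy_predict <- function(model, x_img) toy_forward(model, x_img)$y

#' Occlusion importance map
#'
#' Model-agnostic saliency oracle: the image is divided into a grid of
#' square patches, each patch in turn is replaced by the zero-absorbance
#' background colour (dark blue of the jet colormap), and the absolute
#' change of the predicted Q% is recorded.
#'
#' @param model A trained `qnet` (or toy model).
#' @param dataset A `q_dataset`.
#' @param index Record index.
#' @param branch Image branch to occlude (`"280"` or `"520"`).
#' @param patch_size Patch side length in pixels (>= 1).
#' @return A matrix of |prediction change| values, one per patch.
#' @export
occlusion_importance <- function(model, dataset, index,
                                 branch = c("280", "520"), patch_size = 8) {
  branch <- match.arg(as.character(branch[1]), c("280", "520"))
  if (patch_size < 1) rlang::abort("`patch_size` must be >= 1.")
  key <- paste0("x", branch)
  x0 <- dataset[[key]][, , , index]
  size <- dim(x0)[1]
  background <- jet_colormap(256)[1, ]  # dark blue, zero absorbance
  predict_one <- function(x_img) {
    if (model$variant == "toy_conv") return(toy_predict(model, x_img))
    ds <- dataset
    ds[[key]] <- array(x_img, c(dim(x_img), 1))
    # single-record view with all other modalities untouched
    other <- if (branch == "280") "x520" else "x280"
    ds[[other]] <- dataset[[other]][, , , index, drop = FALSE]
    ds$time_norm <- dataset$time_norm[index]
    ds$cond <- dataset$cond[index, , drop = FALSE]
    ds$q <- dataset$q[index]
    ds$meta <- dataset$meta[index, ]
    predict(model, ds, 1)
  }
  base_pred <- predict_one(x0)
  steps <- seq(1, size, by = patch_size)
  out <- matrix(0, length(steps), length(steps))
  for (i in seq_along(steps)) {
    for (j in seq_along(steps)) {
      xi <- x0
      ri <- steps[i]:min(steps[i] + patch_size - 1, size)
      rj <- steps[j]:min(steps[j] + patch_size - 1, size)
      for (ch in 1:3) xi[ri, rj, ch] <- background[ch]
      out[i, j] <- abs(predict_one(xi) - base_pred)
    }
  }
  out
}

#' Overlay a saliency map on an image
#'
#' Alpha-blends the jet-coloured heatmap onto the source frame:
#' `alpha * colormap(heatmap) + (1 - alpha) * image`.
#'
#' @param map A `saliency_map`.
#' @param image H x W x 3 RGB array in \[0, 255\].
#' @param alpha Blend weight in \[0, 1\] (default 0.5).
#' @return An H x W x 3 RGB array in \[0, 255\].
#' @export
overlay_heatmap <- function(map, image, alpha = 0.5) {
  if (alpha < 0 || alpha > 1) rlang::abort("`alpha` must be in [0, 1].")
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    rlang::abort("`image` must be an H x W x 3 RGB array.")
  }
  h <- map$heatmap
  if (!all(dim(h) == dim(image)[1:2])) {
    h <- resize_matrix(h, dim(image)[1], dim(image)[2])
    if (!all(dim(h) == dim(image)[1:2])) {
      rlang::abort("Heatmap cannot be resized to the image shape.")
    }
  }
  lut <- jet_colormap(256)
  idx <- pmin(256L, pmax(1L, as.integer(floor(pmin(1, pmax(0, h)) * 255)) + 1L))
  out <- array(0, dim(image))
  for (ch in 1:3) {
    heat_ch <- matrix(lut[idx, ch], nrow(h), ncol(h)) * 255
    out[, , ch] <- alpha * heat_ch + (1 - alpha) * image[, , ch]
  }
  out
}

#' Regional localization statistics of a saliency map
#'
#' Mean heatmap importance inside the ground-truth edge, core and holder
#' regions, and the edge/core importance ratio. The ratio is `NA` when the
#' core mean is zero, and a statistic over an empty mask is `NA`.
#'
#' @param map A `saliency_map`.
#' @param truth A `saliency_truth` from [saliency_ground_truth()].
#' @return A one-row tibble: `branch`, `edge_mean`, `core_mean`,
#'   `holder_mean`, `edge_core_ratio`.
#' @export
localization_stats <- function(map, truth) {
  h <- map$heatmap
  mask_mean <- function(mask) {
    m <- resize_mask(mask, dim(h))
    if (!any(m)) return(NA_real_)
    mean(h[m])
  }
  edge <- mask_mean(truth$edge)
  core <- mask_mean(truth$core)
  holder <- mask_mean(truth$holder)
  tibble::tibble(
    branch = map$branch, edge_mean = edge, core_mean = core,
    holder_mean = holder,
    edge_core_ratio = if (is.na(core) || core == 0) NA_real_ else edge / core)
}

resize_mask <- function(mask, dims) {
  if (all(dim(mask) == dims)) return(mask)
  resize_matrix(mask * 1, dims[1], dims[2]) >= 0.5
}
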