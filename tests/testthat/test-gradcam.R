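# direct cross-correlation, written independently of the package kernels
naive_conv_valid <- function(x, k) {
  h <- nrow(x) - 2; w <- ncol(x) - 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- sum(x[i:(i + 2), j:(j + 2)] * k)
  }
  out
}

toy_image <- function(size = 12) {
  img <- array(0, c(size, size, 3))
  withr::with_seed(31, img[, , 1] <- matrix(runif(size^2), size))
  img[, , 2] <- img[, , 1]
  img[, , 3] <- img[, , 1]
  img
}

test_that("Grad-CAM on the single-filter linear toy model is exact", {
  k <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3) / 4
  for (coef in c(0.7, -0.3)) {
    model <- toy_conv_model(k, coef)
    img <- toy_image(12)
    ds <- single_image_dataset(img)
    sm <- gradcam(model, ds, 1, "280")
    # analytic reference: relu(coef * conv(x, k)), min-max normalized
    ref <- pmax(coef * naive_conv_valid(img[, , 1], k), 0)
    expect_equal(dim(sm$heatmap), c(12, 12))
    heat_at_conv_res <- sm$raw
    expect_equal(heat_at_conv_res, ref, tolerance = 1e-12)
    if (max(ref) > 0) {
      expect_equal(max(sm$heatmap), 1)
      expect_equal(min(sm$heatmap), 0)
    }
  }
})

test_that("dead gradients yield an all-zero heatmap, not NaN", {
  # toy with zero output weight: every gradient vanishes
  sm <- gradcam(toy_conv_model(matrix(1, 3, 3), 0),
                single_image_dataset(toy_image(10)), 1, "280")
  expect_true(all(sm$heatmap == 0))
  # deep model whose head ignores the 280 branch entirely (briefly trained so
  # the 520 branch carries live gradients)
  ds <- tiny_dataset(seed = 9, size = 32)
  cfg <- model_config("img_only", epochs = 3, learning_rate = 0.01,
                      batch_size = 4, seed = 1)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  m$params$head$d1$w[m$segments$b280, ] <- 0
  sm2 <- gradcam(m, ds, 1, "280")
  expect_true(all(sm2$heatmap == 0))
  # live branch: the map is all-zero (rectified sum can vanish) or spans [0,1]
  sm3 <- gradcam(m, ds, 1, "520")
  expect_true(max(sm3$heatmap) %in% c(0, 1))  # min-max contract
  expect_error(gradcam(train_model(build_model(
    model_config("linear_baseline", epochs = 1), 6, 32), ds), ds, 1, "280"),
    "image branches")
})

test_that("heatmaps are invariant to positive rescaling of the head weights", {
  ds <- tiny_dataset(seed = 10, size = 32)
  cfg <- model_config("img_time", epochs = 2, learning_rate = 0.01,
                      batch_size = 4, seed = 2)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  sm1 <- gradcam(m, ds, 2, "280")
  m$params$head$d3$w <- m$params$head$d3$w * 7.3
  sm2 <- gradcam(m, ds, 2, "280")
  expect_equal(sm1$heatmap, sm2$heatmap, tolerance = 1e-12)
})

test_that("occlusion importance matches its definitional edge cases", {
  img <- toy_image(12)
  ds <- single_image_dataset(img)
  # constant-output model
  occ0 <- occlusion_importance(toy_conv_model(matrix(0, 3, 3), 1), ds, 1,
                               "280", patch_size = 4)
  expect_true(all(occ0 == 0))
  # one patch covering the whole image
  model <- toy_conv_model(matrix(1, 3, 3) / 9, 2)
  occ_all <- occlusion_importance(model, ds, 1, "280", patch_size = 12)
  bg <- img
  bgc <- jet_colormap(256)[1, ]
  for (ch in 1:3) bg[, , ch] <- bgc[ch]
  expect_equal(dim(occ_all), c(1, 1))
  expect_equal(occ_all[1, 1],
               abs(dissolvis:::toy_predict(model, img) -
                   dissolvis:::toy_predict(model, bg)), tolerance = 1e-12)
})

test_that("occlusion and Grad-CAM agree in rank on the toy model", {
  img <- toy_image(16)
  # localized bright blob on a dark background
  img[, , 1] <- 0.02
  img[4:7, 9:13, 1] <- 1
  img[, , 2] <- img[, , 1]; img[, , 3] <- img[, , 1]
  ds <- single_image_dataset(img)
  model <- toy_conv_model(matrix(1, 3, 3) / 9, 1)
  sm <- gradcam(model, ds, 1, "280")
  occ <- occlusion_importance(model, ds, 1, "280", patch_size = 4)
  # aggregate the heatmap onto the occlusion grid
  agg <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    agg[i, j] <- mean(sm$heatmap[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
  }
  expect_gte(cor(as.vector(agg), as.vector(occ), method = "spearman"), 0.5)
})

test_that("overlays blend exactly at the stated alpha", {
  img <- toy_image(10) * 255
  sm <- gradcam(toy_conv_model(matrix(1, 3, 3) / 9, 1),
                single_image_dataset(img / 255), 1, "280")
  expect_equal(overlay_heatmap(sm, img, alpha = 0), img)
  pure <- overlay_heatmap(sm, img, alpha = 1)
  half <- overlay_heatmap(sm, img, alpha = 0.5)
  expect_equal(half, 0.5 * pure + 0.5 * img, tolerance = 1e-12)
  lut <- jet_colormap(256)
  # alpha = 1 is the raw colormap render of the heatmap
  idx <- pmin(256L, as.integer(floor(sm$heatmap * 255)) + 1L)
  expect_equal(pure[, , 1], matrix(lut[idx, 1] * 255, 10, 10),
               tolerance = 1e-12)
  expect_error(overlay_heatmap(sm, img, alpha = 2), "alpha")
})

test_that("localization statistics summarize mask regions correctly", {
  truth <- structure(list(
    edge = rbind(c(TRUE, TRUE), c(FALSE, FALSE)),
    core = rbind(c(FALSE, FALSE), c(TRUE, TRUE)),
    holder = matrix(FALSE, 2, 2)), class = "saliency_truth")
  map <- structure(list(heatmap = rbind(c(1, 0.5), c(0.25, 0.25)),
                        branch = "280"), class = "saliency_map")
  st <- localization_stats(map, truth)
  expect_equal(st$edge_mean, 0.75)
  expect_equal(st$core_mean, 0.25)
  expect_equal(st$edge_core_ratio, 3)
  expect_true(is.na(st$holder_mean))  # empty mask
  # uniform heatmap: ratio exactly 1
  map$heatmap <- matrix(0.4, 2, 2)
  expect_equal(localization_stats(map, truth)$edge_core_ratio, 1)
  # degenerate: all importance on the edge, none in the core
  map$heatmap <- rbind(c(1, 1), c(0, 0))
  expect_true(is.na(localization_stats(map, truth)$edge_core_ratio))
})
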