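test_that("model builds expose the specified architecture", {
  cfg <- model_config("full_multimodal", epochs = 1, seed = 1)
  m <- build_model(cfg, condition_dim = 6, input_size = 64)
  # fusion vector: two image branches + time branch + condition vector
  expect_named(m$segments, c("b280", "b520", "time", "cond"))
  expect_length(m$segments$cond, 6)
  img_flat <- 6 * 6 * 64    # 64 -> 62/31 -> 29/14 -> 12/6 with 64 filters
  expect_length(m$segments$b280, img_flat)
  expect_length(m$segments[["time"]], 31 * 31 * 16)
  # dense head 128 -> 64 -> 1
  expect_equal(dim(m$params$head$d1$w), c(m$feature_dim, 128))
  expect_equal(dim(m$params$head$d2$w), c(128, 64))
  expect_equal(dim(m$params$head$d3$w), c(64, 1))
  # three convolution layers per image branch, 3x3 kernels
  expect_equal(dim(m$params$b280$c1$w), c(3, 3, 3, 16))
  expect_equal(dim(m$params$b280$c3$w), c(3, 3, 32, 64))
  # time branch: single 16-filter convolution on a 1-channel input
  expect_equal(dim(m$params$time$c$w), c(3, 3, 1, 16))
  expect_error(build_model(model_config("img_only", epochs = 0)), "positive")
})

test_that("initialization is seed-deterministic", {
  cfg <- model_config("img_time", epochs = 1, seed = 77)
  a <- build_model(cfg, 6, 32)
  b <- build_model(cfg, 6, 32)
  expect_identical(qnet_checksum(a), qnet_checksum(b))
  expect_identical(a$params, b$params)
  cfg2 <- model_config("img_time", epochs = 1, seed = 78)
  expect_false(qnet_checksum(build_model(cfg2, 6, 32)) == qnet_checksum(a))
})

test_that("convolution and pooling gradients match numerical differentiation", {
  withr::with_seed(11, {
    x <- array(runif(6 * 6 * 2 * 1), c(6, 6, 2, 1))
    w <- array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3, 3, 2, 3))
    b <- rnorm(3)
    loss <- function(x, w, b) sum(sin(dissolvis:::conv_fwd(x, w, b)))
    y <- dissolvis:::conv_fwd(x, w, b)
    g <- dissolvis:::conv_bwd(x, w, cos(y))
    eps <- 1e-6
    for (probe in 1:5) {
      i <- sample(length(w), 1)
      wp <- w; wp[i] <- wp[i] + eps
      wm <- w; wm[i] <- wm[i] - eps
      expect_equal(g$dw[i], (loss(x, wp, b) - loss(x, wm, b)) / (2 * eps),
                   tolerance = 1e-5)
      j <- sample(length(x), 1)
      xp <- x; xp[j] <- xp[j] + eps
      xm <- x; xm[j] <- xm[j] - eps
      expect_equal(g$dx[j], (loss(xp, w, b) - loss(xm, w, b)) / (2 * eps),
                   tolerance = 1e-5)
    }
    # max pooling routes gradient to the argmax
    p <- dissolvis:::pool_fwd(x)
    dx <- dissolvis:::pool_bwd(array(1, dim(p$out)), p$idx, dim(x))
    expect_equal(sum(dx), length(p$out))
    expect_true(all(dx %in% c(0, 1)))
    expect_equal(sum(x * dx), sum(p$out))
  })
})

test_that("training fits a constant target to within one percent", {
  ds <- tiny_dataset(seed = 2, size = 32)
  ds$q <- rep(50, length(ds$q))
  cfg <- model_config("dnn_numeric", epochs = 250, learning_rate = 0.01,
                      batch_size = 4, seed = 3)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  expect_true(all(abs(predict(m, ds) - 50) < 1))
})

test_that("training reduces the loss and is bit-reproducible under a seed", {
  ds <- tiny_dataset(seed = 4, size = 32)
  cfg <- model_config("img_time", epochs = 15, learning_rate = 0.01,
                      batch_size = 4, seed = 5)
  m1 <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  expect_lte(tail(m1$history$loss, 1), m1$history$loss[1])
  m2 <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  expect_identical(predict(m1, ds), predict(m2, ds))
})

test_that("the linear baseline equals the closed-form least-squares solution", {
  ds <- tiny_dataset(seed = 6, size = 32)
  cfg <- model_config("linear_baseline", epochs = 1, seed = 1)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  # independent normal-equations oracle (ridge-free pseudoinverse via qr)
  x <- cbind(1, ds$time_norm, ds$cond)
  beta <- qr.coef(qr(x), ds$q)
  beta[is.na(beta)] <- 0
  expect_equal(unname(drop(x %*% beta)), unname(predict(m, ds)),
               tolerance = 1e-8)
})

test_that("evaluation metrics match hand arithmetic and handle degeneracy", {
  obs <- c(0, 50, 100); pred <- c(10, 50, 90)
  met <- eval_metrics(obs, pred)
  expect_equal(met$rmse, sqrt(200 / 3), tolerance = 1e-12)  # 8.165
  expect_equal(round(met$rmse, 3), 8.165)
  expect_equal(met$r_squared, 1 - 200 / 5000)               # 0.96
  expect_equal(eval_metrics(obs, obs), list(r_squared = 1, rmse = 0))
  expect_equal(eval_metrics(obs, rep(mean(obs), 3))$r_squared, 0)
  expect_true(is.na(eval_metrics(c(4, 4, 4), c(1, 2, 3))$r_squared))
})

test_that("evaluate() agrees with an independent streaming computation", {
  withr::with_seed(123, {
    for (rep in 1:20) {
      n <- sample(5:200, 1)
      obs <- runif(n, 0, 100)
      pred <- obs + rnorm(n, 0, 15)
      ours <- eval_metrics(obs, pred)
      ref <- streaming_metrics(obs, pred)
      expect_equal(ours$r_squared, ref$r_squared, tolerance = 1e-10)
      expect_equal(ours$rmse, ref$rmse, tolerance = 1e-10)
    }
  })
})

test_that("evaluation reports stratify by medium", {
  ds <- tiny_dataset(seed = 7, size = 32)
  cfg <- model_config("linear_baseline", epochs = 1, seed = 1)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  ev <- evaluate_model(m, ds)
  expect_s3_class(ev, "eval_report")
  expect_equal(sort(ev$per_ph$ph), c(1.2, 6.8))
  expect_equal(sum(ev$per_ph$n), ev$n_test)
  g <- glance(ev)
  expect_equal(g$r_squared, ev$r_squared)
  td <- tidy(ev)
  expect_true("overall" %in% td$stratum)
})

test_that("profile reconstruction orders time points and rejects mixtures", {
  ds <- tiny_dataset(seed = 8, size = 32)
  cfg <- model_config("linear_baseline", epochs = 1, seed = 1)
  m <- train_model(build_model(cfg, ncol(ds$cond), 32), ds)
  idx <- which(ds$meta$formulation_id == "asa_mc" & ds$meta$ph == 1.2)
  prof <- reconstruct_profile(m, ds, indices = rev(idx))
  expect_s3_class(prof, "dissolution_profile")
  expect_true(!is.unsorted(prof$time_min))
  expect_equal(nrow(prof), length(idx))
  one <- reconstruct_profile(m, ds, indices = idx[1])
  expect_equal(nrow(one), 1)
  expect_error(reconstruct_profile(m, ds, indices = seq_along(ds$q)), "mixed")
  # a perfect oracle model reconstructs the simulated ground truth
  oracle <- m
  oracle$coef <- oracle$coef * 0
  perfect <- reconstruct_profile(m, ds, "asa_mc", 1.2)
  expect_equal(perfect$q_observed,
               sort(ds$q[ds$meta$formulation_id == "asa_mc" & ds$meta$ph == 1.2]))
})
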