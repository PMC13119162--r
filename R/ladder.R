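#' Scaled ablation-ladder protocol
#'
#' Runs the full study loop at desk scale for a set of seeds: simulate the
#' 16-experiment study design, assemble the supervised dataset, train the
#' image-only, image+time and full multimodal variants plus the linear
#' baseline, evaluate on the held-out split, and quantify the wavelength
#' dissociation of the full model's saliency (mean edge/core importance
#' ratio of the 280 nm branch versus the 520 nm branch over the test
#' records).
#'
#' The scaled protocol trains at 64 x 64 resolution with a larger step size
#' (0.01), smaller batches (4), a 16 x 16 time-matrix branch and far fewer
#' epochs than the reference protocol; see the methods vignette for the
#' arithmetic behind those choices.
#'
#' @param seeds Integer seeds, one full run each.
#' @param size Image resolution (default 64).
#' @param epochs Named epochs per iterative variant.
#' @param learning_rate Adam step size of the scaled protocol.
#' @param batch_size Minibatch size.
#' @param time_size Time-matrix resolution of the scaled protocol (see
#'   [model_config()]).
#' @param test_fraction Held-out fraction.
#' @param noise_sd Simulated absorbance noise.
#' @param variants Iterative CNN variants to train.
#' @param include_linear Also fit the linear baseline.
#' @param verbose Print progress.
#' @return A list of class `ladder_result`: `metrics` (tibble with `seed`,
#'   `variant`, `r_squared`, `rmse`, `n_test`), `dissociation` (tibble with
#'   `seed`, `ratio_280`, `ratio_520`, `dissociated`), `per_ph` (stratified
#'   metrics of the full model).
#' @export
run_ladder <- function(seeds = c(1L, 2L, 3L), size = 64,
                       epochs = c(img_only = 25, img_time = 25,
                                  full_multimodal = 35),
                       learning_rate = 0.01, batch_size = 4, time_size = 16,
                       test_fraction = 0.2, noise_sd = 0.02,
                       variants = c("img_only", "img_time", "full_multimodal"),
                       include_linear = TRUE, verbose = FALSE) {
  metrics <- list()
  dissoc <- list()
  per_ph <- list()
  for (s in seeds) {
    if (verbose) message(sprintf("-- seed %d: simulating", s))
    sdi <- simulate_dataset(seed = s, noise_sd = noise_sd)
    ds <- build_dataset(sdi, size = size)
    split <- make_split(length(ds$q), test_fraction, seed = s)
    for (v in variants) {
      if (verbose) message(sprintf("   training %s (%d epochs)", v, epochs[[v]]))
      cfg <- model_config(v, epochs = epochs[[v]],
                          learning_rate = learning_rate,
                          batch_size = batch_size, seed = s,
                          time_size = time_size)
      m <- build_model(cfg, condition_dim = ncol(ds$cond), input_size = size)
      m <- train_model(m, ds, split)
      ev <- evaluate_model(m, ds, split$test)
      metrics[[length(metrics) + 1]] <- tibble::tibble(
        seed = s, variant = v, r_squared = ev$r_squared, rmse = ev$rmse,
        n_test = ev$n_test)
      if (v == "full_multimodal") {
        per_ph[[length(per_ph) + 1]] <-
          dplyr::mutate(ev$per_ph, seed = s, .before = 1)
        dissoc[[length(dissoc) + 1]] <-
          wavelength_dissociation(m, ds, sdi, split$test, seed = s)
      }
    }
    if (include_linear) {
      lm_cfg <- model_config("linear_baseline", epochs = 1, seed = s)
      lmod <- train_model(build_model(lm_cfg, ncol(ds$cond), size), ds, split)
      ev <- evaluate_model(lmod, ds, split$test)
      metrics[[length(metrics) + 1]] <- tibble::tibble(
        seed = s, variant = "linear_baseline", r_squared = ev$r_squared,
        rmse = ev$rmse, n_test = ev$n_test)
    }
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 dissociation = dplyr::bind_rows(dissoc),
                 per_ph = dplyr::bind_rows(per_ph)),
            class = "ladder_result")
}

# Median edge/core saliency ratio per branch over a set of records (median:
# single-record ratios explode when the core importance approaches zero).
wavelength_dissociation <- function(model, ds, sdi, indices, seed = NA_integer_) {
  stats_one <- function(branch) {
    vals <- vapply(indices, function(i) {
      truth <- sdi$experiments[[ds$meta$experiment[i]]]$truth
      localization_stats(gradcam(model, ds, i, branch), truth)$edge_core_ratio
    }, numeric(1))
    stats::median(vals, na.rm = TRUE)
  }
  r280 <- stats_one("280")
  r520 <- stats_one("520")
  tibble::tibble(seed = seed, ratio_280 = r280, ratio_520 = r520,
                 dissociated = is.finite(r280) && is.finite(r520) &&
                   r280 > r520)
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("<ladder_result>\n")
  agg <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$variant),
    mean_r2 = mean(.data$r_squared), sd_r2 = stats::sd(.data$r_squared),
    mean_rmse = mean(.data$rmse), .groups = "drop")
  print(agg)
  if (nrow(x$dissociation) > 0) {
    cat(sprintf("wavelength dissociation (280 edge vs 520 core): %d/%d seeds\n",
                sum(x$dissociation$dissociated), nrow(x$dissociation)))
  }
  invisible(x)
}
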