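#' Default experiment configuration
#'
#' Two bundled configurations: `"desk"`, a reduced-resolution configuration
#' (64 x 64 images, short training) suitable for interactive runs and
#' continuous testing, and `"reference"`, mirroring the full imaging
#' protocol (224 x 224 images, seed 1234, 80:20 split, 50/50/200 epochs at
#' learning rate 0.001).
#'
#' @param scale `"desk"` or `"reference"`.
#' @param seed Base seed.
#' @return A nested configuration list (also writable as YAML).
#' @export
default_experiment_config <- function(scale = c("desk", "reference"),
                                      seed = 1234L) {
  scale <- match.arg(scale)
  desk <- identical(scale, "desk")
  list(
    simulator = list(ph_values = c(1.2, 6.8),
                     sample_times = default_schedule(),
                     noise_sd = 0.02, seed = seed),
    dataset = list(size = if (desk) 64 else 224, test_fraction = 0.2,
                   include_ph = TRUE),
    ladder = list(
      variants = c("img_only", "img_time", "full_multimodal",
                   "dnn_numeric", "linear_baseline"),
      epochs = as.list(
        if (desk) c(img_only = 25, img_time = 25, full_multimodal = 35,
                    dnn_numeric = 300, linear_baseline = 1)
        else c(img_only = 50, img_time = 50, full_multimodal = 200,
               dnn_numeric = 200, linear_baseline = 1)),
      learning_rate = if (desk) 0.01 else 0.001,
      batch_size = if (desk) 4 else 8,
      time_size = if (desk) 16 else NULL),
    explain = list(branches = c("280", "520"), alpha = 0.5,
                   max_records = if (desk) 8 else 31)
  )
}

#' Run the full reproduction pipeline
#'
#' One-command orchestration: simulate the study design, write the imaging
#' dataset to disk, assemble the supervised dataset, train every requested
#' model variant, evaluate (overall and per medium), reconstruct example
#' profiles, compute Grad-CAM localization statistics for the full model,
#' and write metrics, predictions, plots and the exact configuration used
#' into the output directory.
#'
#' @param config Configuration list (see [default_experiment_config()]) or
#'   path to a YAML file with the same structure.
#' @param out_dir Output directory.
#' @param verbose Print stage progress.
#' @return A list of class `run_report`: per-variant `eval_report`s,
#'   `metrics` tibble, `localization` tibble and the `config` used.
#' @export
run_pipeline <- function(config = default_experiment_config(), out_dir,
                         verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$simulator$seed %||% 1234L

  say("[simulate] %d media, seed %d", length(config$simulator$ph_values), seed)
  sdi <- simulate_dataset(ph_values = config$simulator$ph_values,
                          sample_times = config$simulator$sample_times,
                          seed = seed,
                          noise_sd = config$simulator$noise_sd)
  write_sdi_dataset(sdi, file.path(out_dir, "sdi"))

  say("[dataset] %d supervised records at %dx%d",
      sum(!is.na(sdi$manifest$q_percent)),
      config$dataset$size, config$dataset$size)
  ds <- build_dataset(sdi, size = config$dataset$size,
                      include_ph = config$dataset$include_ph)
  split <- make_split(length(ds$q), config$dataset$test_fraction, seed = seed)
  jsonlite::write_json(
    list(seed = seed, test_fraction = config$dataset$test_fraction,
         train = split$train, test = split$test,
         condition_order = colnames(ds$cond)),
    file.path(out_dir, "split.json"), auto_unbox = TRUE, pretty = TRUE)

  reports <- list()
  rows <- list()
  full_model <- NULL
  for (v in config$ladder$variants) {
    say("[train] %s", v)
    cfg <- model_config(v, epochs = config$ladder$epochs[[v]] %||% 1,
                        learning_rate = config$ladder$learning_rate,
                        batch_size = config$ladder$batch_size, seed = seed,
                        time_size = config$ladder$time_size)
    m <- build_model(cfg, condition_dim = ncol(ds$cond),
                     input_size = config$dataset$size)
    m <- train_model(m, ds, split)
    ev <- evaluate_model(m, ds, split$test)
    reports[[v]] <- ev
    rows[[v]] <- glance(ev)
    vd <- file.path(out_dir, "runs", v)
    dir.create(vd, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ev$predictions, file.path(vd, "predictions.csv"),
                     row.names = FALSE)
    if (!is.null(m$history)) {
      utils::write.csv(m$history, file.path(vd, "history.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(overall = glance(ev), per_ph = ev$per_ph),
      file.path(vd, "metrics.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (v == "full_multimodal") full_model <- m
  }
  metrics <- dplyr::bind_rows(rows)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  localization <- tibble::tibble()
  if (!is.null(full_model)) {
    say("[explain] Grad-CAM localization of the full model")
    md <- file.path(out_dir, "maps")
    dir.create(md, recursive = TRUE, showWarnings = FALSE)
    take <- head(split$test, config$explain$max_records %||% 8)
    loc <- list()
    for (i in take) {
      truth <- sdi$experiments[[ds$meta$experiment[i]]]$truth
      rec <- sdi$experiments[[ds$meta$experiment[i]]]$records[[ds$meta$record[i]]]
      for (b in config$explain$branches) {
        sm <- gradcam(full_model, ds, i, b)
        st <- localization_stats(sm, truth)
        st$record_id <- ds$meta$record_id[i]
        loc[[length(loc) + 1]] <- st
        frame <- if (b == "280") rec$frame_280 else rec$frame_520
        ov <- overlay_heatmap(sm, frame, config$explain$alpha %||% 0.5)
        png::writePNG(ov / 255, file.path(
          md, sprintf("%s_%s_overlay.png", ds$meta$record_id[i], b)))
      }
    }
    localization <- dplyr::bind_rows(loc)
    utils::write.csv(localization, file.path(md, "localization.csv"),
                     row.names = FALSE)
  }

  say("[report] plots and configuration echo")
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(full_model)) {
    ev <- reports[["full_multimodal"]]
    ggplot2::ggsave(file.path(rep_dir, "predicted_vs_observed.png"),
                    autoplot(ev), width = 5, height = 5, dpi = 120)
    ggplot2::ggsave(file.path(rep_dir, "residuals.png"),
                    autoplot(ev, type = "residuals"),
                    width = 5, height = 4, dpi = 120)
  }
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  structure(list(reports = reports, metrics = metrics,
                 localization = localization, split = split, config = config),
            class = "run_report")
}
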