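#' Simulate one surface dissolution imaging experiment
#'
#' Integrates the tablet erosion/gel kinetics of one formulation in one
#' medium and renders a paired-wavelength image record at every sampling
#' time. Sampling is terminated after full disintegration: the first record
#' whose release reaches 100% is kept and later schedule points are dropped.
#' Placebo formulations are imaged but carry no release label (`q = NA`).
#'
#' @param formulation Formulation row (see [default_formulations()]).
#' @param pH Medium pH (1.2 or 6.8 for the compendial media).
#' @param sample_times Sorted sampling times (min) within \[0, 240\].
#' @param seed Integer seed controlling the rendering noise.
#' @param noise_sd Absorbance noise standard deviation.
#' @param geom A [render_geometry()].
#' @param initial Initial [tablet_state()].
#' @param rate_ceiling Ceiling passed to [effective_release_rate()].
#' @param kinetic_cv Coefficient of variation of a seeded lognormal
#'   batch-to-batch kinetic multiplier (tablet hardness/porosity variation).
#'   0 (the default here) makes noise-free runs identical across seeds;
#'   [simulate_dataset()] uses 0.1 so that imaging carries information about
#'   an experiment beyond its composition and time point, as it does on a
#'   real instrument.
#' @return A list of class `sdi_experiment`: `records` (list of
#'   `image_record`s with 8-bit RGB `frame_280`/`frame_520`, `time_min`,
#'   `q_percent`, `formulation_id`, `ph`), `truth` (saliency masks),
#'   `profile` (tibble `time_min`, `q_percent`) and the experiment metadata.
#' @export
simulate_experiment <- function(formulation, pH, sample_times = default_schedule(),
                                seed = 1L, noise_sd = 0.02,
                                geom = render_geometry(),
                                initial = tablet_state(),
                                rate_ceiling = 50, kinetic_cv = 0) {
  if (length(sample_times) == 0) rlang::abort("`sample_times` must be non-empty.")
  if (is.unsorted(sample_times) || any(sample_times < 0 | sample_times > 240)) {
    rlang::abort("`sample_times` must be sorted within [0, 240].")
  }
  seed <- as.numeric(seed)  # double arithmetic: derived seeds cannot overflow
  mult <- effective_release_rate(formulation, pH, ceiling = rate_ceiling)
  # volumetric capacity -> linear front recession: cube-root coupling keeps
  # fast media observable over several sampling points
  front_mult <- mult^(1 / 3)
  if (kinetic_cv > 0) {
    front_mult <- front_mult *
      withr::with_seed(seed + 7L, exp(stats::rnorm(1, 0, kinetic_cv)))
  }
  has_api <- !identical(formulation$api, "none")

  states <- vector("list", length(sample_times))
  st <- initial
  for (i in seq_along(sample_times)) {
    st <- step_tablet(st, formulation, sample_times[i] - st$time, front_mult)
    states[[i]] <- st
  }
  q <- vapply(states, function(s) s$q_percent, numeric(1))
  # truncate after full disintegration (keep the first saturated point)
  keep <- seq_along(q)
  full <- which(q >= 100 - 1e-9)
  if (length(full) > 0) keep <- seq_len(full[1])

  records <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    s <- states[[i]]
    # instantaneous release rate from a small backward difference
    dt <- 0.5
    rate <- if (s$time <= 0 || s$q_percent >= 100) 0 else {
      prev <- step_tablet(initial, formulation, max(0, s$time - dt), front_mult)
      max(0, (s$q_percent - prev$q_percent) / dt)
    }
    f280 <- render_frame(s, formulation, 280, noise_sd,
                         seed = seed + 1000L * i, release_rate = rate,
                         geom = geom)
    f520 <- render_frame(s, formulation, 520, noise_sd,
                         seed = seed + 1000L * i + 500L, release_rate = rate,
                         geom = geom)
    records[[k]] <- structure(
      list(frame_280 = render_jet(f280), frame_520 = render_jet(f520),
           time_min = s$time,
           q_percent = if (has_api) s$q_percent else NA_real_,
           formulation_id = formulation$formulation_id, ph = pH),
      class = "image_record")
  }
  structure(
    list(records = records,
         truth = saliency_ground_truth(initial, geom),
         profile = tibble::tibble(
           time_min = sample_times[keep],
           q_percent = if (has_api) q[keep] else NA_real_),
         formulation_id = formulation$formulation_id,
         api = formulation$api, excipient = formulation$excipient,
         ph = pH, rate_mult = mult),
    class = "sdi_experiment")
}

#' Simulate the full study design
#'
#' Runs [simulate_experiment()] for every formulation in the registry under
#' every medium, reproducing the study layout of 8 formulations (6 API
#' bearing + 2 placebo) x 2 compendial pH values with the standard sampling
#' schedule.
#'
#' @param formulations Formulation registry tibble.
#' @param ph_values Media pH values.
#' @param sample_times Sampling schedule (min).
#' @param seed Integer seed (noise streams are derived per experiment).
#' @param noise_sd Absorbance noise standard deviation.
#' @param kinetic_cv Batch-to-batch kinetic variability (lognormal CV) drawn
#'   once per experiment; default 0.1 (see [simulate_experiment()]).
#' @param geom A [render_geometry()].
#' @return A list of class `sdi_dataset`: `experiments` (list of
#'   `sdi_experiment`), and `manifest`, a tibble with one row per record
#'   (`formulation_id`, `api`, `excipient`, `ph`, `time_min`, `q_percent`,
#'   `experiment`, `record`).
#' @export
simulate_dataset <- function(formulations = default_formulations(),
                             ph_values = c(1.2, 6.8),
                             sample_times = default_schedule(),
                             seed = 1L, noise_sd = 0.02, kinetic_cv = 0.1,
                             geom = render_geometry()) {
  seed <- as.numeric(seed)
  grid <- expand.grid(f = seq_len(nrow(formulations)), ph = ph_values)
  experiments <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (e in seq_len(nrow(grid))) {
    fr <- formulations[grid$f[e], ]
    exp <- simulate_experiment(fr, grid$ph[e], sample_times,
                               seed = seed + 100000 * e,
                               noise_sd = noise_sd, geom = geom,
                               kinetic_cv = kinetic_cv)
    experiments[[e]] <- exp
    rows[[e]] <- tibble::tibble(
      formulation_id = fr$formulation_id, api = fr$api,
      excipient = fr$excipient, ph = grid$ph[e],
      time_min = exp$profile$time_min, q_percent = exp$profile$q_percent,
      experiment = e, record = seq_along(exp$records))
  }
  structure(list(experiments = experiments,
                 manifest = dplyr::bind_rows(rows)),
            class = "sdi_dataset")
}

#' Write a simulated dataset to disk
#'
#' Produces the on-disk layout consumed by the dataset stage: one directory
#' per experiment with `frames/{t}_{280|520}.png` 8-bit RGB images,
#' `profile.csv`, mask PNGs (`mask_edge.png`, `mask_core.png`,
#' `mask_holder.png`), and a joining `manifest.csv` at the root.
#'
#' @param dataset An `sdi_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble augmented with frame paths.
#' @export
write_sdi_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(dataset$experiments))
  for (e in seq_along(dataset$experiments)) {
    exp <- dataset$experiments[[e]]
    ed <- file.path(dir, sprintf("%s_pH%s", exp$formulation_id, exp$ph))
    dir.create(file.path(ed, "frames"), recursive = TRUE, showWarnings = FALSE)
    p280 <- character(length(exp$records))
    p520 <- character(length(exp$records))
    for (k in seq_along(exp$records)) {
      rec <- exp$records[[k]]
      p280[k] <- file.path(ed, "frames", sprintf("%g_280.png", rec$time_min))
      p520[k] <- file.path(ed, "frames", sprintf("%g_520.png", rec$time_min))
      png::writePNG(rec$frame_280 / 255, p280[k])
      png::writePNG(rec$frame_520 / 255, p520[k])
    }
    utils::write.csv(exp$profile, file.path(ed, "profile.csv"),
                     row.names = FALSE)
    for (m in names(exp$truth)) {
      png::writePNG(exp$truth[[m]] * 1, file.path(ed, sprintf("mask_%s.png", m)))
    }
    rows[[e]] <- tibble::tibble(
      formulation_id = exp$formulation_id, api = exp$api,
      excipient = exp$excipient, ph = exp$ph,
      time_min = exp$profile$time_min, q_percent = exp$profile$q_percent,
      path_280 = p280, path_520 = p520)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
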