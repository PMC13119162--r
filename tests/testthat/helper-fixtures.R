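# Shared fixtures: tiny geometries and datasets keep the unit tests fast.

tiny_geom <- function() render_geometry(grid_px = 96, pixel_mm = 0.16)

get_formulation <- function(id) {
  f <- default_formulations()
  f[f$formulation_id == id, ]
}

# A reduced study design: 2 API formulations x 2 pH, small render grid.
tiny_sdi <- function(seed = 1, noise_sd = 0.02,
                     ids = c("asa_lactose", "asa_mc"),
                     sample_times = c(0, 15, 30, 60, 120, 240)) {
  f <- default_formulations()
  simulate_dataset(f[f$formulation_id %in% ids, ],
                   ph_values = c(1.2, 6.8), sample_times = sample_times,
                   seed = seed, noise_sd = noise_sd, geom = tiny_geom())
}

tiny_dataset <- function(seed = 1, size = 32, ...) {
  build_dataset(tiny_sdi(seed = seed, ...), size = size)
}

# Minimal q_dataset wrapper around a single raw image, for saliency tests.
single_image_dataset <- function(img) {
  structure(list(
    x280 = array(img, c(dim(img), 1)),
    x520 = array(img, c(dim(img), 1)),
    time_norm = 0.5, cond = matrix(1, 1, 6), q = 50,
    meta = tibble::tibble(record_id = "toy", ph = 1.2, time_min = 120,
                          formulation_id = "toy", experiment = 1, record = 1),
    size = dim(img)[1]), class = "q_dataset")
}

holder_px <- function(geom) {
  saliency_ground_truth(tablet_state(), geom)$holder
}

# Independent streaming (Welford-style) R^2 / RMSE for cross-checking
# evaluate(): single pass, no vector arithmetic shared with the package.
streaming_metrics <- function(obs, pred) {
  n <- 0; mean_o <- 0; m2_o <- 0; ss_res <- 0
  for (i in seq_along(obs)) {
    n <- n + 1
    delta <- obs[i] - mean_o
    mean_o <- mean_o + delta / n
    m2_o <- m2_o + delta * (obs[i] - mean_o)
    ss_res <- ss_res + (obs[i] - pred[i])^2
  }
  list(r_squared = 1 - ss_res / m2_o, rmse = sqrt(ss_res / n))
}
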