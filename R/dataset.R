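#' Fit a Beer-Lambert calibration line
#'
#' Ordinary least-squares fit of absorbance against concentration for an
#' API's UV calibration series (typically six standards spanning
#' 2.0-40.0 ug/mL).
#'
#' @param concentrations Standard concentrations (ug/mL), at least two
#'   distinct values.
#' @param absorbances Measured absorbances (same length).
#' @return A one-row tibble: `slope` (absorbance per ug/mL), `intercept`,
#'   `r_squared`, `range_lo`, `range_hi`.
#' @export
#' @examples
#' fit_calibration(c(2, 5, 10, 20, 30, 40), 0.05 * c(2, 5, 10, 20, 30, 40))
fit_calibration <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances)) {
    rlang::abort("Concentration and absorbance vectors must match in length.")
  }
  if (length(unique(concentrations)) < 2) {
    rlang::abort("At least two distinct concentrations are required.")
  }
  fit <- stats::lm(absorbances ~ concentrations)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(fit$residuals^2) / ss_tot
  tibble::tibble(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2,
    range_lo = min(concentrations), range_hi = max(concentrations))
}

#' Cumulative dissolved percentage with sampling-volume correction
#'
#' During the dissolution run a fixed sample volume is withdrawn at each
#' time point and replaced with fresh medium, so drug mass leaves the vessel
#' with every sample. The cumulative dissolved mass at sample `n` is
#' \eqn{C_n V + V_s \sum_{i<n} C_i}, expressed as percent of dose.
#'
#' @param sample_concentrations Measured concentrations (mg/mL) at the
#'   successive sampling times.
#' @param medium_volume Vessel volume `V` (mL), default 900.
#' @param sample_volume Withdrawn volume `Vs` (mL), default 5.
#' @param dose Dose (mg), default 100.
#' @return Cumulative percent dissolved at each sampling time.
#' @export
#' @examples
#' corrected_cumulative_q(c(0.05, 0.05), 900, 5, 100)  # 45.00, 45.25
corrected_cumulative_q <- function(sample_concentrations, medium_volume = 900,
                                   sample_volume = 5, dose = 100) {
  if (any(sample_concentrations < 0)) {
    rlang::abort("Concentrations must be non-negative.")
  }
  if (medium_volume <= sample_volume || sample_volume < 0 || dose <= 0) {
    rlang::abort("Require medium_volume > sample_volume >= 0 and dose > 0.")
  }
  n <- length(sample_concentrations)
  removed <- c(0, cumsum(sample_concentrations))[seq_len(n)]
  100 * (sample_concentrations * medium_volume + sample_volume * removed) / dose
}

#' Uniform time-matrix tensor
#'
#' Spatially constant tensor encoding the normalized dissolution time, kept
#' image-shaped so it can enter a convolutional branch alongside the frames.
#'
#' @param time_min Time point (min) in \[0, `t_max`\].
#' @param t_max Experiment duration (min), default 240.
#' @param size Spatial side length (default 224).
#' @return A `size` x `size` x 1 array, every element `time_min / t_max`.
#' @export
build_time_matrix <- function(time_min, t_max = 240, size = 224) {
  if (!is.finite(time_min) || time_min < 0 || time_min > t_max) {
    rlang::abort("`time_min` must lie in [0, t_max].")
  }
  array(time_min / t_max, c(size, size, 1))
}

#' Preprocess an imaging frame for the network
#'
#' Bilinear resize to the model resolution and scaling of 8-bit channel
#' values to \[0, 1\].
#'
#' @param image H x W x 3 RGB array with values in \[0, 255\].
#' @param size Target side length (default 224).
#' @return A `size` x `size` x 3 array in \[0, 1\].
#' @export
preprocess_frame <- function(image, size = 224) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    rlang::abort("`image` must be an H x W x 3 RGB array.")
  }
  if (!all(dim(image)[1:2] == size)) {
    img <- EBImage::Image(image / 255, colormode = "Color")
    out <- EBImage::imageData(
      EBImage::resize(img, w = size, h = size, filter = "bilinear"))
    array(pmin(1, pmax(0, out)), c(size, size, 3))
  } else {
    image / 255
  }
}

#' Seeded train/test split
#'
#' Deterministic record-level split. The test partition takes
#' `ceil(test_fraction * n)` indices of a seeded permutation, so 153 records
#' at an 80:20 ratio yield exactly 122 training and 31 test records.
#'
#' @param n_records Number of records (>= 2).
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `dataset_split`: `train`, `test` (index vectors),
#'   `seed`, `test_fraction`.
#' @export
#' @examples
#' s <- make_split(153, 0.2, 1234)
#' lengths(s[c("train", "test")])  # 122, 31
make_split <- function(n_records, test_fraction = 0.2, seed = 1234L) {
  if (n_records < 2) rlang::abort("Need at least two records.")
  if (test_fraction <= 0 || test_fraction >= 1) {
    rlang::abort("`test_fraction` must be in (0, 1).")
  }
  n_test <- ceiling(test_fraction * n_records)
  perm <- withr::with_seed(seed, sample.int(n_records))
  structure(list(train = sort(perm[-seq_len(n_test)]),
                 test = sort(perm[seq_len(n_test)]),
                 seed = seed, test_fraction = test_fraction),
            class = "dataset_split")
}

#' One-hot condition encoding
#'
#' Canonical binary encoding of the formulation composition and optionally
#' the medium: API flags in the fixed order (ASA, sodium salicylate,
#' salicylamide), excipient flags (lactose, methylcellulose), and a medium
#' flag (1 for pH 6.8). Placebo formulations encode with all API flags zero.
#'
#' @param formulation_id Identifier present in `registry`.
#' @param pH Medium pH.
#' @param include_ph Append the medium flag (default `TRUE`).
#' @param registry Formulation registry tibble.
#' @return Named numeric vector of length 5 (+1 with the medium flag).
#' @export
#' @examples
#' encode_condition("asa_lactose", 1.2)
encode_condition <- function(formulation_id, pH, include_ph = TRUE,
                             registry = default_formulations()) {
  row <- registry[registry$formulation_id == formulation_id, ]
  if (nrow(row) != 1) {
    rlang::abort(sprintf("Unknown formulation '%s'.", formulation_id))
  }
  api_levels <- c("asa", "nasal", "sam")
  exc_levels <- c("lactose", "methylcellulose")
  v <- c(as.numeric(api_levels == row$api),
         as.numeric(exc_levels == row$excipient))
  names(v) <- c("api_asa", "api_nasal", "api_sam", "exc_lactose", "exc_mc")
  if (include_ph) v <- c(v, ph_68 = as.numeric(isTRUE(all.equal(pH, 6.8))))
  v
}

#' Assemble a supervised dataset from simulated experiments
#'
#' Converts an `sdi_dataset` into the tensors consumed by the models:
#' preprocessed image arrays for both wavelengths, normalized times, one-hot
#' condition vectors and release labels. Placebo records carry no label and
#' are excluded.
#'
#' @param sdi An `sdi_dataset` from [simulate_dataset()].
#' @param size Model image resolution (e.g. 64 or 224).
#' @param include_ph Include the medium flag in the condition vector.
#' @param t_max Normalizing experiment duration (min).
#' @return A list of class `q_dataset`: `x280`, `x520`
#'   (`size x size x 3 x n` arrays), `time_norm` (length-n vector), `cond`
#'   (n x k matrix), `q` (length-n labels), `meta` (tibble), `size`.
#' @export
build_dataset <- function(sdi, size = 64, include_ph = TRUE, t_max = 240) {
  sup <- which(!is.na(sdi$manifest$q_percent))
  n <- length(sup)
  if (n == 0) rlang::abort("No supervised (API-bearing) records found.")
  x280 <- array(0, c(size, size, 3, n))
  x520 <- array(0, c(size, size, 3, n))
  cond <- NULL
  for (j in seq_len(n)) {
    m <- sdi$manifest[sup[j], ]
    rec <- sdi$experiments[[m$experiment]]$records[[m$record]]
    x280[, , , j] <- preprocess_frame(rec$frame_280, size)
    x520[, , , j] <- preprocess_frame(rec$frame_520, size)
    cv <- encode_condition(m$formulation_id, m$ph, include_ph)
    if (is.null(cond)) cond <- matrix(0, n, length(cv),
                                      dimnames = list(NULL, names(cv)))
    cond[j, ] <- cv
  }
  meta <- sdi$manifest[sup, ]
  meta$record_id <- sprintf("%s_pH%s_t%g", meta$formulation_id, meta$ph,
                            meta$time_min)
  structure(list(x280 = x280, x520 = x520,
                 time_norm = meta$time_min / t_max,
                 cond = cond, q = meta$q_percent, meta = meta, size = size),
            class = "q_dataset")
}

#' @export
print.q_dataset <- function(x, ...) {
  cat(sprintf("<q_dataset> %d records, %dx%d frames, %d condition flags\n",
              length(x$q), x$size, x$size, ncol(x$cond)))
  invisible(x)
}
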