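#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Coefficient of determination and RMSE
#'
#' `r_squared = 1 - SS_res / SS_tot` on the observed values and root mean
#' squared error in the units of the response (Q%). When all observations
#' are identical the coefficient of determination is undefined and reported
#' as `NA`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A list with `r_squared` and `rmse`.
#' @export
eval_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0) {
    rlang::abort("`observed` and `predicted` must be non-empty and equal length.")
  }
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  list(r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
       rmse = sqrt(mean((observed - predicted)^2)))
}

#' Evaluate a trained model
#'
#' Computes the coefficient of determination and RMSE of the release
#' prediction on a set of records, with per-medium stratification when
#' several pH groups are present.
#'
#' @param model A trained `qnet`.
#' @param dataset A `q_dataset`.
#' @param indices Record indices to evaluate (e.g. a test partition);
#'   default all.
#' @return An `eval_report`: `r_squared`, `rmse`, `per_ph` (tibble `ph`,
#'   `r_squared`, `rmse`, `n`), `n_test`, `predictions` (tibble `record_id`,
#'   `ph`, `time_min`, `observed`, `predicted`, `residual`).
#' @export
evaluate_model <- function(model, dataset, indices = NULL) {
  idx <- indices %||% seq_along(dataset$q)
  if (length(idx) == 0) rlang::abort("No records to evaluate.")
  pred <- predict(model, dataset, idx)
  obs <- dataset$q[idx]
  overall <- eval_metrics(obs, pred)
  meta <- dataset$meta[idx, ]
  per_ph <- dplyr::group_by(
    tibble::tibble(ph = meta$ph, observed = obs, predicted = pred), .data$ph)
  per_ph <- dplyr::summarise(
    per_ph,
    r_squared = eval_metrics(.data$observed, .data$predicted)$r_squared,
    rmse = eval_metrics(.data$observed, .data$predicted)$rmse,
    n = dplyr::n(), .groups = "drop")
  structure(
    list(r_squared = overall$r_squared, rmse = overall$rmse,
         per_ph = per_ph, n_test = length(idx),
         variant = model$variant,
         predictions = tibble::tibble(
           record_id = meta$record_id, ph = meta$ph,
           time_min = meta$time_min, observed = obs, predicted = pred,
           residual = pred - obs)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: R^2 = %.3f, RMSE = %.2f%% (n = %d)\n",
              x$variant, x$r_squared, x$rmse, x$n_test))
  if (nrow(x$per_ph) > 1) print(x$per_ph)
  invisible(x)
}

#' @rdname evaluate_model
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(variant = x$variant, r_squared = x$r_squared,
                 rmse = x$rmse, n_test = x$n_test)
}

#' @rdname evaluate_model
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(stratum = "overall", r_squared = x$r_squared,
                   rmse = x$rmse, n = x$n_test),
    dplyr::mutate(x$per_ph, stratum = paste0("pH ", .data$ph),
                  .keep = "unused", .before = 1))
}

#' Reconstruct a dissolution profile from per-record predictions
#'
#' Aggregates the model's predictions over the sampled time points of one
#' experiment into a predicted dissolution profile, ordered by time.
#'
#' @param model A trained `qnet`.
#' @param dataset A `q_dataset`.
#' @param formulation_id,ph Experiment selector; alternatively pass
#'   `indices` directly (they must all belong to one experiment).
#' @param indices Optional record indices.
#' @return A tibble of class `dissolution_profile` with `time_min`,
#'   `q_observed`, `q_predicted`.
#' @export
reconstruct_profile <- function(model, dataset, formulation_id = NULL,
                                ph = NULL, indices = NULL) {
  meta <- dataset$meta
  if (is.null(indices)) {
    if (is.null(formulation_id) || is.null(ph)) {
      rlang::abort("Give `formulation_id` and `ph`, or `indices`.")
    }
    indices <- which(meta$formulation_id == formulation_id & meta$ph == ph)
  }
  if (length(indices) == 0) rlang::abort("No records selected.")
  sel <- meta[indices, ]
  if (dplyr::n_distinct(sel$formulation_id) > 1 ||
      dplyr::n_distinct(sel$ph) > 1) {
    rlang::abort("Records from mixed experiments; select one formulation/pH.")
  }
  ord <- order(sel$time_min)
  pred <- predict(model, dataset, indices)
  out <- tibble::tibble(
    formulation_id = sel$formulation_id[ord][1], ph = sel$ph[ord][1],
    time_min = sel$time_min[ord],
    q_observed = dataset$q[indices][ord], q_predicted = pred[ord])
  class(out) <- c("dissolution_profile", class(out))
  out
}
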