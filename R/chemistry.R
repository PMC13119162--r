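#' Registry of model active pharmaceutical ingredients
#'
#' Physicochemical constants for the three salicylate-derivative model drugs:
#' acetylsalicylic acid (ASA), sodium salicylate and salicylamide. Solubilities
#' are equilibrium values in the two compendial media (0.1 N HCl, pH 1.2;
#' phosphate buffer, pH 6.8). Each tablet carries a 100 mg dose of API.
#'
#' Sodium salicylate is stored with the pKa of the parent salicylic acid
#' (2.97), the value consistent with its ionized fractions of about 1.7% at
#' pH 1.2 and 99.98% at pH 6.8.
#'
#' @return A tibble with one row per API: `api` (identifier), `name`, `pKa`,
#'   `is_acid`, `sol_ph12`, `sol_ph68` (mg/mL), `dose_mg`.
#' @export
#' @examples
#' api_specs()
api_specs <- function() {
  tibble::tibble(
    api      = c("asa", "nasal", "sam"),
    name     = c("acetylsalicylic acid", "sodium salicylate", "salicylamide"),
    pKa      = c(3.5, 2.97, 8.2),
    is_acid  = c(TRUE, TRUE, TRUE),
    sol_ph12 = c(3.89, 0.735, 2.06),
    sol_ph68 = c(4.20, 812.1, 2.14),
    dose_mg  = c(100, 100, 100)
  )
}

#' Henderson-Hasselbalch ionized fraction
#'
#' Fraction of a weak acid or base in the ionized form at a given pH.
#' For an acid the fraction is \eqn{1/(1+10^{pKa-pH})}; for a base
#' \eqn{1/(1+10^{pH-pKa})}.
#'
#' @param pKa Dissociation constant (dimensionless, finite).
#' @param pH Medium pH (finite).
#' @param is_acid `TRUE` for an acid (default), `FALSE` for a base.
#' @return Ionized fraction in \[0, 1\], vectorized over `pKa`/`pH`.
#' @export
#' @examples
#' ionized_fraction(2.97, 1.2)  # ~0.017 at gastric pH
#' ionized_fraction(2.97, 6.8)  # ~0.9998 at intestinal pH
ionized_fraction <- function(pKa, pH, is_acid = TRUE) {
  if (!all(is.finite(pKa)) || !all(is.finite(pH))) {
    rlang::abort("`pKa` and `pH` must be finite numbers.")
  }
  if (any(pKa <= 0 | pKa >= 14)) {
    rlang::abort("`pKa` must lie in (0, 14).")
  }
  expo <- if (isTRUE(is_acid)) pKa - pH else pH - pKa
  1 / (1 + 10^expo)
}

#' Solubility-driven release-rate multiplier
#'
#' Ratio of an API's tabulated solubility at the medium pH to its solubility
#' at pH 1.2, clipped to a ceiling. The multiplier scales the base
#' erosion/diffusion kinetics of a formulation; it equals 1 at pH 1.2 by
#' construction. For pH values without a tabulated solubility, log-linear
#' interpolation between the two compendial media can be enabled.
#'
#' The uncapped ratio for sodium salicylate at pH 6.8 is 812.1/0.735, an
#' approximately 1105-fold increase; the default ceiling of 50 keeps the
#' simulated experiment observable over several sampling points.
#'
#' @param formulation A formulation row/list with an `api` field (see
#'   [default_formulations()]), or an API identifier string.
#' @param pH Medium pH.
#' @param ceiling Maximum multiplier (default 50); use `Inf` for the raw ratio.
#' @param interpolate Allow log-linear interpolation for pH values other than
#'   1.2 and 6.8 (default `FALSE`).
#' @return Dimensionless rate multiplier (scalar).
#' @export
#' @examples
#' effective_release_rate("sam", 6.8)                  # ~1.04
#' effective_release_rate("nasal", 6.8, ceiling = Inf) # ~1105
effective_release_rate <- function(formulation, pH, ceiling = 50,
                                   interpolate = FALSE) {
  api_id <- if (is.character(formulation)) formulation else formulation$api
  specs <- api_specs()
  if (is.na(api_id) || !api_id %in% specs$api) {
    if (identical(api_id, "none") || is.na(api_id)) return(1)
    rlang::abort(sprintf("Unknown API '%s'.", api_id))
  }
  row <- specs[specs$api == api_id, ]
  if (!is.finite(pH) || pH <= 0 || pH >= 14) {
    rlang::abort("`pH` must lie in (0, 14).")
  }
  sol <- if (isTRUE(all.equal(pH, 1.2))) {
    row$sol_ph12
  } else if (isTRUE(all.equal(pH, 6.8))) {
    row$sol_ph68
  } else if (interpolate) {
    # log-linear between the two compendial media
    w <- (pH - 1.2) / (6.8 - 1.2)
    10^((1 - w) * log10(row$sol_ph12) + w * log10(row$sol_ph68))
  } else {
    rlang::abort(sprintf(
      "No tabulated solubility at pH %.2f; set `interpolate = TRUE`.", pH))
  }
  min(sol / row$sol_ph12, ceiling)
}
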