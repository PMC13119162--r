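#' Construct a tablet state
#'
#' Snapshot of a dissolving flat-faced cylindrical tablet. The default
#' geometry corresponds to a 10 mm flat-faced punch (radius 5 mm) with a
#' compact height of 3.2 mm.
#'
#' @param time Elapsed time (min).
#' @param radius Current radius (mm).
#' @param height Current height (mm).
#' @param gel_thickness Hydrated gel-layer thickness (mm).
#' @param q_percent Dissolved fraction of the dose (%).
#' @param radius_init,height_init Initial geometry (mm); retained so that the
#'   dissolved fraction and the erosion-depth closed form can be evaluated
#'   from the state alone.
#' @return A list of class `tablet_state`.
#' @export
tablet_state <- function(time = 0, radius = 5, height = 3.2,
                         gel_thickness = 0, q_percent = 0,
                         radius_init = radius, height_init = height) {
  if (radius < 0 || height < 0 || gel_thickness < 0) {
    rlang::abort("Geometry fields must be non-negative.")
  }
  if (radius > radius_init + 1e-12) {
    rlang::abort("`radius` cannot exceed `radius_init`.")
  }
  structure(
    list(time = time, radius = radius, height = height,
         gel_thickness = gel_thickness, q_percent = q_percent,
         radius_init = radius_init, height_init = height_init),
    class = "tablet_state"
  )
}

# Closed-form eroded front depth (mm) at time t for a formulation, with the
# rate multiplier applied as a time-scale factor. Exact in t, so stepping is
# independent of the step partitioning for every kinetic family.
erosion_depth <- function(formulation, t, rate_mult = 1) {
  te <- rate_mult * t
  if (is.finite(formulation$erosion_dmax) &&
      !is.na(formulation$erosion_tau)) {
    formulation$erosion_dmax *
      (1 - exp(-(te / formulation$erosion_tau)^formulation$release_exponent))
  } else {
    formulation$erosion_rate * te^formulation$release_exponent
  }
}

gel_thickness_at <- function(formulation, t) {
  if (formulation$gel_growth_rate <= 0) return(0)
  formulation$gel_max *
    (1 - exp(-t * formulation$gel_growth_rate / formulation$gel_max))
}

#' Dissolved fraction from tablet geometry
#'
#' Ground-truth release label: the volume fraction of the initial compact
#' that has eroded, `100 * (1 - r^2 h / (r0^2 h0))`, clipped to \[0, 100\].
#'
#' @param state Current [tablet_state()].
#' @param initial Initial [tablet_state()]; defaults to the initial geometry
#'   stored in `state`.
#' @return Percent dissolved in \[0, 100\].
#' @export
q_from_geometry <- function(state, initial = NULL) {
  r0 <- if (is.null(initial)) state$radius_init else initial$radius
  h0 <- if (is.null(initial)) state$height_init else initial$height
  if (r0 <= 0 || h0 <= 0) rlang::abort("Initial radius and height must be > 0.")
  q <- 100 * (1 - (state$radius^2 * state$height) / (r0^2 * h0))
  min(100, max(0, q))
}

#' Advance a tablet state in time
#'
#' Steps the erosion/gel mechanism by `dt` minutes. Lactose formulations
#' shrink in radius and (both faces) in height as the erosion front advances;
#' methylcellulose formulations grow a gel annulus while eroding slowly with
#' a saturating front. The front position is integrated exactly from its
#' closed form, so any partitioning of an interval yields the same state.
#' A fully dissolved tablet (radius or height exhausted) is an absorbing
#' state with `q_percent = 100`.
#'
#' @param state A [tablet_state()].
#' @param formulation A formulation row (see [default_formulations()]).
#' @param dt Time step (min), `>= 0`.
#' @param rate_mult Dimensionless kinetic multiplier applied as a time-scale
#'   factor (1 at reference conditions).
#' @return The advanced `tablet_state`.
#' @export
step_tablet <- function(state, formulation, dt, rate_mult = 1) {
  if (dt < 0) rlang::abort("`dt` must be non-negative.")
  if (dt == 0) return(state)
  if (state$radius <= 0 || state$height <= 0) {
    state$time <- state$time + dt
    state$radius <- 0
    state$height <- 0
    state$gel_thickness <- 0
    state$q_percent <- 100
    return(state)
  }
  t2 <- state$time + dt
  d <- erosion_depth(formulation, t2, rate_mult)
  r <- max(0, state$radius_init - d)
  h <- max(0, state$height_init - 2 * d)
  if (r <= 0 || h <= 0) {
    r <- 0
    h <- 0
  }
  out <- tablet_state(
    time = t2, radius = r, height = h,
    gel_thickness = if (r > 0) gel_thickness_at(formulation, t2) else 0,
    radius_init = state$radius_init, height_init = state$height_init
  )
  out$q_percent <- q_from_geometry(out)
  out
}

#' @export
print.tablet_state <- function(x, ...) {
  cat(sprintf(
    "<tablet_state> t = %.1f min, r = %.3f mm, h = %.3f mm, gel = %.3f mm, Q = %.1f%%\n",
    x$time, x$radius, x$height, x$gel_thickness, x$q_percent))
  invisible(x)
}
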