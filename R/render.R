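#' Rendering geometry of the simulated flow cell
#'
#' The native render grid is 256 x 256 pixels at 0.06 mm/pixel (field of view
#' 15.36 mm), so a 10 mm tablet spans about 167 pixels and a 5 mm scale bar
#' about 83 pixels. The tablet is viewed face-on at the grid centre; a static
#' stainless-steel holder bracket flanks it.
#'
#' @param grid_px Grid side length in pixels.
#' @param pixel_mm Pixel size (mm/pixel).
#' @return A list with the grid size, pixel size and per-pixel coordinate
#'   matrices `x`, `y` (mm, origin at the tablet centre) and `r` (radial
#'   distance, mm).
#' @export
render_geometry <- function(grid_px = 256, pixel_mm = 0.06) {
  ctr <- (grid_px + 1) / 2
  xs <- (seq_len(grid_px) - ctr) * pixel_mm
  x <- matrix(xs, grid_px, grid_px, byrow = TRUE)  # column -> x (mm)
  y <- matrix(xs, grid_px, grid_px)                # row    -> y (mm)
  list(grid_px = grid_px, pixel_mm = pixel_mm,
       x = x, y = y, r = sqrt(x^2 + y^2))
}

holder_mask <- function(geom, r0 = 5) {
  inner <- r0 + 0.9
  outer <- r0 + 1.4
  side <- (abs(geom$x) >= inner & abs(geom$x) <= outer & abs(geom$y) <= 4)
  base <- (geom$y >= inner & geom$y <= outer & abs(geom$x) <= 4)
  side | base
}

#' Ground-truth saliency masks for a tablet experiment
#'
#' Binary region masks defined on the initial tablet geometry: an `edge`
#' annulus straddling the tablet boundary (the API release front), the
#' interior `core` disk, and the static `holder` bracket. The masks are
#' pairwise disjoint and edge plus core cover the tablet footprint.
#'
#' @param initial Initial [tablet_state()] (only the radius is used).
#' @param geom A [render_geometry()].
#' @param edge_inner Inner edge-annulus bound as a fraction of the initial
#'   radius (default 0.78).
#' @param edge_outer Outer bound as a fraction of the radius (default 1.06).
#' @return A list of class `saliency_truth` with logical matrices `edge`,
#'   `core`, `holder`.
#' @export
saliency_ground_truth <- function(initial, geom = render_geometry(),
                                  edge_inner = 0.78, edge_outer = 1.06) {
  r0 <- initial$radius_init
  holder <- holder_mask(geom, r0)
  edge <- geom$r >= edge_inner * r0 & geom$r <= edge_outer * r0 & !holder
  core <- geom$r < edge_inner * r0 & !holder
  structure(list(edge = edge, core = core, holder = holder),
            class = "saliency_truth")
}

#' Render a dual-wavelength absorbance field
#'
#' Synthesizes the spatially resolved absorbance map of a dissolving tablet
#' at one of the instrument's two wavelengths. The 280 nm (API absorption)
#' channel shows the API-loaded tablet silhouette plus a downstream
#' concentration plume on the flow-exposed side whose amplitude tracks the
#' instantaneous release rate; the 520 nm (structural) channel shows the
#' tablet bulk, the hydrated gel annulus at intermediate absorbance, and the
#' static holder bracket. Additive Gaussian noise is truncated at zero.
#'
#' @param state A [tablet_state()].
#' @param formulation Formulation row (determines API presence and gel).
#' @param wavelength 280 or 520 (nm).
#' @param noise_sd Standard deviation of additive absorbance noise (>= 0).
#' @param seed Optional integer; when given, rendering is bit-reproducible.
#' @param release_rate Instantaneous release rate dQ/dt (%/min), drives the
#'   plume amplitude at 280 nm.
#' @param geom A [render_geometry()].
#' @return An `absorbance_field`: list with `grid` (non-negative matrix),
#'   `pixel_size` (mm/pixel) and `wavelength`.
#' @export
render_frame <- function(state, formulation, wavelength = c(280, 520),
                         noise_sd = 0.02, seed = NULL, release_rate = 0,
                         geom = render_geometry()) {
  wavelength <- match.arg(as.character(wavelength[1]), c("280", "520"))
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  has_api <- !identical(formulation$api, "none")
  r_t <- state$radius
  gel <- state$gel_thickness
  field <- matrix(0, geom$grid_px, geom$grid_px)
  disk <- geom$r <= r_t
  ring <- geom$r > r_t & geom$r <= r_t + gel

  if (wavelength == "280") {
    if (r_t > 0) {
      field[disk] <- if (has_api) 0.55 else 0.08
      if (has_api) field[ring] <- 0.12
      # lateral concentration plume downstream of the flow-exposed edge
      if (has_api && release_rate > 0) {
        amp <- 0.9 * release_rate / (release_rate + 1.5)
        d <- geom$r - (r_t + gel)
        lobe <- pmax(0, geom$x) / pmax(geom$r, 1e-9)
        plume <- amp * exp(-pmax(d, 0) / 1.5) * lobe^2
        out <- d > 0
        field[out] <- field[out] + plume[out]
      }
    }
  } else {
    if (r_t > 0) {
      # bulk optical density falls as the matrix hydrates and pores open,
      # so the interior itself tracks the release state on the visible channel
      field[disk] <- 0.9 - 0.25 * state$q_percent / 100
      field[ring] <- 0.5
    }
  }
  hold <- holder_mask(geom, state$radius_init)
  field[hold] <- 0.85

  if (noise_sd > 0) {
    add_noise <- function() {
      field + matrix(stats::rnorm(length(field), 0, noise_sd),
                     nrow(field), ncol(field))
    }
    field <- if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
    field <- pmax(field, 0)
  }
  structure(list(grid = field, pixel_size = geom$pixel_mm,
                 wavelength = as.numeric(wavelength)),
            class = "absorbance_field")
}

#' Jet colormap lookup table
#'
#' Classic jet progression from dark blue (zero absorbance) through cyan,
#' green and yellow to dark red, as used for relative-absorbance
#' visualisation of the imaging frames.
#'
#' @param n Number of colours.
#' @return An `n` x 3 matrix of RGB values in \[0, 1\].
#' @export
jet_colormap <- function(n = 256) {
  u <- seq(0, 1, length.out = n)
  interp <- function(v) pmin(1, pmax(0, 1.5 - abs(4 * v)))
  cbind(r = interp(u - 0.75), g = interp(u - 0.5), b = interp(u - 0.25))
}

#' Render an absorbance field through the jet colormap
#'
#' Per-frame min-max normalization (the default) maps the frame minimum to
#' dark blue and the maximum to the warm end, matching relative-absorbance
#' visualisation; a fixed absolute range can be supplied for quantitative
#' rendering. A constant field renders uniformly dark blue.
#'
#' @param field An `absorbance_field` or a numeric matrix.
#' @param range Optional fixed `c(lo, hi)` absorbance range; `NULL` (default)
#'   normalizes per frame.
#' @return An H x W x 3 array of 8-bit RGB values in \[0, 255\].
#' @export
render_jet <- function(field, range = NULL) {
  g <- if (inherits(field, "absorbance_field")) field$grid else field
  if (!all(is.finite(g))) rlang::abort("Field values must be finite.")
  if (is.null(range)) range <- base::range(g)
  span <- range[2] - range[1]
  u <- if (span <= 0) matrix(0, nrow(g), ncol(g)) else
    pmin(1, pmax(0, (g - range[1]) / span))
  lut <- jet_colormap(256)
  idx <- pmin(256L, pmax(1L, as.integer(floor(u * 255)) + 1L))
  out <- array(0, c(nrow(g), ncol(g), 3))
  for (ch in 1:3) out[, , ch] <- matrix(lut[idx, ch], nrow(g), ncol(g))
  round(out * 255)
}
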