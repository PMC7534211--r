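#' Cylindrical capillary geometry
#'
#' Describes a cylindrical capillary tube used as a perfusion channel. The
#' reference device is a borosilicate glass capillary of 560 micrometre inner
#' diameter and 80 mm length, whose bore mimics the pore size of human
#' trabecular bone.
#'
#' @param inner_diameter Inner diameter in metres (> 0).
#' @param length Tube length in metres (> 0). Not used in the fully developed
#'   wall-shear formula; retained for device documentation and future
#'   entrance-length checks.
#' @return An object of class `tube_geometry`.
#' @export
#' @examples
#' tube_geometry(560e-6)
tube_geometry <- function(inner_diameter, length = 80e-3) {
  check_positive(inner_diameter, "inner_diameter")
  check_positive(length, "length")
  structure(list(inner_diameter = inner_diameter, length = length),
            class = "tube_geometry")
}

#' Parallel-plate flow chamber geometry
#'
#' Describes a rectangular parallel-plate flow chamber (PPFC). The reference
#' device has a 5 mm wide, 200 micrometre high, 50 mm long channel. The
#' plane-Poiseuille wall-shear formula assumes height much smaller than width;
#' a warning is issued when height/width > 0.2.
#'
#' @param width Channel width in metres.
#' @param height Channel height (plate separation) in metres; must be smaller
#'   than `width`.
#' @param length Channel length in metres.
#' @return An object of class `chamber_geometry`.
#' @export
#' @examples
#' chamber_geometry(5e-3, 200e-6)
chamber_geometry <- function(width, height, length = 50e-3) {
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(length, "length")
  if (height >= width) {
    stop("invalid geometry: `height` must be smaller than `width`", call. = FALSE)
  }
  if (height / width > 0.2) {
    warning("height/width > 0.2: plane-Poiseuille wall shear assumes a wide, ",
            "shallow channel; the computed stress may be inaccurate",
            call. = FALSE)
  }
  structure(list(width = width, height = height, length = length),
            class = "chamber_geometry")
}

#' Flow condition
#'
#' Volumetric flow rate and fluid properties for a perfusion run. Defaults
#' describe cell-culture medium at 37 degrees C (dynamic viscosity
#' 1.0 mPa s, density 1000 kg/m3); density is used only for the Reynolds
#' number regime check.
#'
#' @param flow_rate Volumetric flow rate in m3/s (>= 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @param density Mass density in kg/m3 (> 0).
#' @return An object of class `flow_condition`.
#' @export
#' @examples
#' flow_condition(ul_min_to_m3s(10))
flow_condition <- function(flow_rate, viscosity = 1.0e-3, density = 1000) {
  if (!is.numeric(flow_rate) || length(flow_rate) != 1 || is.na(flow_rate) ||
      flow_rate < 0) {
    stop("invalid flow condition: `flow_rate` must be a single number >= 0",
         call. = FALSE)
  }
  check_positive(viscosity, "viscosity")
  check_positive(density, "density")
  structure(list(flow_rate = flow_rate, viscosity = viscosity,
                 density = density),
            class = "flow_condition")
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("invalid geometry: `%s` must be a single number > 0", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Unit conversion helpers
#'
#' Convenience converters between the SI units used internally (m3/s, Pa)
#' and the bench units usual in perfusion work (microlitres per minute,
#' millipascal).
#'
#' @param q Flow rate in microlitres per minute (`ul_min_to_m3s`) or m3/s
#'   (`m3s_to_ul_min`).
#' @param tau Shear stress in Pa (`pa_to_mpa`) or mPa (`mpa_to_pa`).
#' @return The converted value.
#' @export
ul_min_to_m3s <- function(q) q * 1e-9 / 60

#' @rdname ul_min_to_m3s
#' @export
m3s_to_ul_min <- function(q) q * 60 / 1e-9

#' @rdname ul_min_to_m3s
#' @export
pa_to_mpa <- function(tau) tau * 1e3

#' @rdname ul_min_to_m3s
#' @export
mpa_to_pa <- function(tau) tau * 1e-3

# Laminar threshold for a pipe/channel Reynolds number.
RE_LAMINAR_THRESHOLD <- 2000

shear_result <- function(tau, reynolds) {
  structure(list(tau = tau, reynolds = reynolds,
                 laminar = reynolds < RE_LAMINAR_THRESHOLD),
            class = "shear_result")
}

#' @export
print.shear_result <- function(x, ...) {
  cat(sprintf("Wall shear stress: %.4g mPa\n", pa_to_mpa(x$tau)))
  cat(sprintf("Reynolds number:   %.4g (%s)\n", x$reynolds,
              if (x$laminar) "laminar" else "NOT laminar"))
  invisible(x)
}

#' Wall shear stress in a cylindrical capillary
#'
#' Hagen-Poiseuille wall shear for fully developed laminar flow in a
#' circular tube: tau = 32 Q mu / (pi d^3). The Reynolds number is computed
#' from the mean velocity 4Q/(pi d^2) and reported alongside, with a laminar
#' flag (Re < 2000); exceeding the threshold raises a warning, not an error.
#'
#' @param geom A [tube_geometry()].
#' @param flow A [flow_condition()].
#' @return A `shear_result` with fields `tau` (Pa), `reynolds`, `laminar`.
#' @export
#' @examples
#' # the reference operating point: ~10 mPa at 10 ul/min
#' fss_capillary(tube_geometry(560e-6), flow_condition(ul_min_to_m3s(10)))
fss_capillary <- function(geom, flow) {
  stopifnot(inherits(geom, "tube_geometry"), inherits(flow, "flow_condition"))
  d <- geom$inner_diameter
  tau <- 32 * flow$flow_rate * flow$viscosity / (pi * d^3)
  v_mean <- 4 * flow$flow_rate / (pi * d^2)
  re <- flow$density * v_mean * d / flow$viscosity
  if (re >= RE_LAMINAR_THRESHOLD) {
    warning(sprintf("Reynolds number %.3g exceeds the laminar threshold %d",
                    re, RE_LAMINAR_THRESHOLD), call. = FALSE)
  }
  shear_result(tau, re)
}

#' Wall shear stress in a parallel-plate flow chamber
#'
#' Plane-Poiseuille wall shear for a wide shallow rectangular channel:
#' tau = 6 Q mu / (w h^2). The Reynolds number uses the hydraulic diameter
#' 2wh/(w+h) and the mean velocity Q/(wh).
#'
#' @param geom A [chamber_geometry()].
#' @param flow A [flow_condition()].
#' @return A `shear_result` with fields `tau` (Pa), `reynolds`, `laminar`.
#' @export
#' @examples
#' # the reference operating point: exactly 10 mPa at 20 ul/min
#' fss_ppfc(chamber_geometry(5e-3, 200e-6), flow_condition(ul_min_to_m3s(20)))
fss_ppfc <- function(geom, flow) {
  stopifnot(inherits(geom, "chamber_geometry"), inherits(flow, "flow_condition"))
  w <- geom$width
  h <- geom$height
  tau <- 6 * flow$flow_rate * flow$viscosity / (w * h^2)
  v_mean <- flow$flow_rate / (w * h)
  d_h <- 2 * w * h / (w + h)
  re <- flow$density * v_mean * d_h / flow$viscosity
  if (re >= RE_LAMINAR_THRESHOLD) {
    warning(sprintf("Reynolds number %.3g exceeds the laminar threshold %d",
                    re, RE_LAMINAR_THRESHOLD), call. = FALSE)
  }
  shear_result(tau, re)
}

#' Wall shear stress for either geometry
#'
#' Dispatches to [fss_capillary()] or [fss_ppfc()] on the geometry class.
#'
#' @inheritParams fss_capillary
#' @return A `shear_result`.
#' @export
fss <- function(geom, flow) {
  if (inherits(geom, "tube_geometry")) return(fss_capillary(geom, flow))
  if (inherits(geom, "chamber_geometry")) return(fss_ppfc(geom, flow))
  stop("unsupported geometry kind: expected tube_geometry or chamber_geometry",
       call. = FALSE)
}

#' Flow rate required for a target wall shear stress
#'
#' Algebraic inverse of the wall-shear formulas: for a capillary,
#' Q = tau pi d^3 / (32 mu); for a parallel-plate chamber,
#' Q = tau w h^2 / (6 mu). The round trip `fss(geom, flow_rate_for_fss(...))`
#' recovers the target stress to machine precision.
#'
#' @param geom A [tube_geometry()] or [chamber_geometry()].
#' @param target_tau Target wall shear stress in Pa (>= 0).
#' @param viscosity Dynamic viscosity in Pa s.
#' @return Volumetric flow rate in m3/s.
#' @export
#' @examples
#' # flow rate for 10 mPa in the reference chamber: exactly 20 ul/min
#' m3s_to_ul_min(flow_rate_for_fss(chamber_geometry(5e-3, 200e-6), 10e-3))
flow_rate_for_fss <- function(geom, target_tau, viscosity = 1.0e-3) {
  if (!is.numeric(target_tau) || length(target_tau) != 1 || target_tau < 0) {
    stop("`target_tau` must be a single number >= 0", call. = FALSE)
  }
  check_positive(viscosity, "viscosity")
  if (inherits(geom, "tube_geometry")) {
    return(target_tau * pi * geom$inner_diameter^3 / (32 * viscosity))
  }
  if (inherits(geom, "chamber_geometry")) {
    return(target_tau * geom$width * geom$height^2 / (6 * viscosity))
  }
  stop("unsupported geometry kind: expected tube_geometry or chamber_geometry",
       call. = FALSE)
}

#' Design report for a perfusion device
#'
#' Tabulates the operating point of a device: wall shear stress, flow rate,
#' Reynolds number and laminar flag. Either the flow rate or the target
#' shear stress must be given; the other is computed.
#'
#' @param geom A [tube_geometry()] or [chamber_geometry()].
#' @param flow_rate Flow rate in m3/s, or `NULL` to solve from `target_tau`.
#' @param target_tau Target wall shear stress in Pa, or `NULL`.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param density Density in kg/m3.
#' @return A one-row data frame with columns `geometry`, `tau_mpa`,
#'   `flow_ul_min`, `reynolds`, `laminar`.
#' @export
design_report <- function(geom, flow_rate = NULL, target_tau = NULL,
                          viscosity = 1.0e-3, density = 1000) {
  if (is.null(flow_rate) == is.null(target_tau)) {
    stop("give exactly one of `flow_rate` and `target_tau`", call. = FALSE)
  }
  if (is.null(flow_rate)) {
    flow_rate <- flow_rate_for_fss(geom, target_tau, viscosity)
  }
  res <- fss(geom, flow_condition(flow_rate, viscosity, density))
  data.frame(
    geometry = if (inherits(geom, "tube_geometry")) "capillary" else "ppfc",
    tau_mpa = pa_to_mpa(res$tau),
    flow_ul_min = m3s_to_ul_min(flow_rate),
    reynolds = res$reynolds,
    laminar = res$laminar,
    stringsAsFactors = FALSE
  )
}
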