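#' Insole sensor geometry
#'
#' Signed moment arms of the three plantar force sensors about the ankle
#' joint, plus the Achilles tendon moment arm used to convert ankle moment
#' to tendon force. Anterior is positive, so the heel sensor arm is
#' negative. Each sensor force is assumed perpendicular to the sole and
#' applied at a fixed per-sensor center of pressure.
#'
#' The default sensor arms correspond to a nominal adult shoe size; they
#' scale linearly with `size_factor` (e.g. 1.1 for a foot ~10% longer).
#' The tendon moment arm default is 0.05 m and is deliberately not scaled
#' by shoe size (it is an anatomical, not a footwear, quantity).
#'
#' @param r_heel,r_mid,r_fore signed sensor moment arms about the ankle (m);
#'   must satisfy `r_fore > r_mid > r_heel`.
#' @param r_at Achilles tendon moment arm (m, > 0).
#' @param size_factor multiplicative scaling applied to the three sensor
#'   arms (not to `r_at`).
#' @return An object of class `sensor_geometry`.
#' @examples
#' geom <- sensor_geometry()
#' geom$r_fore
#' @export
sensor_geometry <- function(r_heel = -0.06, r_mid = 0.04, r_fore = 0.11,
                            r_at = 0.05, size_factor = 1) {
  vals <- c(r_heel = r_heel, r_mid = r_mid, r_fore = r_fore,
            r_at = r_at, size_factor = size_factor)
  if (!all(is.finite(vals)))
    stop("geometry values must be finite numbers", call. = FALSE)
  if (size_factor <= 0) stop("size_factor must be > 0", call. = FALSE)
  r_heel <- r_heel * size_factor
  r_mid <- r_mid * size_factor
  r_fore <- r_fore * size_factor
  if (r_at <= 0) stop("tendon moment arm r_at must be > 0", call. = FALSE)
  if (!(r_fore > r_mid && r_mid > r_heel))
    stop("sensor moment arms must satisfy r_fore > r_mid > r_heel",
         call. = FALSE)
  structure(list(r_heel = r_heel, r_mid = r_mid, r_fore = r_fore,
                 r_at = r_at),
            class = "sensor_geometry")
}

#' @export
print.sensor_geometry <- function(x, ...) {
  cat("<sensor_geometry>\n")
  cat(sprintf("  sensor arms (m): heel %+.3f, mid %+.3f, fore %+.3f\n",
              x$r_heel, x$r_mid, x$r_fore))
  cat(sprintf("  tendon moment arm r_at: %.3f m\n", x$r_at))
  invisible(x)
}

#' Body weight in newtons from body mass
#'
#' @param mass_kg body mass in kilograms (> 0).
#' @param g gravitational acceleration (m/s^2), default 9.81.
#' @return body weight in newtons.
#' @export
body_weight_n <- function(mass_kg, g = 9.81) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    stop("mass_kg must be positive and finite", call. = FALSE)
  mass_kg * g
}
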