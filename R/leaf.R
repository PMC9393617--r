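#' Sample a single grass leaf blade as a point cloud
#'
#' A leaf is modelled as a ruled surface over a curved midrib. The midrib is
#' an arc-length parameterised planar curve whose inclination falls linearly
#' from `elev_deg` at the base to `tip_angle_deg` at the tip (a circular
#' arc), so blades rise, arch over an apex and droop the way wheat leaves
#' do. The blade width follows a profile `w(t)` that tapers to zero at the
#' tip, and the width direction is horizontal, perpendicular to the midrib
#' plane. The single-sided surface area is the exact surface integral of
#' this parameterisation, evaluated by composite trapezoidal quadrature of
#' `L * w(t)` on a fine grid (for this ruled construction the integrand is
#' independent of the across-blade coordinate).
#'
#' Points are drawn uniformly with respect to surface area: the along-blade
#' coordinate is sampled from the width-weighted inverse CDF and the
#' across-blade coordinate uniformly.
#'
#' @param length_cm Midrib length (arc length) in cm.
#' @param max_width_cm Maximum blade width in cm; must be below `length_cm`.
#' @param base Length-3 attachment point.
#' @param yaw_deg Azimuth of the midrib plane, degrees.
#' @param elev_deg Inclination of the blade at its base, degrees above the
#'   horizontal.
#' @param tip_angle_deg Inclination at the tip; negative values droop.
#' @param profile Width profile: `"blade"` (`w = W * sqrt(4 t (1 - t))`,
#'   narrow at both attachment and tip), `"rectangle"` (constant width) or
#'   `"triangle"` (linear taper), or a function of `t` in `[0, 1]` returning
#'   relative width in `[0, 1]`.
#' @param density_per_cm2 Sampling density (points per cm^2 of blade area).
#' @param n_quad Quadrature / lookup grid size.
#' @return A list with `points` (N x 3 matrix), `area_cm2` (single-sided
#'   analytic area) and `apex_z` (maximum midrib height above `base`).
#' @export
#' @examples
#' leaf <- generate_leaf(20, 2, profile = "rectangle", elev_deg = 0,
#'                       tip_angle_deg = 0, density_per_cm2 = 50)
#' leaf$area_cm2  # 40: a flat 20 x 2 rectangle
generate_leaf <- function(length_cm, max_width_cm, base = c(0, 0, 0),
                          yaw_deg = 0, elev_deg = 60, tip_angle_deg = -20,
                          profile = "blade", density_per_cm2 = 500,
                          n_quad = 400) {
  if (length_cm <= 0 || max_width_cm <= 0) abort("leaf dimensions must be positive.")
  if (max_width_cm >= length_cm) abort("leaf width must be smaller than its length.")
  if (density_per_cm2 <= 0) abort("`density_per_cm2` must be positive.")
  wfun <- leaf_width_profile(profile)
  geom <- leaf_midrib(length_cm, base, yaw_deg, elev_deg, tip_angle_deg, n_quad)
  t <- geom$t
  w <- max_width_cm * wfun(t)
  # exact surface integral of the ruled surface: area = L * int w(t) dt
  area <- length_cm * trapz(t, w)
  n <- max(1L, as.integer(round(area * density_per_cm2)))
  # inverse-CDF sampling of t proportional to w(t)
  cdf <- cumsum(c(0, (w[-1] + w[-length(w)]) / 2 * diff(t)))
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(n)
  ti <- stats::approx(cdf, t, xout = u, ties = "ordered")$y
  v <- runif(n, -1, 1)
  mid <- midrib_at(geom, ti)
  wi <- max_width_cm * wfun(ti)
  pts <- mid + outer(v * wi / 2, geom$w_dir)
  list(points = pts, area_cm2 = area, apex_z = max(geom$m[, 3]) - base[3])
}

leaf_width_profile <- function(profile) {
  if (is.function(profile)) return(profile)
  switch(profile,
    blade = function(t) sqrt(pmax(4 * t * (1 - t), 0)),
    rectangle = function(t) rep(1, length(t)),
    triangle = function(t) 1 - t,
    abort(sprintf("unknown width profile '%s'", profile)))
}

## arc-length parameterised midrib: inclination falls linearly base -> tip
leaf_midrib <- function(L, base, yaw_deg, elev_deg, tip_angle_deg, n_quad) {
  t <- seq(0, 1, length.out = n_quad + 1)
  phi <- (elev_deg + (tip_angle_deg - elev_deg) * t) * pi / 180
  yaw <- yaw_deg * pi / 180
  u <- c(cos(yaw), sin(yaw), 0)          # horizontal direction of the midrib plane
  w_dir <- c(-sin(yaw), cos(yaw), 0)     # width direction, horizontal
  dh <- cos(phi); dz <- sin(phi)
  h <- cumtrapz(t, dh) * L
  zz <- cumtrapz(t, dz) * L
  m <- cbind(base[1] + h * u[1], base[2] + h * u[2], base[3] + zz)
  list(t = t, m = m, u = u, w_dir = w_dir)
}

midrib_at <- function(geom, ti) {
  cbind(stats::approx(geom$t, geom$m[, 1], xout = ti)$y,
        stats::approx(geom$t, geom$m[, 2], xout = ti)$y,
        stats::approx(geom$t, geom$m[, 3], xout = ti)$y)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

cumtrapz <- function(x, y) cumsum(c(0, (y[-1] + y[-length(y)]) / 2 * diff(x)))

## dense reference mesh of the same parametric surface; used as an
## independent oracle for the quadrature area in the tests
leaf_surface_points <- function(length_cm, max_width_cm, base = c(0, 0, 0),
                                yaw_deg = 0, elev_deg = 60, tip_angle_deg = -20,
                                profile = "blade", nt = 200, nv = 20) {
  wfun <- leaf_width_profile(profile)
  geom <- leaf_midrib(length_cm, base, yaw_deg, elev_deg, tip_angle_deg, nt)
  t <- geom$t
  w <- max_width_cm * wfun(t)
  v <- seq(-1, 1, length.out = nv + 1)
  grid <- expand.grid(i = seq_along(t), j = seq_along(v))
  P <- geom$m[grid$i, , drop = FALSE] + outer(v[grid$j] * w[grid$i] / 2, geom$w_dir)
  list(points = P, nt = length(t), nv = length(v))
}
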