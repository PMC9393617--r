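#' Convert RGB channels to HSL
#'
#' Standard hue/saturation/lightness conversion with hue in degrees in
#' `[0, 360)`. Lightness is `(max + min) / 2` of the channels exactly;
#' saturation uses the `max - min` chroma normalised by `max + min` below
#' lightness 0.5 and by `2 - max - min` above; on the gray axis
#' (`r = g = b`) both hue and saturation are 0. The hue branches divide the
#' chroma `max - min`; published variants that print `max + min` in the hue
#' denominator do not yield a usable red detector and are treated as a
#' typographical slip (see the methods vignette).
#'
#' @param r,g,b Numeric vectors of channels in `[0, 1]` (recycled to a
#'   common length), or `r` may be an N x 3 matrix.
#' @return A tibble with columns `h`, `s`, `l`.
#' @export
#' @examples
#' rgb_to_hsl(1, 0, 0)      # pure red: h = 0, s = 1, l = 0.5
#' rgb_to_hsl(1, 0, 0.2)    # h = 348
rgb_to_hsl <- function(r, g = NULL, b = NULL) {
  if (is.matrix(r) && is.null(g)) {
    g <- r[, 2]; b <- r[, 3]; r <- r[, 1]
  }
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n); g <- rep_len(as.numeric(g), n); b <- rep_len(as.numeric(b), n)
  if (n > 0 && (min(r, g, b) < -1e-12 || max(r, g, b) > 1 + 1e-12)) {
    abort("RGB channels must lie in [0, 1].")
  }
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  l <- (mx + mn) / 2
  s <- numeric(n)
  nz <- d > 0 & l > 0
  s[nz & l < 0.5] <- d[nz & l < 0.5] / (mx + mn)[nz & l < 0.5]
  s[nz & l >= 0.5] <- d[nz & l >= 0.5] / (2 - mx - mn)[nz & l >= 0.5]
  h <- numeric(n)
  is_r <- nz & mx == r
  is_g <- nz & !is_r & mx == g
  is_b <- nz & !is_r & !is_g
  h[is_r] <- 60 * (g[is_r] - b[is_r]) / d[is_r]
  h[is_g] <- 60 * (b[is_g] - r[is_g]) / d[is_g] + 120
  h[is_b] <- 60 * (r[is_b] - g[is_b]) / d[is_b] + 240
  h <- h %% 360
  tibble(h = h, s = s, l = l)
}

#' Convert HSL to RGB
#'
#' Inverse of [rgb_to_hsl()]; used by the synthetic scene generator to
#' assign colors directly in the space the plate gate is defined in.
#'
#' @param h Hue in degrees (any real; wrapped to `[0, 360)`), or an N x 3 matrix.
#' @param s,l Saturation and lightness in `[0, 1]`.
#' @return A tibble with columns `r`, `g`, `b` in `[0, 1]`.
#' @export
hsl_to_rgb <- function(h, s = NULL, l = NULL) {
  if (is.matrix(h) && is.null(s)) {
    s <- h[, 2]; l <- h[, 3]; h <- h[, 1]
  }
  n <- max(length(h), length(s), length(l))
  h <- rep_len(as.numeric(h), n) %% 360
  s <- rep_len(as.numeric(s), n); l <- rep_len(as.numeric(l), n)
  if (n > 0 && (min(s, l) < -1e-12 || max(s, l) > 1 + 1e-12)) {
    abort("`s` and `l` must lie in [0, 1].")
  }
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  hp <- floor(h / 60) %% 6
  r <- ifelse(hp == 0 | hp == 5, c_, ifelse(hp == 1 | hp == 4, x, 0))
  g <- ifelse(hp == 1 | hp == 2, c_, ifelse(hp == 0 | hp == 3, x, 0))
  b <- ifelse(hp == 3 | hp == 4, c_, ifelse(hp == 2 | hp == 5, x, 0))
  tibble(r = r + m, g = g + m, b = b + m)
}
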