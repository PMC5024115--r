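# Radiometric operations: Rayleigh-corrected reflectance, sunglint
# correction, the Turbidity Index, and true-colour composites.

#' Rayleigh-corrected reflectance
#'
#' R_rc = pi * Lt_star / (F0 * cos(theta0)) - Rr, element-wise, where
#' `Lt_star` is the at-sensor total radiance already adjusted for ozone and
#' gaseous absorption (W m^-2 um^-1 sr^-1), `F0` the extraterrestrial solar
#' irradiance (W m^-2 um^-1; any Earth-sun distance correction is the
#' caller's responsibility and should be folded into F0), `theta0` the solar
#' zenith angle in degrees, and `Rr` the Rayleigh reflectance
#' (dimensionless). The result is dimensionless and linear in `Lt_star`.
#'
#' @param Lt_star radiance scalar, vector or matrix.
#' @param F0 solar irradiance (> 0), scalar or conformable.
#' @param theta0 solar zenith angle in degrees, in `[0, 90)`.
#' @param Rr Rayleigh reflectance, scalar or conformable.
#' @return Rayleigh-corrected reflectance with the shape of `Lt_star`.
#' @examples
#' compute_rrc(10, 150, 30, 0.08)  # ~0.16184
#' @export
compute_rrc <- function(Lt_star, F0, theta0, Rr) {
  if (any(F0 <= 0)) stop("F0 must be > 0")
  if (any(theta0 < 0) || any(theta0 >= 90))
    stop("theta0 must be in [0, 90) degrees (sun above the horizon)")
  pi * Lt_star / (F0 * cos(theta0 * pi / 180)) - Rr
}

#' Glint-correction configuration
#'
#' @param trigger NIR reflectance threshold above which a pixel is treated as
#'   glint-contaminated (default 0.01).
#' @param c469,c645 scaling coefficients for the 469 and 645 nm bands
#'   (defaults 0.67 and 0.94).
#' @export
glint_config <- function(trigger = 0.01, c469 = 0.67, c645 = 0.94) {
  if (trigger <= 0) stop("glint trigger must be > 0")
  if (c469 <= 0 || c469 >= 2 || c645 <= 0 || c645 >= 2)
    stop("scaling coefficients must lie in (0, 2)")
  structure(list(trigger = trigger, C = c(rrc_469 = c469, rrc_645 = c645)),
            class = "glint_config")
}

#' Remove sunglint from the 469 and 645 nm bands
#'
#' For pixels whose 859-nm reflectance exceeds the trigger, the 469 and 645
#' bands are rescaled by subtracting the C-scaled NIR signal:
#' `R_rc(lambda) - C_lambda * R_rc(859)`. Other pixels, and the 859 band
#' itself, are never modified. The returned object carries a `deglinted`
#' attribute and further applications are no-ops, making the operation
#' exactly idempotent.
#'
#' Works on a `scene_observation` (band matrices) or a whole `scene_series`
#' (band arrays).
#'
#' @param scene a `scene_observation` or `scene_series` containing bands
#'   `rrc_469`, `rrc_645` and `rrc_859`.
#' @param cfg a [glint_config()].
#' @return the input with bands 469 and 645 corrected.
#' @export
correct_glint <- function(scene, cfg = glint_config()) {
  UseMethod("correct_glint")
}

#' @export
correct_glint.scene_observation <- function(scene, cfg = glint_config()) {
  if (is.null(scene$rrc_859)) stop("scene lacks the 859-nm band")
  if (isTRUE(attr(scene, "deglinted"))) return(scene)
  nir <- scene$rrc_859
  hit <- nir > cfg$trigger
  scene$rrc_469[hit] <- scene$rrc_469[hit] - cfg$C[["rrc_469"]] * nir[hit]
  scene$rrc_645[hit] <- scene$rrc_645[hit] - cfg$C[["rrc_645"]] * nir[hit]
  attr(scene, "deglinted") <- TRUE
  scene
}

#' @export
correct_glint.scene_series <- function(scene, cfg = glint_config()) {
  if (is.null(scene$bands$rrc_859)) stop("series lacks the 859-nm band")
  if (isTRUE(attr(scene, "deglinted"))) return(scene)
  nir <- scene$bands$rrc_859
  hit <- nir > cfg$trigger
  scene$bands$rrc_469[hit] <- scene$bands$rrc_469[hit] - cfg$C[["rrc_469"]] * nir[hit]
  scene$bands$rrc_645[hit] <- scene$bands$rrc_645[hit] - cfg$C[["rrc_645"]] * nir[hit]
  attr(scene, "deglinted") <- TRUE
  scene
}

#' Turbidity Index
#'
#' The band difference R_rc(469) - R_rc(645). Elevated over sediment plumes,
#' near zero over clear water, negative over submerged reef and strongly
#' negative over land. Invariant under any additive offset applied equally
#' to both bands. Cloud-masked pixels are set to `NA`.
#'
#' @param scene a `scene_observation` (uses its `cloud` mask if present), or
#'   a numeric matrix of 469-nm reflectance.
#' @param b645 469/645 matrices when `scene` is a matrix.
#' @param cloud optional logical cloud mask.
#' @return a numeric matrix of TI values with `NA` where cloudy.
#' @export
compute_ti <- function(scene, b645 = NULL, cloud = NULL) {
  if (inherits(scene, "scene_observation")) {
    ti <- scene$rrc_469 - scene$rrc_645
    if (is.null(cloud)) cloud <- scene$cloud
  } else {
    if (is.null(b645)) stop("supply the 645-nm band")
    ti <- scene - b645
  }
  if (!is.null(cloud)) ti[cloud] <- NA_real_
  ti
}

quantize255 <- function(v) {
  # round-half-away-from-zero on [0, 1] -> 0..255
  as.integer(floor(pmin(pmax(v, 0), 1) * 255 + 0.5))
}

upsample2 <- function(m, ny, nx) {
  up <- m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
  up[seq_len(ny), seq_len(nx), drop = FALSE]
}

block_mean2 <- function(m) {
  ny2 <- ceiling(nrow(m) / 2); nx2 <- ceiling(ncol(m) / 2)
  out <- matrix(0, ny2, nx2)
  cnt <- matrix(0L, ny2, nx2)
  ri <- (seq_len(nrow(m)) + 1L) %/% 2L
  ci <- (seq_len(ncol(m)) + 1L) %/% 2L
  for (i in seq_len(nrow(m))) {
    tab <- tapply(m[i, ], ci, sum)
    out[ri[i], ] <- out[ri[i], ] + tab
    cnt[ri[i], ] <- cnt[ri[i], ] + as.integer(table(ci))
  }
  out / cnt
}

#' True-colour RGB composite
#'
#' Channels are scaled linearly from 0 to the sensor maximum (0.15 for the
#' 250-m MODIS-like sensor, 0.5 for the 30-m OLI-like sensor), clipped to
#' `[0, 1]` and quantised to 0-255 with round-half-away-from-zero. If the
#' green and blue inputs are supplied at half the red band's resolution
#' (native 500-m bands), they are ratio-sharpened to full resolution: the red
#' band is degraded by 2x2 block means, and the upsampled coarse green/blue
#' are multiplied by the red / coarse-red ratio.
#'
#' @param red,green,blue reflectance matrices; green/blue may be half the
#'   red dimensions.
#' @param sensor `"modis"` (scale 0.15) or `"oli"` (scale 0.5).
#' @return an integer array `ny x nx x 3` with values 0-255 (R, G, B).
#' @export
compose_rgb <- function(red, green, blue, sensor = c("modis", "oli")) {
  sensor <- match.arg(sensor)
  smax <- if (sensor == "modis") 0.15 else 0.5
  ny <- nrow(red); nx <- ncol(red)
  sharpen <- function(ch) {
    if (nrow(ch) == ny && ncol(ch) == nx) return(ch)
    if (abs(nrow(ch) - ny / 2) > 1 || abs(ncol(ch) - nx / 2) > 1)
      stop("green/blue must match the red resolution or be its 2x down-sampling")
    rc <- block_mean2(red)
    ratio <- red / upsample2(rc, ny, nx)
    ratio[!is.finite(ratio)] <- 1
    upsample2(ch, ny, nx) * ratio
  }
  g <- sharpen(green); b <- sharpen(blue)
  out <- array(0L, c(ny, nx, 3L))
  out[, , 1L] <- quantize255(red / smax)
  out[, , 2L] <- quantize255(g / smax)
  out[, , 3L] <- quantize255(b / smax)
  out
}
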