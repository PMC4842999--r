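# Shape, size and intensity measurement: the Gaussian line-profile FWHM
# tool used for manual structure sizing, second-moment ellipse axes, and
# the 1NC / 2NC / 3+NC subtype classification.

#' Construct a line profile
#'
#' @param samples Ordered intensity samples along the line (>= 5).
#' @param spacing Physical distance between consecutive samples (nm).
#' @param endpoints Optional 2 x 2 matrix of line endpoints (nm).
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(samples, spacing, endpoints = NULL) {
  if (length(samples) < 5) stop("a line profile needs at least 5 samples")
  if (spacing <= 0) stop("spacing must be > 0")
  structure(list(samples = as.numeric(samples), spacing = spacing,
                 endpoints = endpoints),
            class = "line_profile")
}

#' FWHM of a line profile from a Gaussian fit
#'
#' Fits amplitude * exp(-(t - centre)^2 / (2 sigma^2)) + offset to the
#' profile by Levenberg-Marquardt least squares and reports
#' FWHM = 2 sqrt(2 ln 2) * sigma in nm. The measurement is flagged invalid
#' when the fit does not converge, explains less than half of the variance
#' (r^2 < 0.5), or the profile has no peak (e.g. constant).
#'
#' @param profile A [line_profile()], or a numeric vector combined with
#'   `spacing`.
#' @param spacing Sample spacing in nm when `profile` is a bare vector.
#' @return An object of class `fwhm_measure`: list with `fwhm`,
#'   `fit_centre`, `fit_amplitude`, `fit_offset`, `r_squared`, `valid`.
#' @export
fwhm_from_profile <- function(profile, spacing = NULL) {
  if (!inherits(profile, "line_profile")) {
    profile <- line_profile(profile, spacing)
  }
  y <- profile$samples
  t <- (seq_along(y) - 1) * profile$spacing
  invalid <- structure(list(fwhm = NA_real_, fit_centre = NA_real_,
                            fit_amplitude = NA_real_, fit_offset = NA_real_,
                            r_squared = NA_real_, valid = FALSE),
                       class = "fwhm_measure")
  if (max(y) - min(y) <= 0 || var(y) == 0) return(invalid)
  i0 <- which.max(y)
  amp0 <- max(y) - min(y)
  half <- min(y) + amp0 / 2
  above <- which(y >= half)
  sig0 <- max(diff(range(t[above])), profile$spacing) / 2.355
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(t - mu)^2 / (2 * s^2)) + c0,
      start = list(A = amp0, mu = t[i0], s = sig0, c0 = min(y)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(invalid)
  p <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  if (!is.finite(r2) || r2 < 0.5 || p[["A"]] <= 0 || p[["s"]] <= 0) {
    return(invalid)
  }
  structure(list(fwhm = sigma_to_fwhm(abs(p[["s"]])),
                 fit_centre = p[["mu"]], fit_amplitude = p[["A"]],
                 fit_offset = p[["c0"]], r_squared = r2, valid = TRUE),
            class = "fwhm_measure")
}

#' @export
print.fwhm_measure <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<fwhm_measure> FWHM %.1f nm (r^2 %.3f)\n", x$fwhm,
                x$r_squared))
  } else cat("<fwhm_measure> invalid\n")
  invisible(x)
}

#' Extract an image line profile
#'
#' Samples the image by bilinear interpolation along the segment from
#' `from` to `to` (nm), at `spacing` nm per sample (default half a pixel).
#'
#' @param image A [rendered_image()].
#' @param from,to Endpoints, length-2 numeric (nm).
#' @param spacing Sample spacing (nm); defaults to `pixel_size / 2`.
#' @return A [line_profile()] (samples falling outside the image are
#'   dropped from the ends).
#' @export
extract_profile <- function(image, from, to, spacing = NULL) {
  stopifnot(inherits(image, "rendered_image"))
  if (is.null(spacing)) spacing <- image$pixel_size / 2
  len <- sqrt(sum((to - from)^2))
  n <- max(5L, ceiling(len / spacing) + 1L)
  tt <- seq(0, len, length.out = n)
  dir <- (to - from) / len
  v <- interp_bilinear(image$data, from[1] + tt * dir[1],
                       from[2] + tt * dir[2], image$pixel_size)
  ok <- !is.na(v)
  line_profile(v[ok], spacing = if (n > 1) tt[2] - tt[1] else spacing,
               endpoints = rbind(from, to))
}

#' Manual-style diameter from two perpendicular FWHM profiles
#'
#' Mimics the manual sizing procedure: two perpendicular line profiles are
#' drawn through the estimated structure centre - along the long and short
#' axes when an elongation is detectable - each fitted with a Gaussian,
#' and the diameter reported as the mean of the two FWHM values. The axis
#' direction is the principal axis of the intensity second-moment matrix
#' in a window three times the expected structure size.
#'
#' @param image A [rendered_image()].
#' @param centre Estimated structure centre, length-2 (nm).
#' @param structure_size Expected structure scale (nm); sets the analysis
#'   window (3x) and profile length.
#' @return List with `diameter` (nm, NA when invalid), the two
#'   `fwhm_measure` results (`along`, `across`), the detected `angle`
#'   (radians), and `valid`.
#' @export
manual_diameter <- function(image, centre, structure_size = 300) {
  stopifnot(inherits(image, "rendered_image"))
  px <- image$pixel_size
  half <- 1.5 * structure_size
  m <- image$data
  r0 <- max(1L, floor((centre[2] - half) / px) + 1L)
  r1 <- min(nrow(m), ceiling((centre[2] + half) / px))
  c0 <- max(1L, floor((centre[1] - half) / px) + 1L)
  c1 <- min(ncol(m), ceiling((centre[1] + half) / px))
  win <- m[r0:r1, c0:c1, drop = FALSE]
  w <- pmax(win - min(win), 0)
  if (sum(w) == 0) {
    return(list(diameter = NA_real_, along = NULL, across = NULL,
                angle = NA_real_, valid = FALSE))
  }
  xs <- ((c0:c1) - 0.5) * px
  ys <- ((r0:r1) - 0.5) * px
  W <- sum(w)
  mx <- sum(colSums(w) * xs) / W
  my <- sum(rowSums(w) * ys) / W
  cxx <- sum(colSums(w) * (xs - mx)^2) / W
  cyy <- sum(rowSums(w) * (ys - my)^2) / W
  cxy <- sum(w * outer(ys - my, xs - mx)) / W
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy)   # principal axis angle
  len <- 1.5 * structure_size
  measure_dir <- function(a) {
    d <- c(cos(a), sin(a))
    fwhm_from_profile(extract_profile(image, centre - len * d,
                                      centre + len * d))
  }
  f1 <- measure_dir(ang)
  f2 <- measure_dir(ang + pi / 2)
  valid <- f1$valid && f2$valid
  list(diameter = if (valid) (f1$fwhm + f2$fwhm) / 2 else NA_real_,
       along = f1, across = f2, angle = ang, valid = valid)
}

#' Second-moment ellipse axes of an object mask
#'
#' Fits the mask to its second-moment (covariance) ellipse: a uniform
#' ellipse with semi-axis a has coordinate variance a^2/4, so full axes
#' are 4 sqrt(eigenvalue). The aspect ratio is short / long in (0, 1].
#' Degenerate (collinear) masks report the short axis floored at one
#' pixel.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_size Pixel edge in nm.
#' @return List with `long`, `short` (nm) and `aspect_ratio`.
#' @export
ellipse_axes <- function(mask, pixel_size = 20) {
  stopifnot(is.matrix(mask))
  lab <- array(0L, dim(mask))
  lab[mask > 0] <- 1L
  if (sum(lab) < 5) stop("ellipse_axes needs a mask of at least 5 pixels")
  obj <- measure_labels(lab, lab * 0, pixel_size)
  list(long = obj$long_axis, short = obj$short_axis,
       aspect_ratio = obj$aspect_ratio)
}

#' Classify a PSD by its nanocluster count
#'
#' @param nc_count Integer vector of NC counts (all >= 1).
#' @return Factor with levels `1NC`, `2NC`, `3+NC`.
#' @export
classify_subtype <- function(nc_count) {
  if (any(nc_count < 1)) stop("nc_count must be >= 1 (filter NC-less PSDs upstream)")
  factor(ifelse(nc_count == 1, "1NC", ifelse(nc_count == 2, "2NC", "3+NC")),
         levels = c("1NC", "2NC", "3+NC"))
}
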