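# Detection and splitting of fluorescent structures in pixel images: an
# open re-implementation of the commercial Imaris Cell procedure used for
# both g-STED and PALM-rendered channels. The chain is: Gaussian prefilter
# -> local background subtraction -> threshold -> 8-connected components ->
# seeded watershed splitting at a seed-point granularity -> pixel-count and
# border filters -> morphometry.

#' Segmentation parameters
#'
#' All lengths in nm. The two stock parameter sets of the g-STED workflow
#' are [sted_psd_params()] (confocal channel: background 140 nm, seed point
#' diameter 400 nm, minimum 30 pixels) and [sted_nc_params()] (g-STED
#' channel: prefilter 40 nm, background 140 nm, seed 160 nm, minimum 10
#' pixels).
#'
#' @param prefilter_sigma Gaussian prefilter sigma (nm); 0 disables.
#' @param background_diameter Scale (nm) of the local-background removal:
#'   a Gaussian low-pass with FWHM equal to this diameter is subtracted
#'   and negatives are clipped to zero.
#' @param threshold_fraction Foreground threshold as a fraction of the
#'   robust image maximum (the 99.9th intensity percentile) of the
#'   background-subtracted image. Ignored when `threshold_absolute` is
#'   given.
#' @param threshold_absolute Optional absolute foreground threshold.
#' @param seed_point_diameter Watershed seed-point diameter (nm): local
#'   maxima closer than this are merged to the brighter one, setting the
#'   granularity of object splitting.
#' @param min_pixels Fragments with fewer pixels are discarded.
#' @param exclude_border Drop objects touching the image boundary.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(prefilter_sigma = 0, background_diameter = 140,
                       threshold_fraction = 0.10, threshold_absolute = NULL,
                       seed_point_diameter = 160, min_pixels = 10,
                       exclude_border = TRUE) {
  if (background_diameter <= 0) stop("background_diameter must be > 0")
  if (seed_point_diameter <= 0) stop("seed_point_diameter must be > 0")
  if (min_pixels < 1) stop("min_pixels must be >= 1")
  if (prefilter_sigma < 0) stop("prefilter_sigma must be >= 0")
  structure(list(prefilter_sigma = prefilter_sigma,
                 background_diameter = background_diameter,
                 threshold_fraction = threshold_fraction,
                 threshold_absolute = threshold_absolute,
                 seed_point_diameter = seed_point_diameter,
                 min_pixels = min_pixels,
                 exclude_border = exclude_border),
            class = "seg_params")
}

#' @rdname seg_params
#' @export
sted_psd_params <- function() {
  seg_params(prefilter_sigma = 40, background_diameter = 140,
             seed_point_diameter = 400, min_pixels = 30)
}

#' @rdname seg_params
#' @export
sted_nc_params <- function() {
  seg_params(prefilter_sigma = 40, background_diameter = 140,
             seed_point_diameter = 160, min_pixels = 10)
}

#' Gaussian prefilter
#'
#' Smooths an image with an isotropic Gaussian of the stated physical
#' sigma (converted to pixels internally); sigma 0 returns the input
#' unchanged. Mass is preserved.
#'
#' @param image A [rendered_image()].
#' @param prefilter_sigma Sigma in nm.
#' @return A [rendered_image()].
#' @export
preprocess <- function(image, prefilter_sigma) {
  stopifnot(inherits(image, "rendered_image"))
  if (prefilter_sigma < 0) stop("prefilter_sigma must be >= 0")
  if (prefilter_sigma == 0) return(image)
  rendered_image(blur_matrix(image$data, prefilter_sigma, image$pixel_size),
                 image$pixel_size, image$channel)
}

#' Local background subtraction
#'
#' Estimates the local background as a Gaussian low-pass of the image with
#' FWHM equal to `background_diameter` (sigma = diameter / 2.355) and
#' subtracts it, clipping negative values to zero. A constant image maps
#' to all zeros; structure smaller than the diameter is retained.
#'
#' @param image A [rendered_image()].
#' @param background_diameter Background scale in nm (> 0).
#' @return A [rendered_image()].
#' @export
subtract_background <- function(image, background_diameter) {
  stopifnot(inherits(image, "rendered_image"))
  if (background_diameter <= 0) stop("background_diameter must be > 0")
  low <- blur_matrix(image$data, fwhm_to_sigma(background_diameter),
                     image$pixel_size)
  rendered_image(pmax(image$data - low, 0), image$pixel_size, image$channel)
}

#' Detect and split structures in a background-subtracted image
#'
#' Foreground pixels are those above the threshold rule; 8-connected
#' components are found, and each component is divided among watershed
#' seeds. Seeds are local maxima of the image smoothed at
#' `seed_point_diameter / 4`, greedily merged so that no two seeds within
#' a component are closer than the seed-point diameter (the brighter
#' maximum wins). Fragments smaller than `min_pixels` and, optionally,
#' objects touching the image border are removed.
#'
#' @param image Background-subtracted [rendered_image()] used for
#'   detection.
#' @param params A [seg_params()].
#' @param intensity_image Optional [rendered_image()] (same grid) on which
#'   the intensity statistics are measured; defaults to `image`. The
#'   workflows pass the raw channel here so that reported intensities are
#'   not distorted by background subtraction.
#' @return An object of class `segmentation`: list with `objects` (data
#'   frame of retained objects), `labels` (matrix of retained labels),
#'   `all_labels` (pre-filter watershed partition), `n_removed_small`,
#'   `n_removed_border`, `params`, `pixel_size`.
#' @export
detect_and_split <- function(image, params, intensity_image = NULL) {
  stopifnot(inherits(image, "rendered_image"), inherits(params, "seg_params"))
  if (is.null(intensity_image)) intensity_image <- image
  stopifnot(all(dim(image$data) == dim(intensity_image$data)))
  px <- image$pixel_size
  img <- image$data
  thr <- if (!is.null(params$threshold_absolute)) params$threshold_absolute
         else params$threshold_fraction * quantile(img, 0.999, names = FALSE)
  mask <- img > thr & img > 0
  empty <- list(objects = empty_objects(), labels = array(0L, dim(img)),
                all_labels = array(0L, dim(img)),
                n_removed_small = 0L, n_removed_border = 0L,
                params = params, pixel_size = px)
  class(empty) <- "segmentation"
  if (!any(mask)) return(empty)

  comp <- label_components(mask)
  smooth <- blur_matrix(img, params$seed_point_diameter / 4, px)
  seeds <- seed_points(smooth, comp, params$seed_point_diameter / px)
  frag <- EBImage::imageData(
    EBImage::propagate(smooth, seeds, mask = mask))
  dim(frag) <- dim(img)
  storage.mode(frag) <- "integer"

  objs <- measure_labels(frag, intensity_image$data, px)
  small <- objs$pixel_count < params$min_pixels
  border <- params$exclude_border & objs$touches_border
  keep <- !small & !border
  labels <- frag
  labels[!(frag %in% objs$label[keep])] <- 0L
  out <- list(objects = objs[keep, , drop = FALSE],
              labels = labels, all_labels = frag,
              n_removed_small = sum(small),
              n_removed_border = sum(border & !small),
              params = params, pixel_size = px)
  class(out) <- "segmentation"
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d objects (%d removed small, %d border)\n",
              nrow(x$objects), x$n_removed_small, x$n_removed_border))
  invisible(x)
}

empty_objects <- function() {
  data.frame(label = integer(), pixel_count = integer(), area = numeric(),
             equivalent_diameter = numeric(), centroid_x = numeric(),
             centroid_y = numeric(), long_axis = numeric(),
             short_axis = numeric(), aspect_ratio = numeric(),
             mean_intensity = numeric(), integrated_intensity = numeric(),
             touches_border = logical())
}

# Build the watershed seed image: 3x3 local maxima of the smoothed image
# within the foreground, greedily thinned per component so no two accepted
# seeds are closer than `min_dist_px` (brighter first; ties broken by
# linear index). Components left without any maximum get their brightest
# pixel as seed, so every component yields at least one object.
seed_points <- function(smooth, comp, min_dist_px) {
  cand <- local_maxima(smooth, comp > 0)
  seeds <- array(0L, dim(smooth))
  nseed <- 0L
  if (nrow(cand)) {
    vals <- smooth[cand]
    cid <- comp[cand]
    ord <- order(cid, -vals, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    cid <- cid[ord]
    for (g in split(seq_len(nrow(cand)), cid)) {
      acc_r <- numeric(0); acc_c <- numeric(0)
      for (i in g) {
        r <- cand[i, 1]; c <- cand[i, 2]
        if (length(acc_r)) {
          d2 <- (acc_r - r)^2 + (acc_c - c)^2
          if (any(d2 < min_dist_px^2)) next
        }
        acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
        nseed <- nseed + 1L
        seeds[r, c] <- nseed
      }
    }
  }
  # components with no seed: take the brightest pixel
  seeded <- unique(comp[seeds > 0])
  missing <- setdiff(setdiff(unique(as.vector(comp)), 0L), seeded)
  for (m in missing) {
    idx <- which(comp == m)
    best <- idx[which.max(smooth[idx])]
    nseed <- nseed + 1L
    seeds[best] <- nseed
  }
  seeds
}

# Morphometry of every label in a label matrix, measured against the given
# intensity image. Axes come from the second-moment (covariance) ellipse of
# the mask: a uniform ellipse with semi-axis a has coordinate variance
# a^2/4, so the full axis is 4*sqrt(eigenvalue). A pixel-footprint variance
# of px^2/12 is added per coordinate, and the short axis is floored at one
# pixel for degenerate (collinear) masks.
measure_labels <- function(labels, intensity, px) {
  idx <- which(labels > 0L)
  if (!length(idx)) return(empty_objects())
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  x <- (cols - 0.5) * px
  y <- (rows - 0.5) * px
  inten <- intensity[idx]
  f <- factor(lab)
  ulab <- as.integer(levels(f))
  n <- as.vector(tapply(rep(1, length(lab)), f, sum))
  sx <- as.vector(tapply(x, f, sum)); sy <- as.vector(tapply(y, f, sum))
  sxx <- as.vector(tapply(x * x, f, sum))
  syy <- as.vector(tapply(y * y, f, sum))
  sxy <- as.vector(tapply(x * y, f, sum))
  si <- as.vector(tapply(inten, f, sum))
  swx <- as.vector(tapply(x * inten, f, sum))
  swy <- as.vector(tapply(y * inten, f, sum))
  mx <- sx / n; my <- sy / n
  cxx_raw <- sxx / n - mx^2
  cyy_raw <- syy / n - my^2
  cxy <- sxy / n - mx * my
  # raw (uncorrected) minor eigenvalue flags collinear masks
  tr_raw <- cxx_raw + cyy_raw
  disc_raw <- pmax(tr_raw^2 / 4 - (cxx_raw * cyy_raw - cxy^2), 0)
  l2_raw <- pmax(tr_raw / 2 - sqrt(disc_raw), 0)
  # pixel-footprint variance correction for the reported axes
  cxx <- cxx_raw + px^2 / 12
  cyy <- cyy_raw + px^2 / 12
  tr <- cxx + cyy
  det_ <- cxx * cyy - cxy^2
  disc <- pmax(tr^2 / 4 - det_, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- pmax(tr / 2 - sqrt(disc), 0)
  long <- 4 * sqrt(l1)
  short <- 4 * sqrt(l2)
  # degenerate (collinear) masks: floor the short axis at one pixel and
  # report the long axis as the pixel extent along the principal axis
  degen <- 4 * sqrt(l2_raw) < px / 2
  if (any(degen)) {
    for (k in which(degen)) {
      sel <- lab == ulab[k]
      dx <- x[sel] - mx[k]; dy <- y[sel] - my[k]
      ang <- 0.5 * atan2(2 * cxy[k], cxx_raw[k] - cyy_raw[k])
      proj <- dx * cos(ang) + dy * sin(ang)
      long[k] <- diff(range(proj)) + px
    }
    short[degen] <- px
  }
  long <- pmax(long, short)
  touches <- as.vector(tapply(rows == 1L | rows == nr |
                                cols == 1L | cols == ncol(labels), f, any))
  area <- n * px^2
  data.frame(
    label = ulab, pixel_count = as.integer(n), area = area,
    equivalent_diameter = 2 * sqrt(area / pi),
    centroid_x = ifelse(si > 0, swx / si, mx),
    centroid_y = ifelse(si > 0, swy / si, my),
    long_axis = long, short_axis = short,
    aspect_ratio = short / long,
    mean_intensity = si / n, integrated_intensity = si,
    touches_border = touches)
}

#' Assign nanoclusters to parent PSDs
#'
#' Each NC is assigned to the PSD whose mask contains its centroid pixel;
#' NCs whose centroid falls outside any PSD mask fall back to greatest
#' mask overlap (ties to the larger overlap, then the lower PSD label).
#' PSDs with no assigned NC are excluded from the returned records and the
#' excluded fraction is reported; NCs assignable to no PSD are discarded
#' and counted.
#'
#' @param psd_seg,nc_seg [detect_and_split()] results for the PSD and NC
#'   channels of the same registered field.
#' @return An object of class `psd_records`: list with `psds` (one row per
#'   retained PSD: morphometry plus `nc_count` and `subtype`), `ncs` (one
#'   row per assigned NC with `psd_label`), `excluded_psd_fraction`,
#'   `n_psd_detected`, `n_discarded_nc`.
#' @export
assign_nc_to_psd <- function(psd_seg, nc_seg) {
  stopifnot(inherits(psd_seg, "segmentation"), inherits(nc_seg, "segmentation"))
  stopifnot(all(dim(psd_seg$labels) == dim(nc_seg$labels)))
  px <- psd_seg$pixel_size
  psds <- psd_seg$objects
  ncs <- nc_seg$objects
  n_psd <- nrow(psds)
  if (nrow(ncs)) {
    r <- pmin(pmax(ceiling(ncs$centroid_y / px), 1L), nrow(psd_seg$labels))
    c <- pmin(pmax(ceiling(ncs$centroid_x / px), 1L), ncol(psd_seg$labels))
    parent <- psd_seg$labels[cbind(r, c)]
    for (i in which(parent == 0L)) {
      nc_pix <- which(nc_seg$labels == ncs$label[i])
      over <- psd_seg$labels[nc_pix]
      over <- over[over > 0L]
      if (length(over)) {
        tab <- table(over)
        best <- as.integer(names(tab)[tab == max(tab)])
        parent[i] <- min(best)   # ties: larger overlap first, then lower label
      }
    }
    discarded <- sum(parent == 0L)
    ncs$psd_label <- parent
    ncs <- ncs[parent > 0L, , drop = FALSE]
  } else {
    discarded <- 0L
    ncs$psd_label <- integer(0)
  }
  counts <- table(factor(ncs$psd_label, levels = psds$label))
  psds$nc_count <- as.integer(counts)
  keep <- psds$nc_count >= 1L
  out <- list(
    psds = cbind(psds[keep, , drop = FALSE],
                 subtype = classify_subtype(psds$nc_count[keep])),
    ncs = ncs,
    excluded_psd_fraction = if (n_psd) sum(!keep) / n_psd else 0,
    n_psd_detected = n_psd,
    n_discarded_nc = discarded)
  class(out) <- "psd_records"
  out
}

#' @export
print.psd_records <- function(x, ...) {
  cat(sprintf(
    "<psd_records> %d PSDs (%.1f%% excluded NC-less), %d NCs (%d discarded)\n",
    nrow(x$psds), 100 * x$excluded_psd_fraction, nrow(x$ncs),
    x$n_discarded_nc))
  if (nrow(x$psds)) {
    print(round(100 * prop.table(table(x$psds$subtype)), 1))
  }
  invisible(x)
}

#' Run the g-STED segmentation workflow on a registered channel pair
#'
#' PSDs are segmented on the confocal channel (background 140 nm, seed
#' point diameter 400 nm, minimum 30 pixels) and NCs on the g-STED channel
#' (40 nm prefilter, background 140 nm, seed 160 nm, minimum 10 pixels),
#' then NCs are assigned to PSDs by mask containment. Intensity statistics
#' are measured on the raw channels.
#'
#' @param confocal,sted [rendered_image()] channels on the same pixel
#'   grid.
#' @param psd_params,nc_params [seg_params()] for the two stages.
#' @return A `psd_records` object (see [assign_nc_to_psd()]) with the two
#'   `segmentation` objects attached as attributes `psd_seg` / `nc_seg`.
#' @export
run_sted_workflow <- function(confocal, sted,
                              psd_params = sted_psd_params(),
                              nc_params = sted_nc_params()) {
  stopifnot(inherits(confocal, "rendered_image"),
            inherits(sted, "rendered_image"))
  if (!all(dim(confocal$data) == dim(sted$data)) ||
      confocal$pixel_size != sted$pixel_size) {
    stop("confocal and sted channels must share the same pixel grid")
  }
  psd_seg <- detect_and_split(
    subtract_background(preprocess(confocal, psd_params$prefilter_sigma),
                        psd_params$background_diameter),
    psd_params, intensity_image = confocal)
  nc_seg <- detect_and_split(
    subtract_background(preprocess(sted, nc_params$prefilter_sigma),
                        nc_params$background_diameter),
    nc_params, intensity_image = sted)
  rec <- assign_nc_to_psd(psd_seg, nc_seg)
  attr(rec, "psd_seg") <- psd_seg
  attr(rec, "nc_seg") <- nc_seg
  rec
}
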