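# Ground-truth synaptic scene simulator. Scenes are fields of PSDs, each
# composed of 1-4 elliptical PSD95 nanoclusters (NCs); scenes can be
# rendered as confocal/g-STED-like pixel images, PALM-like localisation
# tables, or two-channel juxtaposition fields. The simulator is first-class
# tested code: it defines the ground truth that the recovery tests and the
# robustness checks of the segmentation pipeline are scored against.

#' Simulation configuration
#'
#' Parameters of the synthetic-scene generator. Defaults reproduce the
#' structure reported for hippocampal CA1 stratum oriens synapses: a PSD
#' density of 19.2 per 20 um^2, a subtype mixture dominated by single-NC
#' PSDs, median NC short/long axes of 86 x 189 nm, within-PSD NC
#' separations of 100-300 nm, a confocal PSF of 240 nm FWHM, a g-STED PSF
#' of 85 nm FWHM, 20 nm pixels, and ~40 nm localisation precision.
#'
#' @param field_width,field_height Field extent in nm.
#' @param psd_density PSDs per 20 um^2 of field area.
#' @param subtype_mixture Probability vector over NC counts 1..4;
#'   normalised internally. The default splits the 3+NC class 3:1 between
#'   3-NC and 4-NC PSDs.
#' @param nc_axis_medians Named or ordered pair `(short, long)` of median NC
#'   axis lengths in nm (full axes, not semi-axes).
#' @param nc_axis_dispersion Log-scale standard deviation of the log-normal
#'   axis distribution (medians are preserved exactly).
#' @param spacing_interval `(min, max)` admissible pairwise NC-centre
#'   separation within a PSD, in nm.
#' @param psf_fwhm_confocal,psf_fwhm_sted PSF FWHM (nm) of the two pixel
#'   modalities.
#' @param pixel_size Pixel edge (nm) of rendered images.
#' @param localisation_precision PALM localisation precision, expressed as
#'   the FWHM-equivalent figure commonly quoted (~40 nm); the Gaussian
#'   error applied to each event has sigma = precision / 2.355.
#' @param localisations_per_nc Mean number of localisation events per NC;
#'   also used as the relative rendering brightness (molecule count) of an
#'   NC.
#' @param nc_brightness `"constant_count"` (default): every NC carries the
#'   same expected molecule count regardless of size;
#'   `"constant_density"`: the molecule count scales with the NC area
#'   (conserved molecular packing), so rendered interior intensity is the
#'   same for all NCs.
#' @param background_rate False localisations per um^2.
#' @param noise_model List with `poisson_gain` (expected photons per unit
#'   of rendered intensity; larger = less shot noise) and
#'   `gaussian_read_sigma` (additive read noise, intensity units). Pass
#'   `NULL` entries to disable either component.
#' @param nc_profile `"uniform"` (filled ellipse, default) or `"gaussian"`
#'   (elliptical Gaussian with sigma = semi-axis / 2).
#' @param n_frames Number of PALM acquisition frames events are spread over.
#' @param edge_margin Minimum distance (nm) of PSD centres from the field
#'   border, so that rendered structures are not truncated.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(field_width = 20000, field_height = 20000,
                       psd_density = 19.2,
                       subtype_mixture = c(0.637, 0.243, 0.090, 0.030),
                       nc_axis_medians = c(short = 86, long = 189),
                       nc_axis_dispersion = 0.25,
                       spacing_interval = c(100, 300),
                       psf_fwhm_confocal = 240, psf_fwhm_sted = 85,
                       pixel_size = 20,
                       localisation_precision = 40,
                       localisations_per_nc = 100,
                       background_rate = 1,
                       noise_model = list(poisson_gain = 200,
                                          gaussian_read_sigma = 0.01),
                       nc_profile = c("uniform", "gaussian"),
                       nc_brightness = c("constant_count", "constant_density"),
                       n_frames = 18000,
                       edge_margin = 600) {
  nc_profile <- match.arg(nc_profile)
  nc_brightness <- match.arg(nc_brightness)
  cfg <- list(
    field_width = field_width, field_height = field_height,
    psd_density = psd_density,
    subtype_mixture = subtype_mixture,
    nc_axis_medians = unname(nc_axis_medians),
    nc_axis_dispersion = nc_axis_dispersion,
    spacing_interval = spacing_interval,
    psf_fwhm_confocal = psf_fwhm_confocal, psf_fwhm_sted = psf_fwhm_sted,
    pixel_size = pixel_size,
    localisation_precision = localisation_precision,
    localisations_per_nc = localisations_per_nc,
    background_rate = background_rate,
    noise_model = noise_model,
    nc_profile = nc_profile,
    nc_brightness = nc_brightness,
    n_frames = n_frames,
    edge_margin = edge_margin
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks invariants (positive lengths, normalisable mixture, ordered
#' spacing interval) and normalises the subtype mixture to sum to one.
#'
#' @param cfg A `sim_config` list.
#' @return The validated (possibly normalised) configuration.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$nc_brightness)) cfg$nc_brightness <- "constant_count"
  if (is.null(cfg$nc_profile)) cfg$nc_profile <- "uniform"
  lens <- c(cfg$field_width, cfg$field_height, cfg$pixel_size,
            cfg$nc_axis_medians)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("field dimensions, pixel size and NC axis medians must all be > 0")
  }
  if (length(cfg$subtype_mixture) != 4L || any(cfg$subtype_mixture < 0) ||
      sum(cfg$subtype_mixture) <= 0) {
    stop("subtype_mixture must be 4 non-negative entries with positive sum")
  }
  cfg$subtype_mixture <- cfg$subtype_mixture / sum(cfg$subtype_mixture)
  if (length(cfg$spacing_interval) != 2L ||
      cfg$spacing_interval[1] >= cfg$spacing_interval[2]) {
    stop("spacing_interval must be (min, max) with min < max")
  }
  if (cfg$psd_density < 0 || cfg$localisation_precision < 0 ||
      cfg$localisations_per_nc <= 0 || cfg$background_rate < 0 ||
      cfg$nc_axis_dispersion < 0) {
    stop("rates, precision and dispersion must be non-negative")
  }
  cfg
}

#' Sample a ground-truth synaptic scene
#'
#' Draws a field of PSDs with a Poisson-distributed count at the configured
#' density. Each PSD draws its NC count from the subtype mixture; NC
#' centres of multi-NC PSDs are placed by rejection sampling so that every
#' pairwise separation lies inside the configured spacing interval
#' (100-300 nm by default). NC axes are log-normal around the configured
#' medians (short <= long enforced by sorting each drawn pair) and
#' orientations are uniform.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   scenes.
#' @param n_psd Optional fixed PSD count, overriding the Poisson draw
#'   (used by calibration tests).
#' @return An object of class `synthetic_scene`: a list with
#'   `field_width`, `field_height`, `psds` (each a `psd_truth` with a list
#'   of `nanoclusters`), and `rng_seed`.
#' @export
sample_scene <- function(config, seed, n_psd = NULL) {
  config <- validate_sim_config(config)
  with_seed(op_seed(seed, "scene"), {
    area_20um2 <- config$field_width * config$field_height / 20e6
    n <- if (is.null(n_psd)) rpois(1, config$psd_density * area_20um2)
         else as.integer(n_psd)
    m <- config$edge_margin
    if (2 * m >= min(config$field_width, config$field_height)) {
      stop("edge_margin too large for the field")
    }
    psds <- vector("list", n)
    if (n > 0) {
      counts <- sample.int(4L, n, replace = TRUE,
                           prob = config$subtype_mixture)
      cx <- runif(n, m, config$field_width - m)
      cy <- runif(n, m, config$field_height - m)
      for (i in seq_len(n)) {
        centres <- place_nc_centres(counts[i], c(cx[i], cy[i]),
                                    config$spacing_interval, psd_index = i)
        med_area <- pi / 4 * prod(config$nc_axis_medians)
        ncs <- lapply(seq_len(counts[i]), function(j) {
          ax <- sort(rlnorm(2,
                            meanlog = log(config$nc_axis_medians),
                            sdlog = config$nc_axis_dispersion))
          count <- config$localisations_per_nc
          if (config$nc_brightness == "constant_density") {
            count <- count * (pi / 4 * ax[1] * ax[2]) / med_area
          }
          list(centre = centres[j, ],
               long_axis = ax[2], short_axis = ax[1],
               orientation = runif(1, 0, pi),
               molecule_count = max(1L, as.integer(round(count))))
        })
        psds[[i]] <- structure(
          list(nanoclusters = ncs, subtype_truth = counts[i],
               centre = c(cx[i], cy[i])),
          class = "psd_truth")
      }
    }
    structure(
      list(field_width = config$field_width,
           field_height = config$field_height,
           psds = psds, rng_seed = as.integer(seed)),
      class = "synthetic_scene")
  })
}

# Place `k` NC centres around `centre` with all pairwise separations inside
# `interval`, by rejection sampling with a bounded retry budget. The first
# NC sits at the PSD centre; candidates for the rest are drawn uniformly in
# the disc of radius max-separation around the first NC.
place_nc_centres <- function(k, centre, interval, psd_index,
                             max_retries = 1e4) {
  pts <- matrix(centre, nrow = 1)
  if (k == 1L) return(pts)
  rmin <- interval[1]; rmax <- interval[2]
  for (j in 2:k) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      r <- rmax * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      cand <- pts[1, ] + r * c(cos(th), sin(th))
      d <- sqrt(colSums((t(pts) - cand)^2))
      if (all(d >= rmin & d <= rmax)) {
        pts <- rbind(pts, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "spacing interval [%g, %g] nm unsatisfiable for %d NCs (PSD %d)",
        rmin, rmax, k, psd_index))
    }
  }
  unname(pts)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  counts <- vapply(x$psds, function(p) p$subtype_truth, numeric(1))
  cat(sprintf("<synthetic_scene> %g x %g nm, %d PSDs, %d NCs (seed %d)\n",
              x$field_width, x$field_height, length(x$psds),
              sum(counts), x$rng_seed))
  invisible(x)
}

#' Ground-truth tables of a scene
#'
#' Flattens a scene into per-NC and per-PSD data frames, including the true
#' equivalent diameter of each NC ellipse, `sqrt(short * long)`.
#'
#' @param scene A `synthetic_scene`.
#' @return List with data frames `ncs` (psd_id, nc_id, x_nm, y_nm,
#'   short_axis, long_axis, orientation, molecule_count, equiv_diameter)
#'   and `psds` (psd_id, x_nm, y_nm, nc_count).
#' @export
scene_truth <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  rows <- list(); prow <- list(); id <- 0L
  for (i in seq_along(scene$psds)) {
    p <- scene$psds[[i]]
    prow[[i]] <- data.frame(psd_id = i, x_nm = p$centre[1],
                            y_nm = p$centre[2],
                            nc_count = p$subtype_truth)
    for (nc in p$nanoclusters) {
      id <- id + 1L
      rows[[id]] <- data.frame(
        psd_id = i, nc_id = id,
        x_nm = nc$centre[1], y_nm = nc$centre[2],
        short_axis = nc$short_axis, long_axis = nc$long_axis,
        orientation = nc$orientation,
        molecule_count = nc$molecule_count,
        equiv_diameter = sqrt(nc$short_axis * nc$long_axis))
    }
  }
  list(ncs = do.call(rbind, rows), psds = do.call(rbind, prow))
}

#' Render a scene as a pixel image
#'
#' Each NC is drawn as a filled ellipse (uniform intensity by default)
#' integrating to its `molecule_count`, sampled onto the pixel grid with
#' 4x4 supersampling per pixel, convolved with an isotropic Gaussian PSF of
#' the given FWHM, and finally degraded with shot and read noise if a noise
#' model is supplied. The PSF has unit mass, so the noiseless integrated
#' intensity equals the summed molecule counts.
#'
#' @param scene A `synthetic_scene`.
#' @param psf_fwhm PSF FWHM in nm; 0 renders without blur.
#' @param pixel_size Pixel edge in nm.
#' @param noise `NULL` for noiseless, or a list with `poisson_gain` and/or
#'   `gaussian_read_sigma` (see [sim_config()]).
#' @param seed Integer seed, required when `noise` is non-NULL.
#' @param nc_profile `"uniform"` or `"gaussian"` intensity profile.
#' @param channel Channel label stored on the image.
#' @param supersample Sub-samples per pixel edge for ellipse rasterisation.
#' @return A [rendered_image()].
#' @export
render_image <- function(scene, psf_fwhm, pixel_size = 20, noise = NULL,
                         seed = NULL, nc_profile = "uniform",
                         channel = "sted", supersample = 4L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  nx <- max(1L, round(scene$field_width / pixel_size))
  ny <- max(1L, round(scene$field_height / pixel_size))
  img <- matrix(0, nrow = ny, ncol = nx)
  S <- as.integer(supersample)
  off <- (seq_len(S) - 0.5) / S   # sub-pixel offsets in pixel units
  for (p in scene$psds) for (nc in p$nanoclusters) {
    img <- add_ellipse(img, nc, pixel_size, off, nc_profile)
  }
  if (psf_fwhm > 0) {
    img <- blur_matrix(img, fwhm_to_sigma(psf_fwhm), pixel_size)
  }
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is required when rendering with noise")
    img <- with_seed(op_seed(seed, "render_noise"), apply_noise(img, noise))
  }
  rendered_image(img, pixel_size, channel)
}

# Accumulate one NC ellipse into `img` by supersampled area coverage. The
# rasterised footprint is renormalised so each NC contributes exactly
# molecule_count to the integrated image (before any border clipping), so
# intensity is conserved and linear in molecule_count by construction.
add_ellipse <- function(img, nc, px, off, profile) {
  a <- nc$long_axis / 2; b <- nc$short_axis / 2
  pad <- if (profile == "uniform") max(a, b) + px else 3 * max(a, b) + px
  c0 <- floor((nc$centre[1] - pad) / px) + 1L
  c1 <- ceiling((nc$centre[1] + pad) / px)
  r0 <- floor((nc$centre[2] - pad) / px) + 1L
  r1 <- ceiling((nc$centre[2] + pad) / px)
  cols <- c0:c1; rows <- r0:r1
  # supersample coordinates (nm) relative to the NC centre
  xs <- as.vector(outer(off, cols - 1, "+")) * px - nc$centre[1]
  ys <- as.vector(outer(off, rows - 1, "+")) * px - nc$centre[2]
  co <- cos(nc$orientation); si <- sin(nc$orientation)
  U <- outer(ys * si, rep(1, length(xs))) + outer(rep(1, length(ys)), xs * co)
  V <- outer(ys * co, rep(1, length(xs))) - outer(rep(1, length(ys)), xs * si)
  S <- length(off)
  if (profile == "uniform") {
    dens <- (((U / a)^2 + (V / b)^2) <= 1) * 1
  } else {
    su <- a / 2; sv <- b / 2
    dens <- exp(-(U^2 / (2 * su^2) + V^2 / (2 * sv^2)))
  }
  # average the S x S sub-samples of each pixel
  dens <- matrix(dens, nrow = S * length(rows))
  block <- sapply(seq_along(cols), function(j) {
    sub <- dens[, ((j - 1) * S + 1):(j * S), drop = FALSE]
    colSums(matrix(rowSums(sub), nrow = S))
  })
  block <- matrix(block, nrow = length(rows))
  tot <- sum(block)
  if (tot <= 0) {
    # NC smaller than the supersampling grid: deposit at the nearest pixel
    rr <- min(max(floor(nc$centre[2] / px) + 1L, 1L), nrow(img))
    cc <- min(max(floor(nc$centre[1] / px) + 1L, 1L), ncol(img))
    img[rr, cc] <- img[rr, cc] + nc$molecule_count
    return(img)
  }
  block <- block * (nc$molecule_count / tot)
  # clip to the image and add
  rk <- rows >= 1L & rows <= nrow(img)
  ck <- cols >= 1L & cols <= ncol(img)
  img[rows[rk], cols[ck]] <- img[rows[rk], cols[ck]] +
    block[rk, ck, drop = FALSE]
  img
}

apply_noise <- function(img, noise) {
  if (!is.null(noise$poisson_gain) && noise$poisson_gain > 0) {
    img <- matrix(rpois(length(img), noise$poisson_gain * pmax(img, 0)),
                  nrow = nrow(img)) / noise$poisson_gain
  }
  if (!is.null(noise$gaussian_read_sigma) && noise$gaussian_read_sigma > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise$gaussian_read_sigma),
                        nrow = nrow(img))
  }
  pmax(img, 0)
}

#' Render the registered confocal / g-STED channel pair of a scene
#'
#' Convenience wrapper producing the two-channel field the g-STED workflow
#' consumes: the same ground truth rendered at confocal (240 nm FWHM) and
#' g-STED (85 nm FWHM) resolution, with the configured noise model.
#'
#' @param scene A `synthetic_scene`.
#' @param config A [sim_config()].
#' @param seed Integer seed for the noise draws.
#' @return List with elements `confocal` and `sted`, both [rendered_image()].
#' @export
render_field <- function(scene, config, seed) {
  config <- validate_sim_config(config)
  list(
    confocal = render_image(scene, config$psf_fwhm_confocal,
                            config$pixel_size, noise = config$noise_model,
                            seed = seed, nc_profile = config$nc_profile,
                            channel = "confocal"),
    sted = render_image(scene, config$psf_fwhm_sted, config$pixel_size,
                        noise = config$noise_model, seed = seed + 1L,
                        nc_profile = config$nc_profile, channel = "sted")
  )
}

#' Simulate a PALM localisation table from a scene
#'
#' Each NC emits a Poisson-distributed number of events (mean
#' `localisations_per_nc`); event positions are uniform points inside the
#' NC ellipse perturbed by isotropic Gaussian localisation error with
#' sigma = precision / 2.355. Uniform background events are added at
#' `background_rate` per um^2. Every signal event carries its true parent
#' NC and PSD id for recovery scoring (background events carry NA).
#'
#' @param scene A `synthetic_scene`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A data frame of class `localisation_table` with columns `x_nm`,
#'   `y_nm`, `frame`, `precision_nm`, `intensity`, `truth_nc_id`,
#'   `truth_psd_id`, and attributes `field_width` / `field_height`.
#' @export
simulate_palm <- function(scene, config, seed) {
  stopifnot(inherits(scene, "synthetic_scene"))
  config <- validate_sim_config(config)
  with_seed(op_seed(seed, "palm"), {
    sig <- fwhm_to_sigma(config$localisation_precision)
    rows <- list(); id <- 0L
    for (i in seq_along(scene$psds)) {
      for (nc in scene$psds[[i]]$nanoclusters) {
        id <- id + 1L
        n <- rpois(1, nc$molecule_count)
        if (n == 0) next
        r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
        u <- (nc$long_axis / 2) * r * cos(th)
        v <- (nc$short_axis / 2) * r * sin(th)
        co <- cos(nc$orientation); si <- sin(nc$orientation)
        x <- nc$centre[1] + u * co - v * si
        y <- nc$centre[2] + u * si + v * co
        if (sig > 0) {
          x <- x + rnorm(n, 0, sig)
          y <- y + rnorm(n, 0, sig)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          x_nm = x, y_nm = y, truth_nc_id = id, truth_psd_id = i)
      }
    }
    area_um2 <- scene$field_width * scene$field_height / 1e6
    nb <- rpois(1, config$background_rate * area_um2)
    if (nb > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        x_nm = runif(nb, 0, scene$field_width),
        y_nm = runif(nb, 0, scene$field_height),
        truth_nc_id = NA_integer_, truth_psd_id = NA_integer_)
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(x_nm = numeric(), y_nm = numeric(),
                 truth_nc_id = integer(), truth_psd_id = integer())
    n <- nrow(tab)
    eps <- 1e-9
    tab$x_nm <- pmin(pmax(tab$x_nm, 0), scene$field_width - eps)
    tab$y_nm <- pmin(pmax(tab$y_nm, 0), scene$field_height - eps)
    tab$frame <- if (n) sample.int(config$n_frames, n, replace = TRUE)
                 else integer()
    tab$precision_nm <- rep(config$localisation_precision, n)
    tab$intensity <- rep(1, n)
    tab <- tab[, c("x_nm", "y_nm", "frame", "precision_nm", "intensity",
                   "truth_nc_id", "truth_psd_id")]
    attr(tab, "field_width") <- scene$field_width
    attr(tab, "field_height") <- scene$field_height
    class(tab) <- c("localisation_table", "data.frame")
    tab
  })
}

#' Simulate a two-channel juxtaposition field
#'
#' Channel A contains the PSD puncta of the scene; channel B contains
#' presynaptic-like puncta: a `fraction_paired` subset of A centres gets a
#' B punctum at a drawn offset, and `round((1 - fraction_paired) * nA)`
#' unpaired B puncta are placed uniformly. Ground-truth pairing is
#' recorded. Both channels are rendered at confocal resolution.
#'
#' @param scene A `synthetic_scene`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param fraction_paired Fraction of A puncta given a true partner, in
#'   `[0, 1]`.
#' @param offset_mean,offset_sd Offset distance distribution (nm) of true
#'   partners; the offset direction is uniform.
#' @param render Render the two channels as images (default); `FALSE`
#'   returns the centres and pairing truth only, for centre-based
#'   analyses.
#' @return List with `image_a`, `image_b` ([rendered_image()]),
#'   `centres_a`, `centres_b` (n x 2 matrices, nm), and `paired` (logical
#'   per A punctum).
#' @export
simulate_two_channel <- function(scene, config, seed, fraction_paired = 1,
                                 offset_mean = 200, offset_sd = 0,
                                 render = TRUE) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (fraction_paired < 0 || fraction_paired > 1) {
    stop("fraction_paired must lie in [0, 1]")
  }
  config <- validate_sim_config(config)
  with_seed(op_seed(seed, "two_channel"), {
    a <- t(vapply(scene$psds, function(p) p$centre, numeric(2)))
    n <- nrow(a)
    paired <- runif(n) < fraction_paired
    bs <- list()
    if (any(paired)) {
      np <- sum(paired)
      d <- pmax(0, rnorm(np, offset_mean, offset_sd))
      th <- runif(np, 0, 2 * pi)
      bs[[1]] <- a[paired, , drop = FALSE] + cbind(d * cos(th), d * sin(th))
    }
    nu <- round((1 - fraction_paired) * n)
    if (nu > 0) {
      m <- config$edge_margin
      bs[[length(bs) + 1L]] <- cbind(
        runif(nu, m, scene$field_width - m),
        runif(nu, m, scene$field_height - m))
    }
    b <- if (length(bs)) do.call(rbind, bs) else matrix(numeric(), ncol = 2)
    fw <- config$psf_fwhm_confocal
    out <- list(image_a = NULL, image_b = NULL,
                centres_a = a, centres_b = b, paired = paired)
    if (render) {
      out$image_a <- render_image(scene, fw, config$pixel_size,
                                  noise = config$noise_model,
                                  seed = seed + 11L, channel = "psd")
      out$image_b <- render_points(b, scene$field_width, scene$field_height,
                                   fw, config$pixel_size,
                                   noise = config$noise_model,
                                   seed = seed + 12L,
                                   channel = "presynaptic")
    }
    out
  })
}

# Render a set of point emitters as unit-mass Gaussian spots.
render_points <- function(pts, field_width, field_height, psf_fwhm,
                          pixel_size, noise = NULL, seed = NULL,
                          channel = "points") {
  nx <- max(1L, round(field_width / pixel_size))
  ny <- max(1L, round(field_height / pixel_size))
  img <- matrix(0, ny, nx)
  if (nrow(pts)) {
    for (i in seq_len(nrow(pts))) {
      r <- pmin(pmax(floor(pts[i, 2] / pixel_size) + 1L, 1L), ny)
      c <- pmin(pmax(floor(pts[i, 1] / pixel_size) + 1L, 1L), nx)
      img[r, c] <- img[r, c] + 1
    }
    if (psf_fwhm > 0) {
      img <- blur_matrix(img, fwhm_to_sigma(psf_fwhm), pixel_size)
    }
  }
  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is required when rendering with noise")
    img <- with_seed(op_seed(seed, "points_noise"), apply_noise(img, noise))
  }
  rendered_image(img, pixel_size, channel)
}
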