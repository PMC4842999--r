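# PALM pipeline: single-molecule peak fitting, DBSCAN cluster definition
# in nm space, nearest-neighbour-weighted disc rendering, and the
# PALM-parameterised segmentation workflow.

#' PALM pipeline parameters
#'
#' Defaults follow the PALM analysis settings: localisation events drawn
#' as 40 nm discs, PSD channel from the NN-rendered image blurred with a
#' 250 nm Gaussian kernel and background-subtracted at 140 nm, NC channel
#' smoothed at 40 nm with 70 nm background subtraction, watershed seed
#' point diameters of 250 nm (PSD) and 70 nm (NC). The DBSCAN radius and
#' minimum point count are not standardised across Imaris-era workflows;
#' defaults
#' (eps 100 nm ~ 2.5x the localisation precision, 10 points) are exposed
#' and echoed into output metadata.
#'
#' @param dbscan_eps DBSCAN neighbourhood radius (nm).
#' @param dbscan_min_points Minimum neighbours (including the point
#'   itself) for a core point; >= 2.
#' @param render_disc_diameter Disc diameter (nm) used to draw each
#'   localisation, representing the fitting precision.
#' @param render_pixel Pixel size (nm) of the rendered image.
#' @param psd_blur_sigma Gaussian kernel (nm) blurring the NN image for
#'   PSD-scale detection.
#' @param psd_background,nc_background Background-subtraction scales (nm).
#' @param nc_smooth Gaussian kernel (nm) smoothing the NN image for NC
#'   detection.
#' @param psd_seed,nc_seed Watershed seed point diameters (nm).
#' @param psd_min_pixels,nc_min_pixels Minimum object sizes in pixels.
#' @param nn_k Number of within-cluster nearest neighbours averaged for
#'   the NN weighting.
#' @param nn_normalisation `"cluster"` (weights median-normalised within
#'   each cluster, default) or `"global"`.
#' @param threshold_fraction Foreground threshold fraction (see
#'   [seg_params()]); the PALM default (0.2) was calibrated by recovery of
#'   known NC sizes on simulated localisation data, the in-silico
#'   counterpart of calibrating against manual quantifications.
#' @return A list of class `palm_params`.
#' @export
palm_params <- function(dbscan_eps = 100, dbscan_min_points = 10,
                        render_disc_diameter = 40, render_pixel = 20,
                        psd_blur_sigma = 250, psd_background = 140,
                        nc_smooth = 40, nc_background = 70,
                        psd_seed = 250, nc_seed = 70,
                        psd_min_pixels = 30, nc_min_pixels = 10,
                        nn_k = 5, nn_normalisation = c("cluster", "global"),
                        threshold_fraction = 0.20) {
  nn_normalisation <- match.arg(nn_normalisation)
  lens <- c(dbscan_eps, render_disc_diameter, render_pixel, psd_blur_sigma,
            psd_background, nc_smooth, nc_background, psd_seed, nc_seed)
  if (any(lens <= 0)) stop("all length parameters must be > 0")
  if (dbscan_min_points < 2) stop("dbscan_min_points must be >= 2")
  structure(as.list(environment()), class = "palm_params")
}

#' Localise single-molecule peaks in a sparse-emitter frame stack
#'
#' Per frame, candidate peaks above a noise-scaled threshold
#' (median + 5 * MAD by default) are fitted with a free 2D Gaussian
#' (x, y, sigma, amplitude, offset) by Levenberg-Marquardt least squares
#' in a window around the candidate. Fits that do not converge, whose
#' centre leaves the window, or whose width is implausible are rejected
#' and counted. The per-event precision is the fitted x/y standard error
#' (averaged), in nm.
#'
#' @param frames List of matrices or a 3D array (rows y, cols x, frames).
#' @param pixel_size Pixel edge (nm).
#' @param fit_window Half-width of the square fit window in pixels.
#' @param threshold_mads Candidate threshold in MADs above the frame
#'   median.
#' @param psf_sigma_px Initial Gaussian sigma in pixels.
#' @return A `localisation_table` data frame (`x_nm`, `y_nm`, `frame`,
#'   `precision_nm`, `intensity`) with attribute `n_rejected`.
#' @export
fit_peaks <- function(frames, pixel_size = 100, fit_window = 3L,
                      threshold_mads = 5, psf_sigma_px = 1.3) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  }
  stopifnot(is.list(frames))
  out <- list(); rejected <- 0L
  w <- as.integer(fit_window)
  for (fi in seq_along(frames)) {
    m <- frames[[fi]]
    thr <- median(m) + threshold_mads * max(mad(m), 1e-12)
    cand <- local_maxima(m, m > thr)
    if (!nrow(cand)) next
    # order brightest first and suppress candidates within the window of
    # an already-fitted brighter one
    cand <- cand[order(-m[cand]), , drop = FALSE]
    used <- matrix(FALSE, nrow(m), ncol(m))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      if (used[r, c]) next
      r0 <- max(1L, r - w); r1 <- min(nrow(m), r + w)
      c0 <- max(1L, c - w); c1 <- min(ncol(m), c + w)
      win <- m[r0:r1, c0:c1]
      if (max(win) - min(win) <= 0) { rejected <- rejected + 1L; next }
      xx <- rep((c0:c1) - 0.5, each = r1 - r0 + 1)
      yy <- rep((r0:r1) - 0.5, times = c1 - c0 + 1)
      zz <- as.vector(win)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          zz ~ A * exp(-((xx - x0)^2 + (yy - y0)^2) / (2 * s^2)) + b0,
          start = list(A = max(win) - min(win), x0 = unname(c) - 0.5,
                       y0 = unname(r) - 0.5,
                       s = psf_sigma_px, b0 = min(win)),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
        error = function(e) NULL)
      ok <- FALSE
      if (!is.null(fit)) {
        p <- coef(fit)
        ok <- p[["A"]] > 0 && p[["s"]] > 0.3 && p[["s"]] < 2 * (2 * w + 1) &&
          p[["x0"]] >= c0 - 1 && p[["x0"]] <= c1 &&
          p[["y0"]] >= r0 - 1 && p[["y0"]] <= r1
      }
      if (!ok) { rejected <- rejected + 1L; next }
      se <- tryCatch(summary(fit)$coefficients[c("x0", "y0"), "Std. Error"],
                     error = function(e) c(NA_real_, NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        x_nm = p[["x0"]] * pixel_size, y_nm = p[["y0"]] * pixel_size,
        frame = fi, precision_nm = mean(se, na.rm = TRUE) * pixel_size,
        intensity = p[["A"]])
      used[r0:r1, c0:c1] <- TRUE
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(x_nm = numeric(), y_nm = numeric(), frame = integer(),
               precision_nm = numeric(), intensity = numeric())
  class(tab) <- c("localisation_table", "data.frame")
  attr(tab, "n_rejected") <- rejected
  tab
}

#' DBSCAN clustering of localisation events
#'
#' Standard DBSCAN in nm space with the point itself counted towards
#' `min_points`. Cluster ids are assigned deterministically and
#' independently of input order ambiguities: clusters are the connected
#' components of the core-point graph expanded in row-index order, border
#' points join the cluster of their lowest-row-index core neighbour, and
#' clusters are numbered by first appearance in the table. Noise events
#' receive cluster id 0 and are excluded from rendering downstream.
#'
#' Neighbourhoods are found with an eps-sized grid index, so runtime is
#' near-linear for the spatially sparse tables produced by PALM fields.
#'
#' @param table A `localisation_table` (needs `x_nm`, `y_nm`).
#' @param eps Neighbourhood radius (nm).
#' @param min_points Core-point threshold (including self), >= 2.
#' @return The table with a `cluster_id` column (0 = noise).
#' @export
cluster_localisations <- function(table, eps = 100, min_points = 10) {
  stopifnot(is.data.frame(table), all(c("x_nm", "y_nm") %in% names(table)))
  if (eps <= 0) stop("eps must be > 0")
  if (min_points < 2) stop("min_points must be >= 2")
  n <- nrow(table)
  table$cluster_id <- integer(n)
  if (n == 0) return(table)
  nbrs <- grid_neighbours(table$x_nm, table$y_nm, eps)
  core <- lengths(nbrs) >= min_points
  cid <- integer(n)   # 0 = unassigned/noise
  cur <- 0L
  # components of the core-core graph
  for (i in seq_len(n)) {
    if (!core[i] || cid[i] != 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (cid[v] != 0L) next
      cid[v] <- cur
      nb <- nbrs[[v]]
      stack <- c(stack, nb[core[nb] & cid[nb] == 0L])
    }
  }
  # border points join their lowest-row-index core neighbour's cluster
  for (i in which(!core)) {
    cn <- nbrs[[i]][core[nbrs[[i]]]]
    if (length(cn)) cid[i] <- cid[min(cn)]
  }
  table$cluster_id <- canonicalise_labels(cid)
  table
}

# Neighbour lists (indices within eps, including self) via an eps-cell
# grid: per occupied cell, distances are computed to points in the 3x3
# cell neighbourhood only.
grid_neighbours <- function(x, y, eps) {
  n <- length(x)
  cxi <- floor(x / eps); cyi <- floor(y / eps)
  key <- paste(cxi, cyi)
  cells <- split(seq_len(n), key)
  # index of neighbouring cells for each occupied cell
  coord <- do.call(rbind, strsplit(names(cells), " "))
  cx <- as.numeric(coord[, 1]); cy <- as.numeric(coord[, 2])
  cell_of <- match(key, names(cells))
  nbrs <- vector("list", n)
  eps2 <- eps^2
  lookup <- new.env(hash = TRUE, size = length(cells))
  for (k in seq_along(cells)) assign(names(cells)[k], k, envir = lookup)
  for (k in seq_along(cells)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      nm <- paste(cx[k] + dx, cy[k] + dy)
      j <- mget(nm, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) cand <- c(cand, cells[[j]])
    }
    pts <- cells[[k]]
    d2 <- outer(x[pts], x[cand], "-")^2 + outer(y[pts], y[cand], "-")^2
    for (ii in seq_along(pts)) {
      nbrs[[pts[ii]]] <- cand[d2[ii, ] <= eps2]
    }
  }
  nbrs
}

#' Reference DBSCAN by explicit core-graph components
#'
#' Independent brute-force implementation used to validate
#' [cluster_localisations()]: the full pairwise distance matrix is formed,
#' core points are those with `min_points` neighbours (including self),
#' clusters are the connected components of the core-core adjacency graph,
#' and border points join the cluster of their lowest-labelled core
#' neighbour. Intended for instances of a few hundred points.
#'
#' @inheritParams cluster_localisations
#' @return Integer vector of cluster labels (0 = noise), relabelled so
#'   that clusters are numbered by their first member's row index.
#' @export
dbscan_reference <- function(table, eps, min_points) {
  n <- nrow(table)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(cbind(table$x_nm, table$y_nm)))
  adj <- d <= eps
  core <- rowSums(adj) >= min_points
  lab <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    comp <- comp + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] != 0L) next
      lab[v] <- comp
      nb <- which(adj[v, ] & core & lab == 0L)
      stack <- c(stack, nb)
    }
  }
  for (i in which(!core & lab == 0L)) {
    cn <- which(adj[i, ] & core)
    if (length(cn)) lab[i] <- lab[min(cn)]
  }
  canonicalise_labels(lab)
}

# Relabel cluster ids by order of first appearance so two labelings can be
# compared directly.
canonicalise_labels <- function(lab) {
  pos <- lab > 0L
  if (!any(pos)) return(lab)
  first <- match(unique(lab[pos]), lab)
  ord <- unique(lab[pos])[order(first)]
  out <- lab
  out[pos] <- match(lab[pos], ord)
  out
}

#' Render a nearest-neighbour-weighted localisation image
#'
#' Each clustered event is drawn as a filled disc (default diameter 40 nm,
#' representing the fitting precision), antialiased by area coverage;
#' overlapping discs sum. The disc amplitude is the event's NN
#' coefficient: the inverse of its mean distance to its `nn_k` nearest
#' within-cluster neighbours (capped at cluster size - 1), normalised by
#' the median coefficient of its cluster (or of the whole table when
#' `nn_normalisation = "global"`). Singleton clusters get weight 1. Noise
#' events are not rendered.
#'
#' @param table A clustered `localisation_table` (`cluster_id` column).
#' @param params A [palm_params()].
#' @param field `(width, height)` of the field in nm; defaults to the
#'   table's `field_width` / `field_height` attributes.
#' @return A [rendered_image()] (channel `"nn"`) with attribute
#'   `n_rendered`.
#' @export
render_nn_image <- function(table, params = palm_params(), field = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(table$cluster_id)) stop("table must be clustered first")
  if (is.null(field)) {
    field <- c(attr(table, "field_width"), attr(table, "field_height"))
  }
  if (length(field) != 2 || any(!is.finite(field)) || any(field <= 0)) {
    stop("field extent (width, height) in nm is required")
  }
  px <- params$render_pixel
  nx <- max(1L, round(field[1] / px)); ny <- max(1L, round(field[2] / px))
  img <- matrix(0, ny, nx)
  keep <- which(table$cluster_id > 0L)
  if (!length(keep)) {
    out <- rendered_image(img, px, "nn")
    attr(out, "n_rendered") <- 0L
    return(out)
  }
  w <- nn_weights(table$x_nm[keep], table$y_nm[keep],
                  table$cluster_id[keep], params$nn_k,
                  params$nn_normalisation)
  rad <- params$render_disc_diameter / 2
  img <- stamp_discs(img, table$x_nm[keep], table$y_nm[keep], w, rad, px)
  out <- rendered_image(img, px, "nn")
  attr(out, "n_rendered") <- length(keep)
  out
}

# NN coefficient per event: median-normalised inverse mean k-NN distance
# within the event's cluster.
nn_weights <- function(x, y, cid, k, normalisation) {
  w <- numeric(length(x))
  for (g in split(seq_along(x), cid)) {
    n <- length(g)
    if (n == 1L) { w[g] <- 1; next }
    kk <- min(k, n - 1L)
    d <- as.matrix(dist(cbind(x[g], y[g])))
    diag(d) <- Inf
    meand <- apply(d, 1, function(r) mean(sort.int(r, partial = kk)[seq_len(kk)]))
    wi <- 1 / pmax(meand, 1e-9)
    if (normalisation == "cluster") wi <- wi / median(wi)
    w[g] <- wi
  }
  if (normalisation == "global") {
    pos <- w > 0
    w[pos] <- w[pos] / median(w[pos])
    w[!pos & seq_along(w) > 0] <- 1
  }
  w
}

# Add discs of radius `rad` (nm) at (x, y) with amplitudes `amp` to `img`,
# antialiased by 4x4 subpixel area coverage.
stamp_discs <- function(img, x, y, amp, rad, px) {
  S <- 4L
  off <- (seq_len(S) - 0.5) / S
  half <- ceiling(rad / px) + 1L
  ny <- nrow(img); nx <- ncol(img)
  for (i in seq_along(x)) {
    cc <- floor(x[i] / px) + 1L
    rr <- floor(y[i] / px) + 1L
    c0 <- max(1L, cc - half); c1 <- min(nx, cc + half)
    r0 <- max(1L, rr - half); r1 <- min(ny, rr + half)
    xs <- as.vector(outer(off, (c0:c1) - 1, "+")) * px - x[i]
    ys <- as.vector(outer(off, (r0:r1) - 1, "+")) * px - y[i]
    inside <- outer(ys^2, xs^2, "+") <= rad^2
    nr <- r1 - r0 + 1L
    cov <- matrix(0, nr, c1 - c0 + 1L)
    inside_m <- matrix(as.numeric(inside), nrow = S * nr)
    for (j in seq_len(ncol(cov))) {
      block <- inside_m[, ((j - 1) * S + 1):(j * S), drop = FALSE]
      cov[, j] <- colSums(matrix(rowSums(block), nrow = S)) / (S * S)
    }
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp[i] * cov
  }
  img
}

#' Run the PALM segmentation workflow
#'
#' From a (clustered) localisation table: render the NN-weighted image,
#' detect PSDs on a version blurred with the large PSD kernel
#' (background-subtracted at `psd_background`, watershed seed
#' `psd_seed`), detect NCs on a version smoothed at `nc_smooth`
#' (background `nc_background`, seed `nc_seed`), assign NCs to PSDs, and
#' attach per-object localisation counts and densities.
#'
#' @param table A `localisation_table`; clustered with
#'   [cluster_localisations()] first if it has no `cluster_id` column.
#' @param params A [palm_params()].
#' @param field `(width, height)` in nm (defaults to table attributes).
#' @return A `psd_records` object whose `psds` and `ncs` tables carry
#'   additional `n_localisations` and `localisation_density_um2` columns;
#'   segmentations and the NN image attached as attributes.
#' @export
run_palm_workflow <- function(table, params = palm_params(), field = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) {
    rec <- list(psds = cbind(empty_objects(), nc_count = integer(),
                             subtype = classify_subtype(integer())),
                ncs = cbind(empty_objects(), psd_label = integer()),
                excluded_psd_fraction = 0, n_psd_detected = 0L,
                n_discarded_nc = 0L)
    class(rec) <- "psd_records"
    return(rec)
  }
  if (is.null(table$cluster_id)) {
    table <- cluster_localisations(table, params$dbscan_eps,
                                   params$dbscan_min_points)
  }
  nn <- render_nn_image(table, params, field)
  psd_img <- rendered_image(
    blur_matrix(nn$data, params$psd_blur_sigma, nn$pixel_size),
    nn$pixel_size, "palm_psd")
  psd_seg <- detect_and_split(
    subtract_background(psd_img, params$psd_background),
    seg_params(seed_point_diameter = params$psd_seed,
               min_pixels = params$psd_min_pixels,
               background_diameter = params$psd_background,
               threshold_fraction = params$threshold_fraction),
    intensity_image = nn)
  nc_img <- rendered_image(
    blur_matrix(nn$data, params$nc_smooth, nn$pixel_size),
    nn$pixel_size, "palm_nc")
  nc_seg <- detect_and_split(
    subtract_background(nc_img, params$nc_background),
    seg_params(seed_point_diameter = params$nc_seed,
               min_pixels = params$nc_min_pixels,
               background_diameter = params$nc_background,
               threshold_fraction = params$threshold_fraction),
    intensity_image = nn)
  rec <- assign_nc_to_psd(psd_seg, nc_seg)
  rec$psds <- add_localisation_counts(rec$psds, psd_seg, table)
  rec$ncs <- add_localisation_counts(rec$ncs, nc_seg, table)
  clustered <- sum(table$cluster_id > 0L)
  rec$n_events_clustered <- clustered
  rec$n_events_in_psds <- sum(rec$psds$n_localisations)
  rec$n_events_unassigned <- clustered - rec$n_events_in_psds
  attr(rec, "psd_seg") <- psd_seg
  attr(rec, "nc_seg") <- nc_seg
  attr(rec, "nn_image") <- nn
  attr(rec, "params") <- params
  rec
}

# Count clustered events whose pixel falls inside each object's mask.
add_localisation_counts <- function(objs, seg, table) {
  if (!nrow(objs)) {
    objs$n_localisations <- integer(0)
    objs$localisation_density_um2 <- numeric(0)
    return(objs)
  }
  px <- seg$pixel_size
  ev <- table[table$cluster_id > 0L, , drop = FALSE]
  cnt <- integer(nrow(objs))
  if (nrow(ev)) {
    r <- pmin(pmax(floor(ev$y_nm / px) + 1L, 1L), nrow(seg$labels))
    c <- pmin(pmax(floor(ev$x_nm / px) + 1L, 1L), ncol(seg$labels))
    lab <- seg$labels[cbind(r, c)]
    tab <- table(factor(lab[lab > 0L], levels = objs$label))
    cnt <- as.integer(tab)
  }
  objs$n_localisations <- cnt
  objs$localisation_density_um2 <- cnt / (objs$area / 1e6)
  objs
}
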