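# Pixel-image container and low-level raster utilities shared by the
# rendering and segmentation code. Images are plain numeric matrices with
# rows indexing y and columns indexing x; physical pixel size travels with
# the matrix in a light S3 wrapper.

#' Construct a rendered image
#'
#' A 2D grayscale raster with a physical pixel size (nm) and a channel
#' label. This is the container used by both the scene renderer and the
#' segmentation code.
#'
#' @param data Numeric matrix; rows index y, columns index x.
#' @param pixel_size Pixel edge length in nm (> 0).
#' @param channel Character label, e.g. `"confocal"`, `"sted"`, `"nn"`.
#' @return An object of class `rendered_image`.
#' @export
rendered_image <- function(data, pixel_size, channel = "unknown") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (nm)")
  }
  structure(
    list(data = data, pixel_size = as.numeric(pixel_size),
         channel = as.character(channel)),
    class = "rendered_image"
  )
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %d x %d px, %.3g nm/px, channel '%s'\n",
              nrow(x$data), ncol(x$data), x$pixel_size, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x$data), max(x$data), sum(x$data)))
  invisible(x)
}

#' @export
dim.rendered_image <- function(x) dim(x$data)

#' Convert between Gaussian FWHM and standard deviation
#'
#' FWHM = 2 * sqrt(2 * ln 2) * sigma, the relationship used for all point
#' spread functions and fitted profile widths in the package.
#'
#' @param fwhm,sigma Width in any length unit.
#' @return The corresponding sigma (or FWHM) in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * (2 * sqrt(2 * log(2)))

# Gaussian blur of a plain matrix at a physical sigma (nm). Sigma below a
# hundredth of a pixel is treated as no-op. Mass is preserved (circular
# boundary in EBImage::filter2 underneath gblur).
blur_matrix <- function(m, sigma_nm, pixel_size) {
  sigma_px <- sigma_nm / pixel_size
  if (sigma_px < 0.01) return(m)
  out <- EBImage::imageData(EBImage::gblur(m, sigma = sigma_px))
  dim(out) <- dim(m)
  out
}

# 8-connected labelling. EBImage::bwlabel is 4-connected; diagonal-adjacent
# labels are merged afterwards with a union-find pass, then relabelled 1..k.
label_components <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  dim(lab) <- dim(mask)
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Local maxima of `m` restricted to mask: pixels equal to the 3x3
# neighbourhood maximum. Returns a 2-column matrix of (row, col) indices.
local_maxima <- function(m, mask = NULL) {
  mx <- EBImage::imageData(EBImage::dilate(m, EBImage::makeBrush(3, "box")))
  dim(mx) <- dim(m)
  cand <- m >= mx
  if (!is.null(mask)) cand <- cand & mask
  which(cand, arr.ind = TRUE)
}

# Bilinear interpolation of matrix `m` at physical coordinates (x, y) in nm.
# Points outside the image return NA.
interp_bilinear <- function(m, x_nm, y_nm, pixel_size) {
  # continuous pixel coordinates: centre of pixel (r, c) at ((c-0.5), (r-0.5)) px
  cx <- x_nm / pixel_size + 0.5
  cy <- y_nm / pixel_size + 0.5
  c0 <- floor(cx); r0 <- floor(cy)
  fx <- cx - c0; fy <- cy - r0
  nr <- nrow(m); nc <- ncol(m)
  ok <- c0 >= 1 & c0 + 1 <= nc & r0 >= 1 & r0 + 1 <= nr
  out <- rep(NA_real_, length(x_nm))
  if (any(ok)) {
    i <- which(ok)
    v00 <- m[cbind(r0[i], c0[i])]
    v01 <- m[cbind(r0[i], c0[i] + 1)]
    v10 <- m[cbind(r0[i] + 1, c0[i])]
    v11 <- m[cbind(r0[i] + 1, c0[i] + 1)]
    out[i] <- v00 * (1 - fx[i]) * (1 - fy[i]) + v01 * fx[i] * (1 - fy[i]) +
      v10 * (1 - fx[i]) * fy[i] + v11 * fx[i] * fy[i]
  }
  out
}

# Derive an operation-specific stream seed from a user seed and a tag, so
# different operations called with the same seed (scene sampling, PALM
# event simulation, noise draws, ...) consume decorrelated RNG streams.
op_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103 + h * 12289) %% 2147483647)
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards. All stochastic operations in the
# package route through this, so nothing touches global randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
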