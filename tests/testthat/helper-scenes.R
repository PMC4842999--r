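# Shared fixture builders: hand-made scenes with known geometry, and an
# independent supersampled ellipse rasteriser used as rendering oracle.

# Build a scene from an explicit list of NC specs per PSD. Each PSD is a
# list of NCs: c(x, y, short, long, orientation, count).
make_scene <- function(psd_ncs, field = c(10000, 10000)) {
  psds <- lapply(psd_ncs, function(ncs) {
    structure(list(
      nanoclusters = lapply(ncs, function(v) list(
        centre = c(v[1], v[2]), short_axis = v[3], long_axis = v[4],
        orientation = v[5], molecule_count = v[6])),
      subtype_truth = length(ncs),
      centre = c(mean(vapply(ncs, `[`, numeric(1), 1)),
                 mean(vapply(ncs, `[`, numeric(1), 2)))),
      class = "psd_truth")
  })
  structure(list(field_width = field[1], field_height = field[2],
                 psds = psds, rng_seed = 0L),
            class = "synthetic_scene")
}

# One PSD with a single circular NC.
make_spot_scene <- function(x, y, diameter = 150, count = 100,
                            field = c(4000, 4000)) {
  make_scene(list(list(c(x, y, diameter, diameter, 0, count))), field)
}

# Independent rasteriser: fraction of each pixel covered by the ellipse,
# estimated on a fine subgrid (distinct code path from add_ellipse).
oracle_ellipse_coverage <- function(nx, ny, px, cx, cy, a, b, theta = 0,
                                    sub = 8) {
  cov <- matrix(0, ny, nx)
  offs <- (seq_len(sub) - 0.5) / sub
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    xs <- (c - 1 + offs) * px
    ys <- (r - 1 + offs) * px
    hits <- 0
    for (yy in ys) for (xx in xs) {
      u <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
      v <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
      if ((u / a)^2 + (v / b)^2 <= 1) hits <- hits + 1
    }
    cov[r, c] <- hits / sub^2
  }
  cov
}

# Gaussian spot image built directly (no scene machinery): FWHMs in nm
# along x / y before rotation.
gaussian_spot_image <- function(nx, ny, px, cx, cy, fwhm_x, fwhm_y,
                                theta = 0, amp = 1, offset = 0) {
  sx <- fwhm_x / (2 * sqrt(2 * log(2)))
  sy <- fwhm_y / (2 * sqrt(2 * log(2)))
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  U <- outer(ys - cy, xs - cx, function(dy, dx) dx * cos(theta) + dy * sin(theta))
  V <- outer(ys - cy, xs - cx, function(dy, dx) -dx * sin(theta) + dy * cos(theta))
  rendered_image(offset + amp * exp(-(U^2 / (2 * sx^2) + V^2 / (2 * sy^2))),
                 px, "synthetic")
}
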