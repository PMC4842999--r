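# Segmentation core: prefilter, background subtraction, detection and
# watershed splitting, NC-to-PSD assignment, and the g-STED workflow.

test_that("preprocess with sigma 0 is the identity and preserves constants", {
  img <- rendered_image(matrix(runif(400), 20, 20), 20)
  expect_identical(preprocess(img, 0), img)
  const <- rendered_image(matrix(3.7, 30, 30), 20)
  sm <- preprocess(const, 60)
  expect_equal(sm$data, const$data, tolerance = 1e-10)
})

test_that("preprocess turns a delta spike into a mass-preserving Gaussian", {
  m <- matrix(0, 41, 41); m[21, 21] <- 1
  img <- preprocess(rendered_image(m, 20), 40)   # sigma 2 px
  expect_equal(sum(img$data), 1, tolerance = 1e-6)
  # second moment of the discrete kernel ~ sigma^2 = 4 px^2
  xs <- 1:41
  v <- sum(img$data * outer(rep(1, 41), (xs - 21)^2)) / sum(img$data)
  expect_equal(v, 4, tolerance = 0.02)
  # peak stays centred
  expect_equal(which.max(img$data), (21 - 1) * 41 + 21)
})

test_that("background subtraction removes flat offsets and keeps sharp spots", {
  const <- rendered_image(matrix(5, 40, 40), 20)
  expect_true(all(subtract_background(const, 140)$data == 0))
  zero <- rendered_image(matrix(0, 20, 20), 20)
  expect_true(all(subtract_background(zero, 140)$data == 0))
  # sharp 100 nm spot on a constant offset: peak survives, offset removed
  spot <- render_image(make_spot_scene(2000, 2000, diameter = 100),
                       0, 20)
  with_offset <- rendered_image(spot$data + 2, 20)
  bg <- subtract_background(with_offset, 140)
  ctr <- bg$data[100, 100]
  expect_gt(ctr, 0)
  expect_equal(bg$data[5, 5], 0)
  # oracle: explicit low-pass of the offset image
  low <- nanopsd:::blur_matrix(with_offset$data, fwhm_to_sigma(140), 20)
  expect_equal(bg$data, pmax(with_offset$data - low, 0), tolerance = 1e-12)
})

test_that("two spots are split or merged according to the seed diameter", {
  field <- c(4000, 4000)
  two <- function(sep) {
    make_scene(list(list(c(2000 - sep / 2, 2000, 120, 120, 0, 100)),
                    list(c(2000 + sep / 2, 2000, 120, 120, 0, 100))),
               field)
  }
  p <- seg_params(seed_point_diameter = 160, min_pixels = 10)
  img_far <- render_image(two(400), 85, 20)
  expect_equal(nrow(detect_and_split(img_far, p)$objects), 2)
  img_near <- render_image(two(60), 85, 20)
  expect_equal(nrow(detect_and_split(img_near, p)$objects), 1)
})

test_that("fragments below min_pixels are removed", {
  m <- matrix(0, 50, 50)
  m[10:12, 10:12] <- 1          # 9 pixels
  m[30:37, 30:37] <- 1          # 64 pixels
  img <- rendered_image(m, 20)
  p9 <- seg_params(seed_point_diameter = 100, min_pixels = 10,
                   threshold_absolute = 0.5, exclude_border = FALSE)
  seg <- detect_and_split(img, p9)
  expect_equal(nrow(seg$objects), 1)
  expect_equal(seg$n_removed_small, 1)
  expect_equal(seg$objects$pixel_count, 64)
})

test_that("empty foreground gives an empty object list, not an error", {
  img <- rendered_image(matrix(0, 30, 30), 20)
  seg <- detect_and_split(img, seg_params())
  expect_equal(nrow(seg$objects), 0)
})

test_that("watershed fragments tile each component exactly", {
  cfg <- sim_config(field_width = 5000, field_height = 5000)
  sc <- sample_scene(cfg, 23)
  img <- render_image(sc, 85, 20, noise = cfg$noise_model, seed = 23)
  p <- sted_nc_params()
  det <- subtract_background(preprocess(img, p$prefilter_sigma),
                             p$background_diameter)
  seg <- detect_and_split(det, p)
  thr <- p$threshold_fraction * quantile(det$data, 0.999, names = FALSE)
  mask <- det$data > thr & det$data > 0
  # every foreground pixel belongs to exactly one fragment and vice versa
  expect_equal(seg$all_labels > 0, mask)
})

test_that("raising min_pixels never increases the object count", {
  cfg <- sim_config(field_width = 5000, field_height = 5000)
  sc <- sample_scene(cfg, 29)
  img <- render_image(sc, 85, 20, noise = cfg$noise_model, seed = 29)
  counts <- vapply(c(1, 5, 10, 20, 40, 80), function(mp) {
    p <- seg_params(prefilter_sigma = 40, seed_point_diameter = 160,
                    min_pixels = mp)
    nrow(detect_and_split(subtract_background(preprocess(img, 40), 140),
                          p)$objects)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("halving the pixel size changes equivalent diameters by < 5%", {
  cfg20 <- sim_config(field_width = 5000, field_height = 5000,
                      pixel_size = 20, subtype_mixture = c(1, 0, 0, 0))
  sc <- sample_scene(cfg20, 31)
  p <- sted_nc_params()
  med <- vapply(c(20, 10), function(px) {
    img <- render_image(sc, 85, px)
    seg <- detect_and_split(
      subtract_background(preprocess(img, p$prefilter_sigma),
                          p$background_diameter), p)
    median(seg$objects$equivalent_diameter)
  }, numeric(1))
  expect_lt(abs(med[2] / med[1] - 1), 0.05)
})

test_that("NCs are assigned to containing PSDs and NC-less PSDs excluded", {
  field <- c(4000, 4000)
  # PSD channel: two large blobs; NC channel: two spots in blob 1 only
  psd_scene <- make_scene(list(list(c(1200, 1200, 500, 500, 0, 100)),
                               list(c(2800, 2800, 500, 500, 0, 100))),
                          field)
  nc_scene <- make_scene(list(list(c(1100, 1200, 120, 120, 0, 100)),
                              list(c(1450, 1200, 120, 120, 0, 100))),
                         field)
  psd_seg <- detect_and_split(render_image(psd_scene, 240, 20),
                              seg_params(seed_point_diameter = 400,
                                         min_pixels = 30))
  nc_seg <- detect_and_split(render_image(nc_scene, 85, 20),
                             seg_params(seed_point_diameter = 160,
                                        min_pixels = 10))
  expect_equal(nrow(psd_seg$objects), 2)
  expect_equal(nrow(nc_seg$objects), 2)
  rec <- assign_nc_to_psd(psd_seg, nc_seg)
  expect_equal(nrow(rec$psds), 1)
  expect_equal(rec$psds$nc_count, 2)
  expect_equal(as.character(rec$psds$subtype), "2NC")
  expect_equal(rec$excluded_psd_fraction, 0.5)
  expect_equal(rec$n_discarded_nc, 0)
})

test_that("the sted workflow recovers hand-built subtype geometry", {
  # blank images -> empty records
  blank <- rendered_image(matrix(0, 100, 100), 20)
  expect_equal(nrow(run_sted_workflow(blank, blank)$psds), 0)
  # mismatched grids are rejected
  expect_error(run_sted_workflow(blank, rendered_image(matrix(0, 50, 50), 20)),
               "grid")
  # one 3-NC PSD with 250 nm separations -> one PSDRecord with nc_count 3
  r3 <- 250 / sqrt(3)
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  ncs <- lapply(ang, function(a)
    c(2000 + r3 * cos(a), 2000 + r3 * sin(a), 110, 110, 0, 100))
  sc3 <- make_scene(list(ncs), field = c(4000, 4000))
  rec3 <- run_sted_workflow(render_image(sc3, 240, 20),
                            render_image(sc3, 85, 20))
  expect_equal(nrow(rec3$psds), 1)
  expect_equal(rec3$psds$nc_count, 3)
  expect_equal(as.character(rec3$psds$subtype), "3+NC")
})

test_that("a sparse 1NC scene yields only 1NC records through the workflow", {
  cfg <- sim_config(field_width = 8000, field_height = 8000,
                    psd_density = 6, subtype_mixture = c(1, 0, 0, 0))
  sc <- sample_scene(cfg, 37)
  f <- render_field(sc, cfg, 37)
  rec <- run_sted_workflow(f$confocal, f$sted)
  expect_gt(nrow(rec$psds), 0)
  expect_true(mean(rec$psds$subtype == "1NC") >= 0.9)
})
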