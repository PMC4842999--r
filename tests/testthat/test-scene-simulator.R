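# Scene simulator: sampling distributions, spacing constraints, rendering
# physics (conservation, linearity, PSF width), and the PALM event model.

test_that("degenerate mixture yields only single-NC PSDs", {
  cfg <- sim_config(field_width = 5000, field_height = 5000,
                    subtype_mixture = c(1, 0, 0, 0))
  sc <- sample_scene(cfg, 1)
  expect_gt(length(sc$psds), 0)
  expect_true(all(vapply(sc$psds, function(p) p$subtype_truth, numeric(1)) == 1))
})

test_that("multi-NC pairwise separations honour the spacing interval", {
  cfg <- sim_config(field_width = 8000, field_height = 8000,
                    subtype_mixture = c(0, 0, 1, 0),
                    spacing_interval = c(100, 300))
  sc <- sample_scene(cfg, 2)
  for (p in sc$psds) {
    xy <- t(vapply(p$nanoclusters, function(nc) nc$centre, numeric(2)))
    d <- as.vector(dist(xy))
    expect_true(all(d >= 100 & d <= 300))
  }
})

test_that("geometrically unsatisfiable spacing fails naming the PSD", {
  # four points pairwise within [290, 300] nm do not exist in the plane
  # (a planar 4-point set cannot be near-equilateral on all 6 pairs)
  cfg <- sim_config(field_width = 5000, field_height = 5000,
                    subtype_mixture = c(0, 0, 0, 1),
                    spacing_interval = c(290, 300))
  expect_error(sample_scene(cfg, 3), "PSD")
})

test_that("PSD count is Poisson at the configured density", {
  # Monte-Carlo oracle: field of 25 um^2 at 19.2 per 20 um^2 -> mean 24
  cfg <- sim_config(field_width = 5000, field_height = 5000,
                    psd_density = 19.2, edge_margin = 500)
  counts <- vapply(1:200, function(s) length(sample_scene(cfg, s)$psds),
                   numeric(1))
  mu <- 19.2 * 25 / 20
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # dispersion consistent with Poisson (variance ~ mean)
  expect_gt(var(counts), mu / 2)
  expect_lt(var(counts), mu * 2)
})

test_that("subtype mixture is recovered over many PSDs", {
  mix <- c(0.637, 0.243, 0.090, 0.030)
  cfg <- sim_config(subtype_mixture = mix)
  sc <- sample_scene(cfg, 4, n_psd = 10000)
  counts <- vapply(sc$psds, function(p) p$subtype_truth, numeric(1))
  emp <- tabulate(counts, 4) / 10000
  se <- sqrt(mix * (1 - mix) / 10000)
  expect_true(all(abs(emp - mix) <= 3 * se))
})

test_that("identical (config, seed) reproduce scenes and outputs byte-for-byte", {
  cfg <- sim_config(field_width = 4000, field_height = 4000)
  s1 <- sample_scene(cfg, 9); s2 <- sample_scene(cfg, 9)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  i1 <- render_image(s1, 85, 20, noise = cfg$noise_model, seed = 5)
  i2 <- render_image(s2, 85, 20, noise = cfg$noise_model, seed = 5)
  expect_identical(serialize(i1, NULL), serialize(i2, NULL))
  t1 <- simulate_palm(s1, cfg, 7); t2 <- simulate_palm(s2, cfg, 7)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("noiseless integrated intensity equals total molecule count", {
  cfg <- sim_config(field_width = 6000, field_height = 6000,
                    edge_margin = 800)
  sc <- sample_scene(cfg, 11)
  tr <- scene_truth(sc)
  for (fwhm in c(0, 85, 240)) {
    img <- render_image(sc, fwhm, 20)
    expect_equal(sum(img$data), sum(tr$ncs$molecule_count),
                 tolerance = 1e-6)
  }
})

test_that("integrated intensity is linear in molecule count", {
  sc1 <- make_spot_scene(2000, 2000, count = 100)
  sc2 <- make_spot_scene(2000, 2000, count = 200)
  i1 <- render_image(sc1, 0, 20)
  i2 <- render_image(sc2, 0, 20)
  expect_equal(sum(i2$data), 2 * sum(i1$data), tolerance = 1e-12)
  expect_equal(i2$data, 2 * i1$data, tolerance = 1e-12)
})

test_that("a point-like NC renders at the PSF width", {
  sc <- make_scene(list(list(c(2000, 2000, 1, 1, 0, 1000))),
                   field = c(4000, 4000))
  img <- render_image(sc, 85, 20)
  prof <- extract_profile(img, c(500, 2000), c(3500, 2000))
  f <- fwhm_from_profile(prof)
  expect_true(f$valid)
  expect_lt(abs(f$fwhm - 85), 20)   # one pixel quantisation
})

test_that("blur-free support equals the rasterised ellipse mask", {
  px <- 20
  sc <- make_scene(list(list(c(1000, 1200, 200, 300, 0.4, 100))),
                   field = c(2000, 2000))
  img <- render_image(sc, 0, px)
  oracle <- oracle_ellipse_coverage(100, 100, px, 1000, 1200, 150, 100, 0.4,
                                    sub = 4)
  expect_equal(img$data > 0, oracle > 0)
})

test_that("zero-precision PALM events lie inside their parent ellipse", {
  cfg <- sim_config(field_width = 6000, field_height = 6000,
                    localisation_precision = 0, background_rate = 0)
  sc <- sample_scene(cfg, 13)
  tab <- simulate_palm(sc, cfg, 13)
  tr <- scene_truth(sc)
  expect_gt(nrow(tab), 0)
  for (i in seq_len(nrow(tab))) {
    nc <- tr$ncs[tr$ncs$nc_id == tab$truth_nc_id[i], ]
    dx <- tab$x_nm[i] - nc$x_nm; dy <- tab$y_nm[i] - nc$y_nm
    u <- dx * cos(nc$orientation) + dy * sin(nc$orientation)
    v <- -dx * sin(nc$orientation) + dy * cos(nc$orientation)
    expect_lte((u / (nc$long_axis / 2))^2 + (v / (nc$short_axis / 2))^2,
               1 + 1e-9)
  }
})

test_that("event counts are Poisson around localisations_per_nc", {
  cfg <- sim_config(field_width = 3000, field_height = 3000,
                    subtype_mixture = c(1, 0, 0, 0), background_rate = 0,
                    localisations_per_nc = 100)
  sc <- make_spot_scene(1500, 1500, field = c(3000, 3000))
  n <- vapply(1:200, function(s) nrow(simulate_palm(sc, cfg, s)),
              numeric(1))
  expect_lt(abs(mean(n) - 100), 3 * sqrt(100 / 200))
})

test_that("without background every PSD contributes distinct parent ids", {
  cfg <- sim_config(field_width = 8000, field_height = 8000,
                    subtype_mixture = c(1, 0, 0, 0), background_rate = 0,
                    localisations_per_nc = 50)
  sc <- sample_scene(cfg, 17)
  tab <- simulate_palm(sc, cfg, 17)
  expect_equal(length(unique(tab$truth_psd_id)), length(sc$psds))
  expect_false(anyNA(tab$truth_nc_id))
})

test_that("fully paired two-channel fields are 100% juxtaposed at 600 nm", {
  cfg <- sim_config(field_width = 8000, field_height = 8000)
  sc <- sample_scene(cfg, 19)
  tc <- simulate_two_channel(sc, cfg, 19, fraction_paired = 1,
                             offset_mean = 200, offset_sd = 0)
  jx <- juxtaposition(tc$centres_a, tc$centres_b, 600, c(8000, 8000))
  expect_equal(jx$percent_juxtaposed, 100)
  expect_true(all(tc$paired))
})
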