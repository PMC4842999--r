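# PALM pipeline: peak fitting, DBSCAN (against the brute-force core-graph
# oracle), NN-weighted rendering, and the PALM segmentation workflow.

make_emitter_frame <- function(nx, ny, centres_px, amp = 3, sigma = 1.3,
                               offset = 0.1) {
  xx <- outer(rep(1, ny), seq_len(nx) - 0.5)
  yy <- outer(seq_len(ny) - 0.5, rep(1, nx))
  m <- matrix(offset, ny, nx)
  for (i in seq_len(nrow(centres_px))) {
    m <- m + amp * exp(-((xx - centres_px[i, 1])^2 +
                           (yy - centres_px[i, 2])^2) / (2 * sigma^2))
  }
  m
}

test_that("a noiseless emitter is localised to sub-millipixel accuracy", {
  m <- make_emitter_frame(21, 21, cbind(10.73, 9.31))
  tab <- fit_peaks(list(m), pixel_size = 100)
  expect_equal(nrow(tab), 1)
  expect_lt(abs(tab$x_nm / 100 - 10.73), 1e-3)
  expect_lt(abs(tab$y_nm / 100 - 9.31), 1e-3)
})

test_that("empty frames yield zero events", {
  expect_equal(nrow(fit_peaks(list(matrix(0, 15, 15)), 100)), 0)
})

test_that("two emitters 10 px apart are both recovered", {
  m <- make_emitter_frame(31, 31, cbind(c(10.2, 20.2), c(15.6, 15.6)))
  tab <- fit_peaks(list(m), pixel_size = 100)
  expect_equal(nrow(tab), 2)
  got <- sort(tab$x_nm / 100)
  expect_lt(abs(got[1] - 10.2), 0.1)
  expect_lt(abs(got[2] - 20.2), 0.1)
  expect_true(all(abs(tab$y_nm / 100 - 15.6) < 0.1))
})

test_that("DBSCAN definitions hold on elementary configurations", {
  # 3 points pairwise within eps, min_points 3 -> one cluster
  tb <- data.frame(x_nm = c(0, 50, 25), y_nm = c(0, 0, 40))
  out <- cluster_localisations(tb, eps = 100, min_points = 3)
  expect_equal(out$cluster_id, c(1L, 1L, 1L))
  # isolated point -> noise
  tb2 <- data.frame(x_nm = c(0, 5000), y_nm = c(0, 0))
  out2 <- cluster_localisations(tb2, eps = 100, min_points = 2)
  expect_equal(out2$cluster_id[2], 0L)
})

test_that("two well-separated blobs form exactly two clusters", {
  set.seed(41)
  eps <- 80
  blob <- function(cx, cy) cbind(rnorm(50, cx, 30), rnorm(50, cy, 30))
  pts <- rbind(blob(500, 500), blob(500 + 5 * eps + 200, 500))
  tb <- data.frame(x_nm = pts[, 1], y_nm = pts[, 2])
  out <- cluster_localisations(tb, eps, 5)
  expect_equal(max(out$cluster_id), 2)
  expect_identical(out$cluster_id, dbscan_reference(tb, eps, 5))
})

test_that("DBSCAN equals the brute-force core-graph oracle on random instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(30:300, 1)
    tb <- data.frame(x_nm = runif(n, 0, 2000), y_nm = runif(n, 0, 2000))
    eps <- runif(1, 40, 250)
    mp <- sample(2:12, 1)
    expect_identical(cluster_localisations(tb, eps, mp)$cluster_id,
                     dbscan_reference(tb, eps, mp),
                     info = sprintf("seed %d", s))
  }
})

test_that("a single event renders as a unit-amplitude 40 nm disc", {
  tb <- data.frame(x_nm = 490, y_nm = 490, cluster_id = 1L)
  img <- render_nn_image(tb, palm_params(), field = c(1000, 1000))
  expect_equal(max(img$data), 1, tolerance = 1e-6)   # plateau amplitude 1
  expect_equal(sum(img$data) * img$pixel_size^2, pi * 20^2,
               tolerance = 0.05)                     # disc area
})

test_that("uniform grids get near-uniform NN weights", {
  g <- expand.grid(x = seq(100, 900, by = 50), y = seq(100, 900, by = 50))
  w <- nanopsd:::nn_weights(g$x, g$y, rep(1L, nrow(g)), k = 5,
                            normalisation = "cluster")
  expect_lt(sd(w) / mean(w), 0.05)
  # brute-force oracle for one interior point: 5 nearest at distance 50
  i <- which(g$x == 500 & g$y == 500)
  d <- sqrt((g$x - g$x[i])^2 + (g$y - g$y[i])^2)
  expect_equal(mean(sort(d[-i])[1:5]), (4 * 50 + sqrt(2) * 50) / 5)
})

test_that("dense cores render brighter than sparse halos", {
  set.seed(43)
  core <- cbind(rnorm(150, 1000, 40), rnorm(150, 1000, 40))
  halo <- cbind(1000 + 350 * cos(seq(0, 2 * pi, length.out = 40)),
                1000 + 350 * sin(seq(0, 2 * pi, length.out = 40)))
  tb <- data.frame(x_nm = c(core[, 1], halo[, 1]),
                   y_nm = c(core[, 2], halo[, 2]),
                   cluster_id = 1L)
  img <- render_nn_image(tb, palm_params(), field = c(2000, 2000))
  ctr <- img$data[48:52, 48:52]
  ring <- img$data[cbind(round(halo[, 2] / 20), round(halo[, 1] / 20))]
  expect_gt(min(ctr), max(ring))
})

test_that("the PALM workflow recovers hand-built PSD geometry", {
  cfg1 <- sim_config(field_width = 3000, field_height = 3000,
                     background_rate = 0)
  sc1 <- make_spot_scene(1500, 1500, diameter = 130, field = c(3000, 3000))
  tab1 <- simulate_palm(sc1, cfg1, 47)
  rec1 <- run_palm_workflow(cluster_localisations(tab1, 100, 10))
  expect_equal(nrow(rec1$psds), 1)
  expect_equal(as.character(rec1$psds$subtype), "1NC")
  # 2-NC PSD at 250 nm separation, precision 40 nm
  sc2 <- make_scene(list(list(c(1375, 1500, 110, 110, 0, 150),
                              c(1625, 1500, 110, 110, 0, 150))),
                    field = c(3000, 3000))
  tab2 <- simulate_palm(sc2, cfg1, 49)
  rec2 <- run_palm_workflow(cluster_localisations(tab2, 100, 10))
  expect_equal(nrow(rec2$psds), 1)
  expect_equal(rec2$psds$nc_count, 2)
  # zero events -> empty output
  empty <- tab1[0, ]
  expect_equal(nrow(run_palm_workflow(empty)$psds), 0)
})

test_that("assigned localisation counts are conserved and accounted", {
  cfg <- sim_config(field_width = 6000, field_height = 6000,
                    background_rate = 2)
  sc <- sample_scene(cfg, 53)
  tab <- cluster_localisations(simulate_palm(sc, cfg, 53), 100, 10)
  rec <- run_palm_workflow(tab)
  expect_lte(rec$n_events_in_psds, rec$n_events_clustered)
  expect_equal(rec$n_events_clustered,
               rec$n_events_in_psds + rec$n_events_unassigned)
  expect_true(all(rec$psds$n_localisations >= 0))
})
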