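# Synthetic slice fixture: arcs with polar back-references, as the transect
# of a scan would carry them.
makeSlice <- function(xy, scanner = c(0, 0), z = 0) {
  pol <- cartesianToPolar(cbind(xy[, 1] - scanner[1], xy[, 2] - scanner[2],
                                rep(0.01, nrow(xy))))
  cloud <- pointCloud(cbind(xy, z),
                      polar = pol[, c("range_m", "theta_deg", "phi_deg")])
  sliceTransect(cloud, z, 0.05)
}

test_that("transect slicing keeps exactly the slab points", {
  cloud <- pointCloud(cbind(0, 0, c(1.26, 1.30, 1.40)))
  sl <- sliceTransect(cloud, 1.3, 0.05)
  expect_equal(npoints(sl@cloud), 2)
  expect_equal(coords(sl@cloud)[, 3], c(1.26, 1.30), ignore_attr = TRUE)
  empty <- sliceTransect(pointCloud(cbind(1, 1, 0)), 1.3, 0.05)
  expect_equal(npoints(empty@cloud), 0)
  expect_error(sliceTransect(cloud, 1.3, 0), "positive")
  # brute-force count on a random cloud
  set.seed(9)
  pts <- matrix(runif(600, -2, 2), ncol = 3)
  sl2 <- sliceTransect(pointCloud(pts), 0.4, 0.1)
  expect_equal(npoints(sl2@cloud), sum(abs(pts[, 3] - 0.4) <= 0.1))
})

test_that("the clustering threshold is the scaled max of adjacent spacings", {
  expect_equal(clusterThreshold(0.02, 0.03, 1.5), 0.045)
  expect_equal(clusterThreshold(0, 0, 1.5), 0)
  expect_error(clusterThreshold(-0.1, 0, 1.5), ">= 0")
  set.seed(2)
  a <- runif(50); b <- runif(50)
  expect_equal(clusterThreshold(a, b, 1.5),
               1.5 * vapply(seq_len(50), function(i) max(a[i], b[i]),
                            numeric(1)))
})

test_that("transect clustering matches the O(n^2) union-find oracle", {
  params <- clusterParams(delta_theta = 0.5, delta_phi = 0.25,
                          min_cluster_size = 5)
  set.seed(21)
  for (rep in 1:5) {
    # a few arcs plus scattered noise, <= 200 points
    xy <- rbind(
      circlePoints(60, c(4, 1), 0.07, arc = c(2.5, 3.9)),
      circlePoints(60, c(2.5, -2), 0.05, arc = c(1.4, 2.9)),
      matrix(runif(40, -5, 5), ncol = 2))
    sl <- makeSlice(xy)
    got <- clusterTransect(sl, params)
    memb <- integer(nrow(xy))
    for (ci in seq_along(got$clusters)) memb[got$clusters[[ci]]] <- ci
    pol <- polarRecords(sl@cloud)
    want <- oracleCluster(coords(sl@cloud)[, 1:2], pol$range_m,
                          params$delta_phi, params$delta_theta, params$k)
    expect_true(samePartition(memb, want))
    # partition property: disjoint and exhaustive
    expect_equal(sort(unlist(got$clusters)), seq_len(nrow(xy)))
    # permutation invariance
    perm <- sample(nrow(xy))
    sl_p <- makeSlice(xy[perm, ])
    got_p <- clusterTransect(sl_p, params)
    memb_p <- integer(nrow(xy))
    for (ci in seq_along(got_p$clusters)) memb_p[got_p$clusters[[ci]]] <- ci
    expect_true(samePartition(memb[perm], memb_p))
  }
})

test_that("two separate stem arcs form two clusters, one arc one", {
  params <- clusterParams(delta_theta = 0.5, delta_phi = 0.1)
  two <- rbind(circlePoints(40, c(5, 0), 0.06, arc = c(pi - 0.7, pi + 0.7)),
               circlePoints(40, c(5, 1.5), 0.06, arc = c(pi - 0.7, pi + 0.7)))
  got <- clusterTransect(makeSlice(two), params)
  expect_equal(sum(!got$small), 2)
  one <- circlePoints(50, c(5, 0), 0.06, arc = c(pi - 0.8, pi + 0.8))
  got1 <- clusterTransect(makeSlice(one), params)
  expect_equal(length(got1$clusters), 1)
  expect_error(clusterTransect(
    new("TransectSlice", cloud = pointCloud(cbind(two, 0)),
        slice_center_z = 0, half_thickness = 0.05), params),
    "back-references")
})

test_that("detectTrunks accepts true stems and audits rejections", {
  # 16-stem plantation-like grid; the rows are staggered so no stem sits in
  # another's shadow as seen from the plot-center scan position
  grid <- expand.grid(x = c(-4.2, -1.4, 1.4, 4.2),
                      y = c(-3.9, -1.1, 1.7, 4.5))
  set.seed(4)
  plt <- makeStemPlot(data.frame(grid, dbh_m = runif(16, 0.08, 0.16),
                                 height_m = runif(16, 7, 9)))
  cfg <- scannerConfig(delta_phi = 0.1, delta_theta = 0.5,
                       range_accuracy_sigma = 0, strict_steps = FALSE)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  cloud <- buildCloud(s$records, cfg)
  cand <- detectTrunks(cloud, clusterParams(cfg), slice_z = 1.3 - 1.5)
  acc <- cand[cand$status == "accepted", ]
  expect_equal(nrow(acc), 16)
  m <- matchTrees(acc[, c("center_x", "center_y")], plt@stems[, c("x", "y")],
                  0.3)
  expect_equal(m$n_correct, 16)
  expect_equal(max(abs(200 * 0.5 * acc$diameter_m[m$pairs$est] -
                       100 * plt@stems$dbh_m[m$pairs$ref])), 0,
               tolerance = 0.15)
})

test_that("implausible fitted diameters and degenerate clusters are rejected", {
  params <- clusterParams(delta_theta = 0.5, delta_phi = 0.25)
  # an arc subtending ~15 degrees of a large circle: the fitted diameter is
  # far above any plausible stem
  arc <- circlePoints(150, c(30, 0), 25, arc = c(pi - 0.13, pi))
  cand <- detectTrunks(pointCloud(cbind(arc, 0),
                                  polar = cartesianToPolar(cbind(arc, 0.01))[,
                                    c("range_m", "theta_deg", "phi_deg")]),
                       params, slice_z = 0)
  expect_true(all(cand$status %in% c("rejected_diameter", "rejected_size")))
  expect_true(any(cand$status == "rejected_diameter"))
  expect_gt(cand$diameter_m[cand$status == "rejected_diameter"][1], 0.30)

  # collinear noise: degenerate circle fit path
  line <- cbind(seq(3, 3.3, length.out = 20), seq(0, 0.003, length.out = 20))
  cand2 <- detectTrunks(pointCloud(cbind(line, 0),
                                   polar = cartesianToPolar(cbind(line, 0.01))[,
                                     c("range_m", "theta_deg", "phi_deg")]),
                        params, slice_z = 0)
  expect_true(all(cand2$status != "accepted"))
  expect_true("rejected_degenerate" %in% cand2$status)
})

test_that("a ground-only scene yields no trunk candidates", {
  plt <- makeStemPlot(data.frame(x = numeric(), y = numeric(),
                                 dbh_m = numeric(), height_m = numeric()))
  cfg <- scannerConfig(delta_phi = 2, delta_theta = 1,
                       range_accuracy_sigma = 0.012, strict_steps = FALSE)
  s <- simulateScan(plt, cfg, seed = 8)
  rep <- processPlot(s$records, cfg, scanner_height = 1.5, seed = 8,
                     verbose = FALSE)
  expect_equal(nrow(rep), 0)
})
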