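test_that("the top window keeps points within 0.5 m of the highest", {
  st <- extractTop(cbind(0, 0, c(8.0, 7.8, 7.4)))
  expect_equal(st$M, 2)
  expect_equal(st$z_max, 8.0)
  one <- extractTop(cbind(1, 2, 5))
  expect_equal(one$M, 1)
  expect_error(extractTop(matrix(numeric(), ncol = 3)), "empty")
  set.seed(8)
  crown <- cbind(runif(200), runif(200), runif(200, 6, 9))
  stc <- extractTop(crown)
  expect_equal(stc$M, sum(abs(max(crown[, 3]) - crown[, 3]) < 0.5))
})

test_that("KNN mean distances match hand calculation and the oracle", {
  # three collinear points at unit spacing, k = 2:
  # middle {1,1} -> 1; ends {1,2} -> 1.5; grand mean 4/3
  coll <- cbind(c(0, 1, 2), 0, 0)
  st <- knnMeanDistances(extractTop(coll, window = 10), k_neighbors = 2)
  expect_equal(sort(st$md_i), c(1, 1.5, 1.5))
  expect_equal(st$md, 4 / 3)

  same <- knnMeanDistances(extractTop(cbind(rep(1, 5), 1, 1), window = 1))
  expect_equal(same$md_i, rep(0, 5))
  expect_equal(same$md, 0)

  set.seed(19)
  pts <- matrix(runif(150, 0, 2), ncol = 3)
  for (k in c(3, 10, 60)) {
    st2 <- knnMeanDistances(list(points = pts, M = nrow(pts)), k_neighbors = k)
    expect_equal(st2$md_i, oracleKnnMeans(pts, k))
    expect_equal(st2$md, mean(st2$md_i))
    expect_equal(st2$k_used, min(k, nrow(pts) - 1))
  }
})

test_that("the top filter separates tree points from a sparse spur", {
  set.seed(23)
  tight <- cbind(rnorm(11, 0, 0.05), rnorm(11, 0, 0.05),
                 rnorm(11, 7.9, 0.05))
  spur <- c(0.05, -0.02, max(tight[, 3]) + 0.4)
  st <- knnMeanDistances(extractTop(rbind(tight, spur), window = 0.6))
  ft <- filterTop(st)
  expect_equal(ft$outlier_idx, 12L)            # the spur
  expect_false(12L %in% ft$tree_idx)
  expect_equal(ft$p_top[3], max(tight[, 3]))   # top of the tight crown
  # mean bounds guarantee a non-empty tree set
  expect_gte(st$md, min(st$md_i))
  expect_lte(st$md, max(st$md_i))
})

test_that("the equality branch keeps a uniform arrangement intact", {
  # equally spaced points with k = 1: every md_i equals the grand mean
  line <- cbind(seq(0, 9), 0, 5)
  stl <- knnMeanDistances(list(points = line, M = 10), k_neighbors = 1)
  expect_equal(stl$md_i, rep(1, 10))
  ftl <- filterTop(stl)
  expect_equal(ftl$tree_idx, 1:10)             # md_i == md keeps everything
  expect_equal(length(ftl$outlier_idx), 0)

  single <- filterTop(extractTop(cbind(3, 4, 5)))
  expect_equal(single$p_top, c(3, 4, 5))
})

test_that("height estimation is the vertical distance, clamped at zero", {
  expect_equal(estimateHeight(c(0, 0, 8.43), c(0, 0, 0))$height_m, 8.43)
  expect_equal(estimateHeight(c(1, 1, 8.0), c(2, 2, 0.2))$height_m, 7.8)
  neg <- estimateHeight(c(0, 0, -0.5), c(0, 0, 0))
  expect_equal(neg$height_m, 0)
  expect_equal(neg$flag, "negative_height_clamped")
  # invariance under rigid horizontal translation
  expect_equal(estimateHeight(c(10, -3, 8.0), c(12, -5, 0.2))$height_m, 7.8)
})

test_that("DBH re-slice recovers a noiseless stem and refines the position", {
  plt <- makeStemPlot(data.frame(x = 5, y = 0, dbh_m = 0.12, height_m = 8.4))
  cfg <- scannerConfig(delta_phi = 0.1, range_accuracy_sigma = 0)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  cloud <- buildCloud(s$records, cfg)
  # ground is flat at z = -1.5 in the cloud frame
  est <- estimateDbh(cloud, c(5, 0, -1.5))
  expect_equal(est$dbh_cm, 12, tolerance = 1e-2)
  expect_equal(circleCenter(est$circle), c(5, 0), tolerance = 1e-3)
  expect_true(is.na(est$flag))
  # the re-slice is taken 1.3 m above the zero point, wherever that is
  est_off <- estimateDbh(cloud, c(5, 0, -1.0))
  expect_true(is.na(est_off$flag))
  expect_equal(est_off$dbh_cm, 12, tolerance = 5e-2)
  miss <- estimateDbh(cloud, c(-5, 0, -1.5))
  expect_equal(miss$flag, "no_dbh")
  expect_true(is.na(miss$dbh_cm))
})

test_that("the full pipeline closes the loop on a noiseless stem", {
  plt <- makeStemPlot(data.frame(x = 5, y = 0, dbh_m = 0.12, height_m = 8.4))
  cfg <- scannerConfig(delta_phi = 0.1, range_accuracy_sigma = 0)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  rep <- processPlot(s$records, cfg, scanner_height = 1.5, seed = 7,
                     verbose = FALSE)
  expect_equal(nrow(rep), 1)
  expect_lt(abs(rep$dbh_cm - 12), 0.1)
  expect_lt(abs(rep$x_m - 5) + abs(rep$y_m), 1e-3)
  # height is discretization-limited: the top lattice row undershoots the
  # stem tip by at most the local vertical spacing
  spacing <- resolutionMetrics(cfg, sqrt(5^2 + 6.9^2))$vertical_spacing
  expect_lte(rep$height_m, 8.4 + 1e-6)
  expect_gt(rep$height_m, 8.4 - 3 * spacing)
  expect_lt(rep$ground_inclination_deg, 0.5)
})

test_that("per-tree failures are flagged without aborting the plot", {
  # a stem floating far from any ground return: ground fit must fail but the
  # tree is still reported
  arc <- circlePoints(80, c(4, 0), 0.08, arc = c(pi - 0.9, pi + 0.9))
  pts <- do.call(rbind, lapply(seq(-0.3, 0.3, by = 0.05), function(dz)
    cbind(arc, dz)))
  cloud <- pointCloud(pts, polar = cartesianToPolar(pts)[,
    c("range_m", "theta_deg", "phi_deg")])
  rep <- processPlot(cloud, scannerConfig(delta_phi = 0.25, delta_theta = 0.5,
                                          strict_steps = FALSE),
                     scanner_height = 1.3, seed = 2, verbose = FALSE)
  expect_equal(nrow(rep), 1)
  expect_true(grepl("no_ground", rep$flags))
  expect_true(is.na(rep$height_m))
  expect_equal(rep$dbh_cm, 16, tolerance = 0.5)
})
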