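# Coarse lattices keep these scans fast; the geometry being checked is
# step-size independent.
coarseConfig <- function(dphi = 1, dtheta = 0.5, sigma = 0) {
  scannerConfig(delta_theta = dtheta, delta_phi = dphi,
                range_accuracy_sigma = sigma)
}

test_that("plot generation follows the planting grid arithmetic", {
  p <- generatePlot(extent = 10, spacing_ns = 1.6, spacing_we = 2.8,
                    vacancy_prob = 0, seed = 3)
  expect_equal(nrow(p@stems), floor(10 / 1.6) * floor(10 / 2.8))
  expect_true(all(abs(p@stems$x) <= 5 & abs(p@stems$y) <= 5))
  expect_true(all(p@stems$dbh_m > 0 & p@stems$height_m > 0))

  none <- generatePlot(vacancy_prob = 1, seed = 3)
  expect_equal(nrow(none@stems), 0)
  expect_error(generatePlot(extent = 1), "smaller than one planting cell")
  expect_error(generatePlot(vacancy_prob = 2), "vacancy_prob")
})

test_that("plot generation is deterministic and vacancy-monotone", {
  a <- generatePlot(seed = 11)
  b <- generatePlot(seed = 11)
  expect_identical(a@stems, b@stems)
  expect_identical(a@crown, b@crown)
  # raising the vacancy probability only removes stems
  probs <- c(0, 0.1, 0.3, 0.6, 1)
  counts <- vapply(probs, function(v)
    nrow(generatePlot(vacancy_prob = v, seed = 11)@stems), numeric(1))
  expect_true(all(diff(counts) <= 0))
  sub <- generatePlot(vacancy_prob = 0.3, seed = 11)
  full <- generatePlot(vacancy_prob = 0, seed = 11)
  expect_true(all(sub@stems$id %in% full@stems$id))
  surv <- full@stems[match(sub@stems$id, full@stems$id), ]
  rownames(surv) <- NULL
  expect_identical(sub@stems, surv)
})

test_that("noiseless stem returns match the analytic ray-cylinder oracle", {
  plt <- makeStemPlot(data.frame(x = 5, y = 0, dbh_m = 0.12, height_m = 8.4))
  cfg <- coarseConfig(dphi = 0.25, dtheta = 0.5)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  df <- as.data.frame(s$records)
  stem <- df[s$labels == "stem", ]
  expect_gt(nrow(stem), 50)
  for (i in seq_len(nrow(stem))) {
    t_oracle <- oracleCylinderRange(c(0, 0, 1.5), stem$theta_deg[i],
                                    stem$phi_deg[i], c(5, 0), 0.06, 0, 8.4)
    expect_equal(stem$range_m[i], t_oracle, tolerance = 1e-9)
  }
})

test_that("ground returns lie on the ground surface", {
  plt <- makeStemPlot(data.frame(x = 5, y = 0, dbh_m = 0.12, height_m = 8.4),
                      ground = groundModel("tilted", z0 = -0.1,
                                           slope_x = 0.05, slope_y = -0.02))
  cfg <- coarseConfig(dphi = 2, dtheta = 1)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  cloud <- buildCloud(s$records, cfg)
  g <- coords(cloud)[s$labels == "ground", , drop = FALSE]
  expect_gt(nrow(g), 500)
  # cloud frame is the plot frame shifted by the scanner position
  zg <- groundHeight(plt@ground, g[, 1], g[, 2]) - 1.5
  expect_equal(g[, 3], zg, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("first-return occlusion shadows a stem hidden behind another", {
  near <- data.frame(x = c(3, 6), y = c(0, 0),
                     dbh_m = c(0.2, 0.2), height_m = c(8, 8))
  plt <- makeStemPlot(near, extent = 14)
  cfg <- coarseConfig(dphi = 0.25, dtheta = 0.5)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  df <- as.data.frame(s$records)
  stem <- df[s$labels == "stem", ]
  # the far stem's near surface sits at 5.9 m; every return on the shared
  # azimuth corridor must come from the near stem (range < 3.2 m)
  hidden_half <- asin(0.1 / 6) * 180 / pi   # far stem's angular half width
  corridor <- stem[abs(stem$phi_deg) < hidden_half |
                   abs(stem$phi_deg - 360) < hidden_half, ]
  expect_gt(nrow(corridor), 0)
  horiz <- corridor$range_m * abs(cos(corridor$theta_deg * pi / 180))
  expect_true(all(horiz < 3.2))
  # no recorded range undercuts the nearest analytic intersection
  for (i in seq_len(nrow(stem))) {
    t1 <- oracleCylinderRange(c(0, 0, 1.5), stem$theta_deg[i],
                              stem$phi_deg[i], c(3, 0), 0.1, 0, 8)
    t2 <- oracleCylinderRange(c(0, 0, 1.5), stem$theta_deg[i],
                              stem$phi_deg[i], c(6, 0), 0.1, 0, 8)
    expect_equal(stem$range_m[i], min(t1, t2), tolerance = 1e-9)
  }
})

test_that("range noise and range limits are applied to the records", {
  plt <- makeStemPlot(data.frame(x = 2, y = 0, dbh_m = 0.15, height_m = 8))
  cfg <- coarseConfig(dphi = 1, dtheta = 0.5, sigma = 0.012)
  a <- simulateScan(plt, cfg, seed = 5)
  b <- simulateScan(plt, cfg, seed = 5)
  c <- simulateScan(plt, cfg, seed = 6)
  expect_identical(as.data.frame(a$records), as.data.frame(b$records))
  expect_false(identical(as.data.frame(a$records)$range_m,
                         as.data.frame(c$records)$range_m))
  clean <- simulateScan(plt, cfg, noise = FALSE)
  expect_true(all(as.data.frame(clean$records)$range_m >= cfg@range_min))
  expect_true(all(as.data.frame(clean$records)$range_m <= cfg@range_max))
  # noiseless ranges differ from noisy ones by a few sigma at most
  expect_lt(max(abs(sort(as.data.frame(a$records)$range_m) -
                    sort(as.data.frame(clean$records)$range_m))), 0.2)
})

test_that("the scan-to-circle-fit closed loop recovers a stem radius", {
  plt <- makeStemPlot(data.frame(x = 5, y = 0, dbh_m = 0.12, height_m = 8.4))
  cfg <- scannerConfig(delta_phi = 0.1, range_accuracy_sigma = 0)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.5), noise = FALSE)
  cloud <- buildCloud(s$records, cfg)
  slice <- sliceTransect(cloud, 1.3 - 1.5, 0.05)
  fit <- fitCirclePratt(coords(slice@cloud)[, 1:2])
  expect_lt(abs(circleRadius(fit) - 0.06), 1e-3)
  expect_equal(circleCenter(fit), c(5, 0), tolerance = 1e-3)
})

test_that("reference tables serialize the ground truth", {
  plt <- makeStemPlot(data.frame(x = 1.2, y = -0.8, dbh_m = 0.1211,
                                 height_m = 8.43))
  tab <- referenceTable(plt)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$dbh_cm, 12.11)
  expect_equal(tab$height_m, 8.43)
  f <- withr::local_tempfile(fileext = ".csv")
  writeReferenceTable(tab, f)
  expect_equal(readReferenceTable(f), tab, tolerance = 1e-6)
})

test_that("undulating ground intersections match the surface", {
  g <- groundModel("undulating", amplitude = 0.4, wavelength = 6)
  plt <- makeStemPlot(data.frame(x = 3, y = 0, dbh_m = 0.15, height_m = 8),
                      extent = 10, ground = g)
  cfg <- coarseConfig(dphi = 4, dtheta = 1)
  s <- simulateScan(plt, cfg, scanner_pos = c(0, 0, 1.8), noise = FALSE)
  cloud <- buildCloud(s$records, cfg)
  gpts <- coords(cloud)[s$labels == "ground", , drop = FALSE]
  expect_gt(nrow(gpts), 200)
  zg <- groundHeight(g, gpts[, 1], gpts[, 2]) - 1.8
  expect_equal(gpts[, 3], zg, tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("empty scenes still produce ground-only scans", {
  plt <- makeStemPlot(data.frame(x = numeric(), y = numeric(),
                                 dbh_m = numeric(), height_m = numeric()))
  cfg <- coarseConfig(dphi = 4, dtheta = 1)
  s <- simulateScan(plt, cfg, noise = FALSE)
  expect_true(all(s$labels == "ground"))
  expect_equal(nrow(s$truth), 0)
  expect_error(simulateScan(plt, cfg, scanner_pos = c(0, 0, -1)),
               "above the local ground")
})
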