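# Per-tree estimates: DBH from a re-slice at 1.3 m above the local zero
# point, position as the refined circle center projected onto the ground
# plane, and total height from the KNN top filter — the mean 10-neighbor
# distance of each point in the 0.5 m top window separates tree points from
# sparse outliers, and the height is the vertical distance from the highest
# surviving point to p_zero.

#' Estimate DBH by re-slicing at breast height
#'
#' Slices the cloud at z(p_zero) + 1.3 m (+- `half_thickness`), restricted to
#' the tree's cylinder, and fits the slice with the chosen circle method
#' (Pratt by default). The fitted center is the refined tree position.
#'
#' @param cloud a [PointCloud-class].
#' @param p_zero local zero-height point `c(x, y, z)`.
#' @param half_thickness re-slice half thickness, meters.
#' @param cylinder_diameter restricting cylinder diameter, meters.
#' @param fit_method `"pratt"`, `"taubin"` or `"gauss-newton"`.
#' @param min_points minimal number of slice points for a fit.
#' @param breast_height breast height above the local zero point, meters.
#' @return list with `dbh_cm`, `circle` (a [CircleModel-class]) and `flag`
#'   (`NA` or `"no_dbh"` when the slice is too small or degenerate).
#' @export
estimateDbh <- function(cloud, p_zero, half_thickness = 0.05,
                        cylinder_diameter = 0.8,
                        fit_method = c("pratt", "taubin", "gauss-newton"),
                        min_points = 10, breast_height = 1.3) {
  fit_method <- match.arg(fit_method)
  nb <- extractCylinder(cloud, p_zero[1:2], cylinder_diameter)
  slice <- sliceTransect(nb, p_zero[3] + breast_height, half_thickness)
  xy <- coords(slice@cloud)[, 1:2, drop = FALSE]
  if (nrow(xy) < min_points)
    return(list(dbh_cm = NA_real_, circle = NULL, flag = "no_dbh"))
  fit <- tryCatch(switch(fit_method,
                         pratt = fitCirclePratt(xy),
                         taubin = fitCircleTaubin(xy),
                         "gauss-newton" = fitCircleGaussNewton(xy)),
                  error = function(e) NULL)
  if (is.null(fit))
    return(list(dbh_cm = NA_real_, circle = NULL, flag = "no_dbh"))
  list(dbh_cm = 200 * fit@radius, circle = fit, flag = NA_character_)
}

#' Extract the tree-top window
#'
#' The set V_top of points whose z lies within `window` (0.5 m) of the
#' highest point of the tree cylinder.
#'
#' @param points n x 3 matrix or [PointCloud-class] (the tree cylinder).
#' @param window top window depth, meters.
#' @return list (top-filter state): `points` (matrix), `M` (count),
#'   `z_max`.
#' @export
extractTop <- function(points, window = 0.5) {
  pts <- if (is(points, "PointCloud")) coords(points) else as.matrix(points)
  if (!nrow(pts)) stop("empty tree cylinder: no top window")
  z_max <- max(pts[, 3])
  v <- pts[abs(z_max - pts[, 3]) < window, , drop = FALSE]
  list(points = v, M = nrow(v), z_max = z_max)
}

#' Mean k-nearest-neighbor distances in the top window
#'
#' For each point p_i of V_top, the distances d_i1..d_ik to its k nearest
#' neighbors, their mean md_i, and the grand mean md over all points. With
#' `M <= k` points the k is reduced to M - 1; a single point passes through
#' untouched (it will be p_top).
#'
#' @param state a top-filter state from [extractTop()].
#' @param k_neighbors number of neighbors (10 by default).
#' @return the state augmented with `md_i` (length M), `md`, `k_used`.
#' @export
knnMeanDistances <- function(state, k_neighbors = 10) {
  M <- state$M
  if (M == 1) {
    state$md_i <- 0; state$md <- 0; state$k_used <- 0L
    return(state)
  }
  k <- min(k_neighbors, M - 1)
  dm <- as.matrix(stats::dist(state$points))
  md_i <- vapply(seq_len(M), function(i) {
    mean(sort(dm[i, -i], partial = k)[seq_len(k)])
  }, numeric(1))
  state$md_i <- md_i
  state$md <- mean(md_i)
  state$k_used <- as.integer(k)
  state
}

#' Partition the top window into tree points and outliers
#'
#' A point is a tree point when its mean neighbor distance md_i is less than
#' or equal to the grand mean md; otherwise it is an outlier (sparse twig or
#' noise). p_top is the highest tree point; ties on z are broken by input
#' order. Because min(md_i) <= md the tree-point set is never empty.
#'
#' @param state a state from [knnMeanDistances()].
#' @return list with `tree_idx`, `outlier_idx` (indices into the state's
#'   points) and `p_top` (`c(x, y, z)`).
#' @export
filterTop <- function(state) {
  if (state$M == 1) {
    return(list(tree_idx = 1L, outlier_idx = integer(),
                p_top = as.numeric(state$points[1, ])))
  }
  if (is.null(state$md_i)) stop("apply knnMeanDistances() first")
  tree <- which(state$md_i <= state$md)
  stopifnot(length(tree) > 0)
  z <- state$points[tree, 3]
  top <- tree[which.max(z)]  # which.max keeps the first occurrence on ties
  list(tree_idx = tree, outlier_idx = setdiff(seq_len(state$M), tree),
       p_top = as.numeric(state$points[top, ]))
}

#' Tree height from the top and zero points
#'
#' The vertical distance z(p_top) - z(p_zero), clamped at zero (a negative
#' value is reported as 0 with a quality flag).
#'
#' @param p_top,p_zero points `c(x, y, z)`.
#' @return list with `height_m` and `flag` (`NA` or
#'   `"negative_height_clamped"`).
#' @export
estimateHeight <- function(p_top, p_zero) {
  h <- p_top[3] - p_zero[3]
  if (h < 0) list(height_m = 0, flag = "negative_height_clamped")
  else list(height_m = h, flag = NA_character_)
}

#' Run the full single-scan pipeline on one plot
#'
#' Builds the cloud, detects trunks at breast height, and for each accepted
#' candidate fits the local ground plane, re-slices for DBH, refines the
#' position and runs the top filter for height. Per-tree failures are
#' flagged, never fatal for the plot.
#'
#' @param records a [ScanRecords-class] (or data.frame) or an already-built
#'   [PointCloud-class].
#' @param config a [ScannerConfig-class].
#' @param scanner_height height of the scanner above the local ground,
#'   meters; places the initial breast-height slice at
#'   `1.3 - scanner_height` in the cloud frame.
#' @param params a [clusterParams()] list.
#' @param half_thickness transect half thickness, meters.
#' @param tree_cyl_diameter cylinder for DBH re-slice and height, meters.
#' @param ground_cyl_diameter cylinder for ground extraction, meters.
#' @param slab_thickness ground slab thickness, meters.
#' @param inlier_tol,ransac_iters,min_inlier_frac RANSAC settings.
#' @param top_window top window depth, meters.
#' @param k_neighbors top-filter neighbor count.
#' @param fit_method circle fit used for the DBH re-slice.
#' @param steep_flag_deg ground inclination above which the tree is flagged.
#' @param seed integer seed driving the per-tree RANSAC draws.
#' @param verbose log per-stage counts with `message()`.
#' @return data.frame (tree report): `id`, `x_m`, `y_m`, `dbh_cm`,
#'   `height_m`, `ground_inclination_deg`, `n_points`, `rms_m`, `flags`.
#' @export
processPlot <- function(records, config = scannerConfig(),
                        scanner_height = 1.5,
                        params = clusterParams(config),
                        half_thickness = 0.05,
                        tree_cyl_diameter = 0.8, ground_cyl_diameter = 0.6,
                        slab_thickness = 0.10,
                        inlier_tol = 0.02, ransac_iters = 200,
                        min_inlier_frac = 0.5,
                        top_window = 0.5, k_neighbors = 10,
                        fit_method = "pratt", steep_flag_deg = 10,
                        seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cloud <- if (is(records, "PointCloud")) records
           else buildCloud(records, config)
  say("cloud: %d points", npoints(cloud))

  slice_z <- 1.3 - scanner_height
  cand <- detectTrunks(cloud, params, slice_z, half_thickness)
  acc <- which(cand$status == "accepted")
  say("transect at z = %.2f m: %d clusters, %d accepted candidates",
      slice_z, nrow(cand), length(acc))

  empty <- data.frame(id = integer(), x_m = numeric(), y_m = numeric(),
                      dbh_cm = numeric(), height_m = numeric(),
                      ground_inclination_deg = numeric(),
                      n_points = integer(), rms_m = numeric(),
                      flags = character())
  if (!length(acc)) return(empty)

  rows <- vector("list", length(acc))
  for (t in seq_along(acc)) {
    i <- acc[t]
    ctr <- c(cand$center_x[i], cand$center_y[i])
    flags <- character()
    incl <- NA_real_

    # local ground plane from the lowest slab of the 0.6 m cylinder
    plane <- NULL
    nb_ground <- extractCylinder(cloud, ctr, ground_cyl_diameter)
    if (npoints(nb_ground) >= 3) {
      slab <- extractGroundSlab(nb_ground, slab_thickness)
      plane <- tryCatch(
        fitPlaneRansac(slab, inlier_tol, ransac_iters, min_inlier_frac,
                       seed = seed + t),
        error = function(e) NULL)
    }
    if (is.null(plane)) {
      flags <- c(flags, "no_ground")
      rows[[t]] <- data.frame(id = t, x_m = ctr[1], y_m = ctr[2],
                              dbh_cm = 100 * cand$diameter_m[i],
                              height_m = NA_real_,
                              ground_inclination_deg = NA_real_,
                              n_points = cand$n_points[i],
                              rms_m = cand$rms_m[i],
                              flags = paste(flags, collapse = ";"))
      next
    }
    incl <- plane@inclination_deg
    if (incl > steep_flag_deg) flags <- c(flags, "steep_ground")
    p_zero <- tryCatch(projectZeroPoint(plane, ctr), error = function(e) NULL)
    if (is.null(p_zero)) {
      flags <- c(flags, "no_ground")
      p_zero <- c(ctr, NA_real_)
    }

    # DBH re-slice at the confirmed breast height; refined position
    dbh <- list(dbh_cm = 100 * cand$diameter_m[i], circle = NULL,
                flag = "no_dbh")
    if (is.finite(p_zero[3])) {
      dbh <- estimateDbh(cloud, p_zero, half_thickness, tree_cyl_diameter,
                         fit_method)
    }
    if (!is.na(dbh$flag)) {
      flags <- c(flags, dbh$flag)
      dbh$dbh_cm <- 100 * cand$diameter_m[i]   # fall back to detection fit
      pos <- ctr
      rms <- cand$rms_m[i]
      n_pts <- cand$n_points[i]
    } else {
      pos <- dbh$circle@center
      rms <- dbh$circle@rms_residual
      n_pts <- dbh$circle@n_points
      p_zero <- tryCatch(projectZeroPoint(plane, pos),
                         error = function(e) p_zero)
    }

    # height via the top filter in the tree cylinder
    height <- NA_real_
    if (is.finite(p_zero[3])) {
      nb_tree <- extractCylinder(cloud, pos, tree_cyl_diameter)
      if (npoints(nb_tree)) {
        st <- knnMeanDistances(extractTop(nb_tree, top_window), k_neighbors)
        ft <- filterTop(st)
        est <- estimateHeight(ft$p_top, p_zero)
        height <- est$height_m
        if (!is.na(est$flag)) flags <- c(flags, est$flag)
      } else {
        flags <- c(flags, "no_height")
      }
    } else {
      flags <- c(flags, "no_height")
    }

    rows[[t]] <- data.frame(id = t, x_m = pos[1], y_m = pos[2],
                            dbh_cm = dbh$dbh_cm, height_m = height,
                            ground_inclination_deg = incl,
                            n_points = n_pts, rms_m = rms,
                            flags = paste(flags, collapse = ";"))
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  say("trees: %d reported, %d with DBH, %d with height",
      nrow(report), sum(is.finite(report$dbh_cm)),
      sum(is.finite(report$height_m)))
  report
}
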