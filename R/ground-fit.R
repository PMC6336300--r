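# Per-tree local ground: extract the cylinder of points around a detected
# trunk, take the lowest ~10 cm slab (ground returns plus the trunk bottom),
# fit a plane with RANSAC, and project the stem center onto it to define the
# local zero-height point. No plot-wide DTM is built: the local plane is
# cheaper and sufficient on the gentle terrain the method targets.

#' Extract a vertical cylinder of points around a plan position
#'
#' @param cloud a [PointCloud-class] (or n x 3 matrix).
#' @param center_xy plan center `c(x, y)`, meters.
#' @param diameter cylinder diameter, meters (> 0); 0.8 m around a stem for
#'   height estimation, 0.6 m for ground extraction.
#' @return A [PointCloud-class] with the contained points (possibly empty).
#' @export
extractCylinder <- function(cloud, center_xy, diameter = 0.8) {
  if (diameter <= 0) stop("diameter must be positive")
  if (!is(cloud, "PointCloud")) cloud <- pointCloud(cloud)
  xy <- coords(cloud)[, 1:2, drop = FALSE]
  d2 <- (xy[, 1] - center_xy[1])^2 + (xy[, 2] - center_xy[2])^2
  cloud[d2 <= (diameter / 2)^2]
}

#' Extract the lowest slab of a neighborhood
#'
#' Points with z within `thickness` of the neighborhood's lowest point.
#' Around a tree this catches the ground returns plus the bottom of the
#' trunk; the trunk points are the outliers RANSAC must reject.
#'
#' @param neighborhood a [PointCloud-class] or n x 3 matrix.
#' @param thickness slab thickness, meters (> 0).
#' @return n x 3 matrix of slab points.
#' @export
extractGroundSlab <- function(neighborhood, thickness = 0.10) {
  if (thickness <= 0) stop("thickness must be positive")
  pts <- if (is(neighborhood, "PointCloud")) coords(neighborhood)
         else as.matrix(neighborhood)
  if (!nrow(pts)) stop("empty neighborhood: no ground slab")
  pts[pts[, 3] <= min(pts[, 3]) + thickness, , drop = FALSE]
}

# orthogonal least-squares plane through a point set (total least squares)
.ls_plane <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr), nu = 0)
  nrm <- sv$v[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  list(normal = nrm, offset = sum(nrm * ctr))
}

#' Fit a local ground plane with RANSAC
#'
#' Repeatedly fits planes through random 3-point samples, keeps the
#' hypothesis with the largest consensus (points within `inlier_tol`
#' orthogonal distance), and refines it by orthogonal least squares on the
#' inliers. Deterministic under a fixed `seed`.
#'
#' @param points n x 3 matrix or [PointCloud-class], n >= 3.
#' @param inlier_tol inlier distance tolerance, meters.
#' @param max_iters number of random hypotheses.
#' @param min_inlier_frac minimal inlier fraction; below it a `noGround`
#'   error condition is raised (callers flag the tree and continue).
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return A [PlaneModel-class].
#' @export
fitPlaneRansac <- function(points, inlier_tol = 0.02, max_iters = 200,
                           min_inlier_frac = 0.5, seed = NULL) {
  pts <- if (is(points, "PointCloud")) coords(points) else as.matrix(points)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to fit a plane")
  .with_seed(seed, {
    best_inl <- integer()
    if (n == 3) {
      best_inl <- 1:3
    } else {
      for (it in seq_len(max_iters)) {
        s <- sample.int(n, 3)
        v1 <- pts[s[2], ] - pts[s[1], ]
        v2 <- pts[s[3], ] - pts[s[1], ]
        nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
                 v1[3] * v2[1] - v1[1] * v2[3],
                 v1[1] * v2[2] - v1[2] * v2[1])
        nl <- sqrt(sum(nrm^2))
        if (nl < 1e-12) next
        nrm <- nrm / nl
        d <- abs(pts %*% nrm - sum(nrm * pts[s[1], ]))
        inl <- which(d <= inlier_tol)
        if (length(inl) > length(best_inl)) best_inl <- inl
      }
    }
    if (length(best_inl) < max(3, ceiling(min_inlier_frac * n))) {
      stop(structure(class = c("noGround", "error", "condition"),
                     list(message = sprintf(
                       "no ground consensus: %d/%d inliers (need %.0f%%)",
                       length(best_inl), n, 100 * min_inlier_frac),
                       call = NULL)))
    }
    # refine on the consensus set, then recompute the inlier set once
    fit <- .ls_plane(pts[best_inl, , drop = FALSE])
    d <- abs(pts %*% fit$normal - fit$offset)
    inl <- which(d <= inlier_tol)
    if (length(inl) >= 3) fit <- .ls_plane(pts[inl, , drop = FALSE])
    new("PlaneModel", normal = fit$normal, offset = fit$offset,
        inliers = as.integer(inl),
        inclination_deg = .rad2deg(acos(min(1, fit$normal[3]))),
        n_points = as.integer(n))
  })
}

#' Project a plan position onto the ground plane
#'
#' The local zero-height point p_zero: the point of the fitted ground plane
#' vertically below/above the stem center. Its z defines the local zero
#' height from which breast height and tree height are measured. Planes
#' inclined more than 45 degrees are rejected as non-ground.
#'
#' @param plane a [PlaneModel-class].
#' @param center_xy plan position `c(x, y)`, meters.
#' @return numeric `c(x, y, z)` of p_zero.
#' @examples
#' # plane z = 0.1 + 0.05 x evaluated at (2, 0): z = 0.2
#' @export
projectZeroPoint <- function(plane, center_xy) {
  if (plane@inclination_deg > 45)
    stop("plane inclined ", round(plane@inclination_deg, 1),
         " degrees: rejected as non-ground")
  nrm <- plane@normal
  if (abs(nrm[3]) < 1e-9) stop("near-vertical plane: cannot project")
  z <- (plane@offset - nrm[1] * center_xy[1] - nrm[2] * center_xy[2]) / nrm[3]
  c(center_xy[1], center_xy[2], z)
}
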