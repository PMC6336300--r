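# Trunk detection by single-slice clustering: slice the cloud at breast
# height, cluster the slice with the angular-adjacency distance rule, fit
# each cluster with the Pratt method and keep the clusters whose fitted
# diameter falls inside the plausible DBH limits.

#' Transect-clustering parameters
#'
#' The clustering links two slice points when their planar distance is below
#' k times the larger of the expected lattice-adjacent spacings d_AB
#' (horizontal, step `delta_phi`) and d_AC (vertical, step `delta_theta`)
#' computed from the points' ranges. `k = 1.5` absorbs range noise and the
#' irregular trunk surface.
#'
#' @param config optional [ScannerConfig-class] supplying the angular steps.
#' @param k threshold multiplier (> 0).
#' @param delta_theta,delta_phi angular steps, degrees (taken from `config`
#'   when given).
#' @param min_cluster_size clusters smaller than this are not fitted.
#' @param dbh_min,dbh_max plausible stem diameter limits, meters.
#' @return list of class parameters used by [clusterTransect()] and
#'   [detectTrunks()].
#' @export
clusterParams <- function(config = NULL, k = 1.5,
                          delta_theta = 0.1667, delta_phi = 0.1,
                          min_cluster_size = 10,
                          dbh_min = 0.05, dbh_max = 0.30) {
  if (!is.null(config)) {
    delta_theta <- config@delta_theta
    delta_phi <- config@delta_phi
  }
  if (k <= 0) stop("k must be positive")
  if (dbh_min >= dbh_max) stop("need dbh_min < dbh_max")
  list(k = k, delta_theta = delta_theta, delta_phi = delta_phi,
       min_cluster_size = min_cluster_size,
       dbh_min = dbh_min, dbh_max = dbh_max)
}

#' Slice a horizontal transect out of a point cloud
#'
#' Keeps exactly the points with |z - center_z| <= half_thickness, together
#' with their polar back-references. The default slab is the breast-height
#' transect (1.3 m above local ground, +-5 cm) expressed in the cloud frame.
#'
#' @param cloud a [PointCloud-class].
#' @param center_z slab center height in the cloud frame, meters.
#' @param half_thickness half thickness, meters (> 0).
#' @return A [TransectSlice-class]; empty slices are allowed.
#' @export
sliceTransect <- function(cloud, center_z = 1.3, half_thickness = 0.05) {
  if (half_thickness <= 0) stop("half_thickness must be positive")
  keep <- abs(coords(cloud)[, 3] - center_z) <= half_thickness
  new("TransectSlice", cloud = cloud[keep],
      slice_center_z = center_z, half_thickness = half_thickness)
}

#' Pairwise clustering threshold
#'
#' Two points join a cluster when their distance is below
#' k * max(d_AB, d_AC), the scaled larger of the expected adjacent spacings.
#'
#' @param d_ab,d_ac expected adjacent spacings, meters (>= 0).
#' @param k threshold multiplier.
#' @return threshold distance, meters (vectorized).
#' @examples
#' clusterThreshold(0.02, 0.03, 1.5)  # 0.045
#' @export
clusterThreshold <- function(d_ab, d_ac, k) {
  if (any(d_ab < 0) || any(d_ac < 0)) stop("spacings must be >= 0")
  k * pmax(d_ab, d_ac)
}

#' Cluster a breast-height transect
#'
#' Projects the slice onto the horizontal plane and forms single-linkage
#' connected components under the adjacency rule: points i and j are linked
#' when their planar distance is below [clusterThreshold()] evaluated at the
#' expected lattice-adjacent spacings of the pair (computed with
#' [adjacentDistance()] from the mean of the two ranges and the scanner's
#' angular steps). The result is a partition of the slice; components
#' smaller than `min_cluster_size` are reported but flagged.
#'
#' @param slice a [TransectSlice-class] whose cloud carries polar
#'   back-references (ranges are required).
#' @param params a [clusterParams()] list.
#' @return list with `clusters` (list of integer index vectors into the
#'   slice, largest first) and `small` (logical, cluster below the size
#'   threshold).
#' @export
clusterTransect <- function(slice, params = clusterParams()) {
  cl <- slice@cloud
  n <- npoints(cl)
  if (n == 0) return(list(clusters = list(), small = logical()))
  pol <- polarRecords(cl)
  if (!nrow(pol)) stop("slice points carry no polar back-references; ",
                       "clustering needs the ranges")
  xy <- coords(cl)[, 1:2, drop = FALSE]
  dmat <- as.matrix(stats::dist(xy))
  rm <- outer(pol$range_m, pol$range_m, function(a, b) (a + b) / 2)
  thr <- clusterThreshold(
    adjacentDistance(rm, rm, params$delta_phi),
    adjacentDistance(rm, rm, params$delta_theta), params$k)
  adj <- dmat < thr
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(seq_len(n), comp)
  clusters <- clusters[order(-lengths(clusters))]
  names(clusters) <- NULL
  list(clusters = clusters,
       small = lengths(clusters) < params$min_cluster_size)
}

#' Detect candidate trunks in a point cloud
#'
#' Slices the breast-height transect, clusters it, fits every sufficiently
#' large cluster with the Pratt method and accepts a candidate when its
#' fitted diameter lies within the plausible DBH limits. All candidates are
#' returned with a status (`accepted`, `rejected_diameter`, `rejected_size`,
#' `rejected_degenerate`) so rejections are auditable.
#'
#' @param cloud a [PointCloud-class] with polar back-references.
#' @param params a [clusterParams()] list.
#' @param slice_z transect center height in the cloud frame, meters.
#' @param half_thickness transect half thickness, meters.
#' @return data.frame with one row per cluster: `cluster`, `n_points`,
#'   `center_x`, `center_y`, `diameter_m`, `rms_m`, `status`; the fitted
#'   [CircleModel-class]s and the point-index lists are attached as
#'   attributes `circles` and `clusters`.
#' @export
detectTrunks <- function(cloud, params = clusterParams(), slice_z = 1.3,
                         half_thickness = 0.05) {
  slice <- sliceTransect(cloud, slice_z, half_thickness)
  cls <- clusterTransect(slice, params)
  n_cl <- length(cls$clusters)
  out <- data.frame(cluster = seq_len(n_cl),
                    n_points = lengths(cls$clusters),
                    center_x = rep(NA_real_, n_cl),
                    center_y = rep(NA_real_, n_cl),
                    diameter_m = rep(NA_real_, n_cl),
                    rms_m = rep(NA_real_, n_cl),
                    status = rep("", n_cl))
  circles <- vector("list", n_cl)
  xy <- coords(slice@cloud)[, 1:2, drop = FALSE]
  for (i in seq_len(n_cl)) {
    idx <- cls$clusters[[i]]
    if (cls$small[i]) { out$status[i] <- "rejected_size"; next }
    fit <- tryCatch(fitCirclePratt(xy[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) { out$status[i] <- "rejected_degenerate"; next }
    circles[[i]] <- fit
    out$center_x[i] <- fit@center[1]
    out$center_y[i] <- fit@center[2]
    out$diameter_m[i] <- 2 * fit@radius
    out$rms_m[i] <- fit@rms_residual
    out$status[i] <- if (2 * fit@radius >= params$dbh_min &&
                         2 * fit@radius <= params$dbh_max) "accepted"
                     else "rejected_diameter"
  }
  structure(out, circles = circles, clusters = cls$clusters, slice = slice)
}
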