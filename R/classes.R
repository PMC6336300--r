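#' @import methods
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head read.csv
NULL

# ---------------------------------------------------------------------------
# ScannerConfig
# ---------------------------------------------------------------------------

#' Scanner configuration
#'
#' Angular lattice and range characteristics of the 2-D line scanner mounted
#' vertically on a rotating platform. The vertical step `delta_theta` is one
#' of the instrument's preset values; the horizontal step `delta_phi` is set
#' by the platform's rotation speed and the scan-line rate and is exposed
#' directly. The mounted vertical field of view `fov_theta` is expressed as
#' elevation from the horizontal plane; the default `c(-95, 95)` orients the
#' sensor's 190-degree window from 5 degrees past nadir to 5 degrees past
#' zenith so the ground around the tripod is visible.
#'
#' @slot delta_theta vertical angular step width, degrees.
#' @slot delta_phi horizontal angular step width, degrees.
#' @slot fov_theta length-2 numeric, mounted vertical field of view
#'   (elevation degrees, min then max).
#' @slot rotation_speed platform rotation speed, degrees per second.
#' @slot range_accuracy_sigma 1-sigma range noise, meters.
#' @slot range_min,range_max valid return range limits, meters.
#' @slot beam_divergence beam divergence, milliradians.
#' @exportClass ScannerConfig
setClass("ScannerConfig",
  representation(
    delta_theta = "numeric",
    delta_phi = "numeric",
    fov_theta = "numeric",
    rotation_speed = "numeric",
    range_accuracy_sigma = "numeric",
    range_min = "numeric",
    range_max = "numeric",
    beam_divergence = "numeric"
  )
)

setValidity("ScannerConfig", function(object) {
  msg <- character()
  if (length(object@delta_theta) != 1L || object@delta_theta <= 0)
    msg <- c(msg, "delta_theta must be a single positive number")
  if (length(object@delta_phi) != 1L || object@delta_phi <= 0)
    msg <- c(msg, "delta_phi must be a single positive number")
  if (length(object@fov_theta) != 2L || diff(object@fov_theta) <= 0)
    msg <- c(msg, "fov_theta must be an increasing length-2 interval")
  if (diff(object@fov_theta) > 360)
    msg <- c(msg, "fov_theta spans more than 360 degrees")
  if (object@range_min <= 0 || object@range_max <= object@range_min)
    msg <- c(msg, "need 0 < range_min < range_max")
  if (object@range_accuracy_sigma < 0)
    msg <- c(msg, "range_accuracy_sigma must be >= 0")
  if (object@beam_divergence < 0)
    msg <- c(msg, "beam_divergence must be >= 0")
  if (length(msg)) msg else TRUE
})

# instrument preset vertical step widths (degrees)
.instrument_theta_steps <- c(0.1667, 0.25, 0.333, 0.5, 0.667, 1)

#' Create a scanner configuration
#'
#' Defaults emulate the instrument used throughout the package: vertical step
#' 0.1667 degrees, 190 x 360 degree field of view, +-12 mm (1-sigma) range
#' accuracy, valid ranges 0.7-80 m, beam divergence 4.7 mrad, platform
#' rotation 1 degree per second.
#'
#' @param delta_theta vertical angular step width, degrees.
#' @param delta_phi horizontal angular step width, degrees.
#' @param fov_theta mounted vertical field of view (elevation degrees).
#' @param rotation_speed platform rotation speed, degrees/second.
#' @param range_accuracy_sigma 1-sigma Gaussian range noise, meters.
#' @param range_min,range_max valid return range, meters.
#' @param beam_divergence beam divergence, milliradians.
#' @param strict_steps if `TRUE` (default), `delta_theta` must be one of the
#'   instrument's preset step widths (to within 1e-3 degrees).
#' @return A [ScannerConfig-class] object.
#' @examples
#' cfg <- scannerConfig(delta_phi = 0.5)
#' resolutionMetrics(cfg, 10)
#' @export
scannerConfig <- function(delta_theta = 0.1667,
                          delta_phi = 0.1,
                          fov_theta = c(-95, 95),
                          rotation_speed = 1,
                          range_accuracy_sigma = 0.012,
                          range_min = 0.7,
                          range_max = 80,
                          beam_divergence = 4.7,
                          strict_steps = TRUE) {
  if (strict_steps &&
      min(abs(delta_theta - .instrument_theta_steps)) > 1e-3) {
    stop("delta_theta ", delta_theta, " is not an instrument preset (",
         paste(.instrument_theta_steps, collapse = ", "),
         "); use strict_steps = FALSE for free values")
  }
  new("ScannerConfig",
      delta_theta = delta_theta, delta_phi = delta_phi,
      fov_theta = as.numeric(fov_theta), rotation_speed = rotation_speed,
      range_accuracy_sigma = range_accuracy_sigma,
      range_min = range_min, range_max = range_max,
      beam_divergence = beam_divergence)
}

setMethod("show", "ScannerConfig", function(object) {
  cat("ScannerConfig\n")
  cat(sprintf("  angular steps : %.4f deg (vertical) x %.4f deg (horizontal)\n",
              object@delta_theta, object@delta_phi))
  cat(sprintf("  vertical FOV  : [%.1f, %.1f] deg elevation\n",
              object@fov_theta[1], object@fov_theta[2]))
  cat(sprintf("  range         : %.2f-%.1f m, sigma %.0f mm\n",
              object@range_min, object@range_max,
              1000 * object@range_accuracy_sigma))
  cat(sprintf("  beam divergence: %.2f mrad\n", object@beam_divergence))
})

# ---------------------------------------------------------------------------
# ScanRecords
# ---------------------------------------------------------------------------

#' Raw polar scan records
#'
#' One row per laser return: horizontal angle `phi_deg` in [0, 360),
#' vertical (elevation) angle `theta_deg`, slant range `range_m` and a
#' non-negative `intensity`. This is the on-disk CSV dialect of the raw data
#' (see [readScanCSV()]).
#'
#' @slot records data.frame with columns `phi_deg`, `theta_deg`, `range_m`,
#'   `intensity`.
#' @exportClass ScanRecords
setClass("ScanRecords", representation(records = "data.frame"))

.scan_columns <- c("phi_deg", "theta_deg", "range_m", "intensity")

setValidity("ScanRecords", function(object) {
  df <- object@records
  missing <- setdiff(.scan_columns, names(df))
  if (length(missing))
    return(paste("missing columns:", paste(missing, collapse = ", ")))
  if (!all(vapply(df[.scan_columns], is.numeric, logical(1))))
    return("all scan record columns must be numeric")
  TRUE
})

#' Construct scan records from a data frame
#'
#' @param df data.frame with columns `phi_deg`, `theta_deg`, `range_m`,
#'   `intensity` (`intensity` may be omitted; zero is filled in).
#' @return A [ScanRecords-class] object.
#' @export
scanRecords <- function(df) {
  if (is(df, "ScanRecords")) return(df)
  df <- as.data.frame(df)
  if (is.null(df$intensity)) df$intensity <- rep(0, nrow(df))
  new("ScanRecords", records = df[, .scan_columns, drop = FALSE])
}

#' @describeIn scanRecords number of records.
#' @param x a `ScanRecords` object.
#' @export
setMethod("length", "ScanRecords", function(x) nrow(x@records))

#' Coerce scan records to a data frame
#' @param x a `ScanRecords` object.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ScanRecords", function(x, ...) x@records)

setMethod("show", "ScanRecords", function(object) {
  cat(sprintf("ScanRecords with %d returns\n", nrow(object@records)))
  if (nrow(object@records)) {
    r <- object@records$range_m
    cat(sprintf("  range: %.3f-%.3f m\n", min(r), max(r)))
    print(head(object@records, 4))
  }
})

# ---------------------------------------------------------------------------
# PointCloud
# ---------------------------------------------------------------------------

#' Cartesian point cloud
#'
#' Points in the scanner frame (scanner at the origin, z up, x toward
#' horizontal angle zero). Each point optionally carries its intensity and a
#' back-reference to the polar record it came from, which the transect
#' clustering needs.
#'
#' @slot coords numeric matrix, n x 3, columns x/y/z in meters.
#' @slot intensity numeric vector of length n (may be length 0).
#' @slot polar data.frame with columns `range_m`, `theta_deg`, `phi_deg`
#'   (may have 0 rows when back-references are unavailable).
#' @exportClass PointCloud
setClass("PointCloud",
  representation(coords = "matrix", intensity = "numeric", polar = "data.frame")
)

setValidity("PointCloud", function(object) {
  if (ncol(object@coords) != 3) return("coords must have 3 columns")
  if (nrow(object@coords) && !all(is.finite(object@coords)))
    return("coords must be finite")
  n <- nrow(object@coords)
  if (length(object@intensity) && length(object@intensity) != n)
    return("intensity length must match the number of points")
  if (nrow(object@polar) && nrow(object@polar) != n)
    return("polar back-references must match the number of points")
  TRUE
})

#' Construct a point cloud
#'
#' @param coords n x 3 numeric matrix (x, y, z in meters).
#' @param intensity optional per-point intensity.
#' @param polar optional data.frame of polar back-references
#'   (`range_m`, `theta_deg`, `phi_deg`).
#' @return A [PointCloud-class] object.
#' @export
pointCloud <- function(coords, intensity = numeric(), polar = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    coords <- matrix(coords, ncol = 3)
  colnames(coords) <- c("x", "y", "z")
  if (is.null(polar)) polar <- data.frame()
  new("PointCloud", coords = coords, intensity = as.numeric(intensity),
      polar = as.data.frame(polar))
}

#' @rdname pointCloud
#' @param x a `PointCloud`.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname pointCloud
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname pointCloud
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname pointCloud
#' @export
setMethod("npoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname pointCloud
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname pointCloud
#' @export
setMethod("intensities", "PointCloud", function(x) x@intensity)

#' @rdname pointCloud
#' @export
setGeneric("polarRecords", function(x) standardGeneric("polarRecords"))

#' @rdname pointCloud
#' @export
setMethod("polarRecords", "PointCloud", function(x) x@polar)

#' Subset a point cloud by point index
#' @param x a `PointCloud`.
#' @param i integer or logical index of points to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  pol <- if (nrow(x@polar)) x@polar[i, , drop = FALSE] else x@polar
  int <- if (length(x@intensity)) x@intensity[i] else x@intensity
  new("PointCloud", coords = x@coords[i, , drop = FALSE],
      intensity = int, polar = pol)
})

setMethod("show", "PointCloud", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("PointCloud with %d points", n))
  cat(if (nrow(object@polar)) " (polar back-references kept)\n" else "\n")
  if (n) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  x: [%.2f, %.2f] m  y: [%.2f, %.2f] m  z: [%.2f, %.2f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

# ---------------------------------------------------------------------------
# CylindricalMap
# ---------------------------------------------------------------------------

#' Cylindrical range or intensity map
#'
#' The scan projected onto the scanner's angular lattice: rows are vertical
#' angle bins, columns horizontal angle bins, and each cell holds the range
#' or intensity of the return recorded in that direction (`NA` where there
#' was no return).
#'
#' @slot values numeric matrix (theta bins x phi bins).
#' @slot theta_centers,phi_centers bin center angles, degrees.
#' @slot kind `"range"` or `"intensity"`.
#' @exportClass CylindricalMap
setClass("CylindricalMap",
  representation(values = "matrix", theta_centers = "numeric",
                 phi_centers = "numeric", kind = "character")
)

setValidity("CylindricalMap", function(object) {
  if (nrow(object@values) != length(object@theta_centers))
    return("row count must match theta_centers")
  if (ncol(object@values) != length(object@phi_centers))
    return("column count must match phi_centers")
  if (!object@kind %in% c("range", "intensity"))
    return("kind must be 'range' or 'intensity'")
  TRUE
})

#' @describeIn buildMap the map's value matrix.
#' @param x a `CylindricalMap`.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname buildMap
#' @export
setMethod("mapValues", "CylindricalMap", function(x) x@values)

setMethod("show", "CylindricalMap", function(object) {
  cat(sprintf("CylindricalMap (%s): %d x %d cells, %d filled\n",
              object@kind, nrow(object@values), ncol(object@values),
              sum(!is.na(object@values))))
})

# ---------------------------------------------------------------------------
# TransectSlice
# ---------------------------------------------------------------------------

#' Horizontal transect slice of a point cloud
#'
#' @slot cloud the sliced [PointCloud-class] (back-references preserved).
#' @slot slice_center_z slice center height, meters (cloud frame).
#' @slot half_thickness half thickness of the slice, meters.
#' @exportClass TransectSlice
setClass("TransectSlice",
  representation(cloud = "PointCloud", slice_center_z = "numeric",
                 half_thickness = "numeric")
)

setValidity("TransectSlice", function(object) {
  if (object@half_thickness <= 0) return("half_thickness must be > 0")
  z <- object@cloud@coords[, 3]
  if (length(z) &&
      any(abs(z - object@slice_center_z) > object@half_thickness + 1e-12))
    return("all slice points must lie within the slab")
  TRUE
})

setMethod("show", "TransectSlice", function(object) {
  cat(sprintf("TransectSlice at z = %.3f m (+-%.3f m): %d points\n",
              object@slice_center_z, object@half_thickness,
              nrow(object@cloud@coords)))
})

# ---------------------------------------------------------------------------
# CircleModel
# ---------------------------------------------------------------------------

#' Fitted circle
#'
#' Algebraic circle A(x^2+y^2) + Bx + Cy + D = 0 with the normalization
#' B^2 + C^2 - 4AD = 1, under which the radius is 1/(2|A|) and the center
#' (-B/2A, -C/2A). All fitters report their result in this convention.
#'
#' @slot A,B,C,D algebraic coefficients (normalized).
#' @slot center circle center (x, y), meters.
#' @slot radius circle radius, meters.
#' @slot rms_residual RMS orthogonal distance of the points, meters.
#' @slot n_points number of points used in the fit.
#' @slot method `"pratt"`, `"taubin"` or `"gauss-newton"`.
#' @slot converged `FALSE` only when an iterative fit stopped at max_iter.
#' @exportClass CircleModel
setClass("CircleModel",
  representation(A = "numeric", B = "numeric", C = "numeric", D = "numeric",
                 center = "numeric", radius = "numeric",
                 rms_residual = "numeric", n_points = "integer",
                 method = "character", converged = "logical")
)

setValidity("CircleModel", function(object) {
  if (object@radius <= 0) return("radius must be positive")
  con <- object@B^2 + object@C^2 - 4 * object@A * object@D
  if (abs(con - 1) > 1e-6)
    return("coefficients must satisfy B^2 + C^2 - 4AD = 1")
  TRUE
})

#' @rdname circleParams
#' @param x a `CircleModel`.
#' @export
setGeneric("circleCenter", function(x) standardGeneric("circleCenter"))

#' @rdname circleParams
#' @export
setMethod("circleCenter", "CircleModel", function(x) x@center)

#' @rdname circleParams
#' @export
setGeneric("circleRadius", function(x) standardGeneric("circleRadius"))

#' @rdname circleParams
#' @export
setMethod("circleRadius", "CircleModel", function(x) x@radius)

setMethod("show", "CircleModel", function(object) {
  cat(sprintf(
    "CircleModel (%s%s): center (%.4f, %.4f) m, radius %.4f m, RMS %.2f mm, n = %d\n",
    object@method, if (object@converged) "" else ", not converged",
    object@center[1], object@center[2], object@radius,
    1000 * object@rms_residual, object@n_points))
})

# ---------------------------------------------------------------------------
# PlaneModel
# ---------------------------------------------------------------------------

#' Fitted local ground plane
#'
#' Plane `normal . p = offset` with an upward unit normal. Inclination is the
#' angle between the normal and vertical, i.e. the ground slope.
#'
#' @slot normal upward unit normal (nx, ny, nz).
#' @slot offset plane offset, meters.
#' @slot inliers indices of the inlier points in the fitted set.
#' @slot inclination_deg plane inclination from horizontal, degrees.
#' @slot n_points number of points offered to the fit.
#' @exportClass PlaneModel
setClass("PlaneModel",
  representation(normal = "numeric", offset = "numeric", inliers = "integer",
                 inclination_deg = "numeric", n_points = "integer")
)

setValidity("PlaneModel", function(object) {
  if (length(object@normal) != 3) return("normal must have length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector")
  if (object@normal[3] < 0) return("normal must point upward (nz >= 0)")
  TRUE
})

#' @rdname fitPlaneRansac
#' @param x a `PlaneModel`.
#' @export
setGeneric("planeNormal", function(x) standardGeneric("planeNormal"))

#' @rdname fitPlaneRansac
#' @export
setMethod("planeNormal", "PlaneModel", function(x) x@normal)

#' @rdname fitPlaneRansac
#' @export
setGeneric("planeInclination", function(x) standardGeneric("planeInclination"))

#' @rdname fitPlaneRansac
#' @export
setMethod("planeInclination", "PlaneModel", function(x) x@inclination_deg)

#' @rdname fitPlaneRansac
#' @export
setGeneric("planeInliers", function(x) standardGeneric("planeInliers"))

#' @rdname fitPlaneRansac
#' @export
setMethod("planeInliers", "PlaneModel", function(x) x@inliers)

setMethod("show", "PlaneModel", function(object) {
  cat(sprintf(
    "PlaneModel: normal (%.3f, %.3f, %.3f), inclination %.2f deg, %d/%d inliers\n",
    object@normal[1], object@normal[2], object@normal[3],
    object@inclination_deg, length(object@inliers), object@n_points))
})

# ---------------------------------------------------------------------------
# SyntheticPlot
# ---------------------------------------------------------------------------

#' Synthetic plantation plot
#'
#' A square plot of vertical (optionally tapered) stems on a planting grid
#' with random vacancies, a ground surface, and sparse crown elements near
#' each stem top. Generated by [generatePlot()]; scanned by [simulateScan()].
#'
#' @slot extent square side length, meters (plot centered on the origin).
#' @slot stems data.frame: `id`, `x`, `y`, `dbh_m`, `height_m`, `taper`.
#' @slot ground list describing the ground surface (see [groundModel()]).
#' @slot crown data.frame of crown elements: `stem_id`, `x`, `y`, `z`,
#'   `radius` (small spheres near the stem tops).
#' @slot seed integer seed the plot was generated with.
#' @exportClass SyntheticPlot
setClass("SyntheticPlot",
  representation(extent = "numeric", stems = "data.frame", ground = "list",
                 crown = "data.frame", seed = "integer")
)

setValidity("SyntheticPlot", function(object) {
  if (object@extent <= 0) return("extent must be positive")
  st <- object@stems
  if (nrow(st)) {
    if (any(st$dbh_m <= 0)) return("all stem DBH values must be positive")
    if (any(st$height_m <= 0)) return("all stem heights must be positive")
    if (any(abs(st$x) > object@extent / 2 + 1e-9) ||
        any(abs(st$y) > object@extent / 2 + 1e-9))
      return("all stems must lie inside the plot extent")
  }
  TRUE
})

setMethod("show", "SyntheticPlot", function(object) {
  cat(sprintf("SyntheticPlot: %.1f x %.1f m, %d stems, ground '%s'\n",
              object@extent, object@extent, nrow(object@stems),
              object@ground$kind))
  if (nrow(object@stems))
    cat(sprintf("  DBH %.1f-%.1f cm, height %.1f-%.1f m, %d crown elements\n",
                100 * min(object@stems$dbh_m), 100 * max(object@stems$dbh_m),
                min(object@stems$height_m), max(object@stems$height_m),
                nrow(object@crown)))
})
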