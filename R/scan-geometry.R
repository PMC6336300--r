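# Polar/Cartesian scan geometry: the scanner sits at the origin, z points up,
# x points toward horizontal angle phi = 0, and theta is the elevation angle
# measured from the horizontal plane. Signed trigonometry makes the spherical
# conversion valid in every quadrant, including overhead sweeps (theta > 90).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Convert polar scan records to Cartesian coordinates
#'
#' x = R cos(theta) cos(phi), y = R cos(theta) sin(phi), z = R sin(theta),
#' with theta the elevation from the horizontal plane and phi the horizontal
#' angle from +x. Vectorized over records.
#'
#' @param range_m slant range(s), meters (> 0).
#' @param theta_deg elevation angle(s), degrees.
#' @param phi_deg horizontal angle(s), degrees.
#' @return n x 3 matrix with columns `x`, `y`, `z`.
#' @examples
#' polarToCartesian(10, 30, 60)  # (4.3301, 7.5, 5)
#' @export
polarToCartesian <- function(range_m, theta_deg, phi_deg) {
  if (any(!is.finite(range_m)) || any(range_m <= 0))
    stop("range_m must be finite and positive")
  th <- .deg2rad(theta_deg)
  ph <- .deg2rad(phi_deg)
  cbind(x = range_m * cos(th) * cos(ph),
        y = range_m * cos(th) * sin(ph),
        z = range_m * sin(th))
}

#' Convert Cartesian points back to polar records
#'
#' Returns the canonical polar representation with elevation between -90 and
#' 90 degrees and horizontal angle in `[0, 360)`. Directions recorded during an
#' overhead sweep (theta > 90) map to the equivalent canonical pair
#' (180 - theta, phi + 180).
#'
#' @param xyz n x 3 matrix of Cartesian coordinates, meters.
#' @return data.frame with columns `range_m`, `theta_deg`, `phi_deg`.
#' @export
cartesianToPolar <- function(xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  r <- sqrt(rowSums(xyz^2))
  if (any(r == 0)) stop("cannot convert the origin to polar angles")
  theta <- .rad2deg(asin(pmin(1, pmax(-1, xyz[, 3] / r))))
  phi <- .rad2deg(atan2(xyz[, 2], xyz[, 1])) %% 360
  data.frame(range_m = r, theta_deg = theta, phi_deg = phi)
}

#' Flag valid scan records
#'
#' A record is valid when its range is finite and within the instrument's
#' measuring limits and its angles are finite. Invalid records are dropped
#' (not clamped) when building clouds and maps.
#'
#' @param records a [ScanRecords-class] object or compatible data.frame.
#' @param config a [ScannerConfig-class].
#' @return logical vector, one element per record.
#' @export
validReturns <- function(records, config) {
  df <- as.data.frame(scanRecords(records))
  is.finite(df$range_m) & is.finite(df$theta_deg) & is.finite(df$phi_deg) &
    df$range_m >= config@range_min & df$range_m <= config@range_max
}

#' Build a Cartesian point cloud from raw scan records
#'
#' Converts every valid record (see [validReturns()]) to a Cartesian point,
#' keeping intensity and the polar back-references that the transect
#' clustering needs. Invalid or out-of-range records are dropped.
#'
#' @param records a [ScanRecords-class] object or compatible data.frame.
#' @param config a [ScannerConfig-class].
#' @return A [PointCloud-class]; errors if no record is valid.
#' @export
buildCloud <- function(records, config = scannerConfig()) {
  df <- as.data.frame(scanRecords(records))
  if (!nrow(df)) stop("no scan records supplied")
  ok <- validReturns(df, config)
  if (!any(ok)) stop("no valid returns: cannot build an empty cloud")
  df <- df[ok, , drop = FALSE]
  xyz <- polarToCartesian(df$range_m, df$theta_deg, df$phi_deg)
  pointCloud(xyz, intensity = df$intensity,
             polar = df[, c("range_m", "theta_deg", "phi_deg")])
}

# Lattice bin centers for a configuration.
.lattice_theta <- function(config) {
  n <- floor(diff(config@fov_theta) / config@delta_theta + 1e-9) + 1
  config@fov_theta[1] + (seq_len(n) - 1) * config@delta_theta
}

.lattice_phi <- function(config) {
  n <- floor(360 / config@delta_phi + 1e-9)
  (seq_len(n) - 1) * config@delta_phi
}

#' Project scan records onto the cylindrical range or intensity map
#'
#' Cells on the scanner's angular lattice hold the range (or intensity) of
#' the record observed in that direction; cells without a return hold `NA`.
#' If two records land in the same cell the nearer return wins (with a
#' warning), mirroring first-return logic.
#'
#' @param records a [ScanRecords-class] object or compatible data.frame.
#' @param config a [ScannerConfig-class] describing the lattice.
#' @param value_kind `"range"` or `"intensity"`.
#' @return A [CylindricalMap-class].
#' @export
buildMap <- function(records, config = scannerConfig(),
                     value_kind = c("range", "intensity")) {
  value_kind <- match.arg(value_kind)
  df <- as.data.frame(scanRecords(records))
  theta_c <- .lattice_theta(config)
  phi_c <- .lattice_phi(config)
  vals <- matrix(NA_real_, length(theta_c), length(phi_c))
  if (nrow(df)) {
    i <- round((df$theta_deg - config@fov_theta[1]) / config@delta_theta) + 1
    j <- round((df$phi_deg %% 360) / config@delta_phi) + 1
    j[j > length(phi_c)] <- 1L  # phi within delta/2 of 360 wraps to bin 1
    keep <- i >= 1 & i <= length(theta_c)
    if (!all(keep)) {
      warning(sum(!keep), " record(s) outside the vertical FOV dropped")
      df <- df[keep, , drop = FALSE]; i <- i[keep]; j <- j[keep]
    }
    # nearest range wins in duplicate cells
    ord <- order(df$range_m)
    cell <- (j[ord] - 1) * length(theta_c) + i[ord]
    dup <- duplicated(cell)
    if (any(dup))
      warning(sum(dup), " duplicate map cell(s); kept the nearest return")
    v <- if (value_kind == "range") df$range_m[ord] else df$intensity[ord]
    vals[cell[!dup]] <- v[!dup]
  }
  new("CylindricalMap", values = vals, theta_centers = theta_c,
      phi_centers = phi_c, kind = value_kind)
}

#' Distance between returns on adjacent rays
#'
#' Law-of-cosines distance between two returns separated by the angular step
#' `delta_angle`: sqrt(Ra^2 + Rb^2 - 2 Ra Rb cos(delta)). This is the
#' expected spacing of lattice-adjacent points used by the transect
#' clustering threshold.
#'
#' @param R_a,R_b slant ranges of the two returns, meters (> 0).
#' @param delta_angle angular separation, degrees.
#' @return distance in meters (vectorized).
#' @examples
#' adjacentDistance(3, 4, 90)  # 5
#' @export
adjacentDistance <- function(R_a, R_b, delta_angle) {
  if (any(R_a <= 0) || any(R_b <= 0)) stop("ranges must be positive")
  d2 <- R_a^2 + R_b^2 - 2 * R_a * R_b * cos(.deg2rad(delta_angle))
  sqrt(pmax(d2, 0))
}

#' Instrument resolution at a given distance
#'
#' Beam footprint (divergence x distance) and vertical point spacing
#' (distance x tan of the vertical step) at a target distance. At 10 m the
#' default configuration gives a 4.7 cm footprint and about 3 cm vertical
#' spacing, which bounds the plot sizes the single-scan method suits.
#'
#' @param config a [ScannerConfig-class].
#' @param distance target distance, meters (> 0 or 0 for the limit).
#' @return list with `footprint` and `vertical_spacing`, meters.
#' @export
resolutionMetrics <- function(config, distance) {
  if (any(distance < 0)) stop("distance must be non-negative")
  list(footprint = config@beam_divergence / 1000 * distance,
       vertical_spacing = distance * tan(.deg2rad(config@delta_theta)))
}
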