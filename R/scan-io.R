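# Readers and writers for the raw-scan CSV dialect and simple point-cloud
# formats (ASCII XYZ and ASCII PLY). Writers use fixed sprintf formats so
# seeded runs are byte-reproducible.

#' Read raw scan records from CSV
#'
#' The raw-scan dialect is a UTF-8 CSV with header
#' `phi_deg,theta_deg,range_m,intensity`, one return per line, '.' decimal
#' separator. Malformed lines raise an error naming the offending line.
#'
#' @param path file path.
#' @return A [ScanRecords-class] object.
#' @export
readScanCSV <- function(path) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), paste(.scan_columns, collapse = ",")))
    stop("bad scan CSV header in ", path, " (line 1): expected '",
         paste(.scan_columns, collapse = ","), "'")
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  for (col in .scan_columns) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (any(is.na(v))) {
      line <- (if (length(bad)) bad[1] else which(is.na(v))[1]) + 1L
      stop("non-numeric value in column '", col, "' of ", path,
           " (line ", line, ")")
    }
    df[[col]] <- v
  }
  scanRecords(df)
}

#' Write raw scan records to CSV
#'
#' @param records a [ScanRecords-class] object or compatible data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScanCSV <- function(records, path) {
  df <- as.data.frame(scanRecords(records))
  lines <- c(paste(.scan_columns, collapse = ","),
             sprintf("%.6f,%.6f,%.6f,%.4f",
                     df$phi_deg, df$theta_deg, df$range_m, df$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Write a point cloud as ASCII XYZ
#'
#' One point per line: `x y z` or `x y z intensity` when the cloud carries
#' intensities.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(cloud, path) {
  xyz <- coords(cloud)
  if (length(intensities(cloud))) {
    lines <- sprintf("%.6f %.6f %.6f %.4f",
                     xyz[, 1], xyz[, 2], xyz[, 3], intensities(cloud))
  } else {
    lines <- sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an ASCII XYZ point cloud
#'
#' @param path file path (3 or 4 whitespace-separated numeric columns).
#' @return A [PointCloud-class].
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  df <- read.table(path, header = FALSE)
  if (ncol(df) < 3) stop("XYZ file must have at least 3 columns: ", path)
  pointCloud(as.matrix(df[, 1:3]),
             intensity = if (ncol(df) >= 4) df[[4]] else numeric())
}

#' Write a point cloud as ASCII PLY
#'
#' Writes vertex elements with `x`, `y`, `z` (and `intensity` when present)
#' as float properties.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePLY <- function(cloud, path) {
  xyz <- coords(cloud)
  has_int <- length(intensities(cloud)) > 0
  header <- c(
    "ply", "format ascii 1.0",
    "comment generated by stemscan",
    sprintf("element vertex %d", nrow(xyz)),
    "property float x", "property float y", "property float z",
    if (has_int) "property float intensity",
    "end_header")
  body <- if (has_int) {
    sprintf("%.6f %.6f %.6f %.4f", xyz[, 1], xyz[, 2], xyz[, 3],
            intensities(cloud))
  } else {
    sprintf("%.6f %.6f %.6f", xyz[, 1], xyz[, 2], xyz[, 3])
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Supports ASCII PLY files with a vertex element whose first properties are
#' `x`, `y`, `z` (an `intensity` property is picked up when present).
#'
#' @param path file path.
#' @return A [PointCloud-class].
#' @export
readPLY <- function(path) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  lines <- readLines(path)
  if (!identical(lines[1], "ply")) stop("not a PLY file: ", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated in ", path)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported: ", path)
  vline <- grep("^element vertex ", header, value = TRUE)
  if (!length(vline)) stop("no vertex element in ", path)
  n <- as.integer(sub("^element vertex ", "", vline[1]))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  body <- lines[end + seq_len(n)]
  df <- read.table(text = body, header = FALSE)
  names(df) <- props[seq_len(ncol(df))]
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  pointCloud(as.matrix(df[, c("x", "y", "z")]),
             intensity = if ("intensity" %in% names(df)) df$intensity
                         else numeric())
}
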