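# Evaluation against reference (tape-measured) tables: one-to-one stem
# matching by position, detection bookkeeping (correct / false / omission),
# and bias/RMSE error statistics with reference-mean-relative percentages.

#' Match estimated to reference stem positions
#'
#' Greedy one-to-one nearest-neighbor matching: candidate pairs closer than
#' `max_dist` are taken in order of increasing distance, each stem used at
#' most once. Unmatched reference stems are omissions, unmatched estimates
#' false detections.
#'
#' @param estimated,reference matrices or data.frames whose first two
#'   columns are plan coordinates (x, y) in meters.
#' @param max_dist matching tolerance, meters (default 0.5, about a third of
#'   the minimum planting spacing).
#' @return list: `pairs` (data.frame `est`, `ref`, `dist`), `n_correct`,
#'   `n_false`, `n_omission`, `n_reference`, `detection_rate`.
#' @export
matchTrees <- function(estimated, reference, max_dist = 0.5) {
  if (max_dist <= 0) stop("max_dist must be positive")
  est <- as.matrix(as.data.frame(estimated)[, 1:2, drop = FALSE])
  ref <- as.matrix(as.data.frame(reference)[, 1:2, drop = FALSE])
  ne <- nrow(est); nr <- nrow(ref)
  pairs <- data.frame(est = integer(), ref = integer(), dist = numeric())
  if (ne && nr) {
    d <- sqrt(outer(est[, 1], ref[, 1], "-")^2 +
              outer(est[, 2], ref[, 2], "-")^2)
    cand <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_e <- logical(ne); used_r <- logical(nr)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_e[i] || used_r[j]) next
        used_e[i] <- TRUE; used_r[j] <- TRUE
        pairs <- rbind(pairs,
                       data.frame(est = i, ref = j, dist = d[i, j]))
      }
    }
  }
  n_correct <- nrow(pairs)
  list(pairs = pairs,
       n_correct = n_correct,
       n_false = ne - n_correct,
       n_omission = nr - n_correct,
       n_reference = nr,
       detection_rate = if (nr) n_correct / nr else NA_real_)
}

#' Bias and RMSE of paired estimates
#'
#' bias = mean(est - ref); rmse = sqrt(mean((est - ref)^2)); the percentage
#' versions are relative to the reference mean (x 100).
#'
#' @param estimates,references paired numeric vectors of equal length >= 1.
#' @return list: `bias`, `bias_pct`, `rmse`, `rmse_pct`, `n`.
#' @export
errorStats <- function(estimates, references) {
  if (!length(estimates) || length(estimates) != length(references))
    stop("estimates and references must be paired and non-empty")
  e <- estimates - references
  rmean <- mean(references)
  list(bias = mean(e),
       bias_pct = 100 * mean(e) / rmean,
       rmse = sqrt(mean(e^2)),
       rmse_pct = 100 * sqrt(mean(e^2)) / rmean,
       n = length(e))
}

#' Per-plot and pooled detection summary
#'
#' Detection rates (correct / reference count) and stem densities from a
#' per-plot bookkeeping table, plus a pooled row over all plots.
#'
#' @param counts data.frame with columns `plot`, `n_trees`, `correct`,
#'   `false`, `omission`.
#' @param plot_area_ha plot area in hectares (0.01 for a 10 m x 10 m plot).
#' @return data.frame with added `detection_rate_pct` and
#'   `stem_density_ha`; the last row (`plot = "pooled"`) pools all plots.
#' @export
detectionSummary <- function(counts, plot_area_ha = 0.01) {
  need <- c("plot", "n_trees", "correct", "false", "omission")
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop("counts table lacks columns: ", paste(missing, collapse = ", "))
  pooled <- data.frame(plot = "pooled",
                       n_trees = sum(counts$n_trees),
                       correct = sum(counts$correct),
                       false = sum(counts$false),
                       omission = sum(counts$omission))
  out <- rbind(data.frame(plot = as.character(counts$plot),
                          counts[need[-1]]), pooled)
  out$detection_rate_pct <- 100 * out$correct / out$n_trees
  area <- c(rep(plot_area_ha, nrow(counts)), plot_area_ha * nrow(counts))
  out$stem_density_ha <- out$n_trees / area
  out
}

# --- reference tables and tree reports -------------------------------------

.reference_columns <- c("id", "x", "y", "dbh_cm", "height_m")

.read_numeric_csv <- function(path, columns, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop(label, " schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in columns) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (length(bad))
      stop(label, " schema error in ", path, ": non-numeric value '",
           df[[col]][bad[1]], "' in column '", col, "' (line ", bad[1] + 1L,
           ")")
    df[[col]] <- v
  }
  df[, columns, drop = FALSE]
}

#' Read or write a reference (tape-measured) tree table
#'
#' CSV schema `id,x,y,dbh_cm,height_m`. The writer rounds to 1e-6, well
#' inside measurement precision, so write/read round trips are lossless at
#' the stated precisions.
#'
#' @param path file path.
#' @return `readReferenceTable`: a data.frame; `writeReferenceTable`:
#'   `path`, invisibly.
#' @export
readReferenceTable <- function(path) {
  .read_numeric_csv(path, .reference_columns, "reference table")
}

#' @rdname readReferenceTable
#' @param table data.frame with the reference schema.
#' @export
writeReferenceTable <- function(table, path) {
  missing <- setdiff(.reference_columns, names(table))
  if (length(missing))
    stop("reference table lacks columns: ", paste(missing, collapse = ", "))
  lines <- c(paste(.reference_columns, collapse = ","),
             sprintf("%d,%.6f,%.6f,%.6f,%.6f", as.integer(table$id),
                     table$x, table$y, table$dbh_cm, table$height_m))
  writeLines(lines, path)
  invisible(path)
}

.report_columns <- c("id", "x_m", "y_m", "dbh_cm", "height_m",
                     "ground_inclination_deg", "flags")

#' Read or write a tree report
#'
#' The pipeline's principal output: CSV schema
#' `id,x_m,y_m,dbh_cm,height_m,ground_inclination_deg,flags`. Positions are
#' written to 0.01 m and DBH to 0.01 cm.
#'
#' @param report a tree report data.frame (from [processPlot()]).
#' @param path file path.
#' @return `readTreeReport`: a data.frame; `writeTreeReport`: `path`,
#'   invisibly.
#' @export
writeTreeReport <- function(report, path) {
  missing <- setdiff(setdiff(.report_columns, "flags"), names(report))
  if (length(missing))
    stop("tree report lacks columns: ", paste(missing, collapse = ", "))
  flags <- if (is.null(report$flags)) rep("", nrow(report)) else report$flags
  num <- function(v, fmt) ifelse(is.finite(v), sprintf(fmt, v), "NA")
  lines <- c(paste(.report_columns, collapse = ","),
             sprintf("%d,%s,%s,%s,%s,%s,%s", as.integer(report$id),
                     num(report$x_m, "%.2f"), num(report$y_m, "%.2f"),
                     num(report$dbh_cm, "%.2f"), num(report$height_m, "%.2f"),
                     num(report$ground_inclination_deg, "%.2f"), flags))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeTreeReport
#' @export
readTreeReport <- function(path) {
  if (!file.exists(path)) stop("tree report not found: ", path)
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(flags = "character"))
  missing <- setdiff(.report_columns, names(df))
  if (length(missing))
    stop("tree report schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

# --- packaged field campaign data ------------------------------------------

#' Field campaign reference data
#'
#' Results of the four-plot plantation field campaign packaged with stemscan:
#' `fieldDetectionCounts()` returns the per-plot trunk-detection bookkeeping
#' (reference tree count, correct, false, omissions) of the four
#' 10 m x 10 m ginkgo plots; `fieldTreePositions()` returns the
#' tape-surveyed and scanner-estimated stem positions (meters, scanner at
#' the origin) of the same campaign.
#'
#' @return a data.frame.
#' @examples
#' detectionSummary(fieldDetectionCounts())
#' @export
fieldDetectionCounts <- function() {
  read.csv(system.file("extdata", "field_detection_counts.csv",
                       package = "stemscan"))
}

#' @rdname fieldDetectionCounts
#' @export
fieldTreePositions <- function() {
  read.csv(system.file("extdata", "field_tree_positions.csv",
                       package = "stemscan"))
}
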