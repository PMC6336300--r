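# Seeded scan simulator: synthetic plantation plots (grid planting with
# vacancies, Gaussian DBH/height, flat/tilted/undulating ground, sparse crown
# elements near the stem tops) scanned by exact first-return ray casting over
# the instrument's angular lattice, with Gaussian range noise and the
# instrument's range limits. Rays are exact geometric intersections (no beam
# width), so the simulator doubles as an analytic oracle for the pipeline.

# run `expr` with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Describe a ground surface
#'
#' Three surface families: `flat` (horizontal plane at `z0`), `tilted`
#' (plane z = z0 + slope_x x + slope_y y), and `undulating`
#' (z = z0 + amplitude sin(2 pi x / wavelength) sin(2 pi y / wavelength)),
#' the last emulating terrain on which single-slice trunk detection breaks
#' down.
#'
#' @param kind `"flat"`, `"tilted"` or `"undulating"`.
#' @param z0 base ground height, meters.
#' @param slope_x,slope_y plane slopes (rise per meter) for `tilted`.
#' @param amplitude,wavelength undulation amplitude and wavelength, meters.
#' @return list describing the surface, with a `height(x, y)` evaluator.
#' @export
groundModel <- function(kind = c("flat", "tilted", "undulating"), z0 = 0,
                        slope_x = 0, slope_y = 0,
                        amplitude = 0.5, wavelength = 8) {
  kind <- match.arg(kind)
  g <- list(kind = kind, z0 = z0)
  if (kind == "tilted") {
    g$slope_x <- slope_x; g$slope_y <- slope_y
  } else if (kind == "undulating") {
    if (amplitude < 0 || wavelength <= 0)
      stop("amplitude must be >= 0 and wavelength > 0")
    g$amplitude <- amplitude; g$wavelength <- wavelength
  }
  g
}

#' Ground height at plan positions
#' @param ground a ground description from [groundModel()].
#' @param x,y plan coordinates, meters (vectorized).
#' @return ground heights, meters.
#' @export
groundHeight <- function(ground, x, y) {
  switch(ground$kind,
    flat = rep(ground$z0, length(x)),
    tilted = ground$z0 + ground$slope_x * x + ground$slope_y * y,
    undulating = ground$z0 + ground$amplitude *
      sin(2 * pi * x / ground$wavelength) * sin(2 * pi * y / ground$wavelength))
}

#' Generate a synthetic plantation plot
#'
#' Stems sit at the interior nodes of a planting grid (`spacing_we` west-east
#' by `spacing_ns` north-south, cells centered in the square plot), each node
#' independently left vacant with probability `vacancy_prob`. DBH and height
#' are drawn from truncated (> 0) normal distributions. One uniform vacancy
#' draw is made per node before any stem attribute is drawn, so raising
#' `vacancy_prob` under a fixed seed only ever removes stems. Sparse crown
#' elements (small spheres) are scattered in the top `crown_top_frac` of each
#' stem to emulate leaf-off branch returns near the tree top.
#'
#' @param extent square plot side, meters (plot centered on the origin).
#' @param spacing_ns,spacing_we planting spacings, meters (north-south is y).
#' @param vacancy_prob per-node probability that the tree is missing.
#' @param dbh_mean,dbh_sd DBH distribution, meters.
#' @param height_mean,height_sd height distribution, meters.
#' @param ground a [groundModel()] description.
#' @param taper linear radius-decay factor per stem (0 = cylinder).
#' @param crown_elements mean number of crown elements per stem (Poisson).
#' @param crown_radius maximal horizontal offset of crown elements, meters.
#' @param crown_top_frac fraction of stem height occupied by the crown.
#' @param element_radius radius of each crown sphere, meters.
#' @param seed integer seed (plots are reproducible given the seed).
#' @return A [SyntheticPlot-class].
#' @examples
#' generatePlot(extent = 10, vacancy_prob = 0, seed = 1)  # 18 stems
#' @export
generatePlot <- function(extent = 10, spacing_ns = 1.6, spacing_we = 2.8,
                         vacancy_prob = 0.05,
                         dbh_mean = 0.1211, dbh_sd = 0.0237,
                         height_mean = 8.43, height_sd = 0.78,
                         ground = groundModel("flat"),
                         taper = 0, crown_elements = 25, crown_radius = 0.5,
                         crown_top_frac = 0.15, element_radius = 0.015,
                         seed = 1L) {
  if (spacing_ns <= 0 || spacing_we <= 0) stop("spacings must be positive")
  if (vacancy_prob < 0 || vacancy_prob > 1)
    stop("vacancy_prob must be in [0, 1]")
  n_we <- floor(extent / spacing_we)
  n_ns <- floor(extent / spacing_ns)
  if (n_we < 1 || n_ns < 1)
    stop("extent smaller than one planting cell")
  xs <- -extent / 2 + spacing_we * (seq_len(n_we) - 0.5)
  ys <- -extent / 2 + spacing_ns * (seq_len(n_ns) - 0.5)
  nodes <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)

  rtruncnorm_pos <- function(n, mean, sd) {
    v <- rnorm(n, mean, sd)
    while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), mean, sd)
    v
  }

  .with_seed(seed, {
    # one vacancy draw per node before any attribute draw, and stem/crown
    # attributes drawn for every node: raising vacancy_prob under the same
    # seed removes stems without perturbing the survivors
    u <- runif(nrow(nodes))
    dbh <- rtruncnorm_pos(nrow(nodes), dbh_mean, dbh_sd)
    hgt <- rtruncnorm_pos(nrow(nodes), height_mean, height_sd)
    all_stems <- data.frame(id = seq_len(nrow(nodes)),
                            x = nodes$x, y = nodes$y,
                            dbh_m = dbh, height_m = hgt,
                            taper = rep(taper, nrow(nodes)))
    crown <- .generate_crown(all_stems, ground, crown_elements, crown_radius,
                             crown_top_frac, element_radius)
    keep <- u >= vacancy_prob
    stems <- all_stems[keep, , drop = FALSE]
    rownames(stems) <- NULL
    crown <- crown[crown$stem_id %in% stems$id, , drop = FALSE]
    rownames(crown) <- NULL
    new("SyntheticPlot", extent = extent, stems = stems, ground = ground,
        crown = crown, seed = as.integer(seed))
  })
}

# crown spheres: uniform in the top fraction of each stem, horizontal offsets
# uniform in a disc of crown_radius, never above the stem top
.generate_crown <- function(stems, ground, crown_elements, crown_radius,
                            crown_top_frac, element_radius) {
  out <- vector("list", nrow(stems))
  for (i in seq_len(nrow(stems))) {
    n <- stats::rpois(1, crown_elements)
    if (n == 0) { out[[i]] <- NULL; next }
    zb <- groundHeight(ground, stems$x[i], stems$y[i])
    zt <- zb + stems$height_m[i]
    rr <- crown_radius * sqrt(runif(n))
    aa <- runif(n, 0, 2 * pi)
    out[[i]] <- data.frame(
      stem_id = stems$id[i],
      x = stems$x[i] + rr * cos(aa),
      y = stems$y[i] + rr * sin(aa),
      z = zt - crown_top_frac * stems$height_m[i] * runif(n),
      radius = element_radius)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(stem_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric())
  out
}

#' Ground-truth reference table of a synthetic plot
#'
#' One row per stem: id, plan position, DBH at 1.3 m above local ground (cm)
#' and total height (m). Serializable with [writeReferenceTable()]. Positions
#' are in the plot frame; subtract the scanner position to compare with
#' estimates from the scan.
#'
#' @param plot a [SyntheticPlot-class].
#' @return data.frame with columns `id`, `x`, `y`, `dbh_cm`, `height_m`.
#' @export
referenceTable <- function(plot) {
  st <- plot@stems
  data.frame(id = st$id, x = st$x, y = st$y,
             dbh_cm = 100 * st$dbh_m, height_m = st$height_m)
}

# --- ray casting helpers ---------------------------------------------------

# smallest positive quadratic root a t^2 + b t + c = 0 satisfying pred(t);
# vectorized; returns Inf where no admissible root exists
.quad_first <- function(a, b, c, pred) {
  disc <- b^2 - 4 * a * c
  t <- rep(Inf, length(a))
  ok <- disc >= 0 & abs(a) > 1e-15
  if (!any(ok)) return(t)
  sq <- sqrt(disc[ok])
  t1 <- (-b[ok] - sq) / (2 * a[ok])
  t2 <- (-b[ok] + sq) / (2 * a[ok])
  lo <- pmin(t1, t2); hi <- pmax(t1, t2)
  cand <- ifelse(lo > 1e-9 & pred(lo, which(ok)), lo,
                 ifelse(hi > 1e-9 & pred(hi, which(ok)), hi, Inf))
  t[ok] <- cand
  t
}

# angular difference in degrees, wrapped to [-180, 180]
.ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# candidate lattice cells whose ray azimuth/elevation windows cover a target;
# returns list(rows, cols0, cols180) index sets. Lattice angles beyond +-90
# (over-zenith / under-nadir sweeps) point at azimuth phi + 180 with the
# reflected elevation.
.cull_cells <- function(theta, phi, az_deg, az_half, el_lo, el_hi) {
  elev <- ifelse(theta > 90, 180 - theta,
                 ifelse(theta < -90, -180 - theta, theta))
  over <- abs(theta) > 90
  rows <- which(elev >= el_lo & elev <= el_hi)
  list(
    rows0 = rows[!over[rows]],
    rows180 = rows[over[rows]],
    cols0 = which(abs(.ang_diff(phi, az_deg)) <= az_half),
    cols180 = which(abs(.ang_diff(phi + 180, az_deg)) <= az_half))
}

#' Simulate a single scan of a synthetic plot
#'
#' Casts one exact ray per lattice direction from the scanner position and
#' records the nearest intersection with any stem (vertical, optionally
#' tapered, cylinder), crown sphere or the ground surface — so occlusion
#' (shadowing) holds by construction. Zero-mean Gaussian range noise with the
#' configuration's 1-sigma accuracy is then added and returns outside the
#' measuring range are dropped. Intensity follows a simple cosine-incidence
#' model (100 x |cos| of the angle between ray and surface normal).
#'
#' Records are expressed in the scanner frame (scanner at the origin): angles
#' on the lattice, ranges along the ray. The ground-truth table stays in the
#' plot frame.
#'
#' @param plot a [SyntheticPlot-class].
#' @param config a [ScannerConfig-class].
#' @param scanner_pos scanner position in the plot frame, `c(x, y, z)`;
#'   default is a 1.5 m tripod at the plot center.
#' @param seed integer seed for the range noise (`NULL` for the current RNG).
#' @param noise logical; set `FALSE` for a noiseless (oracle) scan.
#' @return list with `records` ([ScanRecords-class]), `truth` (the
#'   [referenceTable()]), and `labels` (per-return provenance:
#'   `"ground"`, `"stem"`, or `"crown"`).
#' @export
simulateScan <- function(plot, config = scannerConfig(),
                         scanner_pos = c(0, 0, 1.5), seed = NULL,
                         noise = TRUE) {
  stopifnot(length(scanner_pos) == 3)
  o <- as.numeric(scanner_pos)
  gz <- groundHeight(plot@ground, o[1], o[2])
  if (o[3] <= gz) stop("scanner must be above the local ground")

  theta <- .lattice_theta(config)
  phi <- .lattice_phi(config)
  nt <- length(theta); np <- length(phi)
  ct <- cos(.deg2rad(theta)); st <- sin(.deg2rad(theta))
  cp <- cos(.deg2rad(phi)); sp <- sin(.deg2rad(phi))

  R <- matrix(Inf, nt, np)
  I <- matrix(NA_real_, nt, np)
  lab <- matrix(NA_character_, nt, np)

  half_ext <- plot@extent / 2
  update_cells <- function(idx, t, inten, what) {
    better <- is.finite(t) & t < R[idx]
    if (!any(better)) return(invisible(NULL))
    idx <- idx[better]
    R[idx] <<- t[better]
    I[idx] <<- inten[better]
    lab[idx] <<- what
    invisible(NULL)
  }

  # ground ------------------------------------------------------------------
  g <- plot@ground
  if (g$kind %in% c("flat", "tilted")) {
    sx <- if (g$kind == "tilted") g$slope_x else 0
    sy <- if (g$kind == "tilted") g$slope_y else 0
    nrm <- c(-sx, -sy, 1) / sqrt(sx^2 + sy^2 + 1)
    off <- nrm[3] * g$z0
    # row blocks keep the per-call temporaries small
    for (block in split(seq_len(nt), ceiling(seq_len(nt) / 128))) {
      nb <- length(block)
      ux <- ct[block] %o% cp; uy <- ct[block] %o% sp
      uz <- matrix(st[block], nb, np)
      denom <- nrm[1] * ux + nrm[2] * uy + nrm[3] * uz
      t <- (off - sum(nrm * o)) / denom
      hx <- o[1] + t * ux; hy <- o[2] + t * uy
      valid <- is.finite(t) & t > 1e-9 &
        abs(hx) <= half_ext & abs(hy) <= half_ext
      bidx <- which(valid)
      if (!length(bidx)) next
      rows_glob <- block[(bidx - 1) %% nb + 1]
      cols_glob <- (bidx - 1) %/% nb + 1
      idx <- (cols_glob - 1) * nt + rows_glob
      update_cells(idx, t[bidx], 100 * abs(denom[bidx]), "ground")
    }
  } else {
    # undulating surface: vectorized marching along candidate rays, then
    # bisection refinement; only rays that can reach the surface are marched
    zmax_g <- g$z0 + g$amplitude
    cand_rows <- if (o[3] > zmax_g) which(st < 0) else seq_len(nt)
    if (length(cand_rows)) {
      ux <- ct[cand_rows] %o% cp; uy <- ct[cand_rows] %o% sp
      uz <- matrix(st[cand_rows], length(cand_rows), np)
      f_of <- function(t) o[3] + t * uz -
        groundHeight(g, o[1] + t * ux, o[2] + t * uy)
      t_max <- 2.2 * half_ext / max(min(abs(st[cand_rows])), 1e-3)
      t_max <- min(t_max, config@range_max)
      steps <- seq(0.05, t_max, by = 0.05)
      t_lo <- matrix(NA_real_, length(cand_rows), np)
      prev_f <- f_of(steps[1]); prev_t <- steps[1]
      for (s in steps[-1]) {
        cur_f <- f_of(s)
        cross <- is.na(t_lo) & prev_f > 0 & cur_f <= 0
        t_lo[cross] <- prev_t
        prev_f <- cur_f; prev_t <- s
      }
      hit <- which(!is.na(t_lo))
      if (length(hit)) {
        a <- t_lo[hit]; b <- a + 0.05
        uxh <- ux[hit]; uyh <- uy[hit]; uzh <- uz[hit]
        fa <- o[3] + a * uzh - groundHeight(g, o[1] + a * uxh, o[2] + a * uyh)
        for (k in 1:40) {
          m <- (a + b) / 2
          fm <- o[3] + m * uzh - groundHeight(g, o[1] + m * uxh, o[2] + m * uyh)
          neg <- fm <= 0
          b[neg] <- m[neg]; a[!neg] <- m[!neg]
        }
        t <- (a + b) / 2
        hx <- o[1] + t * uxh; hy <- o[2] + t * uyh
        inside <- abs(hx) <= half_ext & abs(hy) <= half_ext
        # surface normal for intensity
        wl <- g$wavelength; am <- g$amplitude
        dzdx <- am * (2 * pi / wl) * cos(2 * pi * hx / wl) *
          sin(2 * pi * hy / wl)
        dzdy <- am * (2 * pi / wl) * sin(2 * pi * hx / wl) *
          cos(2 * pi * hy / wl)
        nn <- cbind(-dzdx, -dzdy, 1)
        nn <- nn / sqrt(rowSums(nn^2))
        cosi <- abs(nn[, 1] * uxh + nn[, 2] * uyh + nn[, 3] * uzh)
        rows_glob <- cand_rows[(hit - 1) %% length(cand_rows) + 1]
        cols_glob <- (hit - 1) %/% length(cand_rows) + 1
        idx <- (cols_glob - 1) * nt + rows_glob
        update_cells(idx[inside], t[inside], 100 * cosi[inside], "ground")
      }
    }
  }

  # stems (vertical cylinders / cones) --------------------------------------
  pad_az <- 1.5 * config@delta_phi
  pad_el <- 1.5 * config@delta_theta
  for (i in seq_len(nrow(plot@stems))) {
    s <- plot@stems[i, ]
    a <- s$x - o[1]; b <- s$y - o[2]
    d0 <- sqrt(a^2 + b^2)
    zb <- groundHeight(plot@ground, s$x, s$y)
    zt <- zb + s$height_m
    rB <- s$dbh_m / 2
    slope <- s$taper * rB / s$height_m        # radius decrease per meter up
    c0 <- rB - slope * (o[3] - (zb + 1.3))    # radius at the scanner's z
    rmax <- max(rB + slope * 1.3, rB - slope * (s$height_m - 1.3))
    if (d0 <= rmax) next                      # scanner inside the stem
    az <- .rad2deg(atan2(b, a))
    az_half <- .rad2deg(asin(min(1, rmax / d0))) + pad_az
    dn <- max(d0 - rmax, 1e-3); df_ <- d0 + rmax
    el <- .rad2deg(atan2(c(rep(zb - o[3], 2), rep(zt - o[3], 2)),
                         c(dn, df_, dn, df_)))
    cc <- .cull_cells(theta, phi, az, az_half,
                      min(el) - pad_el, max(el) + pad_el)
    for (grp in list(list(rows = cc$rows0, cols = cc$cols0),
                     list(rows = cc$rows180, cols = cc$cols180))) {
      if (!length(grp$rows) || !length(grp$cols)) next
      ii <- rep(grp$rows, times = length(grp$cols))
      jj <- rep(grp$cols, each = length(grp$rows))
      ux <- ct[ii] * cp[jj]; uy <- ct[ii] * sp[jj]; uz <- st[ii]
      c1 <- -slope * uz
      qa <- ux^2 + uy^2 - c1^2
      qb <- -2 * (a * ux + b * uy) - 2 * c0 * c1
      qc <- a^2 + b^2 - c0^2
      pred <- function(t, sub) {
        z <- o[3] + t * uz[sub]
        z >= zb & z <= zt & (c0 + c1[sub] * t) > 0
      }
      t <- .quad_first(qa, qb, qc, pred)
      fin <- which(is.finite(t))
      if (!length(fin)) next
      # radial surface normal for intensity (taper tilt neglected; exact for
      # untapered stems)
      hx <- t[fin] * ux[fin] - a; hy <- t[fin] * uy[fin] - b
      hn <- sqrt(hx^2 + hy^2); hn[hn < 1e-12] <- 1e-12
      cosi <- abs((hx * ux[fin] + hy * uy[fin]) / hn)
      idx <- (jj[fin] - 1) * nt + ii[fin]
      update_cells(idx, t[fin], 100 * cosi, "stem")
    }
  }

  # crown spheres ------------------------------------------------------------
  for (i in seq_len(nrow(plot@crown))) {
    e <- plot@crown[i, ]
    crel <- c(e$x - o[1], e$y - o[2], e$z - o[3])
    d <- sqrt(sum(crel^2))
    if (d <= e$radius) next
    az <- .rad2deg(atan2(crel[2], crel[1]))
    dh <- sqrt(crel[1]^2 + crel[2]^2)
    el <- .rad2deg(atan2(crel[3], dh))
    az_half <- .rad2deg(asin(min(1, e$radius / max(dh, 1e-6)))) + pad_az
    el_half <- .rad2deg(asin(min(1, e$radius / d))) + pad_el
    cc <- .cull_cells(theta, phi, az, az_half, el - el_half, el + el_half)
    for (grp in list(list(rows = cc$rows0, cols = cc$cols0),
                     list(rows = cc$rows180, cols = cc$cols180))) {
      if (!length(grp$rows) || !length(grp$cols)) next
      ii <- rep(grp$rows, times = length(grp$cols))
      jj <- rep(grp$cols, each = length(grp$rows))
      ux <- ct[ii] * cp[jj]; uy <- ct[ii] * sp[jj]; uz <- st[ii]
      qb <- -2 * (ux * crel[1] + uy * crel[2] + uz * crel[3])
      qc <- d^2 - e$radius^2
      t <- .quad_first(rep(1, length(ii)), qb, rep(qc, length(ii)),
                       function(t, sub) rep(TRUE, length(t)))
      fin <- which(is.finite(t))
      if (!length(fin)) next
      nx <- t[fin] * ux[fin] - crel[1]
      ny <- t[fin] * uy[fin] - crel[2]
      nz <- t[fin] * uz[fin] - crel[3]
      nn <- sqrt(nx^2 + ny^2 + nz^2); nn[nn < 1e-12] <- 1e-12
      cosi <- abs((nx * ux[fin] + ny * uy[fin] + nz * uz[fin]) / nn)
      idx <- (jj[fin] - 1) * nt + ii[fin]
      update_cells(idx, t[fin], 100 * cosi, "crown")
    }
  }

  # assemble records ----------------------------------------------------------
  gc(verbose = FALSE)
  hit <- which(is.finite(R))
  rng <- R[hit]
  if (noise && config@range_accuracy_sigma > 0) {
    rng <- .with_seed(seed, rng + rnorm(length(rng),
                                        sd = config@range_accuracy_sigma))
  }
  keep <- rng >= config@range_min & rng <= config@range_max
  hit <- hit[keep]; rng <- rng[keep]
  rows <- (hit - 1) %% nt + 1
  cols <- (hit - 1) %/% nt + 1
  records <- scanRecords(data.frame(
    phi_deg = phi[cols], theta_deg = theta[rows],
    range_m = rng, intensity = I[hit]))
  list(records = records, truth = referenceTable(plot),
       labels = lab[hit])
}
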